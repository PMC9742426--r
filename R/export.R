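# Machine-readable exports: OpenDX density grids, MDHS pseudo-atom PDB,
# and CSV tables for G(r), survival curves and residence times.

#' Write a density grid in OpenDX format
#'
#' The standard map format consumed by VMD/PyMOL; data are written in
#' z-fastest order as OpenDX expects.
#' @param grid a \code{DensityGrid}.
#' @param path output path.
#' @export
write_dx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- grid$shape
  writeLines(c(
    "# bulk-normalized water-oxygen density",
    sprintf("object 1 class gridpositions counts %d %d %d", s[1], s[2], s[3]),
    sprintf("origin %.4f %.4f %.4f",
            grid$origin[1] + grid$step / 2, grid$origin[2] + grid$step / 2,
            grid$origin[3] + grid$step / 2),
    sprintf("delta %.4f 0 0", grid$step),
    sprintf("delta 0 %.4f 0", grid$step),
    sprintf("delta 0 0 %.4f", grid$step),
    sprintf("object 2 class gridconnections counts %d %d %d",
            s[1], s[2], s[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), prod(s))), con)
  # reorder x-fastest -> z-fastest
  arr <- array(grid$values, dim = s)
  v <- as.vector(aperm(arr, c(3, 2, 1)))
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(v))
    writeLines(paste(sprintf("%.6e", v[(n3 + 1):length(v)]), collapse = " "),
               con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Write hydration sites as a pseudo-atom PDB
#'
#' One HETATM per site with the peak density in the B-factor column.
#' @param sites a \code{HydrationSiteTable}.
#' @param path output path.
#' @export
write_sites_pdb <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(sites) > 0)
    writeLines(sprintf(
      "HETATM%5d  O   HOH %5d   %8.3f%8.3f%8.3f  1.00%6.2f           O",
      sites$id, sites$id, sites$x, sites$y, sites$z,
      pmin(99.99, sites$peak_density)), con)
  writeLines("END", con)
  invisible(path)
}

#' Write a surface RDF as CSV
#' @param rdf a \code{SurfaceRDF}.
#' @param path output path.
#' @export
write_rdf_csv <- function(rdf, path) {
  utils::write.csv(data.frame(bin_center = rdf$bin_centers, g = rdf$g,
                              n_samples = rdf$n_samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a survival curve as CSV
#' @param curve a \code{SurvivalCurve}.
#' @param path output path.
#' @export
write_survival_csv <- function(curve, path) {
  utils::write.csv(data.frame(tau_ps = curve$taus, p = curve$p,
                              n_origins = curve$n_origins),
                   path, row.names = FALSE)
  invisible(path)
}
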