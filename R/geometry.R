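# Rigid-body geometry: Kabsch superposition, minimum-image wrapping of
# waters, and nearest-heavy-atom surface distances. All distances in
# Angstrom; boxes are orthorhombic throughout (triclinic input is rejected
# at the I/O boundary).

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping \code{mobile} onto
#' \code{ref}, via SVD of the covariance matrix with the usual
#' determinant correction so the map is a proper rotation.
#'
#' @param mobile,ref \code{n x 3} coordinate matrices (same n).
#' @return list with \code{R} (3x3 rotation), \code{mobile_center},
#'   \code{ref_center}, and \code{rmsd} after superposition.
#' @export
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), ncol(mobile) == 3, ncol(ref) == 3)
  if (nrow(mobile) < 3) stop("degenerate fit: need >= 3 fit atoms")
  mc <- colMeans(mobile)
  rc <- colMeans(ref)
  A <- sweep(mobile, 2, mc)
  B <- sweep(ref, 2, rc)
  # collinearity check: rank of centered reference must exceed 1
  sv <- svd(B)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate fit: fit atoms are collinear")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(R = R, mobile_center = mc, ref_center = rc, rmsd = rmsd)
}

.apply_rigid <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$mobile_center) %*% t(fit$R), 2,
        fit$ref_center, FUN = "+")
}

#' Superpose every frame onto a reference
#'
#' Each frame is rigid-body transformed (Kabsch) so that the RMSD of the
#' fit selection to the reference frame is minimal; the same map is
#' applied to all atoms including waters. The input trajectory is not
#' modified. Box lengths are carried over unchanged (re-imaging after
#' superposition uses the original box lengths; an approximation valid
#' for weak rotations and harmless for bulk-normalized densities).
#'
#' @param traj a Trajectory.
#' @param fit_selection integer atom indices used for fitting (default:
#'   C-alpha atoms).
#' @param reference a \code{Frame} or a frame number (default 1).
#' @return a new, superposed Trajectory; per-frame fit RMSDs in
#'   \code{attr(, "fit_rmsd")}.
#' @export
superpose_frames <- function(traj, fit_selection = NULL, reference = 1L) {
  if (is.null(fit_selection)) fit_selection <- ca_atoms(traj)
  if (length(fit_selection) == 0) stop("degenerate fit: empty fit selection")
  if (any(fit_selection < 1 | fit_selection > n_atoms(traj)))
    stop("fit selection out of range")
  if (length(fit_selection) < 3) stop("degenerate fit: need >= 3 fit atoms")
  ref_coords <- if (inherits(reference, "Frame")) reference$coords
                else traj$coords[, , reference, drop = TRUE]
  ref_sel <- ref_coords[fit_selection, , drop = FALSE]
  out <- traj$coords
  rmsds <- numeric(n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    fr <- traj$coords[, , i, drop = TRUE]
    fit <- kabsch(fr[fit_selection, , drop = FALSE], ref_sel)
    out[, , i] <- .apply_rigid(fr, fit)
    rmsds[i] <- fit$rmsd
  }
  res <- Trajectory(traj$topology, out, traj$box, time = traj$time)
  attr(res, "fit_rmsd") <- rmsds
  res
}

#' Minimum-image wrap of points around a center
#'
#' Maps each point to the periodic image nearest the center under an
#' orthorhombic box.
#' @param points \code{n x 3} matrix.
#' @param center length-3 center.
#' @param box length-3 box lengths.
#' @return wrapped \code{n x 3} matrix.
#' @keywords internal
wrap_points <- function(points, center, box) {
  if (any(box <= 0)) stop("geometry error: box lengths must be > 0")
  d <- sweep(points, 2, center)
  shift <- round(sweep(d, 2, box, FUN = "/"))
  points - sweep(shift, 2, box, FUN = "*")
}

#' Re-image water molecules around the protein
#'
#' Replaces each water molecule by the periodic image whose oxygen is
#' nearest (minimum image) to the geometric center of the protein
#' selection; whole molecules are shifted rigidly by the oxygen's image
#' shift. Protein atoms are untouched.
#'
#' @param frame a \code{Frame}.
#' @param topology the matching \code{hs_topology}.
#' @param protein_selection atom indices defining the protein center
#'   (default: protein heavy atoms).
#' @return a new \code{Frame}.
#' @export
wrap_waters <- function(frame, topology, protein_selection = NULL) {
  if (is.null(protein_selection)) protein_selection <- protein_heavy(topology)
  if (length(protein_selection) == 0) stop("selection error: empty protein selection")
  if (any(frame$box <= 0)) stop("geometry error: box lengths must be > 0")
  center <- colMeans(frame$coords[protein_selection, , drop = FALSE])
  wat_o <- water_oxygens(topology)
  if (length(wat_o) == 0) return(frame)
  coords <- frame$coords
  o_xyz <- coords[wat_o, , drop = FALSE]
  d <- sweep(o_xyz, 2, center)
  shift <- round(sweep(d, 2, frame$box, FUN = "/"))
  shift <- sweep(shift, 2, frame$box, FUN = "*")
  # apply each oxygen's shift to all atoms of its residue
  res_of_o <- topology$residue_index[wat_o]
  wat_atoms <- which(topology$segment == "water")
  pos <- match(topology$residue_index[wat_atoms], res_of_o)
  ok <- !is.na(pos)
  coords[wat_atoms[ok], ] <- coords[wat_atoms[ok], , drop = FALSE] -
    shift[pos[ok], , drop = FALSE]
  structure(list(coords = coords, box = frame$box, time = frame$time),
            class = "Frame")
}

#' Minimum distance from points to a reference atom set
#'
#' Chunked exact nearest-neighbour distance (no periodicity); the
#' workhorse for surface distances.
#' @param points \code{n x 3} matrix (or length-3 vector).
#' @param ref \code{m x 3} matrix of atom centers.
#' @return numeric vector of length n.
#' @keywords internal
min_dist_to_set <- function(points, ref) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(ref) == 0) stop("selection error: empty reference atom set")
  n <- nrow(points)
  ref2 <- rowSums(ref^2)
  out <- numeric(n)
  chunk <- max(1L, as.integer(2e6 / nrow(ref)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    p <- points[i:j, , drop = FALSE]
    d2 <- outer(rowSums(p^2), ref2, "+") - 2 * (p %*% t(ref))
    mi <- max.col(-d2, ties.method = "first")
    out[i:j] <- sqrt(pmax(0, d2[cbind(seq_along(mi), mi)]))
    i <- j + 1L
  }
  out
}

#' Distance from a point to the protein surface
#'
#' The protein surface is operationalized as the set of protein
#' heavy-atom centers: the surface distance of a point is its distance to
#' the nearest protein heavy atom. With \code{metric = "vdw"} the
#' per-element van der Waals radius is subtracted (clamped at zero).
#'
#' @param point length-3 vector or \code{n x 3} matrix of query points.
#' @param frame a \code{Frame}.
#' @param protein_heavy_idx atom indices of protein heavy atoms.
#' @param topology topology (needed for \code{metric = "vdw"}).
#' @param metric \code{"center"} (default) or \code{"vdw"}.
#' @return numeric vector of distances (Angstrom), >= 0.
#' @export
surface_distance <- function(point, frame, protein_heavy_idx,
                             topology = NULL, metric = c("center", "vdw")) {
  metric <- match.arg(metric)
  if (length(protein_heavy_idx) == 0) stop("selection error: empty protein selection")
  ref <- frame$coords[protein_heavy_idx, , drop = FALSE]
  if (metric == "center") return(min_dist_to_set(point, ref))
  if (is.null(topology)) stop("topology required for vdw surface metric")
  radii <- vdw_radius(topology$element[protein_heavy_idx])
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  ref2 <- rowSums(ref^2)
  d2 <- outer(rowSums(point^2), ref2, "+") - 2 * (point %*% t(ref))
  d <- sweep(sqrt(pmax(0, d2)), 2, radii)
  pmax(0, apply(d, 1, min))
}

#' Bondi van der Waals radii by element
#' @param element character vector of element symbols.
#' @return radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}
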