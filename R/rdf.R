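# Surface-referenced radial distribution G(r): water density as a
# function of distance from the protein surface, sampled inside
# cylinders scanned over Euler angles through the protein center of
# mass. Normalized so that the mean over the bulk window (8-10 A) is 1,
# matching the density-grid convention.

#' Cylinder-scanned surface radial distribution function
#'
#' For each orientation (alpha in \code{seq(0, 340, angle_step)},
#' beta in \code{seq(0, 160, angle_step)} degrees) an infinite
#' double-sided cylinder of the given diameter passes through the
#' protein center of mass with axis direction
#' \code{(sin b cos a, sin b sin a, cos b)}. Each water oxygen inside a
#' cylinder contributes its protein-surface distance to a histogram once
#' per containing orientation; the histogram is averaged over frames and
#' orientations and normalized so the mean over \code{bulk_range} bins
#' equals 1. Peaks and the first/second minima are located on a 3-bin
#' moving average of the binned curve.
#'
#' @param traj a superposed \code{Trajectory}.
#' @param diameter cylinder diameter (Angstrom, default 4).
#' @param angle_step Euler angle step (degrees, default 20).
#' @param bin_width histogram bin (Angstrom, default 0.1).
#' @param r_max histogram extent (Angstrom, >= 10; default 12).
#' @param bulk_range normalization window (default \code{c(8, 10)}).
#' @return object of class \code{SurfaceRDF}: \code{bin_centers},
#'   \code{g}, \code{n_samples}, \code{peaks} (data.frame),
#'   \code{first_minimum}, \code{second_minimum}, \code{empty} flag.
#' @export
compute_surface_rdf <- function(traj, diameter = 4, angle_step = 20,
                                bin_width = 0.1, r_max = 12,
                                bulk_range = c(8, 10)) {
  if (bin_width <= 0) stop("parameter error: bin_width must be > 0")
  if (r_max < 10) stop("parameter error: r_max must be >= 10 A (bulk window)")
  prot <- protein_heavy(traj)
  if (length(prot) == 0) stop("selection error: no protein heavy atoms")
  wat <- water_oxygens(traj)

  alpha <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  beta <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  ang <- expand.grid(a = alpha, b = beta)
  U <- cbind(sin(ang$b) * cos(ang$a), sin(ang$b) * sin(ang$a), cos(ang$b))
  R2 <- (diameter / 2)^2

  n_bins <- as.integer(ceiling(r_max / bin_width))
  acc <- numeric(n_bins)
  n_samples <- numeric(n_bins)
  if (length(wat) > 0) {
    for (f in seq_len(n_frames(traj))) {
      fr <- get_frame(traj, f)
      com <- .center_of_mass(fr$coords[prot, , drop = FALSE],
                             traj$topology$mass[prot])
      w <- matrix(fr$coords[wat, ], ncol = 3)
      w <- wrap_points(w, com, fr$box)
      rel <- sweep(w, 2, com)
      d2 <- rowSums(rel^2)
      proj <- rel %*% t(U)
      inside_n <- rowSums(d2 - proj^2 <= R2)   # orientations containing water
      hit <- inside_n > 0
      if (!any(hit)) next
      sd <- min_dist_to_set(w[hit, , drop = FALSE],
                            fr$coords[prot, , drop = FALSE])
      bin <- floor(sd / bin_width) + 1L
      ok <- bin >= 1L & bin <= n_bins
      if (!any(ok)) next
      wts <- inside_n[hit][ok]
      b <- bin[ok]
      acc <- acc + unname(tapply_sum(b, wts, n_bins))
      n_samples <- n_samples + unname(tapply_sum(b, rep(1, length(b)), n_bins))
    }
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  bulk_bins <- centers >= bulk_range[1] & centers <= bulk_range[2]
  bulk_mean <- mean(acc[bulk_bins])
  empty <- !is.finite(bulk_mean) || bulk_mean <= 0
  g <- if (empty) numeric(n_bins) else acc / bulk_mean
  res <- structure(list(bin_centers = centers, g = g, n_samples = n_samples,
                        empty = empty, bulk_range = bulk_range,
                        bin_width = bin_width),
                   class = "SurfaceRDF")
  ext <- .locate_rdf_extrema(centers, g, bulk_range[1])
  res$peaks <- ext$peaks
  res$first_minimum <- ext$first_minimum
  res$second_minimum <- ext$second_minimum
  res
}

# grouped sum via tabulate on weights (fast histogram accumulation)
tapply_sum <- function(bin, w, n_bins) {
  out <- numeric(n_bins)
  s <- rowsum(w, group = bin, reorder = TRUE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.center_of_mass <- function(xyz, mass) {
  colSums(xyz * mass) / sum(mass)
}

# peak/minimum location on a 3-bin moving average, restricted to the
# region below the bulk window
.locate_rdf_extrema <- function(centers, g, r_limit) {
  n <- length(g)
  peaks <- data.frame(position = numeric(0), height = numeric(0))
  out <- list(peaks = peaks, first_minimum = NA_real_,
              second_minimum = NA_real_)
  if (n < 5 || all(g == 0)) return(out)
  sm <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  sm[1] <- g[1]; sm[n] <- g[n]
  sm <- as.numeric(sm)
  region <- which(centers < r_limit)
  is_max <- function(i) i > 1 && i < n && sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]
  maxima <- region[vapply(region, is_max, logical(1))]
  # require peaks to stand above bulk level
  maxima <- maxima[sm[maxima] > 1.05]
  if (length(maxima) == 0) return(out)
  out$peaks <- data.frame(position = centers[maxima], height = g[maxima])
  if (length(maxima) >= 2) {
    seg <- (maxima[1] + 1):(maxima[2] - 1)
    if (length(seg) > 0)
      out$first_minimum <- centers[seg[which.min(sm[seg])]]
    hi <- if (length(maxima) >= 3) maxima[3] - 1 else
      min(n, maxima[2] + as.integer(2 / (centers[2] - centers[1])))
    seg2 <- (maxima[2] + 1):hi
    if (length(seg2) > 0)
      out$second_minimum <- centers[seg2[which.min(sm[seg2])]]
  }
  out
}
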