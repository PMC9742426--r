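# Trajectory-level protein metrics used to establish corresponding
# structural dynamics: per-residue RMSF, backbone N-H order parameters
# S2, radius of gyration, C-alpha RMSD series, and Shrake-Rupley solvent
# accessible surface area.

#' Root-mean-square fluctuations
#'
#' Per atom, the square root of the mean squared deviation from the
#' atom's time-average position over the (already superposed)
#' trajectory; per-residue values average the selected atoms of each
#' residue.
#'
#' @param traj a superposed \code{Trajectory}.
#' @param selection atom indices (default: protein heavy atoms).
#' @param by_residue return per-residue means (default TRUE).
#' @return data.frame with \code{residue_index} (or \code{atom_index})
#'   and \code{rmsf} (Angstrom).
#' @export
compute_rmsf <- function(traj, selection = NULL, by_residue = TRUE) {
  if (is.null(selection)) selection <- protein_heavy(traj)
  stopifnot(length(selection) > 0)
  nf <- n_frames(traj)
  if (nf < 2) warning("single frame: RMSF is identically zero")
  sub <- traj$coords[selection, , , drop = FALSE]
  mean_pos <- apply(sub, c(1, 2), mean)
  dev2 <- (sub - array(mean_pos, dim = dim(sub)))^2
  msf <- apply(dev2, 1, sum) / nf
  rmsf <- sqrt(msf)
  if (!by_residue)
    return(data.frame(atom_index = selection, rmsf = rmsf))
  res <- traj$topology$residue_index[selection]
  agg <- tapply(rmsf, res, mean)
  data.frame(residue_index = as.integer(names(agg)),
             rmsf = as.numeric(agg), row.names = NULL)
}

#' Backbone N-H order parameters S2
#'
#' For each residue's N-H unit vector mu(t), the orientational order
#' parameter from the time-averaged second-rank tensor:
#' \deqn{S^2 = \frac{3}{2}\sum_{a,b} \langle \mu_a \mu_b \rangle^2 - \frac{1}{2}}
#' 1 for a rigid vector, 0 for isotropic reorientation. Values are
#' clamped to [0, 1]; clamping is recorded.
#'
#' @param traj a superposed \code{Trajectory}.
#' @param vector_pairs data.frame with columns \code{residue_index},
#'   \code{n_atom}, \code{h_atom} (atom indices). When NULL, pairs are
#'   resolved from atoms named N and (H|HN) per protein residue;
#'   residues without both atoms are skipped with a warning.
#' @param window optional window length in frames: S2 is computed per
#'   non-overlapping window and averaged, for comparison with
#'   relaxation-timescale order parameters; NULL (default) uses the
#'   full trajectory.
#' @return data.frame: \code{residue_index}, \code{s2}, \code{clamped}.
#' @export
compute_order_parameters <- function(traj, vector_pairs = NULL,
                                     window = NULL) {
  top <- traj$topology
  if (is.null(vector_pairs)) {
    prot_res <- unique(top$residue_index[top$segment == "protein"])
    rows <- lapply(prot_res, function(r) {
      n_i <- which(top$residue_index == r & top$name == "N")
      h_i <- which(top$residue_index == r & top$name %in% c("H", "HN"))
      if (length(n_i) < 1 || length(h_i) < 1) return(NULL)
      data.frame(residue_index = r, n_atom = n_i[1], h_atom = h_i[1])
    })
    miss <- sum(vapply(rows, is.null, logical(1)))
    if (miss > 0)
      warning(sprintf("%d residues lack an N-H pair and were skipped", miss))
    vector_pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(vector_pairs)) stop("no resolvable N-H vectors")
  }
  out <- lapply(seq_len(nrow(vector_pairs)), function(i) {
    n_i <- vector_pairs$n_atom[i]; h_i <- vector_pairs$h_atom[i]
    mu <- t(traj$coords[h_i, , ] - traj$coords[n_i, , ])
    if (n_frames(traj) == 1) mu <- matrix(mu, ncol = 3)
    mu <- mu / sqrt(rowSums(mu^2))
    s2 <- if (is.null(window)) {
      s2_from_vectors(mu)
    } else {
      starts <- seq(1, nrow(mu) - window + 1, by = window)
      mean(vapply(starts, function(s0)
        s2_from_vectors(mu[s0:(s0 + window - 1), , drop = FALSE]),
        numeric(1)))
    }
    clamped <- s2 < 0 || s2 > 1
    data.frame(residue_index = vector_pairs$residue_index[i],
               s2 = min(1, max(0, s2)), clamped = clamped)
  })
  do.call(rbind, out)
}

#' S2 from a matrix of unit vectors
#' @param mu \code{n x 3} matrix of unit vectors.
#' @return the (unclamped) order parameter.
#' @export
s2_from_vectors <- function(mu) {
  xx <- mean(mu[, 1]^2); yy <- mean(mu[, 2]^2); zz <- mean(mu[, 3]^2)
  xy <- mean(mu[, 1] * mu[, 2]); xz <- mean(mu[, 1] * mu[, 3])
  yz <- mean(mu[, 2] * mu[, 3])
  1.5 * (xx^2 + yy^2 + zz^2 + 2 * (xy^2 + xz^2 + yz^2)) - 0.5
}

#' Radius of gyration series
#'
#' Per frame, \code{sqrt(sum m_i |r_i - r_com|^2 / sum m_i)} over the
#' selection (mass-weighted by default).
#'
#' @param traj a \code{Trajectory}.
#' @param selection atom indices (default: protein atoms).
#' @param mass_weighted logical (default TRUE).
#' @return data.frame: \code{time} (ps), \code{rg} (Angstrom).
#' @export
compute_rg <- function(traj, selection = NULL, mass_weighted = TRUE) {
  if (is.null(selection))
    selection <- which(traj$topology$segment == "protein")
  if (length(selection) == 0) stop("parameter error: empty selection")
  m <- if (mass_weighted) traj$topology$mass[selection]
       else rep(1, length(selection))
  if (sum(m) <= 0) stop("parameter error: zero total mass")
  rg <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[selection, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    com <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }, numeric(1))
  data.frame(time = traj$time, rg = rg)
}

#' RMSD series against a reference frame
#'
#' Per frame, Kabsch superposition on \code{fit_selection} followed by
#' RMSD over \code{measure_selection}.
#'
#' @param traj a \code{Trajectory}.
#' @param reference a \code{Frame} or frame number (default 1).
#' @param fit_selection atom indices for fitting (default: C-alpha).
#' @param measure_selection atom indices for the RMSD (default: same as
#'   fit).
#' @return data.frame: \code{time}, \code{rmsd} (Angstrom).
#' @export
compute_rmsd_series <- function(traj, reference = 1L, fit_selection = NULL,
                                measure_selection = NULL) {
  if (is.null(fit_selection)) fit_selection <- ca_atoms(traj)
  if (is.null(measure_selection)) measure_selection <- fit_selection
  ref_coords <- if (inherits(reference, "Frame")) reference$coords
                else traj$coords[, , reference, drop = TRUE]
  ref_fit <- ref_coords[fit_selection, , drop = FALSE]
  ref_meas <- ref_coords[measure_selection, , drop = FALSE]
  rmsd <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- traj$coords[, , f, drop = TRUE]
    fit <- kabsch(fr[fit_selection, , drop = FALSE], ref_fit)
    moved <- .apply_rigid(fr[measure_selection, , drop = FALSE], fit)
    sqrt(mean(rowSums((moved - ref_meas)^2)))
  }, numeric(1))
  data.frame(time = traj$time, rmsd = rmsd)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius \code{r_vdw + probe} is sampled with
#' \code{n_points} quasi-uniform (golden spiral) points; the accessible
#' fraction is the share of points not buried inside any neighbour's
#' expanded sphere, times the sphere area.
#'
#' @param frame a \code{Frame}.
#' @param topology the matching \code{hs_topology}.
#' @param selection atom indices (default: protein heavy atoms).
#' @param radii per-element radii (Angstrom); default Bondi via
#'   \code{\link{vdw_radius}}.
#' @param probe probe radius (Angstrom, default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return list with \code{total_A2}, \code{total_nm2}, and
#'   \code{per_residue} (data.frame: residue_index, sasa_A2).
#' @export
compute_sasa <- function(frame, topology, selection = NULL, radii = NULL,
                         probe = 1.4, n_points = 960) {
  if (is.null(selection)) selection <- protein_heavy(topology)
  stopifnot(length(selection) > 0, probe >= 0, n_points > 0)
  el <- topology$element[selection]
  if (is.null(radii)) {
    r <- vdw_radius(el)
  } else {
    r <- radii[toupper(el)]
    if (any(is.na(r)))
      stop("parameter error: missing radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "))
  }
  xyz <- frame$coords[selection, , drop = FALSE]
  n <- nrow(xyz)
  sph <- .sphere_points(n_points)
  rx <- r + probe
  # neighbour lists from pairwise distances (small systems: dense is fine)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rx[i] + rx)^2 & seq_len(n) != i)
    pts <- sweep(sph * rx[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        # strictly inside a neighbour buries a point; exact boundary
        # ties (coincident spheres) are kept by the lower atom index
        lim <- rx[j]^2 * (1 - 1e-9)
        buried <- dj2 < lim | (dj2 <= rx[j]^2 * (1 + 1e-9) & j < i)
        free <- free & !buried
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    sasa[i] <- frac * 4 * pi * rx[i]^2
  }
  res <- topology$residue_index[selection]
  agg <- tapply(sasa, res, sum)
  list(total_A2 = sum(sasa), total_nm2 = sum(sasa) / 100,
       per_residue = data.frame(residue_index = as.integer(names(agg)),
                                sasa_A2 = as.numeric(agg), row.names = NULL))
}
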