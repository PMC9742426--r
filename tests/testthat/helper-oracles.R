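# Independent oracles and tiny fixture builders. Oracles deliberately
# use different algorithms than the package (quaternion superposition vs
# Kabsch SVD, 27-image enumeration vs minimum-image arithmetic, brute
# double loops vs vectorized paths).

# quaternion (Horn) absolute-orientation oracle: optimal RMSD after
# rigid superposition of mobile onto ref
oracle_quaternion_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# brute-force 27-periodic-image minimum distance of points to a center
oracle_27_image_mindist <- function(points, center, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  apply(points, 1, function(p) {
    min(apply(shifts, 1, function(s)
      sqrt(sum((p + s * box - center)^2))))
  })
}

# exhaustive pairwise minimum distance
oracle_pairwise_min <- function(points, ref) {
  apply(points, 1, function(p)
    min(sqrt(colSums((t(ref) - p)^2))))
}

# rotation matrix about z
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
         nrow = 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# tiny hand-built trajectory: a protein scaffold (given coords) plus
# single-atom waters whose per-frame positions are supplied as a list of
# matrices
make_traj <- function(protein_xyz, water_frames, box = 50, dt = 2,
                      protein_names = NULL, protein_elements = NULL,
                      protein_res = NULL) {
  np <- nrow(protein_xyz)
  nw <- if (length(water_frames) > 0) nrow(water_frames[[1]]) else 0
  nf <- max(1, length(water_frames))
  if (is.null(protein_names)) protein_names <- rep("CA", np)
  if (is.null(protein_elements)) protein_elements <- rep("C", np)
  if (is.null(protein_res)) protein_res <- seq_len(np)
  top <- hs_topology(
    name = c(protein_names, rep("OW", nw)),
    residue_index = c(protein_res, max(protein_res) + seq_len(nw)),
    residue_name = c(rep("GLY", np), rep("SOL", nw)),
    element = c(protein_elements, rep("O", nw)),
    segment = c(rep("protein", np), rep("water", nw)))
  coords <- array(0, dim = c(np + nw, 3, nf))
  for (f in seq_len(nf)) {
    coords[seq_len(np), , f] <- protein_xyz
    if (nw > 0) coords[np + seq_len(nw), , f] <- water_frames[[f]]
  }
  Trajectory(top, coords, box, dt = dt)
}

# occupancy trace built directly from an occupant-id vector
make_trace <- function(occupant, dt = 2, capture_radius = 1.4) {
  structure(list(occupant = as.integer(occupant), dt = dt,
                 capture_radius = capture_radius, site_id = 1L),
            class = "OccupancyTrace")
}

# survival curve built directly (for fit tests)
make_curve <- function(taus, p, n_origins = 1000) {
  structure(list(taus = taus, p = p,
                 n_origins = rep_len(n_origins, length(taus)),
                 n_runs = rep_len(n_origins, length(taus)),
                 mode = "continuous", dt = diff(taus)[1], site_id = 1L),
            class = "SurvivalCurve")
}
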