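# Synthetic water trajectories with planted hydration structure and
# dynamics. The generator is first-class, tested code: it emulates the
# statistical features the analyses must recover (first/second-shell
# enrichment near 1.9 and 2.6 A from the surface, discrete
# high-occupancy sites with exponential dwell times, uniform bulk beyond
# ~8 A, a periodic box) without any physical water model.

#' Describe a planted hydration site
#'
#' A site is a fixed point that is occupied by a water according to a
#' two-state Markov chain: per frame, an occupant leaves with probability
#' \code{dt/dwell_time} (geometric dwell, the discrete analogue of an
#' exponential residence time) and an empty site is re-filled at the rate
#' that makes the stationary occupancy equal \code{occupancy}. While
#' occupied, the occupant water sits uniformly within
#' \code{capture_radius} of the site center; the occupant identity
#' persists across a continuous run and is re-drawn on re-entry.
#'
#' @param position length-3 position (Angstrom, absolute box coordinates).
#' @param dwell_time mean continuous dwell time (ps), > 0.
#' @param occupancy stationary occupancy in (0, 1].
#' @param capture_radius placement/capture radius (Angstrom), > 0.
#' @return list of class \code{PlantedSite}.
#' @export
planted_site <- function(position, dwell_time, occupancy = 0.9,
                         capture_radius = 1.4) {
  stopifnot(length(position) == 3, dwell_time > 0,
            occupancy > 0, occupancy <= 1, capture_radius > 0)
  structure(list(position = as.numeric(position), dwell_time = dwell_time,
                 occupancy = occupancy, capture_radius = capture_radius),
            class = "PlantedSite")
}

#' Specification of a synthetic hydration system
#'
#' @param scaffold list describing the protein-like scaffold:
#'   \code{type} is \code{"single_sphere"} (dummy heavy atoms quasi-uniform
#'   on a sphere of \code{radius}, default 6 A, \code{n_atoms} default 128)
#'   or \code{"bead_chain"} (\code{n_beads} CA beads, default 20, spaced
#'   \code{spacing} = 3.8 A along x); \code{jitter} adds per-frame Gaussian
#'   displacement of that sd (A, default 0 = rigid); \code{element}
#'   defaults to "C".
#' @param n_bulk_waters bulk water count per frame.
#' @param box cubic box length (Angstrom) or length-3 vector.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing (ps).
#' @param sites list of \code{\link{planted_site}}.
#' @param shell_profile optional 2-column matrix/data.frame
#'   \code{(distance A, relative density)} shaping shell enrichment for
#'   the \code{n_shell_waters} extra waters.
#' @param n_shell_waters number of extra shell-enrichment waters per frame.
#' @param exclusion exclusion radius around the scaffold for bulk waters
#'   (A, measured from the scaffold surface for spheres, from atom centers
#'   for chains).
#' @param bulk_mode \code{"iid"} (positions resampled uniformly each
#'   frame; exactly uniform) or \code{"diffusive"} (Gaussian steps of sd
#'   \code{diffusion_step} with periodic wrapping).
#' @param diffusion_step sd of diffusive steps (A/frame).
#' @param seed integer RNG seed; same seed gives a bit-identical system.
#' @return list of class \code{SyntheticSpec}.
#' @export
synthetic_spec <- function(scaffold = list(type = "single_sphere"),
                           n_bulk_waters = 200, box = 40, n_frames = 100,
                           dt = 2, sites = list(), shell_profile = NULL,
                           n_shell_waters = 0, exclusion = 2.5,
                           bulk_mode = c("iid", "diffusive"),
                           diffusion_step = 0.5, seed = 1) {
  bulk_mode <- match.arg(bulk_mode)
  sc <- scaffold
  sc$type <- if (is.null(sc$type)) "single_sphere" else sc$type
  if (sc$type == "single_sphere") {
    if (is.null(sc$radius)) sc$radius <- 6
    if (is.null(sc$n_atoms)) sc$n_atoms <- 128
  } else if (sc$type == "bead_chain") {
    if (is.null(sc$n_beads)) sc$n_beads <- 20
    if (is.null(sc$spacing)) sc$spacing <- 3.8
  } else stop("unknown scaffold type: ", sc$type)
  if (is.null(sc$jitter)) sc$jitter <- 0
  if (is.null(sc$element)) sc$element <- "C"
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(n_frames >= 2, dt > 0, n_bulk_waters >= 0)
  if (inherits(sites, "PlantedSite")) sites <- list(sites)
  spec <- structure(list(scaffold = sc, n_bulk_waters = n_bulk_waters,
                         box = box, n_frames = as.integer(n_frames), dt = dt,
                         sites = sites, shell_profile = shell_profile,
                         n_shell_waters = n_shell_waters,
                         exclusion = exclusion, bulk_mode = bulk_mode,
                         diffusion_step = diffusion_step,
                         seed = as.integer(seed)),
                    class = "SyntheticSpec")
  ext <- .scaffold_extent(spec)
  if (min(box) / 2 < ext + 10)
    stop(sprintf(paste0("geometry error: box too small for a bulk region ",
                        ">= 10 A from the scaffold (need >= %.1f A)"),
                 2 * (ext + 10)))
  spec
}

.scaffold_extent <- function(spec) {
  sc <- spec$scaffold
  if (sc$type == "single_sphere") sc$radius
  else (sc$n_beads - 1) * sc$spacing / 2
}

# quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.scaffold_coords <- function(spec) {
  sc <- spec$scaffold
  center <- spec$box / 2
  if (sc$type == "single_sphere") {
    if (sc$radius == 0 || sc$n_atoms == 1) {
      xyz <- matrix(center, nrow = max(1, sc$n_atoms), ncol = 3, byrow = TRUE)
    } else {
      xyz <- sweep(.sphere_points(sc$n_atoms) * sc$radius, 2, center, "+")
    }
  } else {
    x <- (seq_len(sc$n_beads) - (sc$n_beads + 1) / 2) * sc$spacing
    xyz <- cbind(x + center[1], center[2] + 0 * x, center[3] + 0 * x)
  }
  xyz
}

# uniform points inside the unit ball
.ball_points <- function(n, radius) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  u * r
}

# sample n points uniform in the box but outside the scaffold exclusion
.sample_bulk <- function(n, spec, scaffold_xyz) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  center <- spec$box / 2
  sphere <- spec$scaffold$type == "single_sphere"
  r_excl <- if (sphere) spec$scaffold$radius + spec$exclusion else NA
  out <- matrix(0, nrow = n, ncol = 3)
  got <- 0L
  while (got < n) {
    m <- max(64L, ceiling((n - got) * 1.3))
    p <- cbind(stats::runif(m, 0, spec$box[1]),
               stats::runif(m, 0, spec$box[2]),
               stats::runif(m, 0, spec$box[3]))
    keep <- if (sphere) {
      rowSums(sweep(p, 2, center)^2) > r_excl^2
    } else {
      min_dist_to_set(p, scaffold_xyz) > spec$exclusion
    }
    p <- p[keep, , drop = FALSE]
    take <- min(nrow(p), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- p[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

# simulate one site's occupancy state sequence via run-length sampling:
# alternating geometric occupied/empty runs (memoryless, so starting in
# the stationary state needs no residual-length correction)
.simulate_occupancy_states <- function(n_frames, dt, dwell, occupancy) {
  q <- min(1, dt / dwell)                    # exit prob per step
  if (occupancy >= 1) return(rep(TRUE, n_frames))
  e <- min(1, q * occupancy / (1 - occupancy))  # entry prob per step
  state <- stats::runif(1) < occupancy
  out <- logical(0)
  while (length(out) < n_frames) {
    k <- 64L
    occ_runs <- stats::rgeom(k, q) + 1L
    emp_runs <- stats::rgeom(k, e) + 1L
    runs <- as.vector(rbind(if (state) occ_runs else emp_runs,
                            if (state) emp_runs else occ_runs))
    vals <- rep(c(state, !state), k)
    out <- c(out, rep(vals, runs))
  }
  out[seq_len(n_frames)]
}

#' Generate a synthetic hydration system
#'
#' Deterministic given \code{spec$seed}. Returns the trajectory together
#' with a ground-truth record (site definitions, per-frame occupant
#' identities, bulk number density, shell profile) so analyses can be
#' tested for exact recovery.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{trajectory} (a \code{Trajectory}) and
#'   \code{ground_truth}.
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  nf <- spec$n_frames
  scaffold_xyz <- .scaffold_coords(spec)
  n_sc <- nrow(scaffold_xyz)
  n_sites <- length(spec$sites)
  nw <- spec$n_bulk_waters
  nshell <- spec$n_shell_waters
  if (n_sites > 0 && nw < 2 * n_sites)
    stop("need at least 2 bulk waters per planted site (identity pool)")

  # --- site occupancy and occupant identities ------------------------
  # waters are indexed 1..nw (water-local); each site draws occupants
  # from a dedicated disjoint pool so two sites never claim one water
  occ_id <- matrix(NA_integer_, nrow = nf, ncol = max(1, n_sites))[, seq_len(n_sites), drop = FALSE]
  if (n_sites > 0) {
    pool_size <- max(2L, min(8L, nw %/% n_sites))
    for (s in seq_len(n_sites)) {
      st <- spec$sites[[s]]
      states <- .simulate_occupancy_states(nf, spec$dt, st$dwell_time,
                                           st$occupancy)
      pool <- ((s - 1L) * pool_size + 1L):(s * pool_size)
      r <- rle(states)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ids <- rep(NA_integer_, nf)
      occ_runs <- which(r$values)
      picks <- pool[sample.int(pool_size, length(occ_runs), replace = TRUE)]
      for (j in seq_along(occ_runs)) {
        k <- occ_runs[j]
        ids[starts[k]:ends[k]] <- picks[j]
      }
      occ_id[, s] <- ids
    }
  }

  # --- water coordinates ---------------------------------------------
  coords <- array(0, dim = c(n_sc + nw + nshell, 3, nf))
  wat_rows <- n_sc + seq_len(nw)
  if (spec$bulk_mode == "iid") {
    all_bulk <- .sample_bulk(nw * nf, spec, scaffold_xyz)
    # rows are frame-major blocks of nw waters: reshape in one shot
    coords[wat_rows, , ] <- aperm(array(all_bulk, dim = c(nw, nf, 3)),
                                  c(1, 3, 2))
  } else {
    pos <- .sample_bulk(nw, spec, scaffold_xyz)
    for (f in seq_len(nf)) {
      if (f > 1) {
        pos <- pos + matrix(stats::rnorm(3 * nw, sd = spec$diffusion_step),
                            ncol = 3)
        pos <- pos %% matrix(spec$box, nrow = nw, ncol = 3, byrow = TRUE)
      }
      coords[wat_rows, , f] <- pos
    }
  }
  # overwrite bound waters with in-site placements
  if (n_sites > 0) {
    for (s in seq_len(n_sites)) {
      st <- spec$sites[[s]]
      bound <- which(!is.na(occ_id[, s]))
      if (length(bound) == 0) next
      disp <- .ball_points(length(bound), st$capture_radius)
      p <- sweep(disp, 2, st$position, "+")
      idx <- cbind(rep(n_sc + occ_id[bound, s], 3),
                   rep(1:3, each = length(bound)),
                   rep(bound, 3))
      coords[idx] <- p
    }
  }
  # shell-enrichment waters: placed at planted surface distances along
  # the outward normal of a randomly chosen scaffold atom, so the
  # nearest-atom surface distance equals the planted distance exactly
  if (nshell > 0) {
    if (is.null(spec$shell_profile)) stop("n_shell_waters > 0 needs shell_profile")
    prof <- as.matrix(spec$shell_profile)
    center <- spec$box / 2
    for (f in seq_len(nf)) {
      d <- prof[sample.int(nrow(prof), nshell, replace = TRUE,
                           prob = prof[, 2]), 1]
      a <- sample.int(n_sc, nshell, replace = TRUE)
      if (spec$scaffold$type == "single_sphere" && spec$scaffold$radius > 0) {
        u <- sweep(scaffold_xyz[a, , drop = FALSE], 2, center)
        u <- u / sqrt(rowSums(u^2))
      } else {
        u <- matrix(stats::rnorm(3 * nshell), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
      }
      coords[n_sc + nw + seq_len(nshell), , f] <-
        scaffold_xyz[a, , drop = FALSE] + u * d
    }
  }
  # scaffold (optionally jittered); column-major recycling fills every
  # frame with the same rigid coordinates
  if (spec$scaffold$jitter > 0) {
    for (f in seq_len(nf))
      coords[seq_len(n_sc), , f] <- scaffold_xyz +
        matrix(stats::rnorm(3 * n_sc, sd = spec$scaffold$jitter), ncol = 3)
  } else {
    coords[seq_len(n_sc), , ] <- scaffold_xyz
  }

  # --- topology ------------------------------------------------------
  n_wat_total <- nw + nshell
  top <- hs_topology(
    name = c(rep("CA", n_sc), rep("OW", n_wat_total)),
    residue_index = c(seq_len(n_sc), n_sc + seq_len(n_wat_total)),
    residue_name = c(rep("GLY", n_sc), rep("SOL", n_wat_total)),
    element = c(rep(spec$scaffold$element, n_sc), rep("O", n_wat_total)),
    segment = c(rep("protein", n_sc), rep("water", n_wat_total)))

  traj <- Trajectory(top, coords, spec$box,
                     time = (seq_len(nf) - 1) * spec$dt)

  accessible <- .accessible_volume(spec, scaffold_xyz)
  gt <- list(sites = spec$sites,
             occupancy = occ_id,                # frame x site water ids
             occupant_atom_offset = n_sc,       # atom index = offset + id
             bulk_number_density = nw / accessible,
             accessible_volume = accessible,
             shell_profile = spec$shell_profile,
             spec = spec)
  list(trajectory = traj, ground_truth = gt)
}

.accessible_volume <- function(spec, scaffold_xyz) {
  vbox <- prod(spec$box)
  if (spec$scaffold$type == "single_sphere") {
    vbox - 4 / 3 * pi * (spec$scaffold$radius + spec$exclusion)^3
  } else {
    # Monte-Carlo estimate with a private RNG stream
    n <- 200000L
    st <- .Random.seed
    on.exit(assign(".Random.seed", st, envir = globalenv()))
    set.seed(spec$seed + 7919L)
    p <- cbind(stats::runif(n, 0, spec$box[1]), stats::runif(n, 0, spec$box[2]),
               stats::runif(n, 0, spec$box[3]))
    frac <- mean(min_dist_to_set(p, scaffold_xyz) > spec$exclusion)
    vbox * frac
  }
}

#' Ideal continuous-occupancy survival of a memoryless site
#'
#' Closed form \code{exp(-tau / dwell_time)}: the probability that an
#' exponential dwell of mean \code{dwell_time} survives at least
#' \code{tau}. The analytic reference the survival estimators are tested
#' against.
#'
#' @param dwell_time mean dwell (ps), > 0.
#' @param taus lag times (ps), >= 0.
#' @return survival probabilities.
#' @export
ideal_survival <- function(dwell_time, taus) {
  stopifnot(dwell_time > 0)
  if (any(taus < 0)) stop("domain error: negative lag time")
  exp(-taus / dwell_time)
}
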