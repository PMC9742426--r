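# Water dynamics at hydration sites: occupancy traces, occupancy
# autocorrelation (survival) functions, single-exponential residence
# times with the superstructured-site rule (> 1 ns), shell-wise
# summaries, and protein-water hydrogen-bond lifetimes.

#' Build the occupancy trace of a hydration site
#'
#' Per frame, the occupant is the water oxygen nearest the site center
#' among those within \code{capture_radius} (ties broken toward the
#' lower atom index); frames with no water in range are unoccupied.
#'
#' @param traj a superposed \code{Trajectory}.
#' @param site a length-3 position, or one row of a
#'   \code{HydrationSiteTable}.
#' @param capture_radius capture radius (Angstrom, default 1.4).
#' @param site_id identifier stored on the trace.
#' @return object of class \code{OccupancyTrace}: \code{occupant}
#'   (integer atom index per frame, NA when empty), \code{dt},
#'   \code{capture_radius}, \code{site_id}.
#' @export
build_occupancy_trace <- function(traj, site, capture_radius = 1.4,
                                  site_id = NA_integer_) {
  if (capture_radius <= 0) stop("parameter error: capture_radius must be > 0")
  if (is.data.frame(site)) {
    if (is.na(site_id) && "id" %in% names(site)) site_id <- site$id[1]
    site <- c(site$x[1], site$y[1], site$z[1])
  }
  stopifnot(length(site) == 3)
  wat <- water_oxygens(traj)
  if (length(wat) == 0) stop("empty selection: no water oxygens")
  nf <- n_frames(traj)
  # distance of every water to the site, all frames at once
  dx <- traj$coords[wat, 1, , drop = TRUE] - site[1]
  dy <- traj$coords[wat, 2, , drop = TRUE] - site[2]
  dz <- traj$coords[wat, 3, , drop = TRUE] - site[3]
  d2 <- dx * dx + dy * dy + dz * dz
  if (is.null(dim(d2))) d2 <- matrix(d2, ncol = nf)
  nearest <- max.col(-t(d2), ties.method = "first")  # per frame
  best <- d2[cbind(nearest, seq_len(nf))]
  occ <- ifelse(best <= capture_radius^2, wat[nearest], NA_integer_)
  structure(list(occupant = as.integer(occ), dt = traj$dt,
                 capture_radius = capture_radius, site_id = site_id),
            class = "OccupancyTrace")
}

#' Occupancy autocorrelation (survival) function of a site
#'
#' For each lag tau on the frame grid, time origins are occupied frames
#' with \code{t + tau} inside the trajectory. In \code{intermittent}
#' mode the indicator is 1 when the same water occupies the site at
#' \code{t} and \code{t + tau}; in \code{continuous} mode (default) the
#' same occupant must hold for every frame in between. \code{P(tau)} is
#' the mean indicator over origins, so \code{P(0) = 1}.
#'
#' @param trace an \code{OccupancyTrace}.
#' @param mode \code{"continuous"} or \code{"intermittent"}.
#' @param max_lag maximum lag in ps (default
#'   \code{min(5000, total_time / 5)}).
#' @return object of class \code{SurvivalCurve}: \code{taus} (ps),
#'   \code{p}, \code{n_origins}, \code{n_runs} (continuous mode: number
#'   of independent occupancy runs at least lag long), \code{mode},
#'   \code{dt}.
#' @export
survival_function <- function(trace, mode = c("continuous", "intermittent"),
                              max_lag = NULL) {
  mode <- match.arg(mode)
  occ <- trace$occupant
  n <- length(occ)
  if (n == 0) stop("empty trace")
  occupied <- !is.na(occ)
  if (!any(occupied))
    stop("undefined curve: site is never occupied")
  dt <- trace$dt
  if (is.null(max_lag)) max_lag <- min(5000, (n - 1) * dt / 5)
  K <- max(1L, min(n - 1L, as.integer(floor(max_lag / dt))))
  lags <- 0:K

  occ_pos <- which(occupied)
  # origins(k): occupied frames with t + k <= n
  n_origins <- vapply(lags, function(k) sum(occ_pos <= n - k), numeric(1))

  if (mode == "continuous") {
    r <- rle(ifelse(occupied, occ, -1L))
    L <- r$lengths[r$values > 0]             # continuous occupancy runs
    succ <- vapply(lags, function(k) sum(pmax(0L, L - k)), numeric(1))
    n_runs <- vapply(lags, function(k) sum(L > k), numeric(1))
  } else {
    succ <- c(sum(occupied), vapply(1:K, function(k) {
      a <- occ[1:(n - k)]; b <- occ[(1 + k):n]
      sum(!is.na(a) & !is.na(b) & a == b)
    }, numeric(1)))
    n_runs <- n_origins
  }
  p <- ifelse(n_origins > 0, succ / n_origins, NA_real_)
  structure(list(taus = lags * dt, p = p, n_origins = n_origins,
                 n_runs = n_runs, mode = mode, dt = dt,
                 site_id = trace$site_id),
            class = "SurvivalCurve")
}

#' Fit a single-exponential residence time
#'
#' Least-squares fit of \code{p(tau) = exp(-tau / tau_res)} (amplitude
#' fixed at 1, since \code{P(0) = 1} by construction) to the survival
#' curve, restricted to lags with \code{p >= noise_floor} and at least
#' \code{min_origins} time origins. Sites with residence time above
#' \code{superstructured_threshold} (1 ns) are flagged superstructured.
#' Curves that barely decay (\code{p} at the last usable lag > 0.9) are
#' flagged unreliable and the fitted value is a lower bound.
#'
#' @param curve a \code{SurvivalCurve}.
#' @param noise_floor drop lags with p below this (default 0.01).
#' @param min_origins minimum origins per lag (default 10).
#' @param superstructured_threshold ps (default 1000).
#' @return object of class \code{ResidenceTime}: \code{tau} (ps),
#'   \code{fit_rss}, \code{superstructured}, \code{reliable},
#'   \code{n_points}.
#' @export
fit_residence_time <- function(curve, noise_floor = 0.01, min_origins = 10,
                               superstructured_threshold = 1000) {
  use <- which(curve$taus > 0 & !is.na(curve$p) &
                 curve$p >= noise_floor & curve$n_origins >= min_origins)
  if (length(use) < 5)
    stop("fit error: need >= 5 usable lag points (p above noise floor, ",
         "enough origins)")
  tau_i <- curve$taus[use]
  p_i <- curve$p[use]
  unreliable <- p_i[length(p_i)] > 0.9

  # crude log-linear initial estimate, then 1-parameter least squares
  pos <- p_i > 0
  slope <- stats::coef(stats::lm(log(p_i[pos]) ~ tau_i[pos] - 1))[[1]]
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else max(tau_i) * 10
  sse <- function(lt) {
    m <- exp(-tau_i / exp(lt))
    sum((p_i - m)^2)
  }
  opt <- stats::optimize(sse, interval = log(c(tau0 / 50, tau0 * 50)),
                         tol = 1e-9)
  lt <- opt$minimum
  # polish to full precision: zero of d(SSE)/d(log tau)
  dsse <- function(lt) {
    m <- exp(-tau_i / exp(lt))
    -2 * sum((p_i - m) * m * tau_i / exp(lt))
  }
  lo <- lt - 1e-3; hi <- lt + 1e-3
  if (sign(dsse(lo)) != sign(dsse(hi))) {
    lt <- stats::uniroot(dsse, c(lo, hi), tol = 1e-14)$root
  }
  tau <- exp(lt)
  opt <- list(objective = sse(lt))
  structure(list(tau = tau, fit_rss = opt$objective,
                 superstructured = tau > superstructured_threshold,
                 reliable = !unreliable, n_points = length(use),
                 site_id = curve$site_id),
            class = "ResidenceTime")
}

#' Shell-wise residence-time summary
#'
#' Mean and sd of residence times per shell, excluding superstructured
#' sites (residence time above the threshold) from the averages; the
#' exclusion count is reported per shell, and the raw per-site table is
#' retained.
#'
#' @param times list of \code{ResidenceTime} (or numeric taus).
#' @param shells shell label per site.
#' @param threshold superstructured threshold in ps (default 1000).
#' @return list with \code{summary} (data.frame: shell, mean, sd, n,
#'   n_excluded) and \code{sites} (per-site data.frame).
#' @export
shell_residence_summary <- function(times, shells, threshold = 1000) {
  taus <- if (is.list(times)) vapply(times, function(t) t$tau, numeric(1))
          else as.numeric(times)
  stopifnot(length(taus) == length(shells))
  super <- taus > threshold
  sites <- data.frame(shell = shells, tau = taus, superstructured = super,
                      stringsAsFactors = FALSE)
  lv <- c("first", "second", "outer")
  lv <- c(lv[lv %in% shells], setdiff(unique(shells), lv))
  rows <- lapply(lv, function(sh) {
    in_sh <- shells == sh
    keep <- in_sh & !super
    data.frame(shell = sh,
               mean = if (any(keep)) mean(taus[keep]) else NA_real_,
               sd = if (sum(keep) > 1) stats::sd(taus[keep]) else NA_real_,
               n = sum(keep), n_excluded = sum(in_sh & super),
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), sites = sites)
}

#' Protein-water hydrogen-bond lifetimes
#'
#' An H-bond exists in a frame when the donor-acceptor heavy-atom
#' distance is at most \code{dist_cutoff} and, when hydrogens are
#' available on the donor, the donor-H...acceptor angle is at least
#' \code{angle_cutoff}. Without hydrogens the distance criterion alone
#' is used and the result is flagged \code{geometric_only}. Continuous
#' bonded runs of a protein-polar-atom/water pair define events; an
#' event spanning L frames lasts \code{(L - 1) * dt}, and single-frame
#' events are discarded. The overall mean is weighted by event count.
#'
#' @param traj a \code{Trajectory}.
#' @param dist_cutoff heavy-atom distance cutoff (Angstrom, default 3.5).
#' @param angle_cutoff D-H...A angle cutoff (degrees, default 150).
#' @return list with \code{pairs} (data.frame: protein atom, water atom,
#'   mean lifetime ps, n_events), \code{overall_mean} (ps),
#'   \code{n_events}, \code{geometric_only}.
#' @export
hbond_lifetimes <- function(traj, dist_cutoff = 3.5, angle_cutoff = 150) {
  top <- traj$topology
  polar <- which(top$segment == "protein" & top$element %in% c("N", "O"))
  if (length(polar) == 0)
    stop("selection error: no protein N/O atoms for hydrogen bonding")
  wat <- water_oxygens(traj)
  if (length(wat) == 0) stop("empty selection: no water oxygens")
  h_idx <- which(top$segment == "protein" & top$is_hydrogen)
  geometric_only <- length(h_idx) == 0
  nf <- n_frames(traj)
  cut2 <- dist_cutoff^2
  cosmax <- cos(angle_cutoff * pi / 180)

  # attach each protein hydrogen to its nearest polar atom (frame 1)
  donors_h <- NULL
  if (!geometric_only) {
    ref <- traj$coords[, , 1, drop = TRUE]
    hp <- ref[h_idx, , drop = FALSE]
    pp <- ref[polar, , drop = FALSE]
    d2 <- outer(rowSums(hp^2), rowSums(pp^2), "+") - 2 * (hp %*% t(pp))
    owner <- max.col(-d2, ties.method = "first")
    close <- d2[cbind(seq_along(owner), owner)] <= 1.3^2
    donors_h <- data.frame(h = h_idx[close], polar = polar[owner[close]])
  }

  bonded <- matrix(FALSE, nrow = length(polar) * length(wat), ncol = nf)
  for (f in seq_len(nf)) {
    fr <- wrap_waters(get_frame(traj, f), top)
    p <- fr$coords[polar, , drop = FALSE]
    w <- matrix(fr$coords[wat, ], ncol = 3)
    d2 <- outer(rowSums(p^2), rowSums(w^2), "+") - 2 * (p %*% t(w))
    ok <- d2 <= cut2
    if (!geometric_only && any(ok)) {
      idx <- which(ok, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        pa <- polar[idx[r, 1]]
        hs <- donors_h$h[donors_h$polar == pa]
        if (length(hs) == 0) next  # acceptor-only contact: keep distance rule
        dvec <- fr$coords[pa, ]
        avec <- w[idx[r, 2], ]
        good <- FALSE
        for (h in hs) {
          hv <- fr$coords[h, ]
          v1 <- dvec - hv; v2 <- avec - hv
          ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          if (ca <= cosmax) { good <- TRUE; break }
        }
        if (!good) ok[idx[r, 1], idx[r, 2]] <- FALSE
      }
    }
    bonded[, f] <- as.vector(ok)
  }

  active <- which(rowSums(bonded) > 0)
  res <- lapply(active, function(rid) {
    r <- rle(bonded[rid, ])
    L <- r$lengths[r$values]
    L <- L[L >= 2]
    if (length(L) == 0) return(NULL)
    data.frame(protein_atom = polar[(rid - 1) %% length(polar) + 1],
               water_atom = wat[(rid - 1) %/% length(polar) + 1],
               mean_lifetime = mean((L - 1) * traj$dt), n_events = length(L))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(protein_atom = integer(0),
                                      water_atom = integer(0),
                                      mean_lifetime = numeric(0),
                                      n_events = integer(0))
  total_events <- sum(res$n_events)
  overall <- if (total_events > 0)
    sum(res$mean_lifetime * res$n_events) / total_events else NA_real_
  list(pairs = res, overall_mean = overall, n_events = total_events,
       geometric_only = geometric_only)
}
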