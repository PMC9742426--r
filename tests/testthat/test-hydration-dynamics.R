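# occupancy traces, survival functions, residence-time fits, shell
# summaries, hydrogen-bond lifetimes

test_that("occupancy traces track the nearest in-range water", {
  prot <- matrix(15, 1, 3)
  site <- c(18, 15, 15)
  # two waters alternately closest to the site
  frames <- lapply(1:6, function(f) {
    if (f %% 2 == 1) rbind(site + c(0.2, 0, 0), site + c(0.8, 0, 0))
    else rbind(site + c(0.9, 0, 0), site + c(0.1, 0, 0))
  })
  tr <- make_traj(prot, frames, box = 30)
  trace <- build_occupancy_trace(tr, site, capture_radius = 1.4)
  w1 <- 2L; w2 <- 3L  # atom indices of the two waters
  expect_equal(trace$occupant, rep(c(w1, w2), 3))
  # brute-force nearest-in-range oracle
  oracle <- vapply(1:6, function(f) {
    d <- sqrt(rowSums(sweep(frames[[f]], 2, site)^2))
    inr <- which(d <= 1.4)
    if (length(inr) == 0) NA_integer_ else 1L + inr[which.min(d[inr])]
  }, integer(1))
  expect_equal(trace$occupant, oracle)
  # no water ever in range -> all-NA trace, survival errors
  far <- make_traj(prot, lapply(1:4, function(f) matrix(25, 1, 3)),
                   box = 30)
  tfar <- build_occupancy_trace(far, site)
  expect_true(all(is.na(tfar$occupant)))
  expect_error(survival_function(tfar), "never occupied")
  expect_error(build_occupancy_trace(tr, site, capture_radius = 0),
               "parameter")
})

test_that("survival endpoints: frozen occupant and perfect turnover", {
  frozen <- make_trace(rep(5L, 100))
  for (m in c("continuous", "intermittent")) {
    s <- survival_function(frozen, mode = m)
    expect_equal(s$p[1], 1)
    expect_true(all(s$p == 1))
  }
  turnover <- make_trace(seq_len(100))  # new water every frame
  for (m in c("continuous", "intermittent")) {
    s <- survival_function(turnover, mode = m)
    expect_equal(s$p[1], 1)
    expect_true(all(s$p[-1] == 0))
  }
})

test_that("Markov-site survival matches the geometric closed form", {
  dwell <- 50; dt <- 2
  spec <- synthetic_spec(
    n_bulk_waters = 12, box = 36, n_frames = 50000, dt = dt,
    sites = list(planted_site(c(18, 18, 25.8), dwell_time = dwell,
                              occupancy = 0.6, capture_radius = 1.0)),
    seed = 7)
  sys <- generate_system(spec)
  trace <- build_occupancy_trace(sys$trajectory, c(18, 18, 25.8),
                                 capture_radius = 1.0)
  s <- survival_function(trace, mode = "continuous", max_lag = 150)
  q <- dt / dwell
  k <- s$taus / dt
  expected <- (1 - q)^k
  # binomial error with n = independent occupancy runs at each lag
  sig <- sqrt(pmax(expected * (1 - expected), 1e-12) / pmax(s$n_runs, 1))
  expect_true(all(abs(s$p - expected) <= 3 * sig + 0.01))
})

test_that("continuous survival <= intermittent pointwise, strict on re-entry", {
  set.seed(19)
  strict_seen <- FALSE
  for (seed in 1:6) {
    spec <- synthetic_spec(
      n_bulk_waters = 8, box = 36, n_frames = 4000, dt = 2,
      sites = list(planted_site(c(18, 18, 25.8), dwell_time = 30,
                                occupancy = 0.7, capture_radius = 1.0)),
      seed = seed)
    trace <- build_occupancy_trace(generate_system(spec)$trajectory,
                                   c(18, 18, 25.8), capture_radius = 1.0)
    sc <- survival_function(trace, "continuous", max_lag = 200)
    si <- survival_function(trace, "intermittent", max_lag = 200)
    expect_true(all(sc$p <= si$p + 1e-12))
    if (any(si$p > sc$p + 1e-12)) strict_seen <- TRUE
  }
  expect_true(strict_seen)
})

test_that("exponential fit is exact on a noiseless curve", {
  taus <- seq(0, 490, by = 10)
  cv <- make_curve(taus, exp(-taus / 100))
  ft <- fit_residence_time(cv)
  expect_equal(ft$tau, 100, tolerance = 1e-8)
  expect_false(ft$superstructured)
  # superstructured threshold rule
  cv2 <- make_curve(seq(0, 4900, by = 100), exp(-seq(0, 4900, by = 100) / 2000))
  ft2 <- fit_residence_time(cv2)
  expect_equal(ft2$tau, 2000, tolerance = 1e-6)
  expect_true(ft2$superstructured)
  # scale equivariance: scaling lags scales tau
  cv3 <- make_curve(taus * 3, exp(-taus / 100))
  expect_equal(fit_residence_time(cv3)$tau, 300, tolerance = 1e-6)
  # non-decaying curve flagged unreliable
  cv4 <- make_curve(taus, exp(-taus / 1e7))
  expect_false(fit_residence_time(cv4)$reliable)
})

test_that("planted dwell is recovered through the full pipeline path", {
  errs <- vapply(1:5, function(seed) {
    spec <- synthetic_spec(
      n_bulk_waters = 8, box = 36, n_frames = 50000, dt = 2,
      sites = list(planted_site(c(18, 18, 25.8), dwell_time = 80,
                                occupancy = 0.8, capture_radius = 1.0)),
      seed = 100 + seed)
    trace <- build_occupancy_trace(generate_system(spec)$trajectory,
                                   c(18, 18, 25.8), capture_radius = 1.0)
    ft <- fit_residence_time(survival_function(trace, max_lag = 400))
    abs(ft$tau - 80) / 80
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("tau bias shrinks with trajectory length", {
  med_err <- vapply(c(2000, 10000, 50000), function(nf) {
    errs <- vapply(1:5, function(seed) {
      spec <- synthetic_spec(
        n_bulk_waters = 8, box = 36, n_frames = nf, dt = 2,
        sites = list(planted_site(c(18, 18, 25.8), dwell_time = 60,
                                  occupancy = 0.8, capture_radius = 1.0)),
        seed = 500 + seed)
      trace <- build_occupancy_trace(generate_system(spec)$trajectory,
                                     c(18, 18, 25.8), capture_radius = 1.0)
      ft <- fit_residence_time(survival_function(trace, max_lag = 300))
      abs(ft$tau - 60)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[3], med_err[1])
})

test_that("shell summary applies the superstructured exclusion", {
  s <- shell_residence_summary(c(50, 60, 70), rep("first", 3))
  row <- s$summary[s$summary$shell == "first", ]
  expect_equal(row$mean, 60)
  expect_equal(row$sd, 10)
  expect_equal(row$n_excluded, 0)
  # a 4000 ps site is excluded and leaves the mean unchanged
  s2 <- shell_residence_summary(c(50, 60, 70, 4000), rep("first", 4))
  row2 <- s2$summary[s2$summary$shell == "first", ]
  expect_equal(row2$mean, 60)
  expect_equal(row2$n_excluded, 1)
  # empty shell -> n = 0 row, no crash
  s3 <- shell_residence_summary(c(50, 4000), c("first", "second"))
  row3 <- s3$summary[s3$summary$shell == "second", ]
  expect_equal(row3$n, 0)
  expect_equal(row3$n_excluded, 1)
  expect_true(is.na(row3$mean))
  # recomputation oracle on a mixed population
  set.seed(3)
  taus <- c(runif(20, 10, 500), runif(5, 1500, 5000))
  shells <- sample(c("first", "second"), 25, replace = TRUE)
  s4 <- shell_residence_summary(taus, shells)
  for (sh in c("first", "second")) {
    keep <- shells == sh & taus <= 1000
    expect_equal(s4$summary$mean[s4$summary$shell == sh],
                 if (any(keep)) mean(taus[keep]) else NA_real_)
  }
})

test_that("hydrogen-bond event bookkeeping follows the cutoff rules", {
  prot <- matrix(15, 1, 3)
  # water bonded (3.0 A) in all 10 frames -> one event of 9*dt
  tr1 <- make_traj(prot, lapply(1:10, function(f)
    matrix(c(18, 15, 15), 1, 3)), box = 30, protein_elements = "N",
    protein_names = "N")
  hb1 <- hbond_lifetimes(tr1)
  expect_equal(hb1$pairs$mean_lifetime, 9 * 2)
  expect_equal(hb1$n_events, 1)
  expect_true(hb1$geometric_only)
  # 3.6 A -> no event at the 3.5 A cutoff
  tr2 <- make_traj(prot, lapply(1:10, function(f)
    matrix(c(18.6, 15, 15), 1, 3)), box = 30, protein_elements = "N",
    protein_names = "N")
  expect_equal(hbond_lifetimes(tr2)$n_events, 0)
  # carbon-only protein -> selection error
  tr3 <- make_traj(prot, list(matrix(c(18, 15, 15), 1, 3)), box = 30)
  expect_error(hbond_lifetimes(tr3), "selection error")
})

test_that("hbond angle criterion filters bent geometries", {
  # donor N at origin-ish with H pointing +x; acceptor along +x passes,
  # acceptor perpendicular fails
  prot <- rbind(c(15, 15, 15), c(16, 15, 15))      # N and its H
  straight <- lapply(1:6, function(f) matrix(c(18, 15, 15), 1, 3))
  bent <- lapply(1:6, function(f) matrix(c(15, 17.5, 15), 1, 3))
  mk <- function(wf) make_traj(prot, wf, box = 30,
                               protein_names = c("N", "H"),
                               protein_elements = c("N", "H"),
                               protein_res = c(1, 1))
  expect_equal(hbond_lifetimes(mk(straight))$n_events, 1)
  expect_false(hbond_lifetimes(mk(straight))$geometric_only)
  expect_equal(hbond_lifetimes(mk(bent))$n_events, 0)
})

test_that("a sticky partner's H-bond lifetime matches the planted dwell", {
  errs <- vapply(1:6, function(seed) {
    # single polar atom at the center of a radius-0 scaffold; the site
    # sits 3.0 A away with a tight capture radius, so bonded runs are
    # exactly the occupancy runs
    spec <- synthetic_spec(
      scaffold = list(type = "single_sphere", radius = 0, n_atoms = 1,
                      element = "N"),
      n_bulk_waters = 8, box = 36, n_frames = 20000, dt = 2,
      sites = list(planted_site(c(21, 18, 18), dwell_time = 100,
                                occupancy = 0.5, capture_radius = 0.3)),
      exclusion = 4.5, seed = 900 + seed)
    tr <- generate_system(spec)$trajectory
    hb <- hbond_lifetimes(tr)
    abs(hb$overall_mean - 100) / 100
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})
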