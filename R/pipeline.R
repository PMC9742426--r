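# Pipeline orchestration: a frozen config schema whose defaults are the
# published analysis parameters, a staged end-to-end driver
# (superpose -> density -> MDHS -> G(r) -> shells -> residence ->
# contacts -> H-bonds -> protein metrics), deterministic JSON reports,
# and a two-system comparison.

.REPORT_SCHEMA <- "hydrashell-report/1"

#' Analysis configuration
#'
#' Defaults are the published analysis parameters: 0.5 A grid, 8-10 A
#' bulk shell, MDHS threshold 2.0x bulk with 1.4 A (0.14 nm) radius,
#' 4 A cylinder scanned at 20 degrees, 1 ns superstructured threshold.
#'
#' @param grid_step density grid spacing (A).
#' @param grid_padding grid extent beyond the protein bounding box (A).
#' @param bulk_shell bulk normalization window (A).
#' @param min_density MDHS density threshold (bulk units).
#' @param site_radius MDHS local-max/exclusion radius (A).
#' @param cylinder_diameter G(r) cylinder diameter (A).
#' @param angle_step Euler scan step (degrees).
#' @param rdf_bin_width G(r) bin width (A).
#' @param rdf_r_max G(r) extent (A).
#' @param capture_radius occupancy capture radius (A).
#' @param survival_mode \code{"continuous"} or \code{"intermittent"}.
#' @param max_lag survival max lag (ps; NULL = auto).
#' @param superstructured_threshold ps.
#' @param contact_cutoff residue-water contact cutoff (A).
#' @param hbond_dist,hbond_angle H-bond criteria (A, degrees).
#' @param surface_metric \code{"center"} or \code{"vdw"}.
#' @param compute_hbonds logical; H-bond stage is opt-in (quadratic in
#'   pair count).
#' @param seed integer seed recorded for provenance.
#' @return list of class \code{AnalysisConfig}.
#' @export
analysis_config <- function(grid_step = 0.5, grid_padding = 12,
                            bulk_shell = c(8, 10), min_density = 2.0,
                            site_radius = 1.4, cylinder_diameter = 4.0,
                            angle_step = 20, rdf_bin_width = 0.1,
                            rdf_r_max = 12, capture_radius = 1.4,
                            survival_mode = "continuous", max_lag = NULL,
                            superstructured_threshold = 1000,
                            contact_cutoff = 3.5, hbond_dist = 3.5,
                            hbond_angle = 150, surface_metric = "center",
                            compute_hbonds = FALSE, seed = 1) {
  cfg <- list(grid_step = grid_step, grid_padding = grid_padding,
              bulk_shell = bulk_shell, min_density = min_density,
              site_radius = site_radius,
              cylinder_diameter = cylinder_diameter,
              angle_step = angle_step, rdf_bin_width = rdf_bin_width,
              rdf_r_max = rdf_r_max, capture_radius = capture_radius,
              survival_mode = survival_mode, max_lag = max_lag,
              superstructured_threshold = superstructured_threshold,
              contact_cutoff = contact_cutoff, hbond_dist = hbond_dist,
              hbond_angle = hbond_angle, surface_metric = surface_metric,
              compute_hbonds = compute_hbonds, seed = seed)
  stopifnot(grid_step > 0, site_radius > 0, min_density > 0,
            bulk_shell[1] < bulk_shell[2], capture_radius > 0,
            superstructured_threshold > 0)
  class(cfg) <- c("AnalysisConfig", "list")
  cfg
}

#' Read an analysis config from JSON (or YAML when available)
#' @param path config file; keys as in \code{\link{analysis_config}}.
#' @return an \code{AnalysisConfig}.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, lst)
}

# stable 64-bit-ish FNV-1a hash of the canonical config JSON, for
# provenance without a digest dependency
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 10,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full hydration analysis
#'
#' Stage order: superpose (C-alpha) -> density grid -> surface G(r) ->
#' MDHS detection + shell classification -> per-site occupancy, survival
#' and residence fits -> shell residence summary -> residue-water
#' contacts -> optional H-bond lifetimes -> protein metrics (RMSF, Rg,
#' RMSD series, SASA; S2 when N-H pairs exist). Deterministic: identical
#' inputs and config give byte-identical JSON reports.
#'
#' @param traj a \code{Trajectory} (or list of paths:
#'   \code{list(topology=, coords=)}).
#' @param config an \code{\link{analysis_config}}.
#' @param out_dir optional output directory for report.json, CSV tables,
#'   the OpenDX density map and the MDHS pseudo-atom PDB.
#' @return the report (list), invisibly written to
#'   \code{out_dir/report.json} when requested.
#' @export
run_analysis <- function(traj, config = analysis_config(), out_dir = NULL) {
  warnings_log <- character(0)
  note <- function(stage, w) {
    warnings_log <<- c(warnings_log, paste0(stage, ": ", w))
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        note(name, conditionMessage(w)); invokeRestart("muffleWarning")
      })
  }
  if (!inherits(traj, "Trajectory")) {
    traj <- stage("read", read_trajectory(traj$topology, traj$coords))
  }
  sup <- stage("superpose", superpose_frames(traj))
  grid <- stage("density", compute_density_grid(
    sup, step = config$grid_step, padding = config$grid_padding,
    bulk_range = config$bulk_shell, surface_metric = config$surface_metric))
  rdf <- stage("rdf", compute_surface_rdf(
    sup, diameter = config$cylinder_diameter,
    angle_step = config$angle_step, bin_width = config$rdf_bin_width,
    r_max = config$rdf_r_max, bulk_range = config$bulk_shell))
  sites <- stage("sites", detect_hydration_sites(
    grid, min_density = config$min_density, radius = config$site_radius,
    rdf = rdf))

  residence <- list(); curves <- list()
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      tr <- stage("occupancy", build_occupancy_trace(
        sup, sites[i, ], capture_radius = config$capture_radius))
      cv <- try(survival_function(tr, mode = config$survival_mode,
                                  max_lag = config$max_lag), silent = TRUE)
      if (inherits(cv, "try-error")) {
        note("survival", sprintf("site %d never occupied", sites$id[i]))
        next
      }
      ft <- try(fit_residence_time(
        cv, superstructured_threshold = config$superstructured_threshold),
        silent = TRUE)
      if (inherits(ft, "try-error")) {
        note("residence", sprintf("site %d: unfittable curve", sites$id[i]))
        next
      }
      curves[[length(curves) + 1]] <- cv
      residence[[length(residence) + 1]] <-
        list(site = sites$id[i], shell = sites$shell[i], fit = ft)
    }
  }
  shell_summary <- if (length(residence) > 0) {
    shell_residence_summary(
      lapply(residence, function(r) r$fit),
      vapply(residence, function(r) r$shell, character(1)),
      threshold = config$superstructured_threshold)
  } else list(summary = data.frame(), sites = data.frame())

  contacts <- stage("contacts", residue_water_contacts(
    sup, cutoff = config$contact_cutoff))
  hb <- if (isTRUE(config$compute_hbonds))
    stage("hbonds", hbond_lifetimes(sup, dist_cutoff = config$hbond_dist,
                                    angle_cutoff = config$hbond_angle))
    else NULL
  rmsf <- stage("rmsf", compute_rmsf(sup))
  rg <- stage("rg", compute_rg(sup))
  rmsd <- stage("rmsd", compute_rmsd_series(sup))
  sasa <- stage("sasa", compute_sasa(get_frame(sup, 1), sup$topology))
  s2 <- tryCatch(suppressWarnings(compute_order_parameters(sup)),
                 error = function(e) {
                   note("s2", "no resolvable N-H vectors; S2 skipped")
                   NULL
                 })

  per_site <- if (length(residence) > 0) data.frame(
    site = vapply(residence, function(r) r$site, numeric(1)),
    shell = vapply(residence, function(r) r$shell, character(1)),
    tau_ps = vapply(residence, function(r) r$fit$tau, numeric(1)),
    superstructured = vapply(residence, function(r) r$fit$superstructured,
                             logical(1)),
    reliable = vapply(residence, function(r) r$fit$reliable, logical(1)))
  else data.frame()

  report <- list(
    schema = .REPORT_SCHEMA,
    config = unclass(config),
    config_hash = .config_hash(config),
    n_frames = n_frames(traj), n_atoms = n_atoms(traj), dt_ps = traj$dt,
    mdhs = list(
      n_total = nrow(sites),
      n_by_shell = as.list(table(factor(sites$shell,
                                        c("first", "second", "outer")))),
      sites = sites),
    gr = list(empty = rdf$empty, peaks = rdf$peaks,
              first_minimum = rdf$first_minimum,
              second_minimum = rdf$second_minimum),
    residence = list(per_site = per_site, by_shell = shell_summary$summary),
    hydration = list(overall_mean_waters_per_residue = contacts$overall_mean,
                     per_residue = contacts$table),
    hbonds = if (!is.null(hb)) list(overall_mean_ps = hb$overall_mean,
                                    n_events = hb$n_events,
                                    geometric_only = hb$geometric_only)
             else NULL,
    protein = list(rmsf = rmsf, rg_mean_A = mean(rg$rg),
                   rmsd_max_A = max(rmsd$rmsd),
                   sasa_nm2 = sasa$total_nm2,
                   s2 = s2),
    warnings = warnings_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    write_dx(grid, file.path(out_dir, "density.dx"))
    write_sites_pdb(sites, file.path(out_dir, "mdhs.pdb"))
    write_rdf_csv(rdf, file.path(out_dir, "gr.csv"))
    if (nrow(per_site) > 0)
      utils::write.csv(per_site, file.path(out_dir, "residence.csv"),
                       row.names = FALSE)
    for (cv in curves)
      write_survival_csv(cv, file.path(
        out_dir, sprintf("survival_site%03d.csv", cv$site_id)))
  }
  report
}

#' Serialize a report deterministically to JSON
#' @param report a report list from \code{\link{run_analysis}}.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null", na = "null",
                           dataframe = "columns")
  writeLines(as.character(json), path)
  invisible(path)
}

#' Compare two analysis reports
#'
#' Side-by-side table of the headline metrics with differences and
#' ratios. Reports must share the schema version.
#' @param report_a,report_b reports (lists, or paths to report.json).
#' @return data.frame: metric, a, b, difference, ratio.
#' @export
compare_systems <- function(report_a, report_b) {
  load_rep <- function(r) if (is.character(r))
    jsonlite::read_json(r, simplifyVector = TRUE) else r
  a <- load_rep(report_a); b <- load_rep(report_b)
  if (!identical(a$schema, b$schema))
    stop("versioning error: reports have different schema versions (",
         a$schema, " vs ", b$schema, ")")
  pick <- function(r, shell) {
    s <- r$residence$by_shell
    if (length(s) == 0 || is.null(s$shell) || !(shell %in% s$shell))
      return(NA_real_)
    if (is.data.frame(s)) s$mean[s$shell == shell]
    else unlist(s$mean)[unlist(s$shell) == shell]
  }
  nshell <- function(r, shell) {
    v <- r$mdhs$n_by_shell[[shell]]
    if (is.null(v)) 0 else as.numeric(v)
  }
  metrics <- c("mdhs_total", "mdhs_first", "mdhs_second",
               "residence_first_ps", "residence_second_ps",
               "waters_per_residue", "rg_A", "sasa_nm2")
  va <- c(a$mdhs$n_total, nshell(a, "first"), nshell(a, "second"),
          pick(a, "first"), pick(a, "second"),
          a$hydration$overall_mean_waters_per_residue,
          a$protein$rg_mean_A, a$protein$sasa_nm2)
  vb <- c(b$mdhs$n_total, nshell(b, "first"), nshell(b, "second"),
          pick(b, "first"), pick(b, "second"),
          b$hydration$overall_mean_waters_per_residue,
          b$protein$rg_mean_A, b$protein$sasa_nm2)
  data.frame(metric = metrics, a = va, b = vb, difference = va - vb,
             ratio = ifelse(vb != 0, va / vb, NA_real_))
}
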