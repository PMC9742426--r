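# Text-format trajectory I/O: multi-model PDB and GRO (single structure
# or concatenated frame series). Binary formats (XTC/DCD) are rejected
# with a pointer to conversion; keeping the readers text-only keeps the
# package dependency-free and the fixtures inspectable.

.is_binary_traj <- function(path) {
  grepl("\\.(xtc|dcd|trr|nc)$", tolower(path))
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records, MODEL/ENDMDL frame boundaries and CRYST1
#' box lengths. Only orthorhombic boxes (all angles 90 degrees) are
#' supported. Coordinates in Angstrom.
#'
#' @param path file path.
#' @return list with \code{topology} (hs_topology) and \code{coords}
#'   (\code{n_atoms x 3 x n_models} array), \code{box}.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cryst <- lines[rec == "CRYST1"]
  box <- c(100, 100, 100)
  if (length(cryst) >= 1) {
    a <- as.numeric(substr(cryst[1], 7, 15))
    b <- as.numeric(substr(cryst[1], 16, 24))
    c3 <- as.numeric(substr(cryst[1], 25, 33))
    al <- as.numeric(substr(cryst[1], 34, 40))
    be <- as.numeric(substr(cryst[1], 41, 47))
    ga <- as.numeric(substr(cryst[1], 48, 54))
    if (any(abs(c(al, be, ga) - 90) > 1e-3))
      stop("unsupported geometry: triclinic box (angles != 90)")
    box <- c(a, b, c3)
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records")
  model_starts <- which(rec == "MODEL ")
  n_models <- max(1L, length(model_starts))
  atom_lines <- lines[is_atom]
  n_total <- length(atom_lines)
  if (n_total %% n_models != 0)
    stop("format error: models contain unequal atom counts")
  n_at <- n_total / n_models
  first <- atom_lines[seq_len(n_at)]
  name <- trimws(substr(first, 13, 16))
  resname <- trimws(substr(first, 18, 21))
  resid <- as.integer(trimws(substr(first, 23, 26)))
  element <- trimws(substr(first, 77, 78))
  if (all(element == "")) element <- NULL
  x <- as.numeric(substr(atom_lines, 31, 38))
  y <- as.numeric(substr(atom_lines, 39, 46))
  z <- as.numeric(substr(atom_lines, 47, 54))
  coords <- array(0, dim = c(n_at, 3, n_models))
  coords[, 1, ] <- x; coords[, 2, ] <- y; coords[, 3, ] <- z
  top <- hs_topology(name, resid, resname, element = element)
  list(topology = top, coords = coords, box = box)
}

#' Write a trajectory as a multi-model PDB
#' @param traj a Trajectory.
#' @param path output path.
#' @export
write_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    traj$box[1, 1], traj$box[1, 2], traj$box[1, 3], 90, 90, 90), con)
  for (m in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- traj$coords[, , m, drop = TRUE]
    nm <- ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      (top$index - 1L) %% 99999L + 1L, substr(nm, 1, 4),
      substr(top$residue_name, 1, 4), top$residue_index %% 9999L,
      xyz[, 1], xyz[, 2], xyz[, 3], substr(top$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a GRO file (single frame or concatenated frame series)
#'
#' GRO coordinates are in nm and converted to Angstrom. A trajectory
#' written as repeated GRO blocks is read as a frame series; frame times
#' are taken from \code{t=} markers on title lines when present.
#'
#' @param path file path.
#' @return list with \code{topology}, \code{coords} array, \code{box}
#'   (n_frames x 3, Angstrom) and \code{time} (ps, or NULL).
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("empty input: not a GRO file")
  frames <- list(); boxes <- list(); times <- numeric(0)
  i <- 1L; k <- 0L
  topo <- NULL
  while (i + 1 <= length(lines)) {
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat)) stop("format error: bad atom count line in GRO")
    body <- lines[(i + 2):(i + 1 + nat)]
    boxline <- strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]]
    bv <- as.numeric(boxline)
    if (length(bv) > 3 && any(abs(bv[4:length(bv)]) > 1e-9))
      stop("unsupported geometry: triclinic GRO box")
    k <- k + 1L
    if (is.null(topo)) {
      resid <- as.integer(substr(body, 1, 5))
      resname <- trimws(substr(body, 6, 10))
      name <- trimws(substr(body, 11, 15))
      topo <- hs_topology(name, resid, resname)
    }
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    frames[[k]] <- cbind(x, y, z) * 10
    boxes[[k]] <- bv[1:3] * 10
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times[k] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    i <- i + 3L + nat
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  n_at <- nrow(frames[[1]])
  coords <- array(0, dim = c(n_at, 3, k))
  for (m in seq_len(k)) {
    if (nrow(frames[[m]]) != n_at)
      stop("format error: GRO frames contain unequal atom counts")
    coords[, , m] <- frames[[m]]
  }
  time <- if (all(!is.na(times))) times else NULL
  list(topology = topo, coords = coords,
       box = do.call(rbind, boxes), time = time)
}

#' Write a trajectory as a GRO frame series
#' @param traj a Trajectory.
#' @param path output path.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  for (m in seq_len(n_frames(traj))) {
    writeLines(sprintf("hydrashell t= %.4f", traj$time[m]), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    xyz <- traj$coords[, , m, drop = TRUE] / 10
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$residue_index %% 100000L,
                       substr(top$residue_name, 1, 5),
                       substr(top$name, 1, 5),
                       top$index %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[m, 1] / 10,
                       traj$box[m, 2] / 10, traj$box[m, 3] / 10), con)
  }
  invisible(path)
}

#' Read topology + coordinates into a Trajectory
#'
#' Dispatches on file extension (or \code{format_hint}): PDB and GRO are
#' supported; XTC/DCD-style binary formats are rejected with a conversion
#' hint. Water/protein segments are classified from residue names
#' (water: HOH, SOL, WAT, TIP3, ...). Frame spacing is inferred from
#' timestamps when present, otherwise \code{dt} is required.
#'
#' @param topology_path path to a PDB or GRO topology file.
#' @param coords_path optional path to a multi-model PDB or GRO series;
#'   when NULL the topology file's own frames are used.
#' @param format_hint optional \code{"pdb"} or \code{"gro"}.
#' @param dt frame spacing in ps when timestamps are absent (default 1).
#' @return a \code{Trajectory}.
#' @export
read_trajectory <- function(topology_path, coords_path = NULL,
                            format_hint = NULL, dt = NULL) {
  paths <- c(topology_path, coords_path)
  for (p in paths) {
    if (!is.null(p) && .is_binary_traj(p))
      stop("unsupported format: binary trajectories (XTC/DCD/TRR) are not ",
           "readable here; convert to multi-model PDB or a GRO series ",
           "(e.g. 'gmx trjconv -o traj.gro')")
  }
  for (p in paths) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  read_any <- function(path) {
    fmt <- if (!is.null(format_hint)) tolower(format_hint)
           else tolower(tools::file_ext(path))
    switch(fmt,
           pdb = read_pdb(path),
           gro = read_gro(path),
           stop("unsupported format: ", fmt))
  }
  topo_data <- read_any(topology_path)
  if (is.null(coords_path)) {
    cd <- topo_data
  } else {
    cd <- read_any(coords_path)
    if (dim(cd$coords)[1] != nrow(topo_data$topology))
      stop(sprintf(
        "format error: topology has %d atoms but frames carry %d coordinates",
        nrow(topo_data$topology), dim(cd$coords)[1]))
  }
  if (dim(cd$coords)[3] == 0) stop("empty input: zero frames")
  tm <- cd$time
  if (!is.null(tm) && length(unique(round(diff(tm), 9))) > 0 &&
      length(tm) > 1 && all(diff(tm) > 0)) {
    Trajectory(topo_data$topology, cd$coords, cd$box, time = tm)
  } else {
    Trajectory(topo_data$topology, cd$coords, cd$box, dt = if (is.null(dt)) 1 else dt)
  }
}
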