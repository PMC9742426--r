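#' @keywords internal
"_PACKAGE"

# Standard amino-acid residue names used to classify the protein segment.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP", "MSE")

# Water residue names recognized across force fields.
.WATER_RES <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "SPC", "T3P", "TIP4")

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, D = 2.014, F = 18.998,
                   NA_ = 22.990, CL = 35.45, X = 12.011)

#' Guess an element symbol from an atom name
#'
#' PDB/GRO atom names encode the element in their leading characters
#' (after stripping digits and primes). Used when an explicit element
#' column is absent.
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA") &
                 !grepl("^CA|^CB|^CG|^CD|^CE|^CZ|^NA$", nm),
               two, one)
  # Atom names like CA (C-alpha), NA are carbons/nitrogens in proteins;
  # the heuristic above already keeps the single-letter reading for them.
  el[el == ""] <- "X"
  el
}

.element_mass <- function(element) {
  m <- .ELEMENT_MASS[toupper(element)]
  m[is.na(m)] <- .ELEMENT_MASS[["X"]]
  unname(m)
}

#' Build an atom topology table
#'
#' The topology is a plain data.frame with one row per atom, carrying the
#' fields every analysis needs: atom and residue naming, element, a
#' hydrogen flag, a coarse segment classification
#' (\code{protein}/\code{water}/\code{other}) and the atomic mass in amu.
#'
#' @param name atom names.
#' @param residue_index integer residue index (1-based, need not be dense).
#' @param residue_name 3-letter residue names.
#' @param element optional element symbols; guessed from names if missing.
#' @param segment optional segment labels; classified from residue names
#'   if missing (water residue names: HOH, SOL, WAT, TIP3, ...).
#' @param mass optional masses (amu); from element lookup if missing.
#' @return data.frame of class \code{hs_topology} with columns
#'   \code{index}, \code{name}, \code{element}, \code{is_hydrogen},
#'   \code{residue_index}, \code{residue_name}, \code{segment},
#'   \code{mass}.
#' @export
hs_topology <- function(name, residue_index, residue_name,
                        element = NULL, segment = NULL, mass = NULL) {
  n <- length(name)
  stopifnot(length(residue_index) == n, length(residue_name) == n)
  residue_name <- toupper(trimws(residue_name))
  if (is.null(element)) element <- guess_element(name)
  element <- toupper(trimws(element))
  if (is.null(segment)) {
    segment <- ifelse(residue_name %in% .WATER_RES, "water",
                      ifelse(residue_name %in% .AA3, "protein", "other"))
  }
  if (is.null(mass)) mass <- .element_mass(element)
  top <- data.frame(index = seq_len(n),
                    name = trimws(as.character(name)),
                    element = element,
                    is_hydrogen = element %in% c("H", "D"),
                    residue_index = as.integer(residue_index),
                    residue_name = residue_name,
                    segment = segment,
                    mass = as.numeric(mass),
                    stringsAsFactors = FALSE)
  class(top) <- c("hs_topology", "data.frame")
  top
}

#' Construct a trajectory object
#'
#' A \code{Trajectory} bundles a topology with an ordered stack of frames.
#' Coordinates are stored as a dense \code{n_atoms x 3 x n_frames} array in
#' Angstrom; each frame carries orthorhombic box lengths (Angstrom) and a
#' timestamp (ps). Frame spacing must be uniform.
#'
#' @param topology an \code{hs_topology}.
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (a matrix is
#'   promoted to a single frame).
#' @param box numeric length-3 vector (constant box) or
#'   \code{n_frames x 3} matrix of box lengths in Angstrom.
#' @param time frame times in ps; defaults to \code{0:(n_frames-1) * dt}.
#' @param dt frame spacing in ps, required when \code{time} is absent.
#' @return object of class \code{Trajectory}.
#' @export
Trajectory <- function(topology, coords, box, time = NULL, dt = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_at <- dim(coords)[1]
  n_fr <- dim(coords)[3]
  if (n_fr < 1) stop("empty trajectory: zero frames")
  if (nrow(topology) != n_at) {
    stop(sprintf(
      "format error: topology has %d atoms but frames carry %d coordinates",
      nrow(topology), n_at))
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = n_fr, ncol = 3, byrow = TRUE)
  if (nrow(box) == 1 && n_fr > 1)
    box <- matrix(box[1, ], nrow = n_fr, ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == n_fr, ncol(box) == 3)
  if (any(box <= 0)) stop("geometry error: box lengths must be > 0")
  if (is.null(time)) {
    if (is.null(dt)) dt <- 1
    time <- (seq_len(n_fr) - 1) * dt
  }
  if (length(time) != n_fr) stop("time vector length must equal frame count")
  if (n_fr > 1) {
    dts <- diff(time)
    if (any(dts <= 0)) stop("sampling error: frame times must be increasing")
    if (max(dts) - min(dts) > 1e-6)
      stop("sampling error: non-uniform frame spacing beyond 1e-6 ps")
    dt <- mean(dts)
  } else if (is.null(dt)) dt <- 1
  structure(list(topology = topology, coords = coords, box = box,
                 time = as.numeric(time), dt = dt),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, dt = %g ps\n",
              n_atoms(x), n_frames(x), x$dt))
  cat(sprintf("  segments: %s\n",
              paste(sprintf("%s=%d", names(table(x$topology$segment)),
                            table(x$topology$segment)), collapse = ", ")))
  invisible(x)
}

#' @rdname Trajectory
#' @param traj a Trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname Trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame
#' @param traj a Trajectory.
#' @param i frame number.
#' @return list of class \code{Frame} with \code{coords} (matrix),
#'   \code{box}, \code{time}.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  xyz <- traj$coords[, , i, drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  structure(list(coords = xyz, box = traj$box[i, ], time = traj$time[i]),
            class = "Frame")
}

#' Atom selections
#'
#' Index helpers over a topology: water oxygen atoms, protein heavy atoms,
#' and C-alpha atoms (falling back to all protein heavy atoms, with a
#' warning, for scaffolds without named CA atoms).
#' @param traj a Trajectory (or hs_topology).
#' @return integer atom indices (1-based).
#' @export
water_oxygens <- function(traj) {
  top <- if (inherits(traj, "Trajectory")) traj$topology else traj
  which(top$segment == "water" & top$element == "O")
}

#' @rdname water_oxygens
#' @export
protein_heavy <- function(traj) {
  top <- if (inherits(traj, "Trajectory")) traj$topology else traj
  which(top$segment == "protein" & !top$is_hydrogen)
}

#' @rdname water_oxygens
#' @export
ca_atoms <- function(traj) {
  top <- if (inherits(traj, "Trajectory")) traj$topology else traj
  idx <- which(top$segment == "protein" & top$name == "CA")
  if (length(idx) == 0) {
    idx <- which(top$segment == "protein" & !top$is_hydrogen)
    if (length(idx) > 0)
      warning("no CA atoms found; using all protein heavy atoms for fitting")
  }
  idx
}
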