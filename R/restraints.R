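# Flat-bottom chemical-shift restraint energetics over the six backbone
# atom types (CA, CB, C, N, HN, HA): V = K * sum_i sum_j Delta_ij^2 with
# Delta = max(0, |delta_exp - delta_calc| - epsilon), so the restraining
# force is zero while the deviation is within the experimental
# uncertainty and the potential is C1 at the flat-bottom edge. Only the
# evaluator (energy, gradient, weight schedule) -- no MD integration and
# no shift prediction.

.CS_ATOM_TYPES <- c("CA", "CB", "C", "N", "HN", "HA")

.normalize_cs_atom <- function(x) {
  x <- toupper(trimws(x))
  x[x %in% c("C'", "CO", "CPRIME")] <- "C"
  x[x %in% c("H", "HN")] <- "HN"
  x[x %in% c("HA", "HA1")] <- "HA"
  x
}

#' Build a chemical-shift table
#'
#' @param residue integer residue numbers.
#' @param atom_type one of CA, CB, C (C'), N, HN (H), HA per entry.
#' @param delta_exp experimental shift (ppm); NA = unrestrained entry.
#' @param epsilon experimental uncertainty (ppm, >= 0; default 0 = pure
#'   harmonic).
#' @param delta_calc calculated shift (ppm); may be NA until evaluation.
#' @return data.frame of class \code{ShiftTable}.
#' @export
shift_table <- function(residue, atom_type, delta_exp, epsilon = 0,
                        delta_calc = NA_real_) {
  atom_type <- .normalize_cs_atom(atom_type)
  bad <- setdiff(unique(atom_type), .CS_ATOM_TYPES)
  if (length(bad) > 0)
    stop("atom types outside the six backbone types: ",
         paste(bad, collapse = ", "))
  n <- length(residue)
  tab <- data.frame(residue = as.integer(residue), atom_type = atom_type,
                    delta_exp = as.numeric(delta_exp),
                    epsilon = rep_len(as.numeric(epsilon), n),
                    delta_calc = rep_len(as.numeric(delta_calc), n),
                    stringsAsFactors = FALSE)
  if (any(tab$epsilon < 0, na.rm = TRUE))
    stop("epsilon must be >= 0")
  class(tab) <- c("ShiftTable", "data.frame")
  tab
}

#' Read a shift table from CSV
#'
#' Expects columns \code{residue}, \code{atom_type}, \code{delta_exp}
#' and optionally \code{epsilon}, \code{delta_calc}.
#' @param path CSV file.
#' @return a \code{ShiftTable}.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "atom_type", "delta_exp")
  if (!all(need %in% names(df)))
    stop("shift CSV must have columns: ", paste(need, collapse = ", "))
  shift_table(df$residue, df$atom_type, df$delta_exp,
              epsilon = if ("epsilon" %in% names(df)) df$epsilon else 0,
              delta_calc = if ("delta_calc" %in% names(df)) df$delta_calc
                           else NA_real_)
}

#' Minimal NMR-STAR chemical-shift loop reader
#'
#' Parses the first \code{loop_} whose tags include
#' \code{_Atom_chem_shift.Seq_ID}, \code{.Atom_ID} and \code{.Val}
#' (\code{.Val_err} optional), keeping only the six backbone atom types.
#' @param path NMR-STAR file.
#' @return a \code{ShiftTable} (delta_calc all NA).
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L; tags <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1L
      }
      want <- c(seq_col <- grep("\\.Seq_ID$", tags),
                atom_col <- grep("\\.Atom_ID$", tags),
                val_col <- grep("\\.Val$", tags))
      if (length(want) == 3) {
        err_col <- grep("\\.Val_err$", tags)
        rows <- list(); k <- j
        while (k <= n && !grepl("^\\s*(stop_|loop_)", lines[k])) {
          f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
          if (length(f) >= length(tags)) rows[[length(rows) + 1L]] <- f
          k <- k + 1L
        }
        if (length(rows) > 0) {
          m <- do.call(rbind, rows)
          at <- .normalize_cs_atom(m[, atom_col])
          keep <- at %in% .CS_ATOM_TYPES
          eps <- if (length(err_col) == 1)
            suppressWarnings(as.numeric(m[keep, err_col])) else 0
          eps[is.na(eps)] <- 0
          return(shift_table(as.integer(m[keep, seq_col]), at[keep],
                             as.numeric(m[keep, val_col]), epsilon = eps))
        }
      }
      i <- j
    } else i <- i + 1L
  }
  stop("no _Atom_chem_shift loop found in ", path)
}

.cs_excess <- function(tab) {
  d <- tab$delta_exp - tab$delta_calc
  pmax(0, abs(d) - tab$epsilon)
}

#' Flat-bottom restraint energy
#'
#' Total \code{K * sum(Delta^2)} over restrained shifts, with
#' \code{Delta = max(0, |delta_exp - delta_calc| - epsilon)}. Entries
#' with missing \code{delta_exp} are unrestrained and skipped; a missing
#' \code{delta_calc} on a restrained entry is an error.
#'
#' @param table a \code{ShiftTable}.
#' @param K restraint weight (kJ mol^-1 ppm^-2), >= 0.
#' @return list with \code{total} (kJ/mol) and \code{per_shift}
#'   (data.frame with the excess deviation and contribution).
#' @export
restraint_energy <- function(table, K) {
  if (K < 0) stop("parameter error: negative restraint weight K")
  tab <- table[!is.na(table$delta_exp), , drop = FALSE]
  if (any(is.na(tab$delta_calc)))
    stop("delta_calc missing for restrained shifts")
  delta <- .cs_excess(tab)
  contrib <- K * delta^2
  per <- data.frame(residue = tab$residue, atom_type = tab$atom_type,
                    excess = delta, energy = contrib,
                    stringsAsFactors = FALSE)
  list(total = sum(contrib), per_shift = per)
}

#' Gradient of the restraint energy in the calculated shifts
#'
#' \code{dV/ddelta_calc = -2 K Delta sign(delta_exp - delta_calc)}
#' outside the flat bottom and 0 inside; continuous at the edge.
#'
#' @inheritParams restraint_energy
#' @return data.frame: residue, atom_type, \code{dV_ddelta_calc}
#'   (kJ mol^-1 ppm^-1).
#' @export
restraint_gradient <- function(table, K) {
  if (K < 0) stop("parameter error: negative restraint weight K")
  tab <- table[!is.na(table$delta_exp), , drop = FALSE]
  if (any(is.na(tab$delta_calc)))
    stop("delta_calc missing for restrained shifts")
  d <- tab$delta_exp - tab$delta_calc
  delta <- pmax(0, abs(d) - tab$epsilon)
  g <- -2 * K * delta * sign(d)
  data.frame(residue = tab$residue, atom_type = tab$atom_type,
             dV_ddelta_calc = g, stringsAsFactors = FALSE)
}

#' Restraint weight configuration
#' @param K_max maximum weight (kJ mol^-1 ppm^-2, default 300).
#' @param ramp_duration equilibration ramp length (ps, default 10000).
#' @return list of class \code{RestraintConfig}.
#' @export
restraint_config <- function(K_max = 300, ramp_duration = 10000) {
  stopifnot(K_max >= 0, ramp_duration > 0)
  structure(list(K_max = K_max, ramp_duration = ramp_duration),
            class = "RestraintConfig")
}

#' Restraint weight ramp schedule
#'
#' Linear ramp from zero to \code{K_max} over \code{ramp_duration},
#' constant thereafter.
#' @param t time (ps), >= 0; vectorized.
#' @param config a \code{\link{restraint_config}}.
#' @return K(t) in kJ mol^-1 ppm^-2.
#' @export
ramp_schedule <- function(t, config = restraint_config()) {
  if (any(t < 0)) stop("parameter error: negative time")
  config$K_max * pmin(1, t / config$ramp_duration)
}

#' Diagnostic: restraint-force share of total backbone forces
#'
#' Given externally supplied force-field force magnitudes on backbone
#' atoms, the mean ratio of restraint gradient magnitudes to total force
#' magnitudes. A diagnostic, not a target.
#' @param gradient output of \code{\link{restraint_gradient}}.
#' @param ff_force_magnitudes numeric, same length as the gradient rows.
#' @return fraction in [0, 1].
#' @export
restraint_force_incidence <- function(gradient, ff_force_magnitudes) {
  g <- abs(gradient$dV_ddelta_calc)
  stopifnot(length(ff_force_magnitudes) == length(g))
  mean(g / (g + abs(ff_force_magnitudes)))
}
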