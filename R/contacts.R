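# Per-residue hydration counts: how many waters are in direct contact
# with each residue, averaged over frames. "Direct contact" is a water
# oxygen within a cutoff (default 3.5 A) of any heavy atom of the
# residue; one water can hydrate several residues but counts once per
# residue per frame.

#' Average number of waters in contact with each residue
#'
#' @param traj a superposed \code{Trajectory}.
#' @param cutoff contact cutoff, heavy atom to water oxygen (Angstrom,
#'   inclusive; default 3.5).
#' @param hyper_factor a residue is flagged hyper-hydrated when its mean
#'   water count is at least this multiple of the protein-wide mean
#'   (default 2).
#' @return list with \code{table} (data.frame: \code{residue_index},
#'   \code{residue_name}, \code{mean_waters}, \code{hyper_hydrated}),
#'   \code{overall_mean} (mean over residues), and \code{by_type}
#'   (per-residue-name summary).
#' @export
residue_water_contacts <- function(traj, cutoff = 3.5, hyper_factor = 2) {
  stopifnot(cutoff > 0)
  prot <- protein_heavy(traj)
  if (length(prot) == 0) stop("selection error: empty protein")
  wat <- water_oxygens(traj)
  top <- traj$topology
  res_ids <- sort(unique(top$residue_index[prot]))
  res_of_atom <- match(top$residue_index[prot], res_ids)
  counts <- numeric(length(res_ids))
  nf <- n_frames(traj)
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    if (length(wat) == 0) break
    fr <- get_frame(traj, f)
    fr <- wrap_waters(fr, top)
    p <- fr$coords[prot, , drop = FALSE]
    w <- matrix(fr$coords[wat, ], ncol = 3)
    # prefilter waters to a sphere that can possibly be in contact
    ctr <- colMeans(p)
    reach <- sqrt(max(rowSums(sweep(p, 2, ctr)^2))) + cutoff
    near <- rowSums(sweep(w, 2, ctr)^2) <= reach^2
    if (!any(near)) next
    w <- w[near, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(w^2), "+") - 2 * (p %*% t(w))
    hit <- d2 <= cut2
    # per residue: number of waters within cutoff of >= 1 heavy atom
    per_res <- rowsum(hit + 0, group = res_of_atom)
    counts <- counts + rowSums(per_res > 0)
  }
  mean_w <- counts / nf
  overall <- mean(mean_w)
  rn <- top$residue_name[prot][match(res_ids, top$residue_index[prot])]
  hyper <- overall > 0 & mean_w >= hyper_factor * overall
  tab <- data.frame(residue_index = res_ids, residue_name = rn,
                    mean_waters = mean_w, hyper_hydrated = hyper,
                    stringsAsFactors = FALSE)
  by_type <- do.call(rbind, lapply(split(seq_along(res_ids), rn), function(ii)
    data.frame(residue_name = rn[ii[1]], n = length(ii),
               mean_waters = mean(mean_w[ii]), n_hyper = sum(hyper[ii]),
               stringsAsFactors = FALSE)))
  rownames(by_type) <- NULL
  list(table = tab, overall_mean = overall, by_type = by_type)
}
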