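#' Enumerate candidate assignment windows
#'
#' Slides a fixed-length window one residue at a time, starting at the
#' anchor residue and walking backwards, to enumerate every candidate
#' primary-structure register for an unresolved segment.  Window `k`
#' (k = 0..n_windows-1) covers residues
#' `[anchor_end_res - k - window_len + 1, anchor_end_res - k]`, carries its
#' one-letter sequence, and is split into an N-terminal coil and a
#' C-terminal 9-residue helix by [map_secondary_structure()].
#'
#' Defaults reproduce the 24-candidate scan of a 17-residue segment
#' anchored at residue 842 (the window ends run 842 down to 819).
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @param seq_start_res residue number of the first sequence position.
#' @param window_len window length in residues (default 17).
#' @param anchor_end_res residue number at which the first window ends.
#' @param n_windows number of windows (default 24).
#' @return data.frame with `window_id`, `start_res`, `end_res`, `sequence`,
#'   `coil_start`, `coil_end`, `helix_start`, `helix_end`.
#' @export
enumerate_windows <- function(sequence, seq_start_res = 1L, window_len = 17L,
                              anchor_end_res = 842L, n_windows = 24L) {
  seq_chr <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  seq_end_res <- seq_start_res + length(seq_chr) - 1L
  lo_needed <- anchor_end_res - window_len - n_windows + 2L
  if (seq_start_res > lo_needed || seq_end_res < anchor_end_res)
    stop(sprintf("sequence must cover residues %d-%d (has %d-%d)",
                 lo_needed, anchor_end_res, seq_start_res, seq_end_res),
         call. = FALSE)
  out <- lapply(seq_len(n_windows) - 1L, function(k) {
    end_res <- anchor_end_res - k
    start_res <- end_res - window_len + 1L
    pos <- (start_res:end_res) - seq_start_res + 1L
    ss <- map_secondary_structure(start_res, end_res)
    data.frame(window_id = k + 1L, start_res = start_res, end_res = end_res,
               sequence = paste(seq_chr[pos], collapse = ""),
               coil_start = ss$coil_span[1], coil_end = ss$coil_span[2],
               helix_start = ss$helix_span[1], helix_end = ss$helix_span[2])
  })
  do.call(rbind, out)
}

#' Coil/helix split of an assignment window
#'
#' The unresolved segment's known secondary structure is an N-terminal
#' disordered coil followed by a 9-residue alpha-helix; a window of length
#' `L >= 9` therefore maps its first `L - 9` residues to coil and its last
#' 9 to helix.  A length-9 window is all helix (empty coil, reported as NA).
#'
#' @param start_res,end_res 1-based inclusive window bounds.
#' @param helix_len helix length (default 9).
#' @return list with `coil_span` and `helix_span` (each length-2 inclusive,
#'   coil `c(NA, NA)` when empty).
#' @export
map_secondary_structure <- function(start_res, end_res, helix_len = 9L) {
  len <- end_res - start_res + 1L
  if (len < helix_len)
    stop(sprintf("window of %d residues cannot hold a %d-residue helix",
                 len, helix_len), call. = FALSE)
  helix_start <- end_res - helix_len + 1L
  coil <- if (helix_start > start_res) c(start_res, helix_start - 1L)
          else c(NA_integer_, NA_integer_)
  list(coil_span = coil, helix_span = c(helix_start, end_res))
}

#' Rank assignment windows by simulated stability
#'
#' Orders candidate windows by mean backbone RMSD to the reference
#' structure, ascending: the most stable register (lowest RMSD) gets rank 1.
#' Ties break toward the smaller start residue.
#'
#' @param records data.frame with `start_res`, `end_res` and
#'   `mean_backbone_rmsd` (finite, Angstroms); extra columns pass through.
#' @return the records with a `rank` column, sorted by rank.
#' @export
rank_by_stability <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("start_res", "mean_backbone_rmsd") %in% names(records)))
  if (nrow(records) == 0) stop("no records to rank", call. = FALSE)
  if (any(!is.finite(records$mean_backbone_rmsd)))
    stop("mean_backbone_rmsd must be finite", call. = FALSE)
  ord <- order(records$mean_backbone_rmsd, records$start_res)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Stability score of one candidate assignment
#'
#' Mean backbone C-alpha RMSD of the modeled segment to the reference over
#' a trailing frame window, with the global superposition fit on the rest
#' of the protein (so the score reports how much the segment itself moves).
#'
#' @param traj a [trajectory()].
#' @param reference a [structure_model()] with the same topology.
#' @param segment_resid residue numbers of the modeled segment.
#' @param window frame indices to average over (default all).
#' @return mean segment RMSD, Angstroms.
#' @export
score_assignment <- function(traj, reference, segment_resid,
                             window = seq_len(n_frames(traj))) {
  at <- traj$topology$atoms
  seg_sel <- list(resid = segment_resid, names = "CA")
  rest_resid <- setdiff(unique(at$resid), segment_resid)
  if (length(rest_resid) < 3)
    stop("too few non-segment residues to fit on", call. = FALSE)
  fit_idx <- select_atoms(traj$topology, resid = rest_resid, names = "CA")
  seg_idx <- select_atoms(traj$topology, resid = segment_resid, names = "CA")
  ref_seg <- reference$xyz[select_atoms(reference, resid = segment_resid,
                                        names = "CA"), , drop = FALSE]
  vals <- vapply(window, function(f) {
    fitted <- superpose(traj$coords[, , f], reference$xyz,
                        fit_selection = fit_idx)$coords
    sqrt(mean(rowSums((fitted[seg_idx, , drop = FALSE] - ref_seg)^2)))
  }, numeric(1))
  mean(vals)
}

#' Synthetic stand-in R-domain sequence
#'
#' Deterministic stand-in for the human CFTR R-domain sequence (residues
#' 630-856), used only to exercise the sliding-window machinery: positions
#' the assignment scan depends on carry the residue identities printed for
#' the real protein (F630, L818, E826, F834, T842, H856); all other
#' positions are arbitrary but fixed.  This is NOT the biological sequence.
#'
#' @param first_resid,last_resid numbering bounds (defaults 630, 856).
#' @return one-letter string of length `last_resid - first_resid + 1`.
#' @export
synthetic_rdomain_sequence <- function(first_resid = 630L, last_resid = 856L) {
  n <- last_resid - first_resid + 1L
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(20260910L, kind = "Mersenne-Twister")
  s <- sample(alphabet, n, replace = TRUE)
  anchors <- c(`630` = "F", `818` = "L", `826` = "E", `834` = "F",
               `842` = "T", `856` = "H")
  pos <- as.integer(names(anchors)) - first_resid + 1L
  ok <- pos >= 1 & pos <= n
  s[pos[ok]] <- anchors[ok]
  paste(s, collapse = "")
}
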