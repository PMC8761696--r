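## Side-chain atoms carrying the formal charge of basic / acidic residues,
## used for salt-bridge N-O distances.  Configurable via function arguments.
SIDECHAIN_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))
SIDECHAIN_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Least-squares rigid superposition
#'
#' Kabsch algorithm: finds the proper rotation + translation minimizing the
#' RMSD between `mobile` and `reference` over the fit selection (reflections
#' are excluded by construction), applies it to all mobile coordinates and
#' reports the post-fit RMSD over the fit atoms.
#'
#' @param mobile,reference numeric n x 3 coordinate matrices (Angstroms).
#' @param fit_selection integer indices of the atoms used for the fit
#'   (default: all).  At least 3 non-collinear atoms are required.
#' @return list with `coords` (transformed mobile coordinates) and `rmsd`.
#' @export
superpose <- function(mobile, reference, fit_selection = seq_len(nrow(mobile))) {
  stopifnot(is.matrix(mobile), is.matrix(reference), ncol(mobile) == 3)
  if (length(fit_selection) < 3)
    stop("fit requires at least 3 atoms", call. = FALSE)
  A <- mobile[fit_selection, , drop = FALSE]
  B <- reference[fit_selection, , drop = FALSE]
  if (nrow(A) != nrow(B))
    stop("fit selections must resolve to equal atom counts", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))   # H = A0^T B0 ; R = V' corrections
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2)
    stop("degenerate (collinear) fit geometry", call. = FALSE)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  transform <- function(x) sweep(sweep(x, 2, ca) %*% t(R), 2, cb, "+")
  fitted <- transform(mobile)
  rmsd <- sqrt(mean(rowSums((fitted[fit_selection, , drop = FALSE] - B)^2)))
  list(coords = fitted, rmsd = rmsd)
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

resolve_sel <- function(model, selection) {
  if (is.numeric(selection)) as.integer(selection)
  else if (is.character(selection)) select_atoms(model, selection)
  else if (is.list(selection))
    do.call(select_atoms, c(list(model), selection))
  else stop("unsupported selection", call. = FALSE)
}

#' Per-frame RMSD to a reference structure
#'
#' `RMSD(t) = sqrt(mean_i |x_i(t) - x_i^ref|^2)` over the selection, after
#' optional least-squares superposition of each frame onto the reference
#' (fit on the same selection).
#'
#' @param traj a [trajectory()].
#' @param reference a [structure_model()] sharing the topology.
#' @param selection atom selection (string, index vector, or list of
#'   [select_atoms()] arguments); default all C-alphas.
#' @param fit superpose each frame first (default TRUE).
#' @return numeric vector, one RMSD (Angstroms) per frame.
#' @export
rmsd_series <- function(traj, reference, selection = list(names = "CA"),
                        fit = TRUE) {
  idx <- resolve_sel(traj$topology, selection)
  ref_idx <- resolve_sel(reference, selection)
  if (length(idx) != length(ref_idx))
    stop("selection resolves to different atom counts in trajectory and reference",
         call. = FALSE)
  ref <- reference$xyz[ref_idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj$coords[idx, , f, drop = FALSE][, , 1]
    if (!is.matrix(x)) x <- matrix(x, ncol = 3)
    if (fit) superpose(x, ref)$rmsd else rmsd_of(x, ref)
  }, numeric(1))
}

#' Residue-wise RMSD profile
#'
#' For each frame in the averaging window the whole selection is globally
#' superposed onto the reference (fit on `fit_selection`, default the
#' analysis selection itself), then each residue's deviation from its
#' reference position is accumulated; the profile reports
#' `sqrt(mean_t |x_i(t) - x_i^ref|^2)` per residue.
#'
#' @param traj,reference as in [rmsd_series()].
#' @param selection one atom per residue (default C-alphas).
#' @param window integer frame indices to average over (default all frames).
#' @param fit_selection atoms used for the global fit; default `selection`.
#' @param fit superpose before measuring (default TRUE).
#' @return data.frame `resid`, `value` (Angstroms), attribute
#'   `statistic = "RMSD"`.
#' @export
residue_rmsd <- function(traj, reference, selection = list(names = "CA"),
                         window = seq_len(n_frames(traj)),
                         fit_selection = selection, fit = TRUE) {
  if (any(window < 1 | window > n_frames(traj)))
    stop("window outside trajectory frames", call. = FALSE)
  idx <- resolve_sel(traj$topology, selection)
  resids <- traj$topology$atoms$resid[idx]
  if (anyDuplicated(resids))
    stop("selection must resolve to one atom per residue", call. = FALSE)
  ref_idx <- resolve_sel(reference, selection)
  fit_idx <- resolve_sel(traj$topology, fit_selection)
  fit_ref <- reference$xyz[resolve_sel(reference, fit_selection), , drop = FALSE]
  ref <- reference$xyz[ref_idx, , drop = FALSE]
  acc <- matrix(0, length(idx), 1)
  for (f in window) {
    all_x <- traj$coords[, , f]
    if (fit) {
      pos <- match(idx, seq_len(nrow(all_x)))
      fitted <- superpose(all_x, reference$xyz, fit_selection = fit_idx)
      # superpose fits mobile fit atoms onto reference rows with same indices;
      # ensure reference fit rows correspond
      x <- fitted$coords[idx, , drop = FALSE]
    } else x <- all_x[idx, , drop = FALSE]
    acc <- acc + rowSums((x - ref)^2)
  }
  prof <- data.frame(resid = resids, value = sqrt(acc[, 1] / length(window)))
  attr(prof, "statistic") <- "RMSD"
  attr(prof, "window") <- range(window)
  prof
}

#' Residue-wise RMSF profile
#'
#' Root-mean-square fluctuation per residue over a frame window, after
#' optional per-frame superposition.  Two definitions are provided:
#' `mode = "reference"` measures fluctuation about the reference position,
#' `sqrt(<|x_i - x_i^ref|^2>)`; `mode = "mean"` uses the conventional
#' time-mean position of each atom instead of the reference.  For a rigid
#' structure both are zero; for pure isotropic noise of SD sigma per
#' coordinate both converge to `sigma * sqrt(3)`.
#'
#' @inheritParams residue_rmsd
#' @param mode `"reference"` (default) or `"mean"`.
#' @return data.frame `resid`, `value`, attribute `statistic = "RMSF"`.
#' @export
rmsf <- function(traj, reference, selection = list(names = "CA"),
                 window = seq_len(n_frames(traj)),
                 mode = c("reference", "mean"),
                 fit_selection = selection, fit = TRUE) {
  mode <- match.arg(mode)
  if (any(window < 1 | window > n_frames(traj)))
    stop("window outside trajectory frames", call. = FALSE)
  idx <- resolve_sel(traj$topology, selection)
  resids <- traj$topology$atoms$resid[idx]
  if (anyDuplicated(resids))
    stop("selection must resolve to one atom per residue", call. = FALSE)
  ref_idx <- resolve_sel(reference, selection)
  fit_idx <- resolve_sel(traj$topology, fit_selection)
  ref <- reference$xyz[ref_idx, , drop = FALSE]
  nt <- length(window)
  X <- array(NA_real_, c(length(idx), 3, nt))
  for (k in seq_len(nt)) {
    all_x <- traj$coords[, , window[k]]
    if (fit) all_x <- superpose(all_x, reference$xyz, fit_selection = fit_idx)$coords
    X[, , k] <- all_x[idx, , drop = FALSE]
  }
  center <- if (mode == "reference") ref else apply(X, c(1, 2), mean)
  dev2 <- vapply(seq_len(nt), function(k) rowSums((X[, , k] - center)^2),
                 numeric(length(idx)))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(idx))
  prof <- data.frame(resid = resids, value = sqrt(rowMeans(dev2)))
  attr(prof, "statistic") <- "RMSF"
  attr(prof, "mode") <- mode
  prof
}

#' Per-frame minimum distance between two selections
#'
#' Minimum over all cross pairs of the Euclidean distance, per frame, plus a
#' mean +/- SD summary over a trailing window of frames.  The selections
#' must be disjoint.
#'
#' @param traj a [trajectory()].
#' @param selectionA,selectionB atom selections (as in [rmsd_series()]).
#' @param summary_window number of trailing frames for the summary
#'   (default: all frames).
#' @return list with `distances` (numeric per frame), `mean`, `sd`,
#'   `summary_frames`.
#' @export
min_distance_series <- function(traj, selectionA, selectionB,
                                summary_window = n_frames(traj)) {
  ia <- resolve_sel(traj$topology, selectionA)
  ib <- resolve_sel(traj$topology, selectionB)
  if (length(intersect(ia, ib)) > 0)
    stop("selections must be disjoint", call. = FALSE)
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    A <- traj$coords[ia, , f, drop = FALSE][, , 1, drop = FALSE]
    A <- matrix(A, ncol = 3)
    B <- matrix(traj$coords[ib, , f, drop = FALSE][, , 1, drop = FALSE], ncol = 3)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  tail_idx <- seq(max(1, length(d) - summary_window + 1), length(d))
  list(distances = d,
       mean = mean(d[tail_idx]),
       sd = if (length(tail_idx) > 1) sd(d[tail_idx]) else 0,
       summary_frames = range(tail_idx))
}

#' Salt-bridge direct-contact fraction
#'
#' Fraction of frames in which the minimum distance between the basic
#' residue's side-chain nitrogens and the acidic residue's side-chain
#' oxygens is strictly below the cutoff (default 4 A, the conventional
#' direct-contact criterion; a distance of exactly 4 A does not count).
#'
#' @param traj a [trajectory()].
#' @param basic_residue,acidic_residue residue numbers (optionally named
#'   lists with `chain` and `resid`).
#' @param cutoff contact cutoff, Angstroms.
#' @param n_names,o_names side-chain atom-name tables, keyed by residue
#'   name; defaults cover LYS/ARG/HIS and ASP/GLU.
#' @return list with `fraction`, `distances` (per-frame min N-O distance).
#' @export
saltbridge_contact_fraction <- function(traj, basic_residue, acidic_residue,
                                        cutoff = 4.0,
                                        n_names = SIDECHAIN_N,
                                        o_names = SIDECHAIN_O) {
  at <- traj$topology$atoms
  get_idx <- function(resid, table, kind) {
    rows <- which(at$resid == resid)
    if (length(rows) == 0)
      stop(sprintf("residue %s not found", resid), call. = FALSE)
    resname <- at$resname[rows[1]]
    wanted <- table[[resname]]
    if (is.null(wanted)) wanted <- unlist(table, use.names = FALSE)
    idx <- rows[at$name[rows] %in% wanted]
    if (length(idx) == 0)
      stop(sprintf("residue %d (%s) has no side-chain %s atoms",
                   resid, resname, kind), call. = FALSE)
    idx
  }
  ia <- get_idx(basic_residue, n_names, "N")
  ib <- get_idx(acidic_residue, o_names, "O")
  ds <- min_distance_series(traj, ia, ib)
  list(fraction = mean(ds$distances < cutoff), distances = ds$distances)
}

#' Minimum C-alpha distance between a residue and a residue span
#'
#' Minimum pairwise CA-CA distance between one residue and an inclusive
#' residue range (e.g. a helix), in a single structure.
#'
#' @param structure a [structure_model()].
#' @param residue residue number of the single residue.
#' @param residue_span length-2 inclusive residue range, or vector of
#'   residue numbers.
#' @return minimum distance, Angstroms.
#' @export
min_calpha_distance <- function(structure, residue, residue_span) {
  if (length(residue_span) == 2 && residue_span[2] >= residue_span[1])
    residue_span <- seq(residue_span[1], residue_span[2])
  ia <- select_atoms(structure, resid = residue, names = "CA")
  ib <- select_atoms(structure, resid = residue_span, names = "CA")
  A <- structure$xyz[ia, , drop = FALSE]
  B <- structure$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}
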