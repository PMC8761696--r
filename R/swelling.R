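#' Normalize an organoid-area series to its baseline
#'
#' Converts raw segmented areas into percent of the t=0 area, the standard
#' FIS readout: `normalized[t] = 100 * raw_area[t] / raw_area[1]`, so the
#' series always starts at exactly 100.
#'
#' @param times acquisition times in minutes (default 0,10,...,60).
#' @param raw_area total organoid area per frame, pixels^2; the first value
#'   must be positive (a well with no detected organoids at baseline is
#'   degenerate and rejected).
#' @return object of class `swelling_series`: list with `times`, `raw_area`,
#'   `normalized`.
#' @export
normalize_series <- function(times, raw_area) {
  if (length(times) != length(raw_area))
    stop("times and raw_area must have equal length", call. = FALSE)
  if (!is.finite(raw_area[1]) || raw_area[1] <= 0)
    stop("degenerate well: baseline area must be > 0", call. = FALSE)
  structure(list(times = as.numeric(times), raw_area = as.numeric(raw_area),
                 normalized = 100 * raw_area / raw_area[1]),
            class = "swelling_series")
}

#' Area under the swelling curve
#'
#' The FIS magnitude: trapezoidal integral of the normalized series minus
#' the 100\% baseline over \[0, 60\] minutes, in \%*min.  A flat series gives
#' 0; shrinkage gives a negative value (not clipped).
#'
#' @param series a `swelling_series` from [normalize_series()].
#' @param t_max end of the integration window, minutes (default 60).
#' @return AUC in \%*min.
#' @export
auc <- function(series, t_max = 60) {
  stopifnot(inherits(series, "swelling_series"))
  t <- series$times
  if (t[1] > 0 || max(t) < t_max)
    stop(sprintf("series times must cover [0, %g] min", t_max), call. = FALSE)
  keep <- t <= t_max
  t <- t[keep]
  dev <- series$normalized[keep] - 100
  sum(diff(t) * (dev[-1] + dev[-length(dev)]) / 2)
}

#' Baseline-correct a treated AUC
#'
#' Treatment response relative to the untreated (vehicle) well at the same
#' forskolin concentration: `auc_treated - auc_untreated`.  Condition keys,
#' when provided, must match.
#'
#' @param auc_treated,auc_untreated AUC values, \%*min.
#' @param condition_treated,condition_untreated optional named lists/vectors
#'   identifying genotype and forskolin concentration; compared when both
#'   are given.
#' @return corrected AUC, \%*min (may be negative).
#' @export
baseline_correct <- function(auc_treated, auc_untreated,
                             condition_treated = NULL,
                             condition_untreated = NULL) {
  if (!is.null(condition_treated) && !is.null(condition_untreated) &&
      !identical(condition_treated, condition_untreated))
    stop("pairing error: treated and untreated conditions do not match",
         call. = FALSE)
  auc_treated - auc_untreated
}

#' Fold change between two response magnitudes
#'
#' Ratio `value_a / value_b`, rounded to the nearest integer by default to
#' match the "n-fold" phrasing used when comparing group means.
#'
#' @param value_a,value_b numeric; `value_b` must be positive.
#' @param round_to_integer round the ratio (default TRUE).
#' @return fold change.
#' @export
fold_change <- function(value_a, value_b, round_to_integer = TRUE) {
  if (!is.finite(value_b) || value_b <= 0)
    stop("value_b must be > 0", call. = FALSE)
  fc <- value_a / value_b
  if (isTRUE(round_to_integer)) round(fc) else fc
}

#' Synergy score for a potentiator combination
#'
#' Compares the baseline-corrected AUC of a combination treatment to the sum
#' of its single-agent responses: `auc_combo - (auc_a + auc_b)`.  Positive
#' values flag synergy (response exceeding additivity), zero additivity,
#' negative sub-additivity.
#'
#' @param auc_combo,auc_a,auc_b baseline-corrected AUCs from matched
#'   conditions, \%*min.
#' @return synergy score, \%*min.
#' @export
synergy_score <- function(auc_combo, auc_a, auc_b) {
  auc_combo - (auc_a + auc_b)
}

#' Summarize per-well FIS results by condition
#'
#' Mean and sample SD (n-1 denominator) of the AUC within each condition
#' group.  Groups with a single well report SD 0 and are flagged; flagged
#' (degenerate) wells are excluded and counted.
#'
#' @param results data.frame with at least `auc` and the grouping columns;
#'   an optional logical `flagged` column marks excluded wells.
#' @param grouping character vector of column names to group by.
#' @return data.frame with group keys, `n_wells`, `mean_auc`, `sd_auc`,
#'   `n_flagged`, `single_well` flag.
#' @export
summarize_condition <- function(results, grouping) {
  stopifnot(is.data.frame(results), all(grouping %in% names(results)),
            "auc" %in% names(results))
  if (nrow(results) == 0) stop("no results to summarize", call. = FALSE)
  flagged <- if ("flagged" %in% names(results)) results$flagged else
    rep(FALSE, nrow(results))
  key <- interaction(results[grouping], drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(k) {
    sel <- key == k
    used <- sel & !flagged
    if (!any(used)) stop(sprintf("empty group after flag exclusion: %s", k),
                         call. = FALSE)
    vals <- results$auc[used]
    cbind(results[which(sel)[1], grouping, drop = FALSE],
          data.frame(n_wells = sum(used),
                     mean_auc = mean(vals),
                     sd_auc = if (length(vals) > 1) sd(vals) else 0,
                     n_flagged = sum(sel & flagged),
                     single_well = length(vals) == 1L))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end FIS quantification of a stack
#'
#' Convenience wrapper: segment every frame, normalize the total-area series
#' to baseline and integrate the AUC.
#'
#' @param stack an [image_stack()].
#' @param config a [seg_config()].
#' @param t_max AUC integration end, minutes.
#' @return list with `series` (`swelling_series`), `auc`, and the
#'   segmentation result.
#' @export
quantify_fis <- function(stack, config = seg_config(), t_max = 60) {
  seg <- segment_stack(stack, config)
  series <- normalize_series(seg$times, seg$total_area)
  list(series = series, auc = auc(series, t_max = t_max), segmentation = seg)
}
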