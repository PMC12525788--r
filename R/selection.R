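#' Top-fraction selection match between predicted and reference rankings
#'
#' Emulates truncation selection in a breeding program: the top q% of
#' samples by predicted analyte content are selected, and the match is the
#' percentage of the reference-defined top q% so captured. The selected
#' count is `k = max(1, round_half_up(q * n / 100))`; ties at the k-th
#' rank are broken deterministically by sample id and flagged.
#'
#' @param predicted predicted analyte values.
#' @param reference aligned reference values.
#' @param cutoff_pct selection cutoff as a percentage of samples (e.g. 5).
#' @param sample_id optional ids used for the deterministic tie-break
#'   (defaults to the sample position).
#' @return list of class `selection_report`: `cutoff_pct`, `k`,
#'   `match_pct` (0-100), `tie_at_boundary` (logical).
#' @export
selection_match <- function(predicted, reference, cutoff_pct,
                            sample_id = NULL) {
  n <- length(reference)
  if (length(predicted) != n) stop("vectors are not aligned", call. = FALSE)
  if (cutoff_pct <= 0 || cutoff_pct >= 100)
    stop("cutoff_pct must be in (0, 100)", call. = FALSE)
  k <- max(1L, as.integer(floor(cutoff_pct * n / 100 + 0.5)))
  if (k >= n) stop("cutoff selects every sample", call. = FALSE)
  if (is.null(sample_id)) sample_id <- seq_len(n)
  ord_pred <- order(-predicted, sample_id)
  ord_ref <- order(-reference, sample_id)
  tie <- isTRUE(predicted[ord_pred[k]] == predicted[ord_pred[k + 1]]) ||
    isTRUE(reference[ord_ref[k]] == reference[ord_ref[k + 1]])
  top_pred <- ord_pred[seq_len(k)]
  top_ref <- ord_ref[seq_len(k)]
  structure(list(cutoff_pct = cutoff_pct, k = k,
                 match_pct = 100 * length(intersect(top_pred, top_ref)) / k,
                 tie_at_boundary = tie),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection %g%% (k=%d): match %.0f%%%s\n", x$cutoff_pct, x$k,
              x$match_pct, if (x$tie_at_boundary) " [tie at boundary]" else ""))
  invisible(x)
}

#' Selection match across several cutoffs
#'
#' @inheritParams selection_match
#' @param cutoffs vector of cutoff percentages (default `c(5, 10, 15)`).
#' @return data.frame with one row per cutoff: `cutoff_pct`, `k`,
#'   `match_pct`, `tie_at_boundary`.
#' @export
selection_curve <- function(predicted, reference, cutoffs = c(5, 10, 15),
                            sample_id = NULL) {
  do.call(rbind, lapply(cutoffs, function(q) {
    r <- selection_match(predicted, reference, q, sample_id)
    data.frame(cutoff_pct = q, k = r$k, match_pct = r$match_pct,
               tie_at_boundary = r$tie_at_boundary)
  }))
}
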