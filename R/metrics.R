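#' Missed-detection rates and diagnostic statistics
#'
#' Evaluation follows a two-level scheme. Per slice `j` of sample `i`, the
#' missed-detection rate is the ratio of manually labeled nodes that the
#' computer failed to mark to the number of manually labeled nodes — once
#' for the permissive *suspected-node* profile (`alpha_{i,j}`) and once for
#' the stricter confirmed-node profile (`beta_{i,j}`). Per sample, the rates
#' are the arithmetic means over its `L` slices:
#' `alpha_i = sum_j alpha_{i,j} / L`, `beta_i = sum_j beta_{i,j} / L`.
#'
#' Slices with zero manual nodes have an undefined 0/0 rate and are excluded
#' from the averages by default; `include_empty = TRUE` instead counts them
#' as rate 0 (a slice on which nothing could be missed).
#'
#' @param sample sample identifier.
#' @param slice slice identifier.
#' @param n_manual manually labeled node count for the slice.
#' @param n_suspected_missed,n_node_missed missed counts under the suspected
#'   and confirmed profiles; each must be `<= n_manual`.
#' @return `slice_evaluation()`: a one-row data.frame; rows from several
#'   slices are stacked with `rbind()`.
#' @export
slice_evaluation <- function(sample, slice, n_manual,
                             n_suspected_missed, n_node_missed) {
  if (n_manual < 0 || n_suspected_missed < 0 || n_node_missed < 0) {
    stop_validation("node counts must be non-negative")
  }
  if (n_suspected_missed > n_manual || n_node_missed > n_manual) {
    stop_validation("missed counts cannot exceed the manual node count")
  }
  data.frame(sample = as.character(sample), slice = as.character(slice),
             n_manual = as.integer(n_manual),
             n_suspected_missed = as.integer(n_suspected_missed),
             n_node_missed = as.integer(n_node_missed))
}

rate_mean <- function(missed, manual, include_empty, what) {
  keep <- manual > 0L
  rates <- missed[keep] / manual[keep]
  if (include_empty) rates <- c(rates, rep(0, sum(!keep)))
  if (length(rates) == 0L) {
    stop_degenerate("undefined %s rate: no slice with manual nodes", what)
  }
  mean(rates)
}

#' @rdname slice_evaluation
#' @param evals a data.frame of slice evaluations for one sample.
#' @param include_empty count zero-manual-node slices as rate 0 instead of
#'   excluding them.
#' @export
missed_rate_suspected <- function(evals, include_empty = FALSE) {
  rate_mean(evals$n_suspected_missed, evals$n_manual, include_empty,
            "suspected-node missed")
}

#' @rdname slice_evaluation
#' @export
missed_rate_nodes <- function(evals, include_empty = FALSE) {
  rate_mean(evals$n_node_missed, evals$n_manual, include_empty,
            "node missed")
}

#' @rdname slice_evaluation
#' @details `evaluate_samples()` aggregates stacked slice evaluations by the
#'   `sample` column into per-sample `alpha` and `beta` rates.
#' @export
evaluate_samples <- function(evals, include_empty = FALSE) {
  if (is.null(evals) || nrow(evals) == 0L) {
    stop_validation("no slice evaluations to aggregate")
  }
  samples <- unique(evals$sample)
  do.call(rbind, lapply(samples, function(s) {
    e <- evals[evals$sample == s, , drop = FALSE]
    data.frame(sample = s, L = nrow(e),
               alpha = missed_rate_suspected(e, include_empty),
               beta = missed_rate_nodes(e, include_empty))
  }))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Standard diagnostic ratios against a gold standard:
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, accuracy
#' `(TP + TN) / (TP + FP + FN + TN)`. Each statistic requires a positive
#' denominator; otherwise an error names the undefined statistic.
#'
#' @param tp,fp,fn,tn non-negative integer confusion counts.
#' @return named list with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' diagnostic_stats(tp = 83, fp = 5, fn = 17, tn = 95)
#' @export
diagnostic_stats <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || anyNA(counts) || any(counts != trunc(counts))) {
    stop_validation("confusion counts must be non-negative integers")
  }
  if (tp + fn == 0) stop_degenerate("sensitivity undefined: TP + FN = 0")
  if (tn + fp == 0) stop_degenerate("specificity undefined: TN + FP = 0")
  if (sum(counts) == 0) stop_degenerate("accuracy undefined: no cases")
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / sum(counts))
}

#' Combine per-case CT sign calls
#'
#' Joint detection of several binary CT signs (for gastric tumours:
#' disappearance of gastric wall motility, perigastric fat infiltration,
#' enhancement type) under a Boolean rule. `"any"` calls a case positive
#' when at least one sign fires (the highest-sensitivity reading of joint
#' detection and the default), `"all"` when every sign fires, `"majority"`
#' when more than half do.
#'
#' @param signs a logical matrix (cases in rows, signs in columns) or a list
#'   of equal-length logical vectors, one per sign.
#' @param rule `"any"`, `"all"` or `"majority"`.
#' @return a logical vector of combined per-case calls.
#' @export
combine_signs <- function(signs, rule = c("any", "all", "majority")) {
  rule <- match.arg(rule)
  if (is.list(signs)) {
    len <- unique(lengths(signs))
    if (length(signs) == 0L || length(len) != 1L) {
      stop_validation("sign vectors must be non-empty and of equal length")
    }
    signs <- do.call(cbind, signs)
  }
  if (!is.matrix(signs) || !is.logical(signs) || nrow(signs) == 0L ||
      ncol(signs) == 0L || anyNA(signs)) {
    stop_validation("signs must be a non-empty logical matrix without NAs")
  }
  pos <- rowSums(signs)
  switch(rule,
         any = pos > 0L,
         all = pos == ncol(signs),
         majority = pos > ncol(signs) / 2)
}
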