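#' Metric report container
#'
#' @param protocol one of `"merged_fold"`, `"holdout"`, `"per_allele"`.
#' @param metrics named numeric vector/list of metric values; undefined
#'   metrics are `NA` and named in `notes`.
#' @param n number of (prediction, label) pairs evaluated.
#' @param notes free-text notes (undefined metrics, skips).
#' @return object of class `tl_metric_report`.
#' @export
metric_report <- function(protocol = c("holdout", "merged_fold", "per_allele"),
                          metrics, n, notes = "") {
  protocol <- match.arg(protocol)
  structure(list(protocol = protocol, metrics = as.list(metrics),
                 n = as.integer(n), notes = notes),
            class = "tl_metric_report")
}

#' @export
print.tl_metric_report <- function(x, ...) {
  cat(sprintf("metric report (%s protocol, n = %d)\n", x$protocol, x$n))
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.na(v)) "undefined" else format(v, digits = 5)))
  }
  if (nzchar(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

flag_undefined <- function(reason) {
  structure(NA_real_, undefined = reason)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1,1\], or a flagged `NA` (attribute
#'   `undefined`) when either vector has zero variance.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) return(flag_undefined("zero variance"))
  cor(x, y, method = "pearson")
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau: `(C - D) / sqrt((T0 - Tx)(T0 - Ty))` over all
#' pairs, as computed by [stats::cor()].
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in \[-1,1\], or flagged `NA` when a vector is fully
#'   tied.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(flag_undefined("all values tied"))
  }
  cor(x, y, method = "kendall")
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic with midranks for
#' ties.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (0/1, logical, or `"hit"`/`"decoy"`).
#' @return AUROC in \[0,1\], or flagged `NA` with a single class.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) return(flag_undefined("single class"))
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.character(labels)) return(as.integer(labels %in% c("hit", "1", "positive")))
  as.integer(as.numeric(labels) >= 0.5)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation (no linear segments) with ties grouped by
#' score, so the value is bit-reproducible. The no-skill baseline — the
#' positive fraction — is attached as attribute `baseline`.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels.
#' @return AUPRC in \[0,1\] with attribute `baseline`, or flagged `NA`
#'   with a single class.
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L)
  if (n_pos == 0L || n_pos == length(y)) return(flag_undefined("single class"))
  o <- order(scores, decreasing = TRUE, method = "radix")
  y <- y[o]; s <- scores[o]
  # group tied scores: precision/recall evaluated at each group boundary
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  pred_pos <- grp_end
  precision <- tp / pred_pos
  recall <- tp / n_pos
  area <- sum(diff(c(0, recall)) * precision)
  structure(area, baseline = n_pos / length(y))
}

#' Count positives among the top-N scored items
#'
#' Ties at the cut are broken by stable sort on (score descending,
#' input order), so the result is deterministic.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param n list depth (e.g. 20 or 50, the sizes used when selecting
#'   peptides for a personalized treatment).
#' @return integer count of positives in the top `n`.
#' @export
top_n_count <- function(scores, labels, n) {
  if (n <= 0L) stop("n must be positive")
  if (n > length(scores)) stop("n exceeds the number of items")
  y <- as_binary_labels(labels)
  o <- order(scores, decreasing = TRUE, method = "radix")
  sum(y[o[seq_len(n)]])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum gap between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample formula.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Merged-fold evaluation
#'
#' Concatenates the left-out test predictions and labels of all folds
#' into one set and computes the metrics once on the concatenation —
#' never averaging per-fold coefficients, whose skewed sampling
#' distribution biases the mean (and Fisher's z over-corrects).
#'
#' @param fold_predictions,fold_labels lists (one element per fold) of
#'   numeric vectors.
#' @param fold_indices optional list of the record indices each fold
#'   covers; must be pairwise disjoint.
#' @param metrics named list of metric functions `(pred, label) ->
#'   numeric` (default merged-fold Pearson and Kendall tau-b).
#' @return a [metric_report()] with protocol `"merged_fold"` and `n`
#'   equal to the total dataset size.
#' @export
merged_fold_eval <- function(fold_predictions, fold_labels,
                             fold_indices = NULL,
                             metrics = list(pearson = pearson,
                                            kendall_tau_b = kendall_tau_b)) {
  stopifnot(length(fold_predictions) == length(fold_labels))
  if (!is.null(fold_indices)) {
    all_idx <- unlist(fold_indices)
    if (anyDuplicated(all_idx)) {
      stop("fold index sets overlap: records must appear in exactly one fold")
    }
  }
  pred <- unlist(fold_predictions)
  lab <- unlist(fold_labels)
  vals <- lapply(metrics, function(f) f(pred, lab))
  undef <- names(vals)[vapply(vals, is.na, logical(1L))]
  metric_report("merged_fold", lapply(vals, as.numeric), n = length(pred),
                notes = if (length(undef))
                  paste("undefined:", paste(undef, collapse = ", ")) else "")
}

#' Threshold-mean response curve
#'
#' For each threshold, the mean response over records whose
#' affinity-like value is *strictly better* than the threshold —
#' "better" meaning smaller for `lower_is_better` quantities (nM, ED50)
#' and larger for `higher_is_better` ones (model scores). This is the
#' curve relating affinity cutoffs to mean stability: tighter affinity
#' thresholds select pools of peptides with higher mean stability.
#' Thresholds selecting no records yield `NA` means, never 0.
#'
#' @param affinity_like numeric per-record affinity-type values.
#' @param response numeric per-record response (e.g. stability).
#' @param thresholds sorted numeric thresholds.
#' @param orientation `"lower_is_better"` or `"higher_is_better"`.
#' @return object of class `tl_threshold_curve`: data frame with
#'   columns `threshold`, `mean_response`, `count`.
#' @export
threshold_mean_curve <- function(affinity_like, response, thresholds,
                                 orientation = c("lower_is_better",
                                                 "higher_is_better")) {
  orientation <- match.arg(orientation)
  stopifnot(length(affinity_like) == length(response))
  if (is.unsorted(thresholds)) stop("thresholds must be sorted increasing")
  rows <- lapply(thresholds, function(th) {
    sel <- if (orientation == "lower_is_better") affinity_like < th
           else affinity_like > th
    data.frame(threshold = th,
               mean_response = if (any(sel)) mean(response[sel]) else NA_real_,
               count = sum(sel))
  })
  out <- do.call(rbind, rows)
  attr(out, "orientation") <- orientation
  class(out) <- c("tl_threshold_curve", "data.frame")
  out
}

#' Per-allele metric reports
#'
#' Computes the supplied metrics within each allele; alleles with fewer
#' than two records cannot support the correlation metrics and are
#' reported as skipped.
#'
#' @param alleles character vector of allele names (one per record).
#' @param scores,labels numeric vectors.
#' @param metrics named list of metric functions.
#' @return named list: one [metric_report()] per evaluated allele, plus
#'   attribute `skipped` naming alleles skipped and why.
#' @export
per_allele_report <- function(alleles, scores, labels,
                              metrics = list(pearson = pearson,
                                             kendall_tau_b = kendall_tau_b)) {
  alleles <- normalize_allele(alleles)
  out <- list()
  skipped <- character(0)
  for (al in unique(alleles)) {
    sel <- alleles == al
    if (sum(sel) < 2L) {
      skipped[al] <- "fewer than 2 records"
      next
    }
    vals <- lapply(metrics, function(f) f(scores[sel], labels[sel]))
    undef <- names(vals)[vapply(vals, is.na, logical(1L))]
    out[[al]] <- metric_report("per_allele", lapply(vals, as.numeric),
                               n = sum(sel),
                               notes = if (length(undef))
                                 paste("undefined:", paste(undef, collapse = ", ")) else "")
  }
  attr(out, "skipped") <- skipped
  out
}
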