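#' Stratification keys for cross-validation
#'
#' Discretizes a label vector into strata. Binary and categorical labels
#' stratify on their values; continuous labels are cut into quantile
#' bins (default 4), with exact zeros (the random-negative label) kept
#' as their own stratum so unstable-by-construction records spread
#' evenly across folds.
#'
#' @param labels numeric or character label vector.
#' @param n_bins quantile bins for continuous labels (default 4).
#' @return character vector of stratum ids.
#' @export
stratify_labels <- function(labels, n_bins = 4L) {
  if (is.character(labels) || is.factor(labels) ||
      length(unique(labels)) <= n_bins) {
    return(as.character(labels))
  }
  out <- character(length(labels))
  zero <- !is.na(labels) & labels == 0
  out[zero] <- "zero"
  pos <- labels[!zero]
  qs <- unique(quantile(pos, probs = seq(0, 1, length.out = n_bins + 1L)))
  out[!zero] <- paste0("q", as.integer(cut(pos, qs, include.lowest = TRUE)))
  out
}

#' Stratified k-fold assignment
#'
#' Partitions record indices into `k` disjoint, exhaustive folds with
#' per-fold stratum counts deviating from `n_stratum / k` by less than
#' one: within each stratum, indices are shuffled and dealt round-robin
#' starting from a rotating offset.
#'
#' @param labels label vector (one entry per record); continuous labels
#'   are binned via [stratify_labels()].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param n_bins quantile bins for continuous stratification.
#' @return object of class `tl_fold_plan`: list with `k`, `assignment`
#'   (integer fold id per record, 1..k), `strata`, `seed`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L, n_bins = 4L) {
  if (k < 2L) stop("k must be >= 2")
  n <- length(labels)
  if (k > n) stop("k exceeds the number of records")
  strata <- stratify_labels(labels, n_bins)
  rng <- local_rng(seed)
  assignment <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    assignment[idx] <- folds
    offset <- (offset + length(idx)) %% k
  }
  rng()
  structure(list(k = k, assignment = assignment, strata = strata, seed = seed),
            class = "tl_fold_plan")
}

#' @export
print.tl_fold_plan <- function(x, ...) {
  cat("stratified fold plan: k =", x$k, ", n =", length(x$assignment),
      ", strata =", length(unique(x$strata)), "\n")
  print(table(fold = x$assignment))
  invisible(x)
}

#' Stratified train/validation split within a training fold
#'
#' Splits indices into a training part and a validation part of
#' fraction `val_fraction`, stratified on `labels`. Strata too small to
#' appear in both parts contribute to training only (with a warning).
#'
#' @param labels label vector for the records being split.
#' @param val_fraction validation fraction in (0, 1), e.g. 0.1 for a
#'   90/10 split or 0.2 for 80/20.
#' @param seed integer seed.
#' @param n_bins quantile bins for continuous stratification.
#' @return list with integer index vectors `train` and `val`.
#' @export
nested_split <- function(labels, val_fraction, seed = 1L, n_bins = 4L) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie strictly between 0 and 1")
  }
  strata <- stratify_labels(labels, n_bins)
  rng <- local_rng(seed)
  val <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_val <- round(length(idx) * val_fraction)
    if (n_val == 0L || n_val == length(idx)) {
      if (length(idx) > 1L) n_val <- max(n_val, 0L)
      if (n_val >= length(idx)) n_val <- length(idx) - 1L
      if (n_val == 0L) {
        warning("stratum '", s, "' too small to split; assigned to train")
        next
      }
    }
    val <- c(val, idx[sample.int(length(idx), n_val)])
  }
  rng()
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Serialize / deserialize a fold plan
#'
#' Written as TSV with columns `record_index`, `fold_id`, `stratum`.
#'
#' @param plan a `tl_fold_plan`.
#' @param path file path.
#' @return `read_fold_plan()`: a `tl_fold_plan` (seed not recoverable,
#'   stored as NA).
#' @export
write_fold_plan <- function(plan, path) {
  df <- data.frame(record_index = seq_along(plan$assignment),
                   fold_id = plan$assignment, stratum = plan$strata)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  df <- read.delim(path)
  structure(list(k = max(df$fold_id), assignment = df$fold_id,
                 strata = as.character(df$stratum), seed = NA_integer_),
            class = "tl_fold_plan")
}
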