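test_that("pearson matches the textbook formula and flags degenerate input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), oracle)
  expect_equal(pearson(x, y), 0.8)
  flagged <- pearson(rep(1, 5), 1:5)
  expect_true(is.na(flagged))
  expect_equal(attr(flagged, "undefined"), "zero variance")
})

test_that("kendall tau-b matches brute-force pair enumeration on random fixtures", {
  expect_equal(kendall_tau_b(1:6, 1:6), 1)
  expect_equal(kendall_tau_b(1:6, 6:1), -1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6,
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    x <- sample(1:7, n, replace = TRUE)   # heavy ties
    y <- if (i %% 2) sample(1:7, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y), brute_tau_b(x, y), tolerance = 1e-12)
  }
  expect_true(is.na(kendall_tau_b(rep(2, 4), 1:4)))
})

test_that("auroc equals the Mann-Whitney pair fraction and handles ties", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    s <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    expect_equal(auroc(s, y), brute_auroc(s, y), tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auroc(1:4, rep(1, 4))))
})

test_that("auroc agrees with pROC on a random fixture", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(200, 1, 0.3)
  s <- rnorm(200) + y
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("auprc is exact on hand-checkable fixtures and carries its baseline", {
  # perfect separation
  expect_equal(as.numeric(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1)
  expect_equal(attr(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), "baseline"), 0.5)
  # ranking 1,0,1,0 by descending score: recall reaches 1/2 at precision 1
  # (first item) and 1 at precision 2/3 (two of the top three are hits)
  expect_equal(as.numeric(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))),
               0.5 * 1 + 0.5 * (2 / 3))
  # all scores tied: single group, precision = positive fraction
  expect_equal(as.numeric(auprc(rep(0.5, 10), rep(c(1, 0), 5))), 0.5)
  expect_true(is.na(auprc(1:4, rep(0, 4))))
})

test_that("auprc of random scores approaches the positive fraction", {
  set.seed(16)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.3)
  a <- auprc(scores, labels)
  expect_lt(abs(as.numeric(a) - 0.3), 0.02)
  expect_equal(attr(a, "baseline"), mean(labels))
})

test_that("top-N counting is exact under a brute-force sort with stable ties", {
  scores <- c(5, 4, 4, 3, 2, 2, 2, 1, 0.5, 0)
  labels <- c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0)
  for (n in c(1, 3, 5, 10)) {
    o <- order(scores, decreasing = TRUE, method = "radix")
    expect_equal(top_n_count(scores, labels, n), sum(labels[o[seq_len(n)]]))
  }
  expect_equal(top_n_count(scores, labels, 4), 3)
  # all positives first
  expect_equal(top_n_count(10:1, c(rep(1, 6), rep(0, 4)), 5), 5)
  expect_equal(top_n_count(10:1, rep(0, 10), 5), 0)
  # ties at the cut resolved by input order
  expect_equal(top_n_count(c(1, 1, 1), c(0, 1, 1), 1), 0)
  expect_error(top_n_count(scores, labels, 0), "positive")
  expect_error(top_n_count(scores, labels, 11), "exceeds")
})

test_that("two-sample KS D matches exhaustive ECDF evaluation", {
  a <- c(1, 2, 3); b <- c(1.5, 2.5, 3.5)
  ks <- ks_two_sample(a, b)
  expect_equal(ks$D, brute_ks_D(a, b))
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = 0.5)
    expect_equal(ks_two_sample(x, y)$D, brute_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("merged-fold evaluation concatenates instead of averaging", {
  # two folds, each perfectly predicted on its own scale
  lab1 <- 1:5; pred1 <- 1:5
  lab2 <- 6:10; pred2 <- (6:10) - 10
  expect_equal(pearson(pred1, lab1), 1)
  expect_equal(pearson(pred2, lab2), 1)
  rep <- merged_fold_eval(list(pred1, pred2), list(lab1, lab2),
                          fold_indices = list(1:5, 6:10))
  expect_lt(rep$metrics$pearson, 1)
  expect_equal(rep$n, 10)
  expect_equal(rep$protocol, "merged_fold")
  # single fold degenerates to holdout
  one <- merged_fold_eval(list(pred1), list(lab1))
  expect_equal(one$metrics$pearson, 1)
  expect_error(merged_fold_eval(list(pred1, pred2), list(lab1, lab2),
                                fold_indices = list(1:5, 5:9)), "overlap")
})

test_that("threshold-mean curves respect orientation, strictness, and emptiness", {
  aff <- c(10, 100, 1000, 10000)
  resp <- c(4, 3, 2, 1)
  cur <- threshold_mean_curve(aff, resp, c(5, 100, 500, 50000),
                              orientation = "lower_is_better")
  expect_true(is.na(cur$mean_response[1]))  # nothing strictly below 5
  expect_equal(cur$count[1], 0)
  expect_equal(cur$mean_response[2], 4)     # only aff=10 < 100 (strict)
  expect_equal(cur$mean_response[4], mean(resp))
  expect_equal(cur$mean_response[3], mean(c(4, 3)))  # 10 and 100 < 500
  expect_equal(cur$count, c(0, 1, 2, 4))
  hi <- threshold_mean_curve(aff, resp, c(50, 5000),
                             orientation = "higher_is_better")
  expect_equal(hi$mean_response, c(mean(c(3, 2, 1)), 1))
  expect_error(threshold_mean_curve(aff, resp, c(100, 5)), "sorted")
})

test_that("per-allele reports match global metrics for one allele and skip singletons", {
  scores <- c(0.1, 0.4, 0.7, 0.9)
  labels <- c(1, 2, 3, 5)
  rep1 <- per_allele_report(rep("HLA-A*02:01", 4), scores, labels)
  expect_length(rep1, 1)
  expect_equal(rep1[["HLA-A*02:01"]]$metrics$pearson, pearson(scores, labels))
  mixed <- per_allele_report(c(rep("HLA-A*02:01", 4), "HLA-B*07:02"),
                             c(scores, 0.5), c(labels, 1))
  expect_named(attr(mixed, "skipped"), "HLA-B*07:02")
  # opposite orientations produce opposite per-allele correlation signs
  two <- per_allele_report(rep(c("HLA-A*02:01", "HLA-B*07:02"), each = 4),
                           c(scores, scores), c(labels, -labels))
  expect_gt(two[["HLA-A*02:01"]]$metrics$pearson, 0)
  expect_lt(two[["HLA-B*07:02"]]$metrics$pearson, 0)
})
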