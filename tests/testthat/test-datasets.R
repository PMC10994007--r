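make_stab_records <- function(n = 10, seed = 1) {
  pmhc_records(random_aa_string(n, 9, seed), "HLA-A*02:01", "STAB",
               half_life_hours = seq_len(n) / 2)
}

test_that("record tables round-trip through TSV with field values intact", {
  recs <- pmhc_records(random_aa_string(100, 9, 3),
                       rep(c("HLA-A*02:01", "HLA-B*07:02"), 50), "IMM",
                       imm_label = rep(0:1, 50),
                       recognition_frequency = round(runif(100), 3),
                       source = "unit")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records(recs, f)
  back <- read_records(f, "IMM")
  expect_equal(back$peptide, recs$peptide)
  expect_equal(back$allele, recs$allele)
  expect_equal(back$imm_label, recs$imm_label)
  expect_equal(back$recognition_frequency, recs$recognition_frequency)
})

test_that("schema and numeric parsing errors are specific", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele", "SIINFEKLM\tHLA-A*02:01"), f)
  expect_error(read_records(f, "BA"), "affinity_nm")
  writeLines(c("peptide\tallele\thalf_life_hours",
               "SIINFEKLM\tHLA-A*02:01\t1.5",
               "KLGGALQAK\tHLA-A*02:01\tabc"), f)
  expect_error(read_records(f, "STAB"), "line 3")
})

test_that("record validation enforces task label domains", {
  expect_error(pmhc_records("SIINFEKLM", "HLA-A*02:01", "BA",
                            affinity_nm = -1), "affinity_nm")
  expect_error(pmhc_records("SIINFEKLM", "HLA-A*02:01", "IMM",
                            imm_label = 1.5), "imm_label")
  expect_error(pmhc_records("SIINFEKLM", "HLA-A*02:01", "EL",
                            el_label = "maybe"), "el_label")
})

test_that("affinity transform hits its anchor points and inverts", {
  expect_equal(transform_affinity(50000), 0)
  expect_equal(transform_affinity(1), 1)
  # closed form: 1 - ln(500)/ln(50000)
  expect_equal(transform_affinity(500), 0.4256251898, tolerance = 1e-9)
  nm <- c(3, 50, 500, 5000, 49999)
  expect_equal(inverse_affinity(transform_affinity(nm)), nm, tolerance = 1e-9)
  expect_true(all(diff(transform_affinity(nm)) < 0))
  expect_error(transform_affinity(0), "> 0")
})

test_that("half-life transform is anchored, monotone, and invertible", {
  expect_equal(transform_half_life(0, h0 = 2), 0)
  expect_equal(transform_half_life(2, h0 = 2), 0.5)
  h <- c(0.1, 1, 4, 20)
  expect_true(all(diff(transform_half_life(h, 1)) > 0))
  expect_equal(inverse_half_life(transform_half_life(h, 3), 3), h,
               tolerance = 1e-12)
  expect_error(transform_half_life(-1), ">= 0")
})

test_that("decoy generation yields per_hit decoys per hit, seeded and hit-free", {
  hits <- pmhc_records(random_aa_string(5, 9, 11), "HLA-A*02:01", "EL",
                       el_label = "hit")
  prot <- setNames(random_aa_string(4, 300, 12),
                   paste0("P", 1:4))
  d1 <- generate_decoys(hits, prot, per_hit = 99, seed = 5)
  expect_equal(nrow(d1), 5 * 99)
  expect_true(all(d1$el_label == "decoy"))
  expect_true(all(nchar(d1$peptide) == 9))
  expect_false(any(d1$peptide %in% hits$peptide))
  d2 <- generate_decoys(hits, prot, per_hit = 99, seed = 5)
  expect_identical(d1, d2)
  d3 <- generate_decoys(hits, prot, per_hit = 99, seed = 6)
  expect_false(identical(d1$peptide, d3$peptide))
})

test_that("decoy lengths follow the hits' length distribution", {
  hits <- pmhc_records(c(random_aa_string(6, 9, 21), random_aa_string(2, 11, 22)),
                       "HLA-B*07:02", "EL", el_label = "hit")
  prot <- setNames(random_aa_string(3, 400, 23), paste0("Q", 1:3))
  d <- generate_decoys(hits, prot, per_hit = 50, seed = 1)
  expect_setequal(unique(nchar(d$peptide)), c(9, 11))
  # 3:1 hit length ratio should be roughly preserved
  frac9 <- mean(nchar(d$peptide) == 9)
  expect_gt(frac9, 0.6)
  expect_lt(frac9, 0.9)
})

test_that("strong-binder filter keeps strictly sub-threshold scores in order", {
  recs <- make_stab_records(3)
  kept <- strong_binder_filter(recs, c(100, 600, 499), filter_config())
  expect_equal(nrow(kept), 2)
  expect_equal(kept$peptide, recs$peptide[c(1, 3)])
  expect_equal(nrow(strong_binder_filter(recs[0, ], numeric(0))), 0)
  expect_equal(nrow(strong_binder_filter(recs, c(500, 700, 20000))), 0)
  expect_error(strong_binder_filter(recs, c(1, 2)), "one score per record")
})

test_that("random negatives carry zero half-life and super-threshold affinity", {
  stab <- make_stab_records(6)
  cand <- data.frame(peptide = random_aa_string(50, 9, 31),
                     allele = "HLA-A*02:01",
                     predicted_nm = seq(15000, 39500, by = 500))
  out <- add_random_negatives(stab, cand, n = 10, seed = 2)
  neg <- out[out$is_random_negative, ]
  expect_equal(nrow(neg), 10)
  expect_true(all(neg$half_life_hours == 0))
  expect_true(all(cand$predicted_nm[match(neg$peptide, cand$peptide)] > 20000))
  out2 <- add_random_negatives(stab, cand, n = 10, seed = 2)
  expect_identical(out, out2)
  expect_error(add_random_negatives(stab, cand, n = 100), "shortfall")
})

test_that("per-allele balancing subsamples the majority class to the target", {
  recs <- pmhc_records(random_aa_string(40, 9, 41), "HLA-A*02:01", "IMM",
                       imm_label = rep(c(1, 0), c(10, 30)))
  bal <- balance_per_allele(recs, 0.5, seed = 1)
  expect_equal(sum(bal$imm_label == 1), 10)
  expect_equal(sum(bal$imm_label == 0), 10)
  # already at target: untouched
  at <- pmhc_records(random_aa_string(20, 9, 42), "HLA-B*07:02", "IMM",
                     imm_label = rep(c(1, 0), 10))
  expect_equal(nrow(balance_per_allele(at, 0.5, seed = 1)), 20)
  # single-class allele dropped with a warning
  onecls <- pmhc_records(random_aa_string(5, 9, 43), "HLA-C*07:01", "IMM",
                         imm_label = 1)
  expect_warning(out <- balance_per_allele(rbind(at, onecls), 0.5, seed = 1),
                 "lacks one class")
  expect_false("HLA-C*07:01" %in% out$allele)
})

test_that("balancing never oversamples and lands within integer granularity", {
  set.seed(77)
  for (i in 1:5) {
    n_pos <- sample(5:40, 1); n_neg <- sample(5:40, 1)
    t <- runif(1, 0.25, 0.75)
    recs <- pmhc_records(random_aa_string(n_pos + n_neg, 9, 50 + i),
                         "HLA-A*01:01", "IMM",
                         imm_label = rep(c(1, 0), c(n_pos, n_neg)))
    bal <- balance_per_allele(recs, t, seed = i)
    expect_lte(sum(bal$imm_label == 1), n_pos)
    expect_lte(sum(bal$imm_label == 0), n_neg)
    expect_lte(abs(mean(bal$imm_label) - t), 1 / nrow(bal))
  }
})

test_that("continuous relabelling preserves thresholded binary labels", {
  recs <- pmhc_records(random_aa_string(4, 9, 61), "HLA-A*02:01", "IMM",
                       imm_label = c(1, 0, 1, 0))
  out <- relabel_continuous(recs, c(0.9, 0.3, 0.6, 0.1))
  expect_equal(out$imm_label, c(0.9, 0.3, 0.6, 0.1))
  expect_equal(as.integer(out$imm_label >= 0.5), recs$imm_label)
  expect_identical(relabel_continuous(recs, recs$imm_label)$imm_label,
                   recs$imm_label)
  expect_error(relabel_continuous(recs, c(0.5, 0.5, 0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dedup removes shared pairs case-insensitively and idempotently", {
  train <- pmhc_records(c("SIINFEKLM", "KLGGALQAK", "GLCTLVAML"),
                        "HLA-A*02:01", "STAB", half_life_hours = 1:3)
  eval1 <- pmhc_records("siinfeklm", "HLA-A0201", "STAB", half_life_hours = 9)
  out <- dedup_against(train, eval1)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "removed"), 1L)
  again <- dedup_against(out, eval1)
  expect_equal(again$peptide, out$peptide)
  expect_equal(attr(again, "removed"), 0L)
  disjoint <- pmhc_records("AAAAAAAAA", "HLA-B*07:02", "STAB",
                           half_life_hours = 1)
  expect_equal(nrow(dedup_against(train, disjoint)), 3)
})
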