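# Shared small synthetic world for the pipeline tests: one pretrained
# model, a stability set, and an immunogenicity set.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config(n_alleles = 3, peptides_per_allele = 400,
                        n_proteins = 40, decoys_per_hit = 4, seed = 12)
    al <- make_alleles(cfg)
    tab <- synth_pseudosequence_table(al)
    sim <- simulate_binding(cfg, al)
    pcfg <- pipeline_config(
      max_len = 9, hidden = c(16, 8), decoys_per_hit = 4,
      train = train_config(1e-3, 128, max_epochs = 5, patience = 3, seed = 12),
      seed = 12, out_dir = file.path(tempdir(), "tlmhc-pipe"))
    pre <- run_pretraining(pcfg, sim$ba, sim$el, proteome = sim$proteome,
                           pseudo_table = tab)
    cfg_stab <- cfg; cfg_stab$seed <- 13
    cfg_stab$peptides_per_allele <- 250
    stab <- simulate_stability(cfg_stab, al, simulate_binding(cfg_stab, al))
    cfg_imm <- cfg; cfg_imm$seed <- 14
    cfg_imm$peptides_per_allele <- 120
    imm <- simulate_immunogenicity(cfg_imm, al)
    cache <<- list(cfg = cfg, pcfg = pcfg, alleles = al, tab = tab,
                   pre = pre, stab = stab, imm = imm)
    cache
  }
})

test_that("pretraining runs end to end, archives its artifacts, and reproduces", {
  fx <- pipeline_fixture()
  expect_s3_class(fx$pre$model, "tl_predictor")
  expect_setequal(names(fx$pre$model$heads), c("BA", "EL"))
  expect_gte(fx$pre$removed, 0)
  expect_true(file.exists(file.path(fx$pcfg$out_dir, "pretrained.json")))
  expect_true(file.exists(file.path(fx$pcfg$out_dir,
                                    "pretraining_manifest.json")))
  # reruns with the same seed reproduce the validation-loss trajectory
  sim <- simulate_binding(fx$cfg, fx$alleles)
  cfg2 <- fx$pcfg; cfg2$out_dir <- NULL
  again <- run_pretraining(cfg2, sim$ba, sim$el, proteome = sim$proteome,
                           pseudo_table = fx$tab)
  expect_equal(again$model$training_log$val_loss,
               fx$pre$model$training_log$val_loss)
})

test_that("pretraining removes evaluation-set overlap and reports the count", {
  fx <- pipeline_fixture()
  sim <- simulate_binding(fx$cfg, fx$alleles)
  holdout <- sim$ba[1:25, ]
  cfg2 <- fx$pcfg; cfg2$out_dir <- NULL
  out <- run_pretraining(cfg2, sim$ba, sim$el, proteome = sim$proteome,
                         pseudo_table = fx$tab, eval_sets = holdout)
  expect_gte(out$removed, 25)
  expect_equal(out$log$n_ba, nrow(sim$ba) - 25)
})

test_that("the stability pipeline yields a 10-member ensemble with single-fold predictions", {
  fx <- pipeline_fixture()
  cfg <- fx$pcfg
  cfg$finetune <- train_config(1e-4, 64, max_epochs = 3, patience = 3, seed = 12)
  res <- run_stability_pipeline(cfg, fx$pre$model, fx$stab, fx$tab)
  expect_length(res$ensemble, 10)
  expect_equal(res$fold_plan$k, 10)
  expect_false(anyNA(res$predictions))
  expect_equal(res$report$n, nrow(fx$stab))
  expect_true(all(c("pearson", "kendall_tau_b") %in% names(res$report$metrics)))
  # every record sits in exactly one fold
  expect_equal(sort(unname(unlist(split(seq_len(nrow(fx$stab)),
                                        res$fold_plan$assignment)))),
               seq_len(nrow(fx$stab)))
  expect_true(file.exists(file.path(cfg$out_dir, "fold_plan_stab.tsv")))
  expect_true(file.exists(file.path(cfg$out_dir, "stab_member_10.json")))
})

test_that("the immunogenicity pipeline archives a 5-fold plan and its metrics", {
  fx <- pipeline_fixture()
  cfg <- fx$pcfg
  cfg$finetune <- train_config(1e-4, 64, max_epochs = 3, patience = 3, seed = 12)
  res <- run_immunogenicity_pipeline(cfg, fx$pre$model, fx$imm, fx$tab)
  expect_length(res$ensemble, 5)
  expect_equal(res$fold_plan$k, 5)
  expect_false(anyNA(res$predictions))
  expect_true(all(c("auroc", "auprc", "auprc_baseline", "top_20", "top_50",
                    "recognition_pearson", "recognition_kendall")
                  %in% names(res$report$metrics)))
  expect_equal(res$report$metrics$auprc_baseline,
               mean(fx$imm$imm_label >= 0.5))
  plan_file <- file.path(cfg$out_dir, "fold_plan_imm.tsv")
  expect_true(file.exists(plan_file))
  expect_equal(read_fold_plan(plan_file)$k, 5)
  manifest <- jsonlite::read_json(file.path(cfg$out_dir, "imm_manifest.json"))
  expect_equal(manifest$val_fraction, 0.2)
})

test_that("the balanced variant equalizes training folds; continuous keeps real labels", {
  fx <- pipeline_fixture()
  cfg <- fx$pcfg
  cfg$out_dir <- NULL
  cfg$finetune <- train_config(1e-4, 64, max_epochs = 2, patience = 2, seed = 12)
  cfg$balanced <- TRUE
  imb <- fx$cfg; imb$seed <- 15; imb$peptides_per_allele <- 150
  imb$per_allele_imbalance <- setNames(c(0.8, 0.3, 0.5),
                                       names(fx$tab))
  recs <- simulate_immunogenicity(imb, fx$alleles)
  res <- run_stability_or_null <- run_immunogenicity_pipeline(
    cfg, fx$pre$model, recs, fx$tab)
  expect_length(res$ensemble, 5)
  # the balancing op itself equalizes per-allele fractions on these records
  bal <- balance_per_allele(recs, 0.5, seed = 1)
  fr <- tapply(bal$imm_label, bal$allele, mean)
  expect_true(all(abs(fr - 0.5) <= 0.05))
  cfg$balanced <- FALSE
  cfg$continuous <- TRUE
  res_c <- run_immunogenicity_pipeline(cfg, fx$pre$model, recs, fx$tab)
  expect_length(res_c$ensemble, 5)
})

test_that("nested splits never leak a fold's test records into its training", {
  fx <- pipeline_fixture()
  plan <- stratified_kfold(fx$stab$half_life_hours, 10, seed = 12)
  for (f in 1:3) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    split <- nested_split(fx$stab$half_life_hours[train_idx], 0.1,
                          seed = 112 + f)
    used <- train_idx[c(split$train, split$val)]
    expect_length(intersect(used, test_idx), 0)
    expect_setequal(used, train_idx)
  }
})

test_that("predict_table scores the full peptide-allele grid and flags unknowns", {
  fx <- pipeline_fixture()
  peps <- c("SIINFEKLM", "KLGGALQAK", "GLCTLVAML")
  out <- predict_table(fx$pre$model, peps, names(fx$tab)[1:2], fx$tab, "BA",
                       max_len = 9)
  expect_equal(nrow(out), 6)
  expect_false(anyNA(out$score))
  expect_true(all(is.na(out$error)))
  expect_true(all(out$affinity_nm > 0 & out$affinity_nm <= 50000))
  # ensembles average their members
  ens <- list(fx$pre$model, fx$pre$model)
  out2 <- predict_table(ens, peps, names(fx$tab)[1], fx$tab, "EL",
                        max_len = 9, expand = TRUE)
  one <- predict_table(fx$pre$model, peps, names(fx$tab)[1], fx$tab, "EL",
                       max_len = 9, expand = TRUE)
  expect_equal(out2$score, one$score)
  # unsupported alleles get per-row errors while the rest are scored
  mixed <- predict_table(fx$pre$model, peps, c(names(fx$tab)[1], "HLA-A*99:01"),
                         fx$tab, "BA", max_len = 9)
  expect_equal(sum(is.na(mixed$score)), 3)
  expect_equal(unique(mixed$error[is.na(mixed$score)]), "unsupported allele")
  expect_false(anyNA(mixed$score[is.na(mixed$error)]))
})
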