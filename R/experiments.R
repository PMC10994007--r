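#' Transfer-benefit experiment
#'
#' The mechanism check behind the whole framework: initializing a
#' downstream predictor's weights with binding information and
#' fine-tuning them on the small downstream dataset should generalize
#' better than training the same architecture from scratch — provided
#' the downstream signal is actually coupled to binding.
#'
#' One binding predictor is pretrained on a large simulated
#' binding-affinity / eluted-ligand set; then, for each of `replicates`
#' seeded replicates, a small downstream training set and a held-out
#' test set are freshly simulated and two arms are trained under
#' identical budgets:
#' * fine-tuned: [finetune()] with `unfreeze_all` from the pretrained
#'   model (BA head for stability, EL head for immunogenicity);
#' * scratch: [init_model()] with the same architecture.
#'
#' Held-out performance is Kendall tau-b for stability and AUPRC for
#' immunogenicity.
#'
#' @param cfg a [synth_config()]; `stability_coupling` /
#'   `imm_coupling` set the strength of the transferable signal.
#' @param task `"stability"` or `"immunogenicity"`.
#' @param replicates number of seeded replicates (default 10).
#' @param pretrain_total approximate pretraining set size (BA + EL
#'   records; default 50,000).
#' @param downstream_n downstream training records per replicate
#'   (default 500).
#' @param test_n held-out records per replicate (default 1,000).
#' @param hidden architecture used by both arms (default `c(32, 16)`).
#' @param pretrain_cfg,finetune_cfg,scratch_cfg optional
#'   [train_config()] overrides; fine-tuning defaults to 1/10 of the
#'   pretraining learning rate.
#' @return list of class `tl_transfer_report`: `results` (data frame
#'   with per-replicate `finetuned` and `scratch` metrics), `wins`
#'   (replicates where fine-tuning strictly wins), `metric`, `task`.
#' @export
transfer_benefit_experiment <- function(cfg = synth_config(),
                                        task = c("stability", "immunogenicity"),
                                        replicates = 10L,
                                        pretrain_total = 50000L,
                                        downstream_n = 500L,
                                        test_n = 1000L,
                                        hidden = c(32L, 16L),
                                        pretrain_cfg = NULL,
                                        finetune_cfg = NULL,
                                        scratch_cfg = NULL) {
  task <- match.arg(task)
  alleles <- make_alleles(cfg)
  scheme <- encoding_scheme("blosum62")
  max_len <- cfg$peptide_length
  pre <- pretrain_binding_model(cfg, alleles, scheme, max_len,
                                pretrain_total, hidden, pretrain_cfg)
  if (is.null(pretrain_cfg)) pretrain_cfg <- pre$cfg
  if (is.null(finetune_cfg)) {
    finetune_cfg <- train_config(learning_rate = pretrain_cfg$learning_rate / 10,
                                 batch_size = 32L, max_epochs = 40L,
                                 patience = 5L, seed = cfg$seed)
  }
  if (is.null(scratch_cfg)) {
    scratch_cfg <- train_config(learning_rate = pretrain_cfg$learning_rate,
                                batch_size = 32L, max_epochs = 40L,
                                patience = 5L, seed = cfg$seed)
  }
  source_head <- if (task == "stability") "BA" else "EL"
  target_head <- if (task == "stability") "STAB" else "IMM"
  results <- data.frame(replicate = seq_len(replicates),
                        finetuned = NA_real_, scratch = NA_real_)
  for (r in seq_len(replicates)) {
    ds <- downstream_sets(cfg, alleles, task, downstream_n, test_n,
                          seed = cfg$seed + 1000L * r)
    x_tr <- encode_records(ds$train, alleles, scheme, max_len)
    x_te <- encode_records(ds$test, alleles, scheme, max_len)
    tg_tr <- record_targets(ds$train)
    tg_tr$head <- target_head
    split <- nested_split(tg_tr$value, 0.1, seed = cfg$seed + r)
    ft_cfg <- finetune_cfg; ft_cfg$seed <- cfg$seed + r
    sc_cfg <- scratch_cfg; sc_cfg$seed <- cfg$seed + r
    ft <- finetune(pre$model, "unfreeze_all", source_head, target_head,
                   x_tr[split$train, ], tg_tr[split$train, ],
                   x_tr[split$val, ], tg_tr[split$val, ], ft_cfg)
    spec <- predictor_spec(ncol(x_tr), hidden = hidden, heads = target_head)
    sc <- init_model(spec, seed = cfg$seed + r)
    sc <- train_model(sc, x_tr[split$train, ], tg_tr[split$train, ],
                      x_tr[split$val, ], tg_tr[split$val, ], sc_cfg)
    p_ft <- predict_model(ft, x_te, target_head)
    p_sc <- predict_model(sc, x_te, target_head)
    if (task == "stability") {
      results$finetuned[r] <- kendall_tau_b(p_ft, ds$test$half_life_hours)
      results$scratch[r] <- kendall_tau_b(p_sc, ds$test$half_life_hours)
    } else {
      results$finetuned[r] <- as.numeric(auprc(p_ft, ds$test$imm_label))
      results$scratch[r] <- as.numeric(auprc(p_sc, ds$test$imm_label))
    }
  }
  structure(list(results = results,
                 wins = sum(results$finetuned > results$scratch),
                 metric = if (task == "stability") "kendall_tau_b" else "auprc",
                 task = task, pretrained = pre$model),
            class = "tl_transfer_report")
}

#' @export
print.tl_transfer_report <- function(x, ...) {
  cat(sprintf("transfer-benefit experiment (%s, %s): fine-tuned wins %d/%d\n",
              x$task, x$metric, x$wins, nrow(x$results)))
  cat(sprintf("  mean fine-tuned %.4f vs scratch %.4f\n",
              mean(x$results$finetuned), mean(x$results$scratch)))
  invisible(x)
}

# Pretrain a two-head binding predictor on a simulated BA/EL set of
# roughly `total` examples (shared by the experiment harnesses).
pretrain_binding_model <- function(cfg, alleles, scheme, max_len, total,
                                   hidden, pretrain_cfg = NULL) {
  # per allele: ppa BA records + ppa * q * (1 + per_hit) EL records
  per_allele_factor <- 1 + cfg$el_hit_quantile * (1 + cfg$decoys_per_hit)
  ppa <- max(50L, round(total / (cfg$n_alleles * per_allele_factor)))
  cfg_pre <- cfg
  cfg_pre$peptides_per_allele <- ppa
  sim <- simulate_binding(cfg_pre, alleles)
  ba <- sim$ba; el <- sim$el
  x <- rbind(encode_records(ba, alleles, scheme, max_len),
             encode_records(el, alleles, scheme, max_len))
  tg <- rbind(record_targets(ba), record_targets(el))
  split <- nested_split(paste(tg$head, round(tg$value)), 0.1,
                        seed = cfg$seed + 5L)
  if (is.null(pretrain_cfg)) {
    pretrain_cfg <- train_config(learning_rate = 1e-3, batch_size = 256L,
                                 max_epochs = 15L, patience = 3L,
                                 seed = cfg$seed)
  }
  spec <- predictor_spec(ncol(x), hidden = hidden, heads = c("BA", "EL"))
  model <- init_model(spec, seed = cfg$seed)
  model <- train_model(model, x[split$train, ], tg[split$train, ],
                       x[split$val, ], tg[split$val, ], pretrain_cfg)
  list(model = model, cfg = pretrain_cfg)
}

# Fresh downstream training + test sets for one replicate.
downstream_sets <- function(cfg, alleles, task, n_train, n_test, seed) {
  cfg_r <- cfg
  cfg_r$seed <- seed
  need <- n_train + n_test
  if (task == "stability") {
    # the mechanism experiment isolates the latent binding->stability
    # coupling, so the zero-half-life random negatives -- whose label is
    # itself a function of binding -- are left out of its downstream sets
    cfg_r$random_negative_fraction <- 0
    # strong-binder filtering: oversample, then trim
    cfg_r$peptides_per_allele <- ceiling(2.2 * need / cfg$n_alleles)
    sim <- simulate_binding(cfg_r, alleles)
    stab <- simulate_stability(cfg_r, alleles, sim)
    if (nrow(stab) < need) stop("downstream simulation too small")
    rng <- local_rng(seed + 3L)
    idx <- sample.int(nrow(stab), need)
    rng()
    list(train = stab[idx[seq_len(n_train)], ],
         test = stab[idx[n_train + seq_len(n_test)], ])
  } else {
    cfg_r$peptides_per_allele <- ceiling(1.1 * need / cfg$n_alleles)
    imm <- simulate_immunogenicity(cfg_r, alleles)
    if (nrow(imm) < need) stop("downstream simulation too small")
    rng <- local_rng(seed + 3L)
    idx <- sample.int(nrow(imm), need)
    rng()
    list(train = imm[idx[seq_len(n_train)], ],
         test = imm[idx[n_train + seq_len(n_test)], ])
  }
}

#' Per-allele balancing experiment
#'
#' Mechanism check for per-allele label balancing: under strong
#' per-allele label imbalance in the training data, subsampling each
#' allele to an equal positive fraction ([balance_per_allele()])
#' should generalize at least as well on a balanced held-out set as
#' training on the imbalanced original, in a majority of replicates.
#'
#' Following the fine-tuning protocol of the immunogenicity pipeline,
#' one binding predictor is pretrained on a simulated binding set and
#' shared by both arms; then, per replicate, an immunogenicity
#' training set is simulated with alternating per-allele positive
#' fractions (`imbalance_high` / `imbalance_low`) and a balanced
#' held-out set (positive fraction 0.5 per allele). The eluted-ligand
#' head is fine-tuned once on the imbalanced set and once on its
#' balanced subsample ([balance_per_allele()]), and both are scored by
#' AUPRC on the held-out set. Fine-tuning is the regime where the
#' imbalanced set's extra records add little signal — the trunk
#' already encodes binding — but their per-allele prior skew is
#' absorbed wholesale.
#'
#' @param cfg a [synth_config()].
#' @param replicates number of seeded replicates (default 10).
#' @param n_train_per_allele,n_test_per_allele set sizes per allele
#'   before imbalance subsampling (defaults 1500 / 250).
#' @param imbalance_high,imbalance_low alternating per-allele positive
#'   fractions in the training data (defaults 0.9 / 0.1).
#' @param hidden architecture of the pretrained/fine-tuned predictor
#'   (default `c(32, 16)`).
#' @param pretrain_total approximate pretraining set size (default
#'   20,000).
#' @param fit_cfg optional [train_config()] override for fine-tuning.
#' @return list of class `tl_balance_report`: `results` data frame
#'   (`balanced`, `imbalanced` AUPRC per replicate), `wins` (balanced
#'   arm >= imbalanced arm).
#' @export
balancing_experiment <- function(cfg = synth_config(),
                                 replicates = 10L,
                                 n_train_per_allele = 1500L,
                                 n_test_per_allele = 250L,
                                 imbalance_high = 0.9, imbalance_low = 0.1,
                                 hidden = c(32L, 16L),
                                 pretrain_total = 20000L,
                                 fit_cfg = NULL) {
  alleles <- make_alleles(cfg)
  scheme <- encoding_scheme("blosum62")
  max_len <- cfg$peptide_length
  names_al <- vapply(alleles, `[[`, character(1L), "name")
  imb <- setNames(rep(c(imbalance_high, imbalance_low), length.out = length(names_al)),
                  names_al)
  bal <- setNames(rep(0.5, length(names_al)), names_al)
  pre <- pretrain_binding_model(cfg, alleles, scheme, max_len,
                                pretrain_total, hidden)
  if (is.null(fit_cfg)) {
    fit_cfg <- train_config(learning_rate = 1e-4, batch_size = 64L,
                            max_epochs = 60L, patience = 8L, seed = cfg$seed)
  }
  results <- data.frame(replicate = seq_len(replicates),
                        balanced = NA_real_, imbalanced = NA_real_)
  for (r in seq_len(replicates)) {
    cfg_tr <- cfg
    cfg_tr$seed <- cfg$seed + 2000L * r
    cfg_tr$peptides_per_allele <- n_train_per_allele
    cfg_tr$per_allele_imbalance <- imb
    train <- simulate_immunogenicity(cfg_tr, alleles)
    cfg_te <- cfg
    cfg_te$seed <- cfg$seed + 2000L * r + 1L
    cfg_te$peptides_per_allele <- n_test_per_allele
    cfg_te$per_allele_imbalance <- bal
    test <- simulate_immunogenicity(cfg_te, alleles)
    x_te <- encode_records(test, alleles, scheme, max_len)
    fit_arm <- function(records, seed) {
      x <- encode_records(records, alleles, scheme, max_len)
      tg <- record_targets(records)
      split <- nested_split(tg$value, 0.2, seed = seed)
      cfgr <- fit_cfg; cfgr$seed <- seed
      m <- finetune(pre$model, "unfreeze_all", "EL", "IMM",
                    x[split$train, ], tg[split$train, ],
                    x[split$val, ], tg[split$val, ], cfgr)
      predict_model(m, x_te, "IMM")
    }
    balanced_train <- balance_per_allele(train, 0.5, seed = cfg$seed + r)
    results$imbalanced[r] <- as.numeric(auprc(fit_arm(train, cfg$seed + r),
                                              test$imm_label))
    results$balanced[r] <- as.numeric(auprc(fit_arm(balanced_train, cfg$seed + r),
                                            test$imm_label))
  }
  structure(list(results = results,
                 wins = sum(results$balanced >= results$imbalanced)),
            class = "tl_balance_report")
}

#' @export
print.tl_balance_report <- function(x, ...) {
  cat(sprintf("per-allele balancing experiment: balanced arm wins %d/%d (AUPRC)\n",
              x$wins, nrow(x$results)))
  cat(sprintf("  mean balanced %.4f vs imbalanced %.4f\n",
              mean(x$results$balanced), mean(x$results$imbalanced)))
  invisible(x)
}
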