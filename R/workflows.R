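#' End-to-end pipeline configuration
#'
#' One serializable object carrying everything a run needs, archived
#' alongside its outputs so any run is reproducible from its manifest.
#'
#' @param scheme encoding scheme name (see [encoding_scheme()]).
#' @param max_len peptide positions in the encoding (default 14).
#' @param hidden trunk hidden-layer widths.
#' @param decoys_per_hit decoys per eluted-ligand hit during
#'   pretraining (default 99, about a 1:100 hit:total ratio).
#' @param k_stab stability cross-validation folds (default 10).
#' @param k_imm immunogenicity cross-validation folds (default 5).
#' @param val_fraction_stab nested validation fraction within each
#'   stability training fold (default 0.1, i.e. 90/10).
#' @param val_fraction_imm nested fraction for immunogenicity (default
#'   0.2, i.e. 80/20).
#' @param strategy fine-tuning strategy (default `"unfreeze_all"`).
#' @param stab_source_head,imm_source_head pretrained heads seeding the
#'   downstream heads (defaults BA for stability, EL for
#'   immunogenicity — the best-performing pairings).
#' @param balanced apply [balance_per_allele()] to each immunogenicity
#'   training fold (default `FALSE`).
#' @param continuous use continuous immunogenic-strength labels when a
#'   `strength` column is present (default `FALSE`).
#' @param train a [train_config()] for pretraining / from-scratch fits.
#' @param finetune a [train_config()] for fine-tuning (default: the
#'   pretraining configuration at 1/10 learning rate).
#' @param seed master seed.
#' @param out_dir optional directory where models, fold plans, logs and
#'   the manifest are archived.
#' @return list of class `tl_pipeline_config`.
#' @export
pipeline_config <- function(scheme = "blosum62", max_len = 14L,
                            hidden = c(32L, 16L), decoys_per_hit = 99L,
                            k_stab = 10L, k_imm = 5L,
                            val_fraction_stab = 0.1, val_fraction_imm = 0.2,
                            strategy = "unfreeze_all",
                            stab_source_head = "BA", imm_source_head = "EL",
                            balanced = FALSE, continuous = FALSE,
                            train = train_config(),
                            finetune = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(finetune)) {
    finetune <- train
    finetune$learning_rate <- train$learning_rate / 10
  }
  structure(as.list(environment()), class = "tl_pipeline_config")
}

archive_json <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, file.path(out_dir, name), auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(NULL)
}

#' Pretrain the two-head binding predictor
#'
#' The pretraining protocol: decoys are generated for the
#' eluted-ligand hits from the supplied proteome, training pairs that
#' also occur in any evaluation set are removed ([dedup_against()],
#' count logged), an internal stratified validation split drives early
#' stopping, and the trained model is archived with its configuration
#' and stage log.
#'
#' @param cfg a [pipeline_config()].
#' @param ba_records `tl_records` of task BA.
#' @param el_records `tl_records` of task EL; when it contains hits
#'   only and `proteome` is given, decoys are generated at
#'   `cfg$decoys_per_hit`.
#' @param proteome decoy source (see [generate_decoys()]); may be
#'   `NULL` when `el_records` already contains decoys.
#' @param pseudo_table named allele -> pseudo-sequence vector.
#' @param eval_sets optional `tl_records` (or list of them) whose
#'   (peptide, allele) pairs are removed from training.
#' @return list with `model` (a `tl_predictor`), `log` (stage counts)
#'   and `removed` (leakage pairs dropped).
#' @export
run_pretraining <- function(cfg, ba_records, el_records, proteome = NULL,
                            pseudo_table, eval_sets = NULL) {
  stopifnot(inherits(cfg, "tl_pipeline_config"))
  if (nrow(ba_records) == 0L && nrow(el_records) == 0L) {
    stop("empty pretraining task stream")
  }
  stage_log <- list()
  if (all(el_records$el_label == "hit") && !is.null(proteome)) {
    decoys <- generate_decoys(el_records[, RECORD_COLUMNS], proteome,
                              per_hit = cfg$decoys_per_hit,
                              seed = cfg$seed + 13L)
    el_records <- rbind(el_records[, RECORD_COLUMNS], decoys)
    stage_log$decoys_added <- nrow(decoys)
  }
  removed <- 0L
  if (!is.null(eval_sets)) {
    ba_records <- dedup_against(ba_records, eval_sets)
    el_records <- dedup_against(el_records, eval_sets)
    removed <- attr(ba_records, "removed") + attr(el_records, "removed")
  }
  stage_log$duplicates_removed <- removed
  stage_log$n_ba <- nrow(ba_records)
  stage_log$n_el <- nrow(el_records)
  scheme <- encoding_scheme(cfg$scheme)
  x <- rbind(encode_records(ba_records, pseudo_table, scheme, cfg$max_len),
             encode_records(el_records, pseudo_table, scheme, cfg$max_len))
  tg <- rbind(record_targets(ba_records), record_targets(el_records))
  split <- nested_split(paste(tg$head, round(tg$value)), 0.1,
                        seed = cfg$seed + 5L)
  spec <- predictor_spec(ncol(x), hidden = cfg$hidden, heads = c("BA", "EL"))
  model <- init_model(spec, seed = cfg$seed)
  model <- train_model(model, x[split$train, ], tg[split$train, ],
                       x[split$val, ], tg[split$val, ], cfg$train)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(model, file.path(cfg$out_dir, "pretrained.json"))
    archive_json(list(config = unclass(cfg), stages = stage_log),
                 cfg$out_dir, "pretraining_manifest.json")
  }
  list(model = model, log = stage_log, removed = removed)
}

#' Stability fine-tuning pipeline (nested cross-validation ensemble)
#'
#' Stratified k-fold cross-validation (default k = 10; continuous
#' half-life labels are stratified by quantile bins with zero-labels
#' as their own stratum). Within each training fold a further
#' stratified 90/10 train/validation split drives early stopping, the
#' pretrained predictor is fine-tuned (BA head, `unfreeze_all` by
#' default), and the left-out fold is predicted — so no test record
#' ever influences early stopping within its own fold. The deliverable
#' is the k-member ensemble (prediction = member mean) plus a
#' merged-fold report: metrics computed once on the concatenated
#' left-out predictions, never averaged across folds.
#'
#' @param cfg a [pipeline_config()].
#' @param pretrained a `tl_predictor` from [run_pretraining()].
#' @param records `tl_records` of task STAB (typically including
#'   random negatives).
#' @param pseudo_table named allele -> pseudo-sequence vector.
#' @return list with `ensemble` (list of k models), `report`
#'   ([metric_report()], merged-fold Pearson and Kendall tau-b),
#'   `fold_plan`, `predictions` (one left-out prediction per record).
#' @export
run_stability_pipeline <- function(cfg, pretrained, records, pseudo_table) {
  run_finetune_cv(cfg, pretrained, records, pseudo_table,
                  task = "STAB", k = cfg$k_stab,
                  val_fraction = cfg$val_fraction_stab,
                  source_head = cfg$stab_source_head)
}

#' Immunogenicity fine-tuning pipeline
#'
#' Same nested protocol as [run_stability_pipeline()] with k = 5 folds
#' and 80/20 nested splits, fine-tuning the eluted-ligand head by
#' default. Dataset variants are applied per config: `balanced`
#' subsamples each training fold with [balance_per_allele()] (the test
#' folds are never touched), `continuous` swaps binary labels for the
#' records' `strength` column. The report carries AUROC, AUPRC with
#' its positive-fraction baseline, Top-20/Top-50 counts, and — when
#' recognition frequencies are present — their Pearson and Kendall
#' tau-b against the predictions.
#'
#' @inheritParams run_stability_pipeline
#' @param records `tl_records` of task IMM.
#' @return as [run_stability_pipeline()].
#' @export
run_immunogenicity_pipeline <- function(cfg, pretrained, records, pseudo_table) {
  run_finetune_cv(cfg, pretrained, records, pseudo_table,
                  task = "IMM", k = cfg$k_imm,
                  val_fraction = cfg$val_fraction_imm,
                  source_head = cfg$imm_source_head)
}

run_finetune_cv <- function(cfg, pretrained, records, pseudo_table,
                            task, k, val_fraction, source_head) {
  stopifnot(inherits(cfg, "tl_pipeline_config"),
            all(records$task == task))
  if (task == "IMM" && cfg$continuous) {
    if (is.null(records$strength)) {
      stop("continuous labelling requested but records carry no 'strength' column")
    }
    records <- relabel_continuous(records, records$strength)
  }
  scheme <- encoding_scheme(cfg$scheme)
  x <- encode_records(records, pseudo_table, scheme, cfg$max_len)
  strat_label <- if (task == "STAB") records$half_life_hours else
    as_binary_labels(records$imm_label)
  plan <- stratified_kfold(strat_label, k, seed = cfg$seed)
  predictions <- rep(NA_real_, nrow(records))
  ensemble <- vector("list", k)
  balance_log <- list()
  for (f in seq_len(k)) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    fold_records <- records[train_idx, , drop = FALSE]
    fold_x <- x[train_idx, , drop = FALSE]
    if (task == "IMM" && cfg$balanced) {
      rownames(fold_records) <- NULL
      keep <- balance_indices(fold_records, 0.5, seed = cfg$seed + f)
      balance_log[[f]] <- list(before = nrow(fold_records),
                               after = length(keep))
      fold_records <- fold_records[keep, , drop = FALSE]
      fold_x <- fold_x[keep, , drop = FALSE]
    }
    tg <- record_targets(fold_records)
    tg$head <- task
    split <- nested_split(tg$value, val_fraction, seed = cfg$seed + 100L + f)
    member <- finetune(pretrained, cfg$strategy, source_head, task,
                       fold_x[split$train, , drop = FALSE], tg[split$train, ],
                       fold_x[split$val, , drop = FALSE], tg[split$val, ],
                       within_fold_cfg(cfg$finetune, cfg$seed + f),
                       init_seed = cfg$seed + f)
    ensemble[[f]] <- member
    predictions[test_idx] <- predict_model(member, x[test_idx, , drop = FALSE],
                                           task)
  }
  fold_pred <- split(predictions, plan$assignment)
  report <- if (task == "STAB") {
    merged_fold_eval(fold_pred,
                     split(transform_half_life(records$half_life_hours),
                           plan$assignment),
                     fold_indices = split(seq_len(nrow(records)),
                                          plan$assignment))
  } else {
    imm_report(predictions, records)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fold_plan(plan, file.path(cfg$out_dir,
                                    sprintf("fold_plan_%s.tsv", tolower(task))))
    for (f in seq_len(k)) {
      save_model(ensemble[[f]],
                 file.path(cfg$out_dir, sprintf("%s_member_%02d.json",
                                                tolower(task), f)))
    }
    archive_json(list(config = unclass(cfg), task = task, k = k,
                      val_fraction = val_fraction,
                      balance_log = balance_log,
                      metrics = report$metrics, n = report$n),
                 cfg$out_dir, sprintf("%s_manifest.json", tolower(task)))
  }
  list(ensemble = ensemble, report = report, fold_plan = plan,
       predictions = predictions)
}

within_fold_cfg <- function(tc, seed) {
  tc$seed <- as.integer(seed %% .Machine$integer.max)
  tc
}

imm_report <- function(predictions, records) {
  y <- as_binary_labels(records$imm_label)
  pr <- auprc(predictions, y)
  metrics <- list(auroc = as.numeric(auroc(predictions, y)),
                  auprc = as.numeric(pr),
                  auprc_baseline = attr(pr, "baseline"))
  for (n in c(20L, 50L)) {
    if (n <= length(predictions)) {
      metrics[[sprintf("top_%d", n)]] <- top_n_count(predictions, y, n)
    }
  }
  if (!all(is.na(records$recognition_frequency))) {
    ok <- !is.na(records$recognition_frequency)
    metrics$recognition_pearson <-
      as.numeric(pearson(predictions[ok], records$recognition_frequency[ok]))
    metrics$recognition_kendall <-
      as.numeric(kendall_tau_b(predictions[ok], records$recognition_frequency[ok]))
  }
  metric_report("merged_fold", metrics, n = length(predictions))
}

#' Score peptide-allele pairs with a model or ensemble
#'
#' @param model a `tl_predictor`, a list of them (ensemble; prediction
#'   is the member mean), or a `tl_stacked` model.
#' @param peptides character vector of peptides.
#' @param alleles allele names, recycled against `peptides` (all
#'   peptide x allele combinations are scored when `expand = TRUE`).
#' @param pseudo_table named allele -> pseudo-sequence vector.
#' @param head head to read out.
#' @param scheme encoding scheme name.
#' @param max_len peptide positions.
#' @param expand score every peptide x allele combination (default
#'   `TRUE` when lengths differ).
#' @return data frame with `peptide`, `allele`, `score`, `error`
#'   (per-row message for unsupported alleles, `NA` otherwise) and,
#'   for the BA head, `affinity_nm` via [inverse_affinity()].
#' @export
predict_table <- function(model, peptides, alleles, pseudo_table, head,
                          scheme = "blosum62", max_len = 14L,
                          expand = length(peptides) != length(alleles)) {
  if (expand) {
    grid <- expand.grid(peptide = peptides, allele = alleles,
                        stringsAsFactors = FALSE)
  } else {
    grid <- data.frame(peptide = peptides, allele = alleles,
                       stringsAsFactors = FALSE)
  }
  grid$allele <- vapply(grid$allele, function(a) {
    tryCatch(normalize_allele(a), error = function(e) a)
  }, character(1L))
  grid$score <- NA_real_
  grid$error <- NA_character_
  known <- grid$allele %in% names(pseudo_table)
  grid$error[!known] <- "unsupported allele"
  if (any(known)) {
    sch <- encoding_scheme(scheme)
    x <- encode_dataset(grid$peptide[known],
                        unname(pseudo_table[grid$allele[known]]),
                        sch, max_len)
    grid$score[known] <- if (is.list(model) && !inherits(model, "tl_predictor")) {
      ensemble_predict(model, x, head)
    } else if (inherits(model, "tl_stacked")) {
      predict(model, x)
    } else {
      predict_model(model, x, head)
    }
  }
  if (head == "BA") grid$affinity_nm <- inverse_affinity(grid$score)
  grid
}
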