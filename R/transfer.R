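#' Fine-tune a pretrained predictor on a downstream task
#'
#' Repurposes a head of the pretrained binding predictor for a new
#' task: the target head is initialized from the source head's weights
#' (binding-affinity head for stability, eluted-ligand head for
#' immunogenicity by default) and the network is trained on the
#' downstream data under one of three strategies:
#'
#' * `unfreeze_all` — every weight is trainable (the configuration that
#'   performs best for both downstream tasks, consistent with
#'   non-anchor peptide positions mattering for stability and the
#'   middle, TCR-facing positions mattering for immunogenicity);
#' * `freeze_trunk` — trunk weights stay bit-identical, only the head
#'   adapts;
#' * `replace_top` — the last hidden layer and the target head are
#'   re-initialized (seeded), deeper layers are inherited, and all
#'   weights train.
#'
#' Chained transfer is expressible by passing an already fine-tuned
#' model (e.g. a stability model) as `pretrained` with
#' `source_head = "STAB"`.
#'
#' @param pretrained a `tl_predictor` (any trained or fine-tuned model).
#' @param strategy one of `"unfreeze_all"`, `"freeze_trunk"`,
#'   `"replace_top"`.
#' @param source_head head whose weights seed the target head.
#' @param target_head head to create/train (`"STAB"` or `"IMM"`).
#' @param x,targets training design matrix and targets (see
#'   [train_model()]; `targets$head` must equal `target_head`).
#' @param x_val,targets_val validation split for early stopping.
#' @param cfg a [train_config()]; fine-tuning conventionally uses a
#'   smaller learning rate than pretraining (default 1/10).
#' @param init_seed seed for `replace_top` re-initialization.
#' @return the fine-tuned `tl_predictor`.
#' @export
finetune <- function(pretrained,
                     strategy = c("unfreeze_all", "freeze_trunk", "replace_top"),
                     source_head, target_head, x, targets, x_val, targets_val,
                     cfg, init_seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(pretrained, "tl_predictor"))
  if (!source_head %in% names(pretrained$heads)) {
    stop("pretrained model has no '", source_head, "' head")
  }
  state <- pretrained
  state$heads[[target_head]] <- state$heads[[source_head]]
  if (!target_head %in% state$spec$heads) {
    state$spec$heads <- c(state$spec$heads, target_head)
  }
  if (strategy == "replace_top") {
    fresh <- init_model(state$spec, seed = init_seed)
    last <- length(state$trunk)
    state$trunk[[last]] <- fresh$trunk[[last]]
    state$heads[[target_head]] <- fresh$heads[[target_head]]
  }
  if (!all(targets$head == target_head)) {
    stop("all fine-tuning targets must carry head '", target_head, "'")
  }
  train_model(state, x, targets, x_val, targets_val, cfg,
              freeze = if (strategy == "freeze_trunk") "trunk" else NULL)
}

#' "BA as a feature" stacked baseline
#'
#' The simpler knowledge-transfer baseline: a fresh task predictor is
#' trained on the encoded example concatenated with the pretrained
#' predictor's score (one extra input feature). The pretrained
#' predictor itself is never updated.
#'
#' @param pretrained a `tl_predictor` supplying the feature score.
#' @param feature_head head of `pretrained` to use as the feature.
#' @param x,targets training data (targets for the task head).
#' @param x_val,targets_val validation split.
#' @param cfg a [train_config()].
#' @param hidden hidden layer widths of the fresh task predictor.
#' @param init_seed seed for the fresh predictor's initialization.
#' @return object of class `tl_stacked`: list with `base`,
#'   `feature_head`, `task_model`, `task_head`.
#' @export
ba_as_feature_model <- function(pretrained, feature_head, x, targets,
                                x_val, targets_val, cfg,
                                hidden = c(32L, 16L), init_seed = 1L) {
  task_head <- unique(targets$head)
  stopifnot(length(task_head) == 1L)
  aug <- function(m) cbind(m, predict_model(pretrained, m, feature_head))
  spec <- predictor_spec(ncol(x) + 1L, hidden = hidden, heads = task_head)
  task <- init_model(spec, seed = init_seed)
  task <- train_model(task, aug(x), targets, aug(x_val), targets_val, cfg)
  structure(list(base = pretrained, feature_head = feature_head,
                 task_model = task, task_head = task_head),
            class = "tl_stacked")
}

#' Predict with a stacked "score as a feature" model
#'
#' @param object a `tl_stacked` model.
#' @param x design matrix (base encoding width, without the feature
#'   column — it is appended internally).
#' @param ... unused.
#' @return numeric scores in \[0,1\].
#' @export
predict.tl_stacked <- function(object, x, ...) {
  feat <- predict_model(object$base, x, object$feature_head)
  predict_model(object$task_model, cbind(x, feat), object$task_head)
}

#' Mix task and base predictor scores
#'
#' The classical score-mixing form of knowledge transfer: a convex
#' combination `(1 - alpha) * task + alpha * base` with a weighting
#' factor alpha in \[0,1\].
#'
#' @param task_scores,base_scores equal-length numeric score vectors.
#' @param alpha mixing weight in \[0,1\]; 0 returns the task scores,
#'   1 the base scores.
#' @return mixed scores.
#' @export
alpha_mix <- function(task_scores, base_scores, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (length(task_scores) != length(base_scores)) {
    stop("score vectors must have equal length")
  }
  (1 - alpha) * task_scores + alpha * base_scores
}

#' Tune the mixing weight on validation labels
#'
#' Exhaustively evaluates `metric` over an alpha grid and returns the
#' maximizer; ties break toward smaller alpha.
#'
#' @param task_scores,base_scores equal-length score vectors.
#' @param labels validation labels passed to `metric`.
#' @param metric function `(scores, labels) -> numeric`, larger =
#'   better (e.g. [auroc()], or negative error for regression).
#' @param grid candidate alphas in \[0,1\] (default 0 to 1 by 0.05).
#' @return the selected alpha.
#' @export
tune_alpha <- function(task_scores, base_scores, labels, metric,
                       grid = seq(0, 1, by = 0.05)) {
  if (length(grid) == 0L || any(grid < 0 | grid > 1)) {
    stop("grid must be non-empty within [0, 1]")
  }
  grid <- sort(grid)
  vals <- vapply(grid, function(a) {
    v <- metric(alpha_mix(task_scores, base_scores, a), labels)
    if (!is.finite(v)) stop("metric undefined at alpha = ", a)
    v
  }, numeric(1L))
  grid[which.max(vals)]
}
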