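#' Describe the predictor architecture
#'
#' The predictor is a multilayer perceptron with a trunk shared by all
#' heads and one sigmoid output unit per head. Regression heads (`BA`,
#' `STAB`) train with squared error on the \[0,1\] target scale
#' ([transform_affinity()], [transform_half_life()]); classification
#' heads (`EL`, `IMM`) train with binary cross-entropy.
#'
#' @param input_width number of input features (from [encode_dataset()]).
#' @param hidden integer vector of hidden layer widths (default
#'   `c(128, 64)`).
#' @param heads character subset of `c("BA","EL","STAB","IMM")`.
#' @param activation trunk activation, `"tanh"` or `"relu"`.
#' @return object of class `tl_predictor_spec`.
#' @export
predictor_spec <- function(input_width, hidden = c(128L, 64L),
                           heads = c("BA", "EL"),
                           activation = c("tanh", "relu")) {
  activation <- match.arg(activation)
  if (length(heads) == 0L) stop("spec needs at least one head")
  heads <- match.arg(heads, TASKS, several.ok = TRUE)
  if (length(hidden) < 1L || any(hidden < 1L)) {
    stop("need at least one hidden layer of positive width")
  }
  if (input_width < 1L) stop("input_width must be positive")
  structure(list(input_width = as.integer(input_width),
                 hidden = as.integer(hidden), heads = heads,
                 activation = activation, output_activation = "sigmoid"),
            class = "tl_predictor_spec")
}

#' Training hyperparameters
#'
#' @param learning_rate step size (default 1e-3, Adam).
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs.
#' @param patience epochs without validation improvement before
#'   stopping (0 stops at the first non-improving epoch).
#' @param seed integer seed governing initialization-independent
#'   shuffling.
#' @param optimizer `"adam"` or `"sgd"` (with momentum 0.9).
#' @return object of class `tl_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 128L,
                         max_epochs = 100L, patience = 5L, seed = 1L,
                         optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            patience >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed), optimizer = optimizer),
            class = "tl_train_config")
}

MODEL_FORMAT_VERSION <- "tlmhc-model-1"

#' Initialize predictor weights
#'
#' Glorot-uniform initialization, deterministic under `seed`.
#'
#' @param spec a [predictor_spec()].
#' @param seed integer seed; identical seeds give bitwise-identical
#'   weights.
#' @return object of class `tl_predictor` holding `spec`, trunk and head
#'   weights, and an (empty) training log.
#' @export
init_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tl_predictor_spec"))
  rng <- local_rng(seed)
  widths <- c(spec$input_width, spec$hidden)
  trunk <- vector("list", length(spec$hidden))
  for (l in seq_along(spec$hidden)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    trunk[[l]] <- list(W = matrix(runif(fan_in * fan_out, -lim, lim),
                                  fan_in, fan_out),
                       b = rep(0, fan_out))
  }
  d_last <- spec$hidden[length(spec$hidden)]
  heads <- lapply(setNames(spec$heads, spec$heads), function(h) {
    lim <- sqrt(6 / (d_last + 1))
    list(w = runif(d_last, -lim, lim), b = 0)
  })
  rng()
  structure(list(spec = spec, trunk = trunk, heads = heads,
                 training_log = data.frame(epoch = integer(0),
                                           train_loss = numeric(0),
                                           val_loss = numeric(0)),
                 version = MODEL_FORMAT_VERSION),
            class = "tl_predictor")
}

#' @export
print.tl_predictor <- function(x, ...) {
  cat("tlmhc predictor:", x$spec$input_width, "->",
      paste(x$spec$hidden, collapse = " -> "), "->",
      paste(names(x$heads), collapse = "/"),
      sprintf("(%s trunk, sigmoid heads)\n", x$spec$activation))
  if (nrow(x$training_log)) {
    cat("trained", max(x$training_log$epoch), "epochs; best val loss",
        format(min(x$training_log$val_loss), digits = 5), "\n")
  }
  invisible(x)
}

trunk_forward <- function(state, x, keep_all = FALSE) {
  act <- if (state$spec$activation == "tanh") tanh else function(z) pmax(z, 0)
  A <- x
  all_A <- if (keep_all) vector("list", length(state$trunk)) else NULL
  for (l in seq_along(state$trunk)) {
    A <- act(sweep(A %*% state$trunk[[l]]$W, 2L, state$trunk[[l]]$b, "+"))
    if (keep_all) all_A[[l]] <- A
  }
  if (keep_all) all_A else A
}

head_forward <- function(state, A_last, head) {
  h <- state$heads[[head]]
  plogis(drop(A_last %*% h$w) + h$b)
}

head_is_classification <- function(head) head %in% c("EL", "IMM")

# Mean per-example loss for (prediction, target) rows grouped by head.
example_losses <- function(p, y, heads) {
  eps <- 1e-12
  loss <- numeric(length(p))
  cls <- head_is_classification(heads)
  loss[!cls] <- (p[!cls] - y[!cls])^2
  pc <- pmin(pmax(p[cls], eps), 1 - eps)
  loss[cls] <- -(y[cls] * log(pc) + (1 - y[cls]) * log(1 - pc))
  loss
}

model_loss <- function(state, x, targets) {
  A <- trunk_forward(state, x)
  p <- numeric(nrow(x))
  for (h in unique(targets$head)) {
    rows <- targets$head == h
    p[rows] <- head_forward(state, A[rows, , drop = FALSE], h)
  }
  mean(example_losses(p, targets$value, targets$head))
}

# One gradient step worth of gradients for a minibatch, as a named flat
# list parallel to flatten_params().
batch_gradients <- function(state, xb, yb, headb) {
  acts <- trunk_forward(state, xb, keep_all = TRUE)
  nL <- length(state$trunk)
  A_last <- acts[[nL]]
  n <- nrow(xb)
  delta <- matrix(0, n, ncol(A_last))
  grads <- list()
  for (h in names(state$heads)) {
    rows <- which(headb == h)
    gw <- numeric(length(state$heads[[h]]$w)); gb <- 0
    if (length(rows)) {
      Ah <- A_last[rows, , drop = FALSE]
      p <- head_forward(state, Ah, h)
      y <- yb[rows]
      dz <- if (head_is_classification(h)) p - y else 2 * (p - y) * p * (1 - p)
      gw <- drop(crossprod(Ah, dz)) / n
      gb <- sum(dz) / n
      delta[rows, ] <- delta[rows, ] + outer(dz, state$heads[[h]]$w)
    }
    grads[[paste0("head.", h, ".w")]] <- gw
    grads[[paste0("head.", h, ".b")]] <- gb
  }
  for (l in rev(seq_len(nL))) {
    A_l <- acts[[l]]
    dz <- if (state$spec$activation == "tanh") delta * (1 - A_l^2) else delta * (A_l > 0)
    A_prev <- if (l == 1L) xb else acts[[l - 1L]]
    grads[[paste0("trunk.", l, ".W")]] <- crossprod(A_prev, dz) / n
    grads[[paste0("trunk.", l, ".b")]] <- colSums(dz) / n
    if (l > 1L) delta <- dz %*% t(state$trunk[[l]]$W)
  }
  grads
}

param_names <- function(state) {
  c(unlist(lapply(seq_along(state$trunk),
                  function(l) paste0("trunk.", l, c(".W", ".b")))),
    unlist(lapply(names(state$heads),
                  function(h) paste0("head.", h, c(".w", ".b")))))
}

get_param <- function(state, nm) {
  p <- strsplit(nm, ".", fixed = TRUE)[[1L]]
  if (p[1L] == "trunk") state$trunk[[as.integer(p[2L])]][[p[3L]]]
  else state$heads[[p[2L]]][[p[3L]]]
}

set_param <- function(state, nm, value) {
  p <- strsplit(nm, ".", fixed = TRUE)[[1L]]
  if (p[1L] == "trunk") state$trunk[[as.integer(p[2L])]][[p[3L]]] <- value
  else state$heads[[p[2L]]][[p[3L]]] <- value
  state
}

#' Train the predictor with early stopping
#'
#' Minibatch training on examples whose targets are routed to
#' per-record heads: each example contributes only to its own head's
#' loss, so mixed binding-affinity / eluted-ligand batches update both
#' heads without cross-talk. After every epoch the mean per-example
#' validation loss is evaluated; training stops once `patience` epochs
#' pass without improvement and the state at the best epoch is
#' returned. Deterministic under `cfg$seed` with fixed data order.
#'
#' @param state a `tl_predictor` from [init_model()] (or a previously
#'   trained one).
#' @param x numeric design matrix (`n` x `input_width`).
#' @param targets data frame with columns `value` (in \[0,1\]) and
#'   `head` (one of the spec's heads), one row per row of `x`.
#' @param x_val,targets_val validation set in the same form.
#' @param cfg a [train_config()].
#' @param freeze `NULL` or `"trunk"` (trunk weights left untouched).
#' @return the `tl_predictor` at the best-validation epoch, with
#'   `training_log` appended.
#' @export
train_model <- function(state, x, targets, x_val, targets_val, cfg,
                        freeze = NULL) {
  stopifnot(inherits(state, "tl_predictor"), inherits(cfg, "tl_train_config"))
  if (nrow(x) == 0L) stop("empty training set")
  if (!all(targets$head %in% names(state$heads))) {
    stop("target head(s) absent from model: ",
         paste(setdiff(unique(targets$head), names(state$heads)), collapse = ", "))
  }
  if (ncol(x) != state$spec$input_width) {
    stop("design matrix width ", ncol(x), " does not match spec input_width ",
         state$spec$input_width)
  }
  if (cfg$max_epochs == 0L) return(state)
  nms <- param_names(state)
  frozen <- if (identical(freeze, "trunk")) grepl("^trunk\\.", nms) else
    rep(FALSE, length(nms))
  names(frozen) <- nms
  # optimizer moment buffers
  m1 <- m2 <- lapply(setNames(nms, nms), function(nm) get_param(state, nm) * 0)
  t_step <- 0L
  best <- list(loss = Inf, state = state, epoch = 0L)
  since_best <- 0L
  n <- nrow(x)
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  log <- state$training_log
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      grads <- batch_gradients(state, xb, targets$value[idx], targets$head[idx])
      t_step <- t_step + 1L
      for (nm in nms) {
        if (frozen[[nm]]) next
        g <- grads[[nm]]
        if (cfg$optimizer == "adam") {
          m1[[nm]] <- 0.9 * m1[[nm]] + 0.1 * g
          m2[[nm]] <- 0.999 * m2[[nm]] + 0.001 * g^2
          mhat <- m1[[nm]] / (1 - 0.9^t_step)
          vhat <- m2[[nm]] / (1 - 0.999^t_step)
          step <- cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8)
        } else {
          m1[[nm]] <- 0.9 * m1[[nm]] + g
          step <- cfg$learning_rate * m1[[nm]]
        }
        state <- set_param(state, nm, get_param(state, nm) - step)
      }
    }
    train_loss <- model_loss(state, x, targets)
    val_loss <- model_loss(state, x_val, targets_val)
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop("non-finite loss at epoch ", epoch,
           " (train ", train_loss, ", val ", val_loss,
           "); reduce the learning rate")
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                 val_loss = val_loss))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, state = state, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > cfg$patience) break
    }
  }
  out <- best$state
  out$training_log <- log
  out
}

#' Predict scores for encoded examples
#'
#' @param state a `tl_predictor`.
#' @param x design matrix from [encode_dataset()].
#' @param head which head to read out.
#' @return numeric scores in \[0,1\], one per row of `x`. BA-head scores
#'   convert back to nM via [inverse_affinity()].
#' @export
predict_model <- function(state, x, head) {
  stopifnot(inherits(state, "tl_predictor"))
  if (!head %in% names(state$heads)) {
    stop("unknown head '", head, "'; model has: ",
         paste(names(state$heads), collapse = ", "))
  }
  head_forward(state, trunk_forward(state, x), head)
}

#' Average predictions over a model ensemble
#'
#' @param states non-empty list of `tl_predictor`s sharing one spec.
#' @param x design matrix.
#' @param head which head to read out.
#' @return arithmetic mean of the member predictions.
#' @export
ensemble_predict <- function(states, x, head) {
  if (length(states) == 0L) stop("empty ensemble")
  ref <- states[[1L]]$spec
  for (s in states) {
    sp <- s$spec
    if (sp$input_width != ref$input_width || !identical(sp$hidden, ref$hidden) ||
        sp$activation != ref$activation) {
      stop("ensemble members must share one architecture spec")
    }
  }
  rowMeans(vapply(states, predict_model, numeric(nrow(x)), x = x, head = head))
}

num_to_chr <- function(v) sprintf("%.17g", v)

#' Save / load a predictor
#'
#' A versioned JSON archive holding the spec and all weights (printed at
#' full double precision, so the round trip is exact).
#'
#' @param state a `tl_predictor`.
#' @param path file path.
#' @return `load_model()`: the restored `tl_predictor`.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "tl_predictor"))
  obj <- list(
    version = MODEL_FORMAT_VERSION,
    spec = unclass(state$spec),
    trunk = lapply(state$trunk, function(l) {
      list(dim = dim(l$W), W = num_to_chr(l$W), b = num_to_chr(l$b))
    }),
    heads = lapply(state$heads, function(h) {
      list(w = num_to_chr(h$w), b = num_to_chr(h$b))
    }),
    training_log = state$training_log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    stop("model file version '", obj$version, "' does not match supported '",
         MODEL_FORMAT_VERSION, "'")
  }
  spec <- predictor_spec(obj$spec$input_width, obj$spec$hidden,
                         obj$spec$heads, obj$spec$activation)
  trunk <- lapply(if (is.data.frame(obj$trunk)) split(obj$trunk, seq_len(nrow(obj$trunk))) else obj$trunk,
                  function(l) {
    list(W = matrix(as.numeric(unlist(l$W)), unlist(l$dim)[1L], unlist(l$dim)[2L]),
         b = as.numeric(unlist(l$b)))
  })
  heads <- lapply(obj$heads, function(h) {
    list(w = as.numeric(unlist(h$w)), b = as.numeric(unlist(h$b)))
  })
  log <- as.data.frame(obj$training_log)
  if (nrow(log) == 0L) {
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  }
  structure(list(spec = spec, trunk = unname(trunk), heads = heads,
                 training_log = log, version = MODEL_FORMAT_VERSION),
            class = "tl_predictor")
}
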