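# Small deterministic design matrix for model tests.
toy_data <- function(n = 120, d = 12, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  list(x = x, sep = as.numeric(x[, 1] > 0))
}

test_that("initialization is seed-deterministic and validates the spec", {
  spec <- predictor_spec(10, hidden = c(8, 4), heads = c("BA", "EL"))
  m1 <- init_model(spec, seed = 42)
  m2 <- init_model(spec, seed = 42)
  m3 <- init_model(spec, seed = 43)
  expect_identical(m1$trunk, m2$trunk)
  expect_identical(m1$heads, m2$heads)
  expect_false(identical(m1$trunk[[1]]$W, m3$trunk[[1]]$W))
  expect_error(predictor_spec(10, hidden = c(8), heads = character(0)),
               "at least one head")
  expect_error(predictor_spec(10, hidden = c(0)), "positive width")
})

test_that("a separable eluted-ligand toy task trains below the no-skill cross-entropy", {
  td <- toy_data(200)
  tg <- data.frame(value = td$sep, head = "EL")
  sp <- nested_split(td$sep, 0.25, seed = 1)
  m <- init_model(predictor_spec(ncol(td$x), hidden = 8, heads = "EL"), 1)
  m <- train_model(m, td$x[sp$train, ], tg[sp$train, ],
                   td$x[sp$val, ], tg[sp$val, ],
                   train_config(0.01, 32, max_epochs = 60, patience = 60, seed = 1))
  q <- mean(td$sep[sp$val])
  no_skill <- -(q * log(q) + (1 - q) * log(1 - q))
  expect_lt(min(m$training_log$val_loss), no_skill)
  # early-stopping selection: returned weights attain the minimum logged loss
  p <- predict_model(m, td$x[sp$val, ], "EL")
  y <- td$sep[sp$val]
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce, min(m$training_log$val_loss), tolerance = 1e-12)
})

test_that("per-record head masking leaves unexercised heads untouched", {
  td <- toy_data(80)
  tg <- data.frame(value = plogis(td$x[, 1]), head = "BA")
  m0 <- init_model(predictor_spec(ncol(td$x), hidden = 6,
                                  heads = c("BA", "EL")), 2)
  m1 <- train_model(m0, td$x, tg, td$x, tg,
                    train_config(0.01, 16, max_epochs = 3, patience = 3, seed = 1))
  # trunk moved, BA head moved, EL head weights bit-identical
  expect_false(identical(m0$trunk[[1]]$W, m1$trunk[[1]]$W))
  expect_false(identical(m0$heads$BA, m1$heads$BA))
  expect_identical(m0$heads$EL, m1$heads$EL)
})

test_that("mixed-head batches update both heads", {
  td <- toy_data(80)
  tg <- data.frame(value = c(plogis(td$x[1:40, 1]), as.numeric(td$x[41:80, 2] > 0)),
                   head = rep(c("BA", "EL"), each = 40))
  m0 <- init_model(predictor_spec(ncol(td$x), hidden = 6,
                                  heads = c("BA", "EL")), 2)
  m1 <- train_model(m0, td$x, tg, td$x, tg,
                    train_config(0.01, 80, max_epochs = 2, patience = 2, seed = 1))
  expect_false(identical(m0$heads$BA, m1$heads$BA))
  expect_false(identical(m0$heads$EL, m1$heads$EL))
})

test_that("training is reproducible and patience bounds the post-optimum epochs", {
  td <- toy_data(100)
  tg <- data.frame(value = td$sep, head = "EL")
  sp <- nested_split(td$sep, 0.2, seed = 2)
  fit <- function(patience) {
    m <- init_model(predictor_spec(ncol(td$x), hidden = 6, heads = "EL"), 3)
    train_model(m, td$x[sp$train, ], tg[sp$train, ],
                td$x[sp$val, ], tg[sp$val, ],
                train_config(0.02, 25, max_epochs = 40, patience = patience,
                             seed = 7))
  }
  a <- fit(3); b <- fit(3)
  expect_identical(a$trunk, b$trunk)
  expect_identical(a$training_log, b$training_log)
  # with patience p, at most p+1 trailing epochs fail to improve the minimum
  log <- fit(0)$training_log
  if (nrow(log) < 40) {
    expect_equal(which.min(log$val_loss), nrow(log) - 1)
  }
  expect_equal(min(a$training_log$val_loss),
               a$training_log$val_loss[which.min(a$training_log$val_loss)])
})

test_that("prediction is deterministic, bounded, and head-checked", {
  td <- toy_data(30)
  m <- init_model(predictor_spec(ncol(td$x), hidden = 5, heads = c("BA", "EL")), 1)
  p1 <- predict_model(m, td$x, "BA")
  p2 <- predict_model(m, td$x, "BA")
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(predict_model(m, td$x, "STAB"), "unknown head")
  # BA scores convert back to nM through the inverse affinity transform
  nm <- inverse_affinity(p1)
  expect_true(all(nm >= 1 & nm <= 50000))
  expect_equal(transform_affinity(nm), p1, tolerance = 1e-9)
})

test_that("ensembles average member predictions and validate specs", {
  td <- toy_data(20)
  spec <- predictor_spec(ncol(td$x), hidden = 5, heads = "BA")
  ms <- lapply(1:3, function(s) init_model(spec, s))
  em <- ensemble_predict(ms, td$x, "BA")
  expect_equal(em, (predict_model(ms[[1]], td$x, "BA") +
                      predict_model(ms[[2]], td$x, "BA") +
                      predict_model(ms[[3]], td$x, "BA")) / 3)
  expect_equal(ensemble_predict(ms[1], td$x, "BA"),
               predict_model(ms[[1]], td$x, "BA"))
  expect_equal(ensemble_predict(ms[c(1, 1, 1)], td$x, "BA"),
               predict_model(ms[[1]], td$x, "BA"))
  # ensemble variance never exceeds the largest member variance
  vs <- vapply(ms, function(m) var(predict_model(m, td$x, "BA")), numeric(1))
  expect_lte(var(em), max(vs))
  other <- init_model(predictor_spec(ncol(td$x), hidden = 7, heads = "BA"), 1)
  expect_error(ensemble_predict(c(ms, list(other)), td$x, "BA"),
               "share one architecture")
  expect_error(ensemble_predict(list(), td$x, "BA"), "empty")
})

test_that("model persistence round-trips predictions exactly and rejects bad files", {
  td <- toy_data(100, d = 9, seed = 5)
  tg <- data.frame(value = td$sep, head = "EL")
  m <- init_model(predictor_spec(9, hidden = c(7, 3), heads = c("BA", "EL")), 4)
  m <- train_model(m, td$x, tg, td$x, tg,
                   train_config(0.01, 32, max_epochs = 2, patience = 2, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(predict_model(back, td$x, "EL"), predict_model(m, td$x, "EL"))
  expect_identical(predict_model(back, td$x, "BA"), predict_model(m, td$x, "BA"))
  expect_equal(back$spec, m$spec)
  corrupt <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", corrupt)
  expect_error(load_model(corrupt), "cannot read model file")
  vfile <- withr::local_tempfile(fileext = ".json")
  obj <- jsonlite::read_json(f)
  obj$version <- "tlmhc-model-99"
  jsonlite::write_json(obj, vfile, auto_unbox = TRUE)
  expect_error(load_model(vfile), "version")
})

test_that("training errors are informative", {
  td <- toy_data(20)
  m <- init_model(predictor_spec(ncol(td$x), hidden = 4, heads = "BA"), 1)
  tg <- data.frame(value = rep(0.5, 20), head = "STAB")
  expect_error(train_model(m, td$x, tg, td$x, tg, train_config()),
               "absent from model")
  expect_error(train_model(m, td$x[0, , drop = FALSE], tg[0, ],
                           td$x, tg, train_config()), "empty training set")
})
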