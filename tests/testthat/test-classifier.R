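# Small synthetic feature tables keyed like real cluster outputs.
synth_features <- function(n, seed, ts = "t1") {
  set.seed(seed)
  tibble::tibble(
    cluster_id = sprintf("greedy.%s:%d", ts, seq_len(n)),
    size = sample(4:60, n, replace = TRUE),
    gene_ratio = stats::runif(n),
    disease_specificity = stats::runif(n),
    edges_inside = sample(2:200, n, replace = TRUE),
    aid = stats::runif(n, 1, 20),
    ngm = stats::runif(n, -0.1, 0.5),
    ae = stats::runif(n),
    conductance = stats::runif(n),
    cut = stats::runif(n, 0, 0.2)
  )
}

pvals_for <- function(features, p) {
  tibble::tibble(cluster_id = features$cluster_id, observed = 0L,
                 replicates = 100L, p = p)
}

test_that("training tables are balanced by down-sampling without duplication", {
  feats <- synth_features(14, seed = 81)
  p <- c(rep(0.01, 10), rep(0.9, 4))
  tbl <- make_training_table(feats, pvals_for(feats, p), threshold = 0.35,
                             seed = 1)
  expect_equal(sum(tbl$label == 1), 4)
  expect_equal(sum(tbl$label == 0), 4)
  expect_equal(anyDuplicated(tbl$cluster_id), 0)
  expect_equal(attr(tbl, "threshold"), 0.35)

  # labels use strict inequality: p exactly at the threshold is negative
  pb <- c(rep(0.35, 7), rep(0.01, 7))
  tb <- make_training_table(feats, pvals_for(feats, pb), threshold = 0.35)
  expect_equal(sum(tb$label), 7)

  expect_error(
    make_training_table(feats, pvals_for(feats, rep(0.9, 14)), 0.35),
    "cannot balance"
  )
})

test_that("temporal splits refuse leakage from the future", {
  f1 <- synth_features(10, seed = 82, ts = "t1")
  f2 <- synth_features(10, seed = 83, ts = "t2")
  feats <- dplyr::bind_rows(f1, f2)
  tbl <- make_training_table(feats, pvals_for(feats, rep(c(0.01, 0.9), 10)),
                             threshold = 0.35, seed = 1)
  sp <- temporal_split(tbl, test_timestamps = "t2")
  expect_true(all(sp$train$timestamp == "t1"))
  expect_true(all(sp$test$timestamp == "t2"))
  expect_error(temporal_split(tbl, test_timestamps = "t1"),
               "strictly earlier")
  expect_error(temporal_split(tbl, test_timestamps = "zzz"), "empty")
})

test_that("forward selection finds an oracle feature before noise", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 120
    oracle <- stats::runif(n)
    tbl <- tibble::tibble(
      cluster_id = sprintf("greedy.t1:%d", 1:n),
      timestamp = "t1",
      label = as.integer(oracle > 0.5),
      oracle_feature = oracle,
      noise = stats::runif(n)
    )
    sel <- sequential_feature_selection(
      tbl, candidate_features = c("noise", "oracle_feature"),
      k_folds = 4, seed = seed
    )
    expect_equal(sel[1], "oracle_feature")
  }

  # single candidate: returned as-is
  tbl1 <- tibble::tibble(cluster_id = "x.t1:1", timestamp = "t1",
                         label = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
                         f = c(0.1, 0.9, 0.2, 0.8, 0.15, 0.85, 0.1, 0.95))
  tbl1 <- tbl1[rep(1:8, 4), ]
  sel1 <- sequential_feature_selection(tbl1, candidate_features = "f",
                                       k_folds = 4, seed = 1)
  expect_equal(as.character(sel1), "f")
})

test_that("the genetic tuner honours its contracts", {
  set.seed(91)
  n <- 80
  x <- stats::runif(n)
  tbl <- tibble::tibble(
    cluster_id = sprintf("g.t1:%d", 1:n), timestamp = "t1",
    label = as.integer(x > 0.5), size = x, gene_ratio = stats::runif(n)
  )
  point <- hyperparam_space(
    learning_rate = c(0.1, 0.1), gamma = c(0.1, 0.1),
    n_estimators = c(20, 20), max_depth = c(3, 3),
    max_leaves = c(4, 4), subsample = c(0.9, 0.9)
  )
  res <- ga_tune(tbl, space = point, population = 4, generations = 2,
                 features = c("size", "gene_ratio"), k_folds = 3, seed = 1)
  expect_equal(res$best$learning_rate, 0.1)
  expect_equal(res$best$n_estimators, 20)
  expect_equal(length(unique(res$trace$hall_of_fame)), 1)

  space <- hyperparam_space(n_estimators = c(5, 60), max_depth = c(1, 6))
  res2 <- ga_tune(tbl, space = space, population = 6, generations = 4,
                  features = c("size", "gene_ratio"), k_folds = 3, seed = 2)
  expect_true(all(diff(res2$trace$hall_of_fame) >= 0))
  expect_gte(utils::tail(res2$trace$hall_of_fame, 1),
             res2$trace$hall_of_fame[1])
  expect_true(res2$best$n_estimators >= 5 && res2$best$n_estimators <= 60)
  expect_error(ga_tune(tbl, population = 1), ">= 2")
})

test_that("model training is reproducible and fits separable data", {
  set.seed(93)
  n <- 200
  x <- stats::runif(n)
  tbl <- tibble::tibble(
    cluster_id = sprintf("g.t1:%d", 1:n), timestamp = "t1",
    label = as.integer(x > 0.5), size = x, conductance = stats::runif(n)
  )
  attr(tbl, "threshold") <- 0.35
  m <- train_model(tbl, features = c("size", "conductance"), seed = 7)
  pred <- predict(m, tbl)
  expect_equal(mean(pred$call == tbl$label), 1.0)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))

  m2 <- train_model(tbl, features = c("size", "conductance"), seed = 7)
  expect_equal(predict(m2, tbl)$prob, pred$prob)

  bad <- tbl
  bad$size[1] <- NaN
  expect_error(train_model(bad, features = c("size", "conductance")),
               "non-finite")
  expect_error(predict(m, tbl[, c("cluster_id", "size")]),
               "missing feature")

  # broom-style accessors
  td <- tidy(m)
  expect_true(all(c("feature", "gain") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$threshold, 0.35)
  expect_equal(gl$n_features, 2L)
})

test_that("a planted linear signal is learned with high held-out AUC", {
  set.seed(95)
  n <- 800
  feats <- synth_features(n, seed = 95)
  signal <- 0.8 * feats$gene_ratio + 0.2 * feats$conductance > 0.5
  noise <- stats::runif(n) < 0.05
  feats$label <- as.integer(xor(signal, noise))
  feats$timestamp <- "t1"
  train <- feats[1:600, ]
  test <- feats[601:800, ]
  m <- train_model(train, seed = 3)
  expect_gte(evaluate_auc(m, test), 0.90)

  # shuffled labels carry no signal
  aucs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    tr <- train
    tr$label <- sample(tr$label)
    te <- test
    te$label <- sample(te$label)
    evaluate_auc(train_model(tr, seed = 3), te)
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("AUC evaluation matches the rank-statistic oracle", {
  tbl <- tibble::tibble(label = c(1, 1, 0, 0, 1, 0))
  expect_equal(evaluate_auc(c(1, 1, 0, 0, 1, 0), tbl), 1.0)
  expect_equal(evaluate_auc(c(0, 0, 1, 1, 0, 1), tbl), 0.0)
  expect_equal(evaluate_auc(rep(0.5, 6), tbl), 0.5)
  expect_error(evaluate_auc(c(0.2, 0.4), tibble::tibble(label = c(1, 1))),
               "single label class")

  set.seed(97)
  for (i in 1:5) {
    scores <- stats::runif(60)
    labels <- sample(0:1, 60, replace = TRUE)
    expect_equal(evaluate_auc(scores, tibble::tibble(label = labels)),
                 oracle_auc(scores, labels))
  }

  # random scores on large n hover near 0.5
  set.seed(98)
  scores <- stats::runif(1000)
  labels <- sample(0:1, 1000, replace = TRUE)
  expect_lt(abs(evaluate_auc(scores, tibble::tibble(label = labels)) - 0.5),
            0.05)
})

test_that("SHAP importance concentrates on informative features", {
  set.seed(99)
  n <- 300
  tbl <- tibble::tibble(
    cluster_id = sprintf("g.t1:%d", 1:n), timestamp = "t1",
    informative = stats::runif(n),
    noise1 = stats::runif(n), noise2 = stats::runif(n)
  )
  tbl$label <- as.integer(tbl$informative > 0.5)
  m <- train_model(tbl, features = c("informative", "noise1", "noise2"),
                   seed = 1)
  imp <- shap_importance(m, tbl)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$feature[1], "informative")

  # a single-feature model puts all mass on that feature
  m1 <- train_model(tbl, features = "informative", seed = 1)
  imp1 <- shap_importance(m1, tbl)
  expect_equal(imp1$feature, "informative")
  expect_gt(imp1$importance, 0)
})

test_that("cluster prediction tables cover every model threshold", {
  feats <- synth_features(30, seed = 101)
  p <- rep(c(0.01, 0.9), 15)
  models <- lapply(c(0.35, 0.05), function(thr) {
    tbl <- make_training_table(feats, pvals_for(feats, p), thr, seed = 1)
    train_model(tbl, seed = 1)
  })
  pred <- predict_clusters(models, feats)
  expect_equal(nrow(pred), 60)
  expect_setequal(unique(pred$threshold), c(0.35, 0.05))
  expect_true(all(pred$call %in% 0:1))
})
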