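#' Build a balanced training table for one significance threshold
#'
#' Labels every cluster 1 if its empirical p-value is strictly below
#' `threshold` and 0 otherwise, then randomly down-samples the majority
#' class without replacement to the minority class size. Four thresholds
#' are used in practice - 1.00, 0.35, 0.10 and 0.05 - each training its own
#' model; `p < 1.00` is the loosest meaningful label ("had more
#' rediscoveries than at least one synthetic cluster").
#'
#' @param features Feature table ([feature_table()]) keyed by `cluster_id`.
#' @param pvalues P-value table ([cluster_pvalues()]) keyed by `cluster_id`.
#' @param threshold Label threshold in (0, 1].
#' @param seed Seed for the down-sampling draw.
#' @return A balanced tibble with `cluster_id`, `label`, `timestamp`
#'   (parsed from the cluster id) and the feature columns; the threshold,
#'   seed and original class sizes are recorded as attributes.
#' @export
make_training_table <- function(features, pvalues, threshold, seed = 1) {
  tbl <- dplyr::inner_join(features, pvalues[, c("cluster_id", "p")],
                           by = "cluster_id")
  tbl$label <- as.integer(tbl$p < threshold)
  tbl$timestamp <- cluster_timestamp(tbl$cluster_id)
  tbl$p <- NULL
  n1 <- sum(tbl$label == 1)
  n0 <- sum(tbl$label == 0)
  if (n1 == 0 || n0 == 0) {
    stop("cannot balance: a label class is empty at threshold ", threshold,
         call. = FALSE)
  }
  n_min <- min(n0, n1)
  out <- with_seed(seed, {
    dplyr::group_by(tbl, .data$label) |>
      dplyr::slice_sample(n = n_min) |>
      dplyr::ungroup()
  })
  attr(out, "threshold") <- threshold
  attr(out, "seed") <- seed
  attr(out, "class_sizes") <- c(`0` = n0, `1` = n1)
  out
}

# Timestamp component of a cluster id "<method...>.<timestamp>:<index>".
cluster_timestamp <- function(cluster_id) {
  stem <- stringr::str_remove(cluster_id, ":\\d+$")
  stringr::str_extract(stem, "[^.]+$")
}

#' Split a labeled table into temporally disjoint train and test sets
#'
#' The evaluation contract is temporal: models are trained on clusters from
#' snapshots strictly earlier than the evaluation snapshot (train on the
#' past, test on the past's future). This helper enforces it and errors if
#' any training row is not strictly earlier than every test row
#' (timestamps compare lexicographically).
#'
#' @param table A labeled table carrying a `timestamp` column.
#' @param test_timestamps Timestamps forming the test set.
#' @return A list with `train` and `test` tibbles.
#' @export
temporal_split <- function(table, test_timestamps) {
  test <- table[table$timestamp %in% test_timestamps, ]
  train <- table[!table$timestamp %in% test_timestamps, ]
  if (nrow(train) == 0 || nrow(test) == 0) {
    stop("temporal split produced an empty train or test set", call. = FALSE)
  }
  if (max(train$timestamp) >= min(test$timestamp)) {
    stop("temporal split violated: training timestamps must be strictly ",
         "earlier than every test timestamp", call. = FALSE)
  }
  list(train = train, test = test)
}

rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("AUC undefined: table has a single label class", call. = FALSE)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

f1_score <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

default_hyperparams <- function() {
  list(learning_rate = 0.1, gamma = 0.1, n_estimators = 50,
       max_depth = 4, max_leaves = 8, subsample = 0.8)
}

xgb_params <- function(hp, seed, rate_drop = 0.1, skip_drop = 0.5) {
  list(
    booster = "dart", objective = "binary:logistic",
    eta = hp$learning_rate, gamma = hp$gamma,
    max_depth = as.integer(hp$max_depth),
    max_leaves = as.integer(hp$max_leaves),
    subsample = hp$subsample,
    rate_drop = rate_drop, skip_drop = skip_drop,
    tree_method = "hist", grow_policy = "lossguide",
    nthread = 1, seed = as.integer(seed)
  )
}

fit_booster <- function(x, y, hp, seed, rate_drop = 0.1, skip_drop = 0.5) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  with_seed(seed, {
    xgboost::xgb.train(
      params = xgb_params(hp, seed, rate_drop, skip_drop),
      data = dtrain, nrounds = as.integer(hp$n_estimators), verbose = 0
    )
  })
}

cv_score <- function(table, features, hp, k_folds, seed,
                     metric = c("auc", "f1")) {
  metric <- match.arg(metric)
  x <- as.matrix(table[, features, drop = FALSE])
  y <- table$label
  fold <- stratified_folds(y, k_folds, seed)
  scores <- vapply(seq_len(k_folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
    booster <- fit_booster(x[tr, , drop = FALSE], y[tr], hp,
                           seed = derive_seed(seed, f))
    p <- predict(booster, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
    if (metric == "auc") {
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      rank_auc(p, y[!tr])
    } else {
      f1_score(as.integer(p > 0.5), y[!tr])
    }
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Forward sequential feature selection
#'
#' Greedy forward selection: starting from the empty set, repeatedly adds
#' the candidate feature that most improves the stratified
#' cross-validated score, stopping when no candidate improves it (or all
#' are added). Deterministic given the seed.
#'
#' @param table A balanced labeled table ([make_training_table()]).
#' @param candidate_features Candidate feature columns; defaults to the
#'   nine cluster features.
#' @param k_folds Stratified CV folds (default 5).
#' @param seed Integer seed (fixes folds and model fits).
#' @param hyperparams Hyperparameters for the scoring model.
#' @param metric `"auc"` (default) or `"f1"`.
#' @return Character vector of selected feature names, with the score
#'   trace in the `"trace"` attribute.
#' @export
sequential_feature_selection <- function(table,
                                         candidate_features = bocc_feature_names(),
                                         k_folds = 5, seed = 1,
                                         hyperparams = default_hyperparams(),
                                         metric = "auc") {
  stopifnot(length(candidate_features) >= 1)
  selected <- character(0)
  best_score <- -Inf
  trace <- list()
  remaining <- candidate_features
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(f) {
      cv_score(table, c(selected, f), hyperparams, k_folds, seed, metric)
    }, numeric(1))
    top <- which.max(scores)
    if (scores[top] <= best_score) break
    best_score <- scores[top]
    selected <- c(selected, remaining[top])
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(selected), feature = remaining[top], score = best_score
    )
    remaining <- remaining[-top]
  }
  structure(selected, trace = dplyr::bind_rows(trace))
}

#' Hyperparameter search space
#'
#' The six tuned gradient-boosting hyperparameters and their ranges.
#' Integer parameters (`n_estimators`, `max_depth`, `max_leaves`) are
#' sampled as integers. A range may be collapsed to a point.
#'
#' @param learning_rate,gamma,n_estimators,max_depth,max_leaves,subsample
#'   Length-2 numeric ranges `c(min, max)`.
#' @return A named list of ranges with integer flags.
#' @export
hyperparam_space <- function(learning_rate = c(0.001, 0.1),
                             gamma = c(0.01, 1.00),
                             n_estimators = c(1, 500),
                             max_depth = c(1, 30),
                             max_leaves = c(1, 10),
                             subsample = c(0.01, 1.00)) {
  space <- list(learning_rate = learning_rate, gamma = gamma,
                n_estimators = n_estimators, max_depth = max_depth,
                max_leaves = max_leaves, subsample = subsample)
  stopifnot(all(vapply(space, length, 0L) == 2),
            all(vapply(space, function(r) r[1] <= r[2], TRUE)))
  attr(space, "integer") <- c("n_estimators", "max_depth", "max_leaves")
  space
}

# sample() semantics are unsafe for length-1 ranges; draw by index.
sample_range <- function(r, integer = FALSE) {
  if (integer) {
    v <- seq(r[1], r[2])
    v[sample.int(length(v), 1)]
  } else {
    stats::runif(1, r[1], r[2])
  }
}

sample_individual <- function(space) {
  int_params <- attr(space, "integer")
  out <- lapply(names(space), function(nm) {
    sample_range(space[[nm]], integer = nm %in% int_params)
  })
  stats::setNames(out, names(space))
}

#' Genetic-algorithm hyperparameter tuning
#'
#' Tunes the six boosting hyperparameters by a genetic algorithm with
#' tournament selection (k = 3), uniform crossover (p = 0.5), per-gene
#' uniform-resample mutation (p = 0.1) and elitism of 1, using the
#' cross-validated F1 score as fitness. The best-so-far (hall-of-fame)
#' fitness trace is non-decreasing by construction.
#'
#' The defaults of 40 individuals and 100 generations match full-scale
#' practice; fixture-scale runs use far fewer.
#'
#' @param table A balanced labeled table.
#' @param space A [hyperparam_space()].
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param features Feature columns used for fitness fits.
#' @param k_folds CV folds for fitness.
#' @param seed Integer seed.
#' @param mutation_p,crossover_p,tournament_k GA operator settings.
#' @return A list: `best` (named hyperparameter list), `best_fitness`, and
#'   `trace` (tibble: `generation`, `generation_best`, `hall_of_fame`).
#' @export
ga_tune <- function(table, space = hyperparam_space(), population = 40,
                    generations = 100, features = bocc_feature_names(),
                    k_folds = 5, seed = 1, mutation_p = 0.1,
                    crossover_p = 0.5, tournament_k = 3) {
  if (population < 2) stop("population must be >= 2", call. = FALSE)
  features <- intersect(features, names(table))
  cache <- new.env(parent = emptyenv())
  fitness <- function(ind) {
    key <- paste(signif(unlist(ind), 8), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- cv_score(table, features, ind, k_folds, seed, metric = "f1")
    cache[[key]] <- val
    val
  }
  with_seed(seed, {
    pop <- lapply(seq_len(population), function(i) sample_individual(space))
    fit <- vapply(pop, fitness, numeric(1))
    hof <- pop[[which.max(fit)]]
    hof_fit <- max(fit)
    trace <- list(tibble::tibble(generation = 0L, generation_best = max(fit),
                                 hall_of_fame = hof_fit))
    int_params <- attr(space, "integer")
    for (gen in seq_len(generations)) {
      select_one <- function() {
        idx <- sample.int(population, min(tournament_k, population))
        pop[[idx[which.max(fit[idx])]]]
      }
      offspring <- lapply(seq_len(population - 1), function(i) {
        p1 <- select_one(); p2 <- select_one()
        child <- p1
        for (nm in names(space)) {
          if (stats::runif(1) < crossover_p) child[[nm]] <- p2[[nm]]
          if (stats::runif(1) < mutation_p) {
            child[[nm]] <- sample_range(space[[nm]],
                                        integer = nm %in% int_params)
          }
        }
        child
      })
      pop <- c(list(hof), offspring)  # elitism of 1
      fit <- vapply(pop, fitness, numeric(1))
      if (max(fit) > hof_fit) {
        hof <- pop[[which.max(fit)]]
        hof_fit <- max(fit)
      }
      trace[[gen + 1]] <- tibble::tibble(
        generation = gen, generation_best = max(fit), hall_of_fame = hof_fit
      )
    }
    list(best = hof, best_fitness = hof_fit, trace = dplyr::bind_rows(trace))
  })
}

#' Train a threshold significance model
#'
#' Fits a dropout-regularised gradient-boosted tree classifier (DART
#' booster) predicting the cluster label of a balanced training table.
#' Training is reproducible given the seed.
#'
#' @param table A balanced labeled table ([make_training_table()]).
#' @param features Feature columns to train on.
#' @param hyperparams Named list of the six tuned hyperparameters.
#' @param seed Integer seed.
#' @param rate_drop,skip_drop DART dropout rates (defaults 0.1 / 0.5).
#' @return A `bocc_model` object.
#' @export
train_model <- function(table, features = bocc_feature_names(),
                        hyperparams = default_hyperparams(), seed = 1,
                        rate_drop = 0.1, skip_drop = 0.5) {
  features <- intersect(features, names(table))
  x <- as.matrix(table[, features, drop = FALSE])
  if (!all(is.finite(x))) {
    stop("non-finite feature values in the training table", call. = FALSE)
  }
  booster <- fit_booster(x, table$label, hyperparams, seed,
                         rate_drop, skip_drop)
  structure(list(
    booster = booster,
    threshold = attr(table, "threshold") %||% NA_real_,
    features = features,
    hyperparams = hyperparams,
    seed = seed,
    class_sizes = table(table$label),
    train_timestamps = sort(unique(table$timestamp))
  ), class = "bocc_model")
}

#' @export
print.bocc_model <- function(x, ...) {
  cat(sprintf(
    "<bocc_model p < %s> %d features, %d boosting rounds, %d training rows\n",
    format(x$threshold), length(x$features),
    as.integer(x$hyperparams$n_estimators), sum(x$class_sizes)
  ))
  invisible(x)
}

#' Predict cluster significance
#'
#' @param object A `bocc_model`.
#' @param newdata A feature table containing the model's feature columns
#'   (and optionally `cluster_id`).
#' @param ... Unused.
#' @return A tibble with `cluster_id` (if present), `prob` in \[0, 1\] and
#'   the binary `call` at probability 0.5.
#' @export
predict.bocc_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  prob <- predict(object$booster, xgboost::xgb.DMatrix(x))
  out <- tibble::tibble(prob = prob, call = as.integer(prob > 0.5))
  if ("cluster_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(newdata["cluster_id"], out)
  }
  out
}

#' Held-out ROC AUC of a threshold model
#'
#' Standard rank-statistic ROC AUC of the model's probabilities against the
#' table's labels (computed through pROC); constant scores give 0.5.
#'
#' @param model A `bocc_model` (or a numeric score vector).
#' @param table A labeled table with both classes present.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(model, table) {
  scores <- if (inherits(model, "bocc_model")) {
    predict(model, table)$prob
  } else {
    model
  }
  if (length(unique(table$label)) < 2) {
    stop("AUC undefined: table has a single label class", call. = FALSE)
  }
  if (length(unique(scores)) < 2) return(0.5)
  roc <- pROC::roc(response = table$label, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(roc))
}

#' SHAP feature importance
#'
#' Mean absolute SHAP (TreeSHAP) attribution per feature over the rows of a
#' table, via the booster's additive feature contributions.
#'
#' @param model A `bocc_model`.
#' @param table A feature table covering the model's features.
#' @return A tibble (`feature`, `importance`) sorted by importance.
#' @export
shap_importance <- function(model, table) {
  x <- as.matrix(table[, model$features, drop = FALSE])
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(x),
                     predcontrib = TRUE)
  contrib <- contrib[, colnames(contrib) %in% model$features, drop = FALSE]
  tibble::tibble(
    feature = colnames(contrib),
    importance = colMeans(abs(contrib))
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Tree-level feature importances of a threshold model
#'
#' @param x A `bocc_model`.
#' @param ... Unused.
#' @return A tibble with `feature`, `gain`, `cover`, `frequency`.
#' @method tidy bocc_model
#' @export
tidy.bocc_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(
    feature = imp$Feature,
    gain = imp$Gain,
    cover = imp$Cover,
    frequency = imp$Frequency
  )
}

#' One-row training summary of a threshold model
#'
#' @param x A `bocc_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance bocc_model
#' @export
glance.bocc_model <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_features = length(x$features),
    nrounds = as.integer(x$hyperparams$n_estimators),
    n_train = as.integer(sum(x$class_sizes)),
    seed = x$seed
  )
}
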