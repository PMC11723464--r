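#' Train/test split specification
#'
#' @param test_fraction Fraction of records held out for testing,
#'   in (0, 1) (default 0.2).
#' @param stratified Preserve class proportions in both partitions
#'   (default TRUE).
#' @param seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, stratified = TRUE, seed = 0L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Classifier specification
#'
#' The three supervised algorithms compared by the pipeline, with the fixed
#' hyperparameters used for the final models: random forest (100 trees,
#' Gini split criterion, unbounded depth), k-nearest neighbours (k = 5,
#' uniform weights, Euclidean metric) and l2-penalised logistic regression.
#' Optionally, hyperparameters can instead be tuned by seeded random search
#' over documented spaces with stratified `cv_folds`-fold cross-validation
#' maximising accuracy.
#'
#' @param algorithm One of `"random_forest"`, `"knn"`,
#'   `"logistic_regression"`.
#' @param n_estimators Random forest tree count (default 100).
#' @param n_neighbors KNN neighbour count (default 5).
#' @param C Inverse l2 penalty strength for logistic regression
#'   (default 1; the penalty is `lambda = 1 / (C * n_train)`).
#' @param cv_folds Folds for cross-validation (default 5, >= 2).
#' @param search `"none"` (fixed hyperparameters, default) or
#'   `"random_search"`.
#' @param search_budget Number of random-search draws (default 20).
#' @param standardize Standardise features before fitting (default FALSE;
#'   provided because KNN is scale-sensitive).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("random_forest", "knn",
                                     "logistic_regression"),
                       n_estimators = 100L, n_neighbors = 5L, C = 1,
                       cv_folds = 5L, search = c("none", "random_search"),
                       search_budget = 20L, standardize = FALSE) {
  algorithm <- match.arg(algorithm)
  search <- match.arg(search)
  stopifnot(n_estimators >= 1L, n_neighbors >= 1L, C > 0, cv_folds >= 2L,
            search_budget >= 1L)
  structure(list(algorithm = algorithm,
                 n_estimators = as.integer(n_estimators),
                 n_neighbors = as.integer(n_neighbors), C = C,
                 cv_folds = as.integer(cv_folds), search = search,
                 search_budget = as.integer(search_budget),
                 standardize = isTRUE(standardize)),
            class = "model_spec")
}

#' Default feature set: the selected vegetation indices
#' @return Character vector `gndvi, gci, ndrei, nri, gi`.
#' @export
default_features <- function() c("gndvi", "gci", "ndrei", "nri", "gi")

#' Stratified train/test split
#'
#' Per class, `round(class_n * test_fraction)` records go to the test set
#' (simple random within class, seeded); with `stratified = FALSE` a single
#' unstratified draw of `round(n * test_fraction)` records is used.
#'
#' @param table Data frame with a binary `label` column; both classes must
#'   be present and `nrow >= 10`.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` data frames (disjoint, exhaustive).
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (length(unique(table$label)) < 2L) {
    stop("both classes must be present for a stratified split",
         call. = FALSE)
  }
  if (nrow(table) < 10L && spec$test_fraction * nrow(table) < 2) {
    stop("too few records to split", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    test_idx <- if (spec$stratified) {
      unlist(lapply(unique(table$label), function(cl) {
        ii <- which(table$label == cl)
        sample(ii, round(length(ii) * spec$test_fraction))
      }))
    } else {
      sample.int(nrow(table), round(nrow(table) * spec$test_fraction))
    }
    list(train = table[-test_idx, , drop = FALSE],
         test = table[test_idx, , drop = FALSE])
  })
}

#' Fit a binary health classifier
#'
#' Trains the classifier named in `spec` on per-slice VI features. With
#' `spec$search = "random_search"`, hyperparameters are first tuned by
#' seeded random search (stratified `cv_folds`-fold cross-validated
#' accuracy) and the winner is refit on the full training set.
#'
#' @param spec A [model_spec()].
#' @param train Data frame with feature columns and a binary `label`.
#' @param feature_names Feature columns to use (default: the selected VI
#'   set from [default_features()]).
#' @param seed Integer seed (controls forest growth, tie-breaks and search).
#' @return An object of class `health_model` with a [predict][predict.health_model] method.
#' @export
fit_health_model <- function(spec, train, feature_names = default_features(),
                             seed = 0L) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(train),
            all(feature_names %in% names(train)),
            "label" %in% names(train))
  x <- as.matrix(train[feature_names])
  if (any(!is.finite(x))) {
    bad <- which(!stats::complete.cases(x) | rowSums(!is.finite(x)) > 0)[1]
    id <- if ("slice_id" %in% names(train)) train$slice_id[bad] else bad
    stop("non-finite feature value in slice ", id, call. = FALSE)
  }
  y <- as.integer(train$label)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)

  if (spec$search == "random_search") {
    spec <- tune_random_search(spec, train, feature_names, seed)
  }
  ctr <- NULL; scl <- NULL
  if (spec$standardize) {
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- scale(x, ctr, scl)
  }
  fit <- withr::with_seed(seed, switch(spec$algorithm,
    random_forest = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0L, 1L)),
      ntree = spec$n_estimators),
    knn = list(x = x, y = y),  # lazy learner: keep the training set
    logistic_regression = glmnet::glmnet(
      x = x, y = y, family = "binomial", alpha = 0,
      lambda = 1 / (spec$C * nrow(x)), thresh = 1e-10)
  ))
  structure(list(spec = spec, fit = fit, feature_names = feature_names,
                 center = ctr, scale = scl, seed = as.integer(seed)),
            class = "health_model")
}

# seeded random search over documented spaces, stratified CV accuracy
tune_random_search <- function(spec, train, feature_names, seed) {
  draws <- withr::with_seed(seed + 1L, lapply(seq_len(spec$search_budget),
    function(i) switch(spec$algorithm,
      random_forest = list(n_estimators = sample(c(50L, 100L, 200L, 300L,
                                                   500L), 1L)),
      knn = list(n_neighbors = sample(1:15, 1L)),
      logistic_regression = list(C = 10^stats::runif(1, -3, 3)))))
  accs <- vapply(draws, function(d) {
    cand <- spec
    cand[names(d)] <- d
    cand$search <- "none"
    cv <- crossval_health(cand, train, feature_names, seed = seed + 2L)
    cv$mean_accuracy
  }, numeric(1))
  best <- draws[[which.max(accs)]]
  spec[names(best)] <- best
  spec$search <- "none"
  spec
}

#' Predict health labels
#'
#' @param object A [fit_health_model()] result.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.health_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$feature_names])
  if (!is.null(object$center)) x <- scale(x, object$center, object$scale)
  withr::with_seed(object$seed + 17L, switch(object$spec$algorithm,
    random_forest = as.integer(as.character(
      stats::predict(object$fit, x))),
    knn = as.integer(as.character(class::knn(
      train = object$fit$x, test = x,
      cl = factor(object$fit$y, levels = c(0L, 1L)),
      k = object$spec$n_neighbors))),
    logistic_regression = as.integer(
      stats::predict(object$fit, newx = x, type = "response")[, 1] >= 0.5)
  ))
}

#' Evaluate binary predictions
#'
#' Builds the full evaluation report with unhealthy (label 1) as the
#' positive class: confusion counts, accuracy, per-class precision, recall
#' and F1, macro and support-weighted averages, and the false-negative
#' count and rate. A false negative is a truly unhealthy slice predicted
#' healthy; its rate is reported relative to the whole test set.
#'
#' @param truth Integer vector of true 0/1 labels.
#' @param pred Integer vector of predicted 0/1 labels.
#' @return An object of class `eval_report`.
#' @export
evaluate_predictions <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0,
            all(truth %in% c(0L, 1L)), all(pred %in% c(0L, 1L)))
  tp <- sum(truth == 1L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  n <- length(truth)
  safe_div <- function(a, b) if (b > 0) a / b else 0
  prec1 <- safe_div(tp, tp + fp); rec1 <- safe_div(tp, tp + fn)
  prec0 <- safe_div(tn, tn + fn); rec0 <- safe_div(tn, tn + fp)
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  f1_1 <- f1(prec1, rec1); f1_0 <- f1(prec0, rec0)
  n0 <- tn + fp; n1 <- tp + fn
  structure(list(
    tn = tn, fp = fp, fn = fn, tp = tp, n_test = n,
    accuracy = (tp + tn) / n,
    precision_0 = prec0, recall_0 = rec0, f1_0 = f1_0,
    precision_1 = prec1, recall_1 = rec1, f1_1 = f1_1,
    macro_precision = (prec0 + prec1) / 2,
    macro_recall = (rec0 + rec1) / 2,
    macro_f1 = (f1_0 + f1_1) / 2,
    weighted_precision = (n0 * prec0 + n1 * prec1) / n,
    weighted_recall = (n0 * rec0 + n1 * rec1) / n,
    weighted_f1 = (n0 * f1_0 + n1 * f1_1) / n,
    fn_count = fn, fn_rate = fn / n),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n=%d acc=%.3f F1(0)=%.3f F1(1)=%.3f FN=%d (%.1f%%)\n",
              x$n_test, x$accuracy, x$f1_0, x$f1_1, x$fn_count,
              100 * x$fn_rate))
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' @param model A [fit_health_model()] result.
#' @param test Data frame with feature columns and binary `label`; both
#'   classes must be present.
#' @return An `eval_report` (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(nrow(test) > 0)
  if (length(unique(test$label)) < 2L) {
    stop("test set must contain both classes", call. = FALSE)
  }
  evaluate_predictions(test$label, predict(model, test))
}

#' Stratified k-fold cross-validation
#'
#' Partitions the records into `spec$cv_folds` stratified folds (seeded);
#' each record is tested exactly once. Returns the per-fold reports plus the
#' mean and standard deviation of fold accuracies.
#'
#' @param spec A [model_spec()] (its `search` setting is ignored here).
#' @param table Data frame with features and binary `label`.
#' @param feature_names Feature columns.
#' @param seed Integer seed.
#' @return List with `fold_reports`, `mean_accuracy`, `sd_accuracy`,
#'   `fold_assignment`.
#' @export
crossval_health <- function(spec, table, feature_names = default_features(),
                            seed = 0L) {
  k <- spec$cv_folds
  stopifnot(nrow(table) >= k)
  counts <- table(table$label)
  if (any(counts < k)) {
    stop("every class needs at least cv_folds members", call. = FALSE)
  }
  fold <- integer(nrow(table))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      ii <- which(table$label == as.integer(cl))
      fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
    }
  })
  fit_spec <- spec
  fit_spec$search <- "none"
  reports <- lapply(seq_len(k), function(f) {
    m <- fit_health_model(fit_spec, table[fold != f, , drop = FALSE],
                          feature_names, seed = seed + f)
    evaluate_predictions(table$label[fold == f],
                         predict(m, table[fold == f, , drop = FALSE]))
  })
  accs <- vapply(reports, `[[`, numeric(1), "accuracy")
  list(fold_reports = reports, mean_accuracy = mean(accs),
       sd_accuracy = stats::sd(accs), fold_assignment = fold)
}
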