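#' Classifier configuration
#'
#' Defaults follow the comparison settings used throughout the pipeline:
#' gradient boosting with 1000 trees and learning rate 0.1 (remaining
#' backend parameters at their documented defaults); AdaBoost with
#' depth-10 decision-tree weak learners and minimum split size 5; random
#' forest with depth cap 10 and at most 100 candidate features per split;
#' an RBF-kernel SVM with `C = 50`.
#'
#' @param kind one of `"gbdt"`, `"adaboost"`, `"random_forest"`, `"svm"`.
#' @param ... kind-specific overrides (e.g. `nrounds`, `eta` for gbdt;
#'   `n_rounds`, `max_depth`, `min_split` for adaboost; `ntree`, `max_depth`,
#'   `max_features` for random_forest; `cost`, `gamma` for svm).
#' @param seed integer seed for the backend's randomness.
#' @return A list of class `clf_config`.
#' @export
classifier_config <- function(kind = c("gbdt", "adaboost", "random_forest",
                                       "svm"),
                              ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    gbdt = list(nrounds = 1000L, eta = 0.1, max_depth = 6L),
    adaboost = list(n_rounds = 50L, max_depth = 10L, min_split = 5L),
    random_forest = list(ntree = 500L, max_depth = 10L, max_features = 100L),
    svm = list(cost = 50, gamma = NULL))
  override <- list(...)
  if (length(bad <- setdiff(names(override), names(defaults)))) {
    stop("unknown ", kind, " parameter: ", bad[1])
  }
  defaults[names(override)] <- override
  structure(list(kind = kind, parameters = defaults, seed = as.integer(seed)),
            class = "clf_config")
}

# mean-impute NA columns; all-NA columns fall back to 0
impute_columns <- function(X, means = NULL) {
  if (is.null(means)) {
    means <- colMeans(X, na.rm = TRUE)
    means[!is.finite(means)] <- 0
  }
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- means[nas[, 2]]
  list(X = X, means = means)
}

#' Train a classifier on a pair feature table
#'
#' Gradient boosting consumes missing feature values natively; the other
#' backends require complete data, so their training matrix is mean-imputed
#' column-wise (with a warning) and the imputation means are stored for
#' scoring.
#'
#' @param table a `pair_feature_table` with both labels present.
#' @param config a [classifier_config()].
#' @return Object of class `trained_model`: the fitted backend, the config,
#'   feature-block metadata and (where applicable) imputation means.
#' @export
train_classifier <- function(table, config = classifier_config()) {
  X <- table$X
  y <- table$label
  if (!nrow(X)) stop("empty feature table")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  p <- config$parameters
  imp_means <- NULL
  if (config$kind != "gbdt" && anyNA(X)) {
    warning("backend '", config$kind,
            "' cannot consume missing values: mean-imputing ",
            sum(is.na(X)), " cells")
    imp <- impute_columns(X)
    X <- imp$X
    imp_means <- imp$means
  }
  fit <- switch(config$kind,
    gbdt = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$eta,
                      max_depth = p$max_depth, nthread = 1,
                      seed = config$seed),
        data = dtrain, nrounds = p$nrounds, verbose = 0)
    },
    adaboost = adaboost_fit(X, y, n_rounds = p$n_rounds,
                            max_depth = p$max_depth, min_split = p$min_split,
                            seed = config$seed),
    random_forest = {
      requireNamespace("randomForest", quietly = TRUE) ||
        stop("randomForest package required")
      withr::with_seed(config$seed,
        randomForest::randomForest(
          x = X, y = factor(y, levels = c(0, 1)),
          ntree = p$ntree, mtry = min(p$max_features, ncol(X)),
          maxnodes = min(2L^p$max_depth, nrow(X))))
    },
    svm = {
      requireNamespace("e1071", quietly = TRUE) ||
        stop("e1071 package required")
      withr::with_seed(config$seed,
        e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                   kernel = "radial", cost = p$cost,
                   gamma = if (is.null(p$gamma)) 1 / ncol(X) else p$gamma,
                   probability = TRUE, scale = FALSE))
    })
  structure(list(fit = fit, config = config, width = ncol(X),
                 blocks = table$blocks, mode = table$mode,
                 impute_means = imp_means),
            class = "trained_model")
}

#' Score pairs with a trained classifier
#'
#' @param model a `trained_model`.
#' @param table a `pair_feature_table` with the same feature width as the
#'   training table.
#' @return Numeric vector of scores in `[0, 1]`, one per row, in row order.
#' @export
predict_scores <- function(model, table) {
  X <- if (inherits(table, "pair_feature_table")) table$X else as.matrix(table)
  if (!nrow(X)) return(numeric(0))
  if (ncol(X) != model$width) {
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(X), model$width))
  }
  if (!is.null(model$impute_means) && anyNA(X)) {
    X <- impute_columns(X, model$impute_means)$X
  } else if (is.null(model$impute_means) && model$config$kind != "gbdt" &&
             anyNA(X)) {
    X <- impute_columns(X)$X
  }
  switch(model$config$kind,
    gbdt = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X))),
    adaboost = adaboost_score(model$fit, X),
    random_forest = unname(predict(model$fit, X, type = "prob")[, "1"]),
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    })
}

# --- AdaBoost (SAMME with two classes) ------------------------------------
# Weighted rpart stumps/trees re-fit on reweighted samples; the returned
# score is the alpha-weighted vote share for the positive class.
adaboost_fit <- function(X, y, n_rounds = 50L, max_depth = 10L,
                         min_split = 5L, seed = 1L) {
  requireNamespace("rpart", quietly = TRUE) || stop("rpart package required")
  df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  withr::with_seed(seed, {
    for (t in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, minsplit = min_split,
                            cp = 0, xval = 0))
      pred <- predict(fit, df, type = "class")
      err <- sum(w * (pred != df$.y))
      if (err <= 1e-12) {           # perfect weak learner: take it and stop
        trees[[t]] <- fit; alphas[t] <- 10; break
      }
      if (err >= 0.5) break         # no better than chance on weighted data
      alpha <- 0.5 * log((1 - err) / err)
      trees[[t]] <- fit
      alphas[t] <- alpha
      w <- w * exp(alpha * ifelse(pred != df$.y, 1, -1))
      w <- w / sum(w)
    }
  })
  if (!length(trees)) {  # fall back to a single unweighted tree
    trees <- list(rpart::rpart(.y ~ ., data = df, method = "class",
                               control = rpart::rpart.control(
                                 maxdepth = max_depth, minsplit = min_split,
                                 cp = 0, xval = 0)))
    alphas <- 1
  }
  list(trees = trees, alphas = alphas, columns = colnames(X))
}

adaboost_score <- function(fit, X) {
  df <- as.data.frame(X, check.names = FALSE)
  votes <- numeric(nrow(df))
  for (t in seq_along(fit$trees)) {
    pred <- predict(fit$trees[[t]], df, type = "class")
    votes <- votes + fit$alphas[t] * (pred == "1")
  }
  votes / sum(fit$alphas)
}
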