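#' Classifier configuration
#'
#' @param model one of `"KNN"`, `"RF"`, `"SVM"`, `"NB"`, `"LR"`.
#' @param params named list of model parameters:
#'   \describe{
#'     \item{KNN}{`n_neighbors` (default 5), `p` (Minkowski exponent, 1 or
#'       2), `weights` (`"uniform"` or `"distance"`)}
#'     \item{RF}{`n_estimators` (default 300), `max_depth` (mapped to a
#'       `maxnodes` cap of `2^max_depth`), `mtry`}
#'     \item{SVM}{`C` (cost), `kernel` (`"linear"` or `"radial"`)}
#'     \item{NB}{none (Gaussian likelihoods)}
#'     \item{LR}{optional `penalty` (`"l1"`/`"l2"`) with inverse strength
#'       `C`; unpenalized maximum likelihood otherwise}
#'   }
#' @param dataset_variant optional tag recording which preprocessing
#'   variant the config is meant for (`"IMV"`, `"IMV+SS"`, ...).
#' @return object of class `model_config`.
#' @export
model_config <- function(model = c("LR", "KNN", "RF", "SVM", "NB"),
                         params = list(), dataset_variant = NULL) {
  model <- match.arg(model)
  structure(list(model = model, params = params,
                 dataset_variant = dataset_variant),
            class = "model_config")
}

# Deterministic exact k-NN: Minkowski p in {1, 2}, uniform or inverse-
# distance vote weights; neighbor-distance ties broken by training index,
# vote ties by class 0. Written in-package because the benchmark needs
# Manhattan distance, distance weighting and deterministic tie-breaks.
knn_predict <- function(X_train, y_train, X_test, k = 5L, p = 2L,
                        weights = c("uniform", "distance")) {
  weights <- match.arg(weights)
  k <- min(as.integer(k), nrow(X_train))
  score <- numeric(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    d <- abs(X_train - matrix(X_test[i, ], nrow(X_train), ncol(X_train),
                              byrow = TRUE))
    dist_i <- if (p == 1) rowSums(d) else sqrt(rowSums(d^2))
    nb <- order(dist_i, seq_along(dist_i))[seq_len(k)]
    w <- if (weights == "uniform") rep(1, k) else 1 / pmax(dist_i[nb], 1e-12)
    score[i] <- sum(w * (y_train[nb] == 1L)) / sum(w)
  }
  list(pred = as.integer(score > 0.5), score = score)
}

#' Fit a classifier on a training split and predict a test split
#'
#' The single dispatch point used by cross-validation, grid search and the
#' wrapper searches. Returns hard 0/1 predictions plus a class-1 score
#' (probability, vote fraction or decision value) for AUC computation.
#' Models with internal randomness (RF) are seeded so the same inputs give
#' the same predictions.
#'
#' @param config a [model_config()].
#' @param X_train,X_test numeric matrices (same columns).
#' @param y_train 0/1 training labels.
#' @param seed integer seed for stochastic fitters.
#' @return list with `pred` (integer 0/1) and `score` (numeric).
#' @export
fit_predict <- function(config, X_train, y_train, X_test, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  pr <- config$params
  colnames(X_train) <- colnames(X_test) <- paste0("V", seq_len(ncol(X_train)))
  switch(
    config$model,
    KNN = knn_predict(X_train, y_train, X_test,
                      k = pr$n_neighbors %||% 5L, p = pr$p %||% 2L,
                      weights = pr$weights %||% "uniform"),
    RF = {
      maxnodes <- if (!is.null(pr$max_depth)) {
        min(2^pr$max_depth, max(2L, nrow(X_train)))
      } else {
        NULL
      }
      fit <- with_seed(seed, randomForest::randomForest(
        x = X_train, y = factor(y_train, levels = c(0, 1)),
        ntree = pr$n_estimators %||% 300L, maxnodes = maxnodes,
        mtry = pr$mtry %||% max(1L, floor(sqrt(ncol(X_train))))
      ))
      prob <- stats::predict(fit, X_test, type = "prob")[, "1"]
      list(pred = as.integer(prob > 0.5), score = as.numeric(prob))
    },
    SVM = {
      fit <- e1071::svm(X_train, factor(y_train, levels = c(0, 1)),
                        kernel = pr$kernel %||% "linear",
                        cost = pr$C %||% 1, scale = FALSE)
      dvm <- attr(stats::predict(fit, X_test, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # e1071 orients the decision value toward the first-named class;
      # flip when that class is 0 so larger always means class 1
      if (startsWith(colnames(dvm)[1], "0/")) dv <- -dv
      list(pred = as.integer(dv > 0), score = as.numeric(dv))
    },
    NB = {
      df_tr <- as.data.frame(X_train)
      fit <- e1071::naiveBayes(df_tr, factor(y_train, levels = c(0, 1)))
      prob <- stats::predict(fit, as.data.frame(X_test), type = "raw")[, "1"]
      list(pred = as.integer(prob > 0.5), score = as.numeric(prob))
    },
    LR = {
      if (!is.null(pr$penalty)) {
        alpha <- if (identical(pr$penalty, "l1")) 1 else 0
        lambda <- 1 / ((pr$C %||% 1) * nrow(X_train))
        fit <- glmnet::glmnet(X_train, y_train, family = "binomial",
                              alpha = alpha, lambda = lambda,
                              standardize = FALSE)
        prob <- as.numeric(stats::predict(fit, X_test, type = "response"))
      } else {
        df <- as.data.frame(X_train)
        df$.y <- y_train
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = df, family = stats::binomial())
        )
        prob <- suppressWarnings(
          stats::predict(fit, as.data.frame(X_test), type = "response")
        )
      }
      list(pred = as.integer(prob > 0.5), score = as.numeric(prob))
    }
  )
}
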