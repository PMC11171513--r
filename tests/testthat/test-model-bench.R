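test_that("metric suite satisfies its internal identities", {
  # 124 correct of 136: the accuracy/RMSE pair and their identity
  y <- rep(c(0L, 1L), each = 68)
  yhat <- y
  flip <- c(1:6, 69:74) # 12 errors
  yhat[flip] <- 1L - yhat[flip]
  rep <- compute_metrics(y, yhat)
  expect_equal(round(rep$accuracy, 4), 0.9118)
  expect_equal(round(rep$rmse, 4), 0.2970)
  expect_equal(rep$rmse^2, 1 - rep$accuracy, tolerance = 1e-12)
  # perfect prediction
  perfect <- compute_metrics(y, y, scores = y + 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$std, 0)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  # identities on random confusion patterns
  set.seed(7)
  for (i in 1:25) {
    n <- 50
    yy <- rbinom(n, 1, 0.5)
    pp <- rbinom(n, 1, 0.5)
    if (length(unique(yy)) < 2) next
    r <- compute_metrics(yy, pp)
    expect_equal(r$accuracy, sum(diag(r$confusion)) / n, tolerance = 1e-12)
    expect_equal(r$rmse^2, 1 - r$accuracy, tolerance = 1e-12)
    if (!is.na(r$f1)) {
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC is a rank statistic: monotone-invariant and pROC-consistent", {
  set.seed(11)
  y <- rbinom(200, 1, 0.5)
  s <- rnorm(200) + y
  a1 <- compute_metrics(y, as.integer(s > 0.5), scores = s)$auc
  a2 <- compute_metrics(y, as.integer(s > 0.5), scores = exp(3 * s))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(a1, ref, tolerance = 1e-10)
})

test_that("null AUC and permuted-label accuracy are calibrated", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rep(c(0L, 1L), 1000)
    compute_metrics(y, y, scores = rnorm(2000))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  accs <- vapply(1:20, function(s) {
    tab <- generate_cohort(planted_spec(2, 2, d = 0, n = 100), s)
    cross_validate(tab, feature_names(tab), model_config("LR"),
                   folds = 5, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("cross-validation is deterministic and aces separable data", {
  x <- c(rnorm(25, -4), rnorm(25, 4))
  set.seed(3)
  tab <- tiny_table(cbind(sep = x, noise = rnorm(50)),
                    rep(c(0L, 1L), each = 25))
  knn1 <- model_config("KNN", list(n_neighbors = 1L))
  rep <- cross_validate(tab, "sep", knn1, folds = 5, seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$rmse, 0)
  r2 <- cross_validate(tab, "sep", knn1, folds = 5, seed = 1)
  expect_equal(rep$accuracy, r2$accuracy)
  expect_identical(rep$fold_ids, r2$fold_ids)
  expect_error(cross_validate(tab, "sep", knn1, folds = 30, seed = 1),
               "fold count")
})

test_that("every classifier family fits, predicts and scores", {
  tab <- generate_cohort(planted_spec(3, 2, d = 1, n = 80), 6)
  feats <- feature_names(tab)
  configs <- list(
    model_config("KNN", list(n_neighbors = 5L, p = 1L, weights = "distance")),
    model_config("RF", list(n_estimators = 50L, max_depth = 4L)),
    model_config("SVM", list(C = 1, kernel = "linear")),
    model_config("NB"),
    model_config("LR"),
    model_config("LR", list(penalty = "l1", C = 10))
  )
  for (cfg in configs) {
    rep <- cross_validate(tab, feats, cfg, folds = 5, seed = 2)
    expect_gte(rep$accuracy, 0.6) # d = 1 on 3 features is an easy problem
    expect_false(is.na(rep$auc))
    expect_gte(rep$auc, 0.6)
  }
})

test_that("grid search is exhaustive with first-in-order tie-breaks", {
  tab <- generate_cohort(planted_spec(2, 2, d = 1.2, n = 60), 9)
  feats <- feature_names(tab)
  single <- grid_search(tab, feats, "KNN", list(list(n_neighbors = 3L)),
                        folds = 5, seed = 1)
  expect_equal(single$params$n_neighbors, 3L)
  grid <- list(list(n_neighbors = 3L), list(n_neighbors = 7L))
  dup <- c(grid, grid)
  w1 <- grid_search(tab, feats, "KNN", grid, folds = 5, seed = 1)
  w2 <- grid_search(tab, feats, "KNN", dup, folds = 5, seed = 1)
  expect_identical(w1$params, w2$params) # duplicates cannot change the winner
  expect_equal(nrow(attr(w2, "results")), 4L)
  # the published RF setting is representable and runnable
  rf <- grid_search(tab, feats, "RF",
                    list(list(max_depth = 16L, n_estimators = 300L)),
                    folds = 3, seed = 1)
  expect_equal(rf$params$n_estimators, 300L)
  expect_gt(attr(rf, "accuracy"), 0.5)
  expect_error(grid_search(tab, feats, "KNN", list(), 5, 1), "non-empty")
})

test_that("method comparison is paired and Table-6 shaped", {
  tab <- generate_cohort(planted_spec(4, 8, d = 0.8, n = 150), 3)
  reports <- compare_methods(tab, model = model_config("LR"), k = 6,
                             folds = 5, seed = 3)
  expect_named(reports, c("HCMFS", "FS", "R_F", "MI", "DCFS"))
  folds0 <- reports[[1]]$fold_ids
  for (r in reports) {
    expect_identical(r$fold_ids, folds0) # identical fold partitions
    expect_true(all(r$subset %in% feature_names(tab)))
  }
  sizes <- vapply(reports[c("FS", "R_F", "MI", "DCFS")],
                  function(r) length(r$subset), numeric(1))
  expect_true(all(sizes == 6))
  expect_error(compare_methods(tab, methods = "XX"), "unknown method")
})

test_that("the bundled model settings ship all five methods and models", {
  grids <- model_grids()
  expect_named(grids, c("HCMFS", "FS", "R_F", "MI", "DCFS"))
  for (m in names(grids)) {
    expect_setequal(names(grids[[m]]), c("KNN", "RF", "SVM", "NB", "LR"))
  }
  expect_equal(grids$HCMFS$RF$params$max_depth, 16)
  expect_equal(grids$HCMFS$RF$params$n_estimators, 300)
})
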