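fake_classes <- function(assignment) {
  structure(list(classes = assignment, k = max(assignment)),
            class = "feature_classes")
}

test_that("per-class mean Fisher scores are plain arithmetic means", {
  sv <- score_vector("FS", c(a = 0.5, b = 0.1, c = 0.3, d = 0.3))
  cl <- fake_classes(c(a = 1L, b = 1L, c = 2L, d = 2L))
  mfs <- mean_fisher_by_class(sv, cl)
  expect_equal(unname(mfs), c(0.3, 0.3))
  single <- mean_fisher_by_class(sv, fake_classes(c(a = 1L, b = 2L, c = 2L, d = 2L)))
  expect_equal(single[["1"]], 0.5) # singleton class mean = its only score
  sv2 <- score_vector("FS", c(a = 0.5))
  expect_error(mean_fisher_by_class(sv2, cl), "no score")
})

test_that("seeding keeps only features strictly above their class mean", {
  sv <- score_vector("FS", c(a = 0.5, b = 0.1, c = 0.3, d = 0.3))
  cl <- fake_classes(c(a = 1L, b = 1L, c = 2L, d = 2L))
  seed <- initial_subset(sv, cl)
  expect_identical(seed$features, "a") # class 2 all-tied: strict > drops both
  # k = 1: everything above the global mean
  glob <- initial_subset(sv, fake_classes(c(a = 1L, b = 1L, c = 1L, d = 1L)))
  expect_setequal(glob$features, c("a")) # mean 0.3; only a exceeds it strictly
  # the seed can reach 8 of 20 features on a cohort-shaped table
  tab <- generate_cohort(table1_spec(missing_rate = 0), 1)
  std <- standardize_table(tab)
  cl20 <- cut_tree(ward_cluster(feature_distance_matrix(std)), 3)
  s20 <- initial_subset(rank_features(tab, "FS"), cl20)
  expect_gte(length(s20$features), 1L)
  expect_lte(length(s20$features), 19L)
  expect_length(s20$class_means, 3L)
})

test_that("forward search accepts only strict CV-accuracy gains", {
  tab <- generate_cohort(planted_spec(2, 3, d = 1.5, n = 60), 4)
  cfg <- hcmfs_config(classifier = model_config("KNN",
                                                list(n_neighbors = 1L)),
                      seed = 4)
  res <- forward_search(tab, c("inf1"), cfg)
  expect_s3_class(res, "selection_result")
  expect_equal(res$direction, "forward")
  expect_true("inf1" %in% res$subset)
  accs <- vapply(res$accuracy_trace, `[[`, numeric(1), "accuracy")
  expect_equal(res$final_accuracy, max(accs))
  expect_true(all(diff(accs) > 0)) # strict acceptance rule
  # under a duplication-invariant classifier a copied column can never add
  # accuracy, so it is rejected
  v <- cbind(tab$values, inf1copy = tab$values[, "inf1"])
  tabd <- tiny_table(v, tab$labels)
  resd <- forward_search(tabd, c("inf1"), hcmfs_config(seed = 4))
  expect_false("inf1copy" %in% resd$subset)
  expect_error(forward_search(tab, "ghost", cfg), "subset")
})

test_that("backward search protects the seed and removes redundancy", {
  tab <- generate_cohort(planted_spec(2, 3, d = 1.5, n = 60), 5)
  v <- cbind(tab$values, inf1copy = tab$values[, "inf1"])
  tabd <- tiny_table(v, tab$labels)
  # logistic regression aliases an exactly collinear column, so dropping the
  # duplicate can never cost accuracy and the no-decrease rule removes it
  cfg <- hcmfs_config(seed = 5)
  res <- backward_search(tabd, c("inf1", "inf2"), cfg)
  expect_equal(res$direction, "backward")
  expect_true(all(c("inf1", "inf2") %in% res$subset)) # seed never removed
  expect_false("inf1copy" %in% res$subset) # exact duplicate dropped
  accs <- vapply(res$accuracy_trace, `[[`, numeric(1), "accuracy")
  expect_true(all(diff(accs) >= 0)) # removals never decrease accuracy
})

test_that("forward search reproduces the exhaustive 1-NN oracle", {
  cfg <- hcmfs_config(classifier = model_config("KNN", list(n_neighbors = 1L)),
                      cv_folds = 3, seed = 1)
  for (s in 1:20) {
    tab <- generate_cohort(planted_spec(2, (s %% 4) + 1, d = 1.2, n = 30), s)
    p <- ncol(tab$values)
    seed_idx <- 1L
    cfg$seed <- s
    res <- forward_search(tab, feature_names(tab)[seed_idx], cfg)
    fold_ids <- stratified_folds(tab$labels, 3, s)
    oracle <- oracle_forward_1nn(tab$values, tab$labels, seed_idx, fold_ids)
    expect_identical(match(res$subset, feature_names(tab)),
                     as.integer(oracle$subset))
    expect_equal(res$final_accuracy, oracle$accuracy, tolerance = 1e-12)
  }
})

test_that("noise candidates around a strong seed are rejected", {
  rejected <- vapply(1:30, function(s) {
    tab <- generate_cohort(planted_spec(1, 4, d = 2.5, n = 100), s)
    res <- forward_search(tab, "inf1", hcmfs_config(seed = s))
    sum(grepl("^noise", res$subset)) <= 1
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})

test_that("backward search prunes a mostly-noise table", {
  pruned <- vapply(1:30, function(s) {
    tab <- generate_cohort(planted_spec(2, 8, d = 1.5, n = 100), s)
    res <- backward_search(tab, c("inf1", "inf2"), hcmfs_config(seed = s))
    length(res$subset) < ncol(tab$values)
  }, logical(1))
  expect_gte(mean(pruned), 0.9)
})

test_that("the full pipeline is deterministic and beats its own seed subset", {
  tab <- generate_cohort(planted_spec(4, 6, n = 120), 8)
  cfg <- hcmfs_config(seed = 8)
  r1 <- hc_mfs_select(tab, cfg)
  r2 <- hc_mfs_select(tab, cfg)
  expect_identical(r1$subset, r2$subset)
  expect_identical(r1$final_accuracy, r2$final_accuracy)
  # acceptance rules never accept a strict loss relative to the seed
  fold_ids <- stratified_folds(tab$labels, cfg$cv_folds, cfg$seed)
  seed_acc <- hcmfs:::cv_accuracy(tab, r1$seed$features, cfg$classifier,
                                  fold_ids, cfg$seed)
  expect_gte(r1$final_accuracy, seed_acc)
  expect_equal(r1$direction,
               if (r1$backward$final_accuracy > r1$forward$final_accuracy) {
                 "backward"
               } else if (r1$forward$final_accuracy > r1$backward$final_accuracy) {
                 "forward"
               } else if (length(r1$backward$subset) < length(r1$forward$subset)) {
                 "backward"
               } else {
                 "forward"
               })
})

test_that("exact accuracy ties fall to the smaller subset, then forward", {
  # perfectly separable data: the seed alone reaches accuracy 1, forward
  # adds nothing, backward prunes to the protected seed -> tie in accuracy
  # and size -> forward wins
  x <- c(rnorm(30, -5), rnorm(30, 5))
  set.seed(2)
  tab <- tiny_table(cbind(sep = x, n1 = rnorm(60), n2 = rnorm(60)),
                    rep(c(0L, 1L), each = 30))
  cfg <- hcmfs_config(classifier = model_config("KNN", list(n_neighbors = 1L)),
                      seed = 2)
  fwd <- forward_search(tab, "sep", cfg)
  bwd <- backward_search(tab, "sep", cfg)
  expect_equal(fwd$final_accuracy, 1)
  expect_equal(bwd$final_accuracy, 1)
  expect_identical(sort(fwd$subset), sort(bwd$subset))
})

test_that("selection is stable under feature-column permutation", {
  tab <- generate_cohort(planted_spec(3, 5, n = 100), 13)
  cfg <- hcmfs_config(seed = 13)
  r <- hc_mfs_select(tab, cfg)
  set.seed(99)
  perm <- sample(8)
  tabp <- feature_table(tab$values[, perm], tab$labels, tab$meta[perm, ])
  rp <- hc_mfs_select(tabp, cfg)
  expect_setequal(r$subset, rp$subset)
})
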