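test_that("z-scoring standardizes exactly and is affine-invariant", {
  co <- quiet_generate(null_config(seed = 2, n = 10, n_features = 4))
  z <- zscore_features(co)
  for (f in feature_names(co)) {
    expect_lt(abs(mean(z[[f]])), 1e-10)
    expect_lt(abs(sd(z[[f]]) - 1), 1e-10)
  }
  co2 <- co
  co2$vol_striatum <- 3 * co$vol_striatum + 10
  z2 <- zscore_features(co2)
  expect_equal(z2$vol_striatum, z$vol_striatum, tolerance = 1e-10)
  # train-only scope leaves held-out means nonzero in general
  rows <- 1:14
  zt <- zscore_features(co, scope_rows = rows)
  expect_lt(abs(mean(zt$vol_striatum[rows])), 1e-10)
  expect_gt(abs(mean(zt$vol_striatum[-rows])), 1e-6)
  const <- co
  const$vol_striatum <- 1
  expect_error(zscore_features(const), "vol_striatum")
})

test_that("logistic ranking respects sign conventions", {
  cfg <- null_config(seed = 3, n = 13, n_features = 6)
  cfg$features$d_genotype <- c(3, 0, 0, 0, 0, 0)
  co <- quiet_generate(cfg)
  task <- classification_task("genotype")
  r <- logistic_rank(co, task)
  expect_setequal(r$feature, feature_names(co))
  # negating one feature column negates its coefficient
  co_neg <- co
  co_neg$vol_cortex <- -co_neg$vol_cortex + 5
  r_neg <- logistic_rank(co_neg, task)
  expect_equal(r_neg$coefficient[r_neg$feature == "vol_cortex"],
               -r$coefficient[r$feature == "vol_cortex"], tolerance = 1e-6)
  keep <- setdiff(r$feature, "vol_cortex")
  expect_equal(r_neg$coefficient[match(keep, r_neg$feature)],
               r$coefficient[match(keep, r$feature)], tolerance = 1e-6)
})

test_that("a single informative feature dominates the logistic ranking", {
  hits <- 0
  for (s in 1:100) {
    cfg <- null_config(seed = 1000 + s, n = 13, n_features = 6)
    cfg$features$d_genotype <- c(3, 0, 0, 0, 0, 0)
    co <- quiet_generate(cfg)
    r <- logistic_rank(co, classification_task("genotype"))
    if (r$feature[1] == "vol_striatum") hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("genotype class coding makes disease-elevated features positive", {
  cfg <- null_config(seed = 8, n = 13, n_features = 6)
  cfg$features$d_genotype <- c(-2.5, 0, 0, 0, 0, 2.5)
  co <- quiet_generate(cfg)
  r <- logistic_rank(co, classification_task("genotype"))
  # class 1 = R6/2-Veh: a decreased feature gets a negative coefficient
  expect_lt(r$coefficient[r$feature == "vol_striatum"], 0)
  expect_gt(r$coefficient[r$feature == "vol_corpus_callosum"], 0)
})

test_that("both rankers put a lone informative feature first", {
  for (rk in c("svm_linear", "xgb")) {
    hits <- 0
    for (s in 1:40) {
      cfg <- null_config(seed = 500 + s, n = 13, n_features = 6)
      cfg$features$d_genotype <- c(3, 0, 0, 0, 0, 0)
      co <- quiet_generate(cfg)
      sub <- task_subset(zscore_features(co), classification_task("genotype"))
      ranking <- rank_features(sub, feature_names(co), ranker = rk, seed = s)
      if (ranking[1] == "vol_striatum") hits <- hits + 1
    }
    expect_gte(hits, 38)
  }
})

test_that("feature-column order does not change the importance ordering", {
  cfg <- null_config(seed = 21, n = 13, n_features = 6)
  cfg$features$d_genotype <- c(2, -1.5, 1, -0.5, 0.2, 0)
  co <- quiet_generate(cfg)
  feats <- feature_names(co)
  sub <- task_subset(zscore_features(co), classification_task("genotype"))
  r1 <- rank_features(sub, feats, ranker = "svm_linear")
  r2 <- rank_features(sub, rev(feats), ranker = "svm_linear")
  expect_equal(r1, r2)
})

test_that("subset evaluation returns perfect metrics on separated data", {
  set.seed(9)
  n <- 13
  train <- tibble::tibble(.class = rep(0:1, each = n),
                          f1 = c(rnorm(n, 0, 0.1), rnorm(n, 10, 0.1)),
                          f2 = rnorm(2 * n), f3 = rnorm(2 * n))
  test <- tibble::tibble(.class = rep(0:1, each = 6),
                         f1 = c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1)),
                         f2 = rnorm(12), f3 = rnorm(12))
  m <- evaluate_subsets(c("f1", "f2", "f3"), train, test, "knn3_distance")
  expect_equal(m$k, 2:3)
  expect_true(all(m$accuracy == 1))
  expect_true(all(m$precision == 1))
  expect_true(all(m$recall == 1))
  m2 <- evaluate_subsets(c("f1", "f2", "f3"), train, test, "rfc200", seed = 4)
  expect_true(all(m2$accuracy == 1))
  bad_test <- dplyr::filter(test, .class == 1)
  expect_error(evaluate_subsets(c("f1", "f2"), train, bad_test, "knn3_distance"),
               "both classes")
})

test_that("distance-weighted 3-NN handles coincident and weighted votes", {
  train_x <- matrix(c(0, 0, 1, 10), ncol = 1)
  train_y <- c(0L, 0L, 1L, 1L)
  # exact match with two coincident class-0 points
  expect_equal(knn_distance_weighted(train_x, matrix(0), train_y), 0L)
  # point at 0.9: neighbours 1 (d=.1, class1), 0 (d=.9), 0 (d=.9);
  # w1 = 10 > w0 = 2/0.9 -> class 1 despite 2-vs-1 majority
  expect_equal(knn_distance_weighted(train_x, matrix(0.9), train_y), 1L)
})

test_that("stability selection is reproducible and conserves occurrence counts", {
  cfg <- null_config(seed = 30, n = 13, n_features = 6)
  cfg$features$d_genotype <- c(2, -2, 1.5, 0, 0, 0)
  co <- quiet_generate(cfg)
  task <- classification_task("genotype")
  r1 <- run_stability(co, task, "SVM-KNN", n_permutations = 12, seed = 6)
  r2 <- run_stability(co, task, "SVM-KNN", n_permutations = 12, seed = 6)
  expect_identical(r1$curves, r2$curves)
  expect_identical(r1$occurrence, r2$occurrence)
  r3 <- run_stability(co, task, "SVM-KNN", n_permutations = 12, seed = 7)
  expect_false(identical(r1$curves, r3$curves))
  # occurrence conservation: top_n = min(15, 6) features count per permutation
  expect_equal(sum(r1$occurrence$percent), 100 * 6)
  expect_equal(r1$curves$k, 2:6)
  expect_true(all(r1$curves$accuracy_mean >= 0 & r1$curves$accuracy_mean <= 1))
})

test_that("one permutation with 27 features marks exactly 15 features at 100%", {
  co <- quiet_generate(cohort_config(seed = 41))
  r <- run_stability(co, classification_task("genotype"), "SVM-KNN",
                     n_permutations = 1, seed = 2, max_per_class = 13)
  expect_equal(sum(r$occurrence$percent == 100), 15)
  expect_equal(sum(r$occurrence$percent == 0), 12)
})

test_that("insufficient subjects per class is a clear error", {
  co <- quiet_generate(null_config(seed = 31, n = 8, n_features = 4))
  expect_error(
    run_stability(co, classification_task("genotype"), "SVM-KNN",
                  n_permutations = 2, seed = 1),
    "12 subjects")
})

test_that("null cohorts classify at chance for every combo", {
  # mean accuracy per cohort: permutations reuse the same subjects, so the
  # Monte-Carlo error must be taken across independent cohorts
  task <- classification_task("genotype")
  for (combo in c("SVM-KNN", "SVM-RFC", "XGB-KNN", "XGB-RFC")) {
    cohort_acc <- vapply(1:10, function(s) {
      co <- quiet_generate(null_config(seed = 5500 + s, n = 13, n_features = 6))
      r <- run_stability(co, task, combo, n_permutations = 15, seed = 77 + s)
      mean(r$permutations$accuracy)
    }, numeric(1))
    sem <- sd(cohort_acc) / sqrt(length(cohort_acc))
    expect_lt(abs(mean(cohort_acc) - 0.5), max(3 * sem, 0.02))
  }
})

test_that("accuracy rises with the configured effect scale", {
  task <- classification_task("genotype")
  acc <- vapply(c(0, 0.5, 1), function(lambda) {
    cfg <- null_config(seed = 60, n = 13, n_features = 6)
    cfg$features$d_genotype <- lambda * c(2.5, -2, 2, -1.5, 1.5, 1)
    co <- quiet_generate(cfg)
    r <- run_stability(co, task, "SVM-KNN", n_permutations = 30, seed = 8)
    mean(r$curves$accuracy_mean)
  }, numeric(1))
  expect_true(all(diff(acc) > -0.03))
  expect_gt(acc[3], acc[1] + 0.2)
})

test_that("model comparison orders combos and rejects mismatched tasks", {
  cfg <- null_config(seed = 70, n = 13, n_features = 6)
  cfg$features$d_genotype <- c(2.5, -2, 2, 0, 0, 0)
  co <- quiet_generate(cfg)
  g <- classification_task("genotype")
  r1 <- run_stability(co, g, "SVM-KNN", n_permutations = 10, seed = 1)
  r2 <- run_stability(co, g, "SVM-RFC", n_permutations = 10, seed = 1)
  cmp <- compare_models(list(r1, r2))
  expect_equal(nrow(cmp), 2)
  expect_true(all(diff(cmp$accuracy_best) <= 0))
  expect_identical(compare_models(list(r1, r2)), cmp)
  other <- run_stability(co, classification_task("treatment"), "SVM-KNN",
                         n_permutations = 5, seed = 1, test_per_class = 2)
  expect_error(compare_models(list(r1, other)), "task")
})

test_that("refit-per-step RFE runs and agrees at the full panel size", {
  cfg <- null_config(seed = 80, n = 13, n_features = 5)
  cfg$features$d_genotype <- c(2, -1.5, 1, 0, 0)
  co <- quiet_generate(cfg)
  task <- classification_task("genotype")
  a <- run_stability(co, task, "SVM-KNN", n_permutations = 4, seed = 3)
  b <- run_stability(co, task, "SVM-KNN", n_permutations = 4, seed = 3,
                     refit_per_step = TRUE)
  k_full <- max(a$curves$k)
  expect_equal(dplyr::filter(a$curves, k == k_full),
               dplyr::filter(b$curves, k == k_full))
})
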