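#' Ranker-classifier combinations
#'
#' The four two-step pipelines: features ranked by a linear SVM or a
#' gradient-boosted ensemble, classification by distance-weighted 3-NN or a
#' 200-tree random forest.
#'
#' @param name One of `"SVM-KNN"`, `"SVM-RFC"`, `"XGB-KNN"`, `"XGB-RFC"`.
#' @return A list with `ranker` and `classifier` identifiers.
#' @export
model_combo <- function(name = c("SVM-KNN", "SVM-RFC", "XGB-KNN", "XGB-RFC")) {
  name <- match.arg(name)
  parts <- strsplit(name, "-")[[1]]
  structure(
    list(name = name,
         ranker = c(SVM = "svm_linear", XGB = "xgb")[[parts[1]]],
         classifier = c(KNN = "knn3_distance", RFC = "rfc200")[[parts[2]]]),
    class = "model_combo")
}

#' Permutation-based stability selection and classification
#'
#' Runs the two-step pipeline over `n_permutations` random stratified
#' train/test splits: per permutation, 6 subjects per class are held out as
#' the test set (the remaining 6-7 per class train), features are ranked on
#' the training set by the combo's ranker, and the combo's classifier is
#' evaluated on nested top-k subsets from the full panel down to 2 features.
#' Mean and SD of accuracy, precision and recall per subset size are
#' aggregated across permutations, and each feature is scored by the
#' percentage of permutations in which it ranked in the top `top_n`
#' (default 15) -- the occurrence matrix.
#'
#' Features are z-scored before splitting by default (`zscore_scope =
#' "full"`, matching a pre-standardized analysis table); `"train"` restricts
#' the scaling sample to each permutation's training subjects to avoid
#' test-set leakage. With `refit_per_step = TRUE` the ranker is refitted
#' after each elimination (classical RFE) instead of ranking once per
#' permutation.
#'
#' @param table A `biomarker_tbl`.
#' @param task A [classification_task()].
#' @param combo A [model_combo()] or its name.
#' @param n_permutations Number of random splits (default 1000).
#' @param seed Master seed; per-permutation seeds are derived from it by
#'   counter, so runs are bit-reproducible.
#' @param test_per_class Held-out subjects per class (default 6).
#' @param max_per_class Optional cap on subjects per class before splitting
#'   (classes larger than the cap are subsampled once, seeded), mirroring an
#'   analysis run at 12-13 subjects per group.
#' @param top_n Occurrence-count depth (default 15).
#' @param zscore_scope `"full"` or `"train"`.
#' @param refit_per_step Refit the ranker at every elimination step.
#' @return An object of class `stability_result` with elements `curves`
#'   (tibble: k, mean/SD accuracy, precision, recall), `occurrence` (tibble:
#'   feature, percent), `permutations` (per-permutation long metrics),
#'   `rankings` (list of per-permutation orderings), and the run settings.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(seed = 3))
#' res <- run_stability(cohort, classification_task("genotype"),
#'                      "SVM-KNN", n_permutations = 25, seed = 3)
#' tidy(res)
#' }
run_stability <- function(table, task, combo, n_permutations = 1000L,
                          seed = 1L, test_per_class = 6L,
                          max_per_class = NULL, top_n = 15L,
                          zscore_scope = c("full", "train"),
                          refit_per_step = FALSE) {
  stopifnot(inherits(task, "classification_task"))
  if (is.character(combo)) combo <- model_combo(combo)
  zscore_scope <- match.arg(zscore_scope)
  feats <- task$features %||% feature_names(table)

  sub <- task_subset(table, task)
  seeds <- derive_seeds(seed, n_permutations + 1L)
  if (!is.null(max_per_class)) {
    sub <- with_preserved_seed(seeds[n_permutations + 1L], {
      keep <- unlist(lapply(split(seq_len(nrow(sub)), sub$.class), function(i) {
        if (length(i) > max_per_class) sort(sample(i, max_per_class)) else i
      }))
      sub[sort(keep), , drop = FALSE]
    })
  }
  class_n <- table(sub$.class)
  if (any(class_n < 2 * test_per_class)) {
    abort(sprintf(
      "each class needs >= %d subjects (%d test + >= %d train); got %s",
      2 * test_per_class, test_per_class, test_per_class,
      paste(class_n, collapse = "/")))
  }
  if (zscore_scope == "full") sub <- zscore_features(sub, feats)

  k_range <- seq(2L, length(feats))
  idx_by_class <- split(seq_len(nrow(sub)), sub$.class)

  perms <- purrr::map(seq_len(n_permutations), function(b) {
    s <- seeds[b]
    test_idx <- with_preserved_seed(s, {
      sort(unlist(lapply(idx_by_class, sample, size = test_per_class)))
    })
    train <- sub[-test_idx, , drop = FALSE]
    test <- sub[test_idx, , drop = FALSE]
    if (zscore_scope == "train") {
      mu <- colMeans(train[, feats])
      sg <- vapply(train[, feats], sd, numeric(1))
      if (any(sg == 0)) abort("zero-SD training feature under train-scope z-scoring")
      for (f in feats) {
        train[[f]] <- (train[[f]] - mu[[f]]) / sg[[f]]
        test[[f]] <- (test[[f]] - mu[[f]]) / sg[[f]]
      }
    }
    ranking <- rank_features(train, feats, ranker = combo$ranker, seed = s)
    metrics <- if (!refit_per_step) {
      evaluate_subsets(ranking, train, test, classifier = combo$classifier,
                       k_range = k_range, seed = s)
    } else {
      # classical RFE: re-rank within the surviving subset at each step
      surv <- ranking
      out <- vector("list", length(k_range))
      for (i in rev(seq_along(k_range))) {
        k <- k_range[i]
        if (length(surv) > k) {
          surv <- rank_features(train, surv, ranker = combo$ranker,
                                seed = s)[seq_len(k)]
        }
        out[[i]] <- evaluate_subsets(surv, train, test,
                                     classifier = combo$classifier,
                                     k_range = k, seed = s)
      }
      bind_rows(out)
    }
    list(ranking = ranking, metrics = mutate(metrics, permutation = b))
  })

  metrics <- bind_rows(purrr::map(perms, "metrics"))
  curves <- metrics |>
    group_by(.data$k) |>
    summarise(across(c("accuracy", "precision", "recall"),
                     list(mean = mean, sd = sd)), .groups = "drop")
  top_n_eff <- min(top_n, length(feats))
  occ_counts <- table(factor(
    unlist(purrr::map(perms, ~ .x$ranking[seq_len(top_n_eff)])),
    levels = feats))
  occurrence <- tibble(feature = feats,
                       percent = 100 * as.numeric(occ_counts) / n_permutations)

  structure(
    list(curves = curves, occurrence = occurrence,
         permutations = metrics, rankings = purrr::map(perms, "ranking"),
         combo = combo$name, task = task$contrast,
         n_permutations = n_permutations, seed = seed, top_n = top_n_eff,
         n_per_class = as.integer(class_n)),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  best <- x$curves[which.max(x$curves$accuracy_mean), ]
  cat(sprintf("<stability_result> %s on %s task: %d permutations, n/class = %s\n",
              x$combo, x$task, x$n_permutations,
              paste(x$n_per_class, collapse = "/")))
  cat(sprintf("  best mean accuracy %.3f at k = %d\n",
              best$accuracy_mean, best$k))
  invisible(x)
}

#' @rdname run_stability
#' @param x A `stability_result`.
#' @param ... Unused.
#' @export
tidy.stability_result <- function(x, ...) {
  mutate(x$curves, combo = x$combo, task = x$task, .before = 1)
}

#' @rdname run_stability
#' @export
glance.stability_result <- function(x, ...) {
  best <- x$curves[which.max(x$curves$accuracy_mean), ]
  tibble(combo = x$combo, task = x$task,
         n_permutations = x$n_permutations,
         best_k = best$k, accuracy_best = best$accuracy_mean,
         precision_best = best$precision_mean, recall_best = best$recall_mean)
}

#' Compare stability-selection pipelines on one task
#'
#' @param results List of `stability_result` objects fitted on the same task.
#' @return A tibble (one row per combo) of best-k mean metrics, ordered by
#'   mean accuracy at each combo's best k.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 2)
  tasks <- unique(vapply(results, function(r) r$task, character(1)))
  if (length(tasks) != 1) {
    abort(paste("all results must share one task; got:",
                paste(tasks, collapse = ", ")))
  }
  bind_rows(purrr::map(results, glance)) |>
    arrange(desc(.data$accuracy_best))
}
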