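#' Distance-weighted k-nearest-neighbour classification
#'
#' Euclidean 3-NN (configurable k) with inverse-distance vote weighting on
#' standardized features. A test point coinciding with one or more training
#' points takes the majority label of the coincident points. Vote ties break
#' toward class 0 (deterministic).
#'
#' @param train_x,test_x Numeric matrices (columns = features).
#' @param train_y Integer 0/1 labels for the training rows.
#' @param k Number of neighbours (default 3).
#' @return Integer vector of 0/1 predictions for the test rows.
#' @export
knn_distance_weighted <- function(train_x, test_x, train_y, k = 3L) {
  stopifnot(nrow(train_x) >= k, ncol(train_x) == ncol(test_x))
  apply(test_x, 1, function(pt) {
    d <- sqrt(colSums((t(train_x) - pt)^2))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (any(dn == 0)) {
      lab <- train_y[nn[dn == 0]]
      return(as.integer(mean(lab) > 0.5))
    }
    w <- 1 / dn
    as.integer(sum(w * train_y[nn]) / sum(w) > 0.5)
  })
}

#' Test-set metrics for nested top-k feature subsets
#'
#' Walks the ranked feature list from the full panel down to two features;
#' for each subset size `k` the classifier is fitted on the training rows
#' restricted to the top-k features and evaluated on the test rows. Accuracy
#' is the fraction of correct test predictions; precision and recall take
#' class 1 as positive (precision is 0 when nothing is predicted positive).
#'
#' @param ranking Character vector of all features, most important first.
#' @param train,test Data frames with the feature columns and a 0/1 `.class`
#'   column.
#' @param classifier `"knn3_distance"` (inverse-distance-weighted 3-NN) or
#'   `"rfc200"` (random forest, 200 trees).
#' @param k_range Integer subset sizes to evaluate (default `2:length(ranking)`).
#' @param seed Seed for the stochastic classifier.
#' @return A tibble with columns `k`, `accuracy`, `precision`, `recall`.
#' @export
evaluate_subsets <- function(ranking, train, test,
                             classifier = c("knn3_distance", "rfc200"),
                             k_range = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  if (length(unique(test$.class)) < 2) {
    abort("test set must contain both classes")
  }
  k_range <- k_range %||% seq(2L, length(ranking))
  stopifnot(min(k_range) >= 2, max(k_range) <= length(ranking))
  y_tr <- train$.class
  y_te <- test$.class

  purrr::map_dfr(sort(k_range), function(k) {
    feats <- ranking[seq_len(k)]
    Xtr <- as.matrix(train[, feats])
    Xte <- as.matrix(test[, feats])
    pred <- if (classifier == "knn3_distance") {
      knn_distance_weighted(Xtr, Xte, y_tr, k = 3L)
    } else {
      fit <- with_preserved_seed(seed + k, {
        randomForest::randomForest(x = Xtr, y = factor(y_tr, levels = c(0, 1)),
                                   ntree = 200)
      })
      as.integer(as.character(predict(fit, Xte)))
    }
    tp <- sum(pred == 1 & y_te == 1)
    fp <- sum(pred == 1 & y_te == 0)
    fn <- sum(pred == 0 & y_te == 1)
    tibble(
      k = k,
      accuracy = mean(pred == y_te),
      precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      recall = tp / (tp + fn)
    )
  })
}
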