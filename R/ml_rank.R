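#' Define a two-class classification task on a cohort
#'
#' The two tasks mirror the reported contrasts: `"genotype"` codes WT-Veh as
#' class 0 and R6/2-Veh as class 1; `"treatment"` codes R6/2-Veh as 0 and
#' R6/2-C31 as 1. Positive model coefficients are therefore features
#' positively associated with the class-1 group.
#'
#' @param contrast `"genotype"` or `"treatment"`.
#' @param features Optional character vector restricting the feature panel
#'   (default: all features of the table at fit time).
#' @return A list of class `classification_task`.
#' @export
classification_task <- function(contrast = c("genotype", "treatment"),
                                features = NULL) {
  contrast <- match.arg(contrast)
  grp <- switch(contrast,
    genotype = c(class0 = "WT-Veh", class1 = "R6/2-Veh"),
    treatment = c(class0 = "R6/2-Veh", class1 = "R6/2-C31"))
  structure(list(contrast = contrast, groups = grp, features = features),
            class = "classification_task")
}

# Subjects of the two task groups, with class labels 0/1.
task_subset <- function(table, task) {
  grp <- group_label(table$genotype, table$treatment)
  keep <- grp %in% task$groups
  out <- table[keep, , drop = FALSE]
  out$.class <- as.integer(grp[keep] == task$groups[["class1"]])
  out
}

#' Z-score feature columns
#'
#' Standardizes each feature to mean 0, SD 1 over a chosen set of subjects.
#' With `scope_rows` given (e.g. a training set), the scaling learned there
#' is applied to all rows, so held-out columns generally keep nonzero means.
#'
#' @param table A data frame with feature columns.
#' @param features Character vector of feature columns to standardize.
#' @param scope_rows Optional integer row indices defining the
#'   standardization sample; default all rows.
#' @return The table with standardized feature columns.
#' @export
zscore_features <- function(table, features = feature_names(table),
                            scope_rows = NULL) {
  rows <- scope_rows %||% seq_len(nrow(table))
  for (f in features) {
    mu <- mean(table[[f]][rows], na.rm = TRUE)
    sg <- sd(table[[f]][rows], na.rm = TRUE)
    if (is.na(sg) || sg == 0) {
      abort(sprintf("feature '%s' has zero SD over the standardization subjects", f))
    }
    table[[f]] <- (table[[f]] - mu) / sg
  }
  table
}

#' Ridge-logistic coefficient ranking of a biomarker panel
#'
#' Fits one L2-regularized logistic regression on all z-scored features
#' jointly (fixed unit penalty on the average log-likelihood scale, intercept
#' included, deterministic coordinate-descent solver at tolerance 1e-8) and
#' returns the signed coefficients sorted by magnitude. With class coding as
#' in [classification_task()], positive coefficients mark features positively
#' associated with the class-1 group. Regularization keeps coefficients
#' finite under the quasi-separation typical of strong panels.
#'
#' @param table A `biomarker_tbl`.
#' @param task A [classification_task()].
#' @return An object of class `logistic_ranking`: tibble with `feature`,
#'   `coefficient`, `rank` (by |coefficient|, ties broken by table feature
#'   order) plus the task as attribute.
#' @export
logistic_rank <- function(table, task) {
  stopifnot(inherits(task, "classification_task"))
  feats <- task$features %||% feature_names(table)
  sub <- task_subset(table, task)
  if (min(table(sub$.class)) < 6) {
    abort("each class needs >= 6 subjects for the coefficient ranking")
  }
  sub <- zscore_features(sub, feats)
  X <- as.matrix(sub[, feats])
  y <- sub$.class
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1 / length(y), standardize = FALSE,
                        intercept = TRUE, thresh = 1e-8)
  beta <- as.numeric(fit$beta[, 1])
  ord <- order(-abs(beta), seq_along(feats))
  out <- tibble(feature = feats, coefficient = beta)[ord, ]
  out$rank <- seq_len(nrow(out))
  structure(out, task = task$contrast,
            class = c("logistic_ranking", class(out)))
}

#' Rank features by training-set importance
#'
#' Two rankers are available. `"svm_linear"` fits a linear-kernel
#' maximum-margin classifier (cost C = 1, no class weights) on the z-scored
#' training data and orders features by the magnitude of the primal weight
#' vector. `"xgb"` fits a gradient-boosted tree ensemble (100 rounds, depth
#' 3, learning rate 0.3, logistic objective, single thread, seeded) and
#' orders features by total split-gain importance; features the ensemble
#' never splits on rank last. All ties are broken by the table's feature
#' order (stable).
#'
#' @param train Data frame of training subjects carrying the feature columns
#'   and a 0/1 `.class` column (see [classification_task()]).
#' @param features Character vector of feature names.
#' @param ranker `"svm_linear"` or `"xgb"`.
#' @param seed Integer seed for the stochastic ranker.
#' @return Character vector of all features, most important first.
#' @export
rank_features <- function(train, features, ranker = c("svm_linear", "xgb"),
                          seed = 1L) {
  ranker <- match.arg(ranker)
  y <- train$.class
  if (length(unique(y)) < 2) abort("training set contains a single class")
  X <- as.matrix(train[, features])

  score <- if (ranker == "svm_linear") {
    fit <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)  # primal weights of the linear machine
    abs(as.numeric(w))
  } else {
    booster <- with_preserved_seed(seed, {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dm, nrounds = 100, verbose = 0)
    })
    imp <- xgboost::xgb.importance(model = booster)
    gain <- setNames(rep(0, length(features)), features)
    gain[imp$Feature] <- imp$Gain
    unname(gain)
  }
  features[order(-score, seq_along(features))]
}
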