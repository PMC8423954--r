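#' Planned contrasts of the 2x2 design
#'
#' The three comparisons reported throughout the analysis: genotype
#' (WT-Veh vs R6/2-Veh), treatment (R6/2-Veh vs R6/2-C31), and wild-type
#' treatment control (WT-Veh vs WT-C31). WT-C31 vs R6/2-C31 is not a planned
#' contrast and is never computed.
#'
#' @return A tibble with columns `contrast`, `group_a`, `group_b`.
#' @export
planned_contrasts <- function() {
  tibble(
    contrast = c("genotype", "treatment", "wt_treatment"),
    group_a = c("WT-Veh", "R6/2-Veh", "WT-Veh"),
    group_b = c("R6/2-Veh", "R6/2-C31", "WT-C31")
  )
}

#' Options for the univariate statistics pipeline
#'
#' @param alpha Significance level for the normality and variance-ratio
#'   screens (default 0.05).
#' @param q Target false discovery rate for the two-stage adaptive
#'   adjustment (default 0.05).
#' @param outlier_filter Apply the single-pass per-feature, per-group 2-SD
#'   filter before testing (default TRUE).
#' @param min_group Minimum per-group n after filtering for a contrast to be
#'   evaluated without a flag (default 3).
#' @param max_missing_frac Features missing in more than this fraction of
#'   subjects are excluded, mirroring assays measured below their detection
#'   limit (default 0.5).
#' @param contrasts Planned contrasts tibble (default [planned_contrasts()]).
#' @return A list of class `stats_options`.
#' @export
stats_options <- function(alpha = 0.05, q = 0.05, outlier_filter = TRUE,
                          min_group = 3L, max_missing_frac = 0.5,
                          contrasts = planned_contrasts()) {
  structure(list(alpha = alpha, q = q, outlier_filter = outlier_filter,
                 min_group = as.integer(min_group),
                 max_missing_frac = max_missing_frac, contrasts = contrasts),
            class = "stats_options")
}

#' Univariate statistics for every biomarker feature
#'
#' Reproduces the univariate pipeline for each feature of a cohort table:
#' single-pass 2-SD outlier removal per group, composite-normality screening
#' ([ks_normality()]) of the two groups of each planned contrast, an F
#' variance-ratio screen, and dispatch to the matching test -- one-way ANOVA
#' over all four groups with Fisher's-LSD planned contrasts when both groups
#' pass normality with equal variances, Welch's t when variances differ, and
#' Mann-Whitney when either group is non-normal. Cohen's d, noncentral-t
#' post-hoc power and percent change (first-named group as denominator) are
#' attached to every contrast, and the two-stage adaptive FDR ([bky_fdr()])
#' is applied within each modality family (each MRI metric and the cytokine
#' panel adjusted separately; the single urinary p75 feature unadjusted).
#'
#' @param table A `biomarker_tbl`.
#' @param options A [stats_options()] list.
#' @return An object of class `feature_stats`: list with `results` (tibble,
#'   one row per feature x contrast), `exclusions` (features dropped and
#'   why), `removed` (outlier log) and `options`. Use [generics::tidy()] to
#'   extract the results tibble.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' fit <- analyze_features(cohort)
#' dplyr::filter(tidy(fit), contrast == "genotype", q_decision)
analyze_features <- function(table, options = stats_options()) {
  stopifnot(inherits(table, "biomarker_tbl"))
  meta <- feature_meta(table)
  feats <- feature_names(table)
  grp <- group_label(table$genotype, table$treatment)
  n_subj <- nrow(table)
  opts <- options

  exclusions <- list()
  removed_log <- list()
  rows <- list()

  for (f in feats) {
    x <- table[[f]]
    if (mean(is.na(x)) > opts$max_missing_frac) {
      exclusions[[length(exclusions) + 1L]] <- tibble(
        feature = f, reason = sprintf(
          "missing in %d/%d subjects (> %.0f%%): treated as below detection limit",
          sum(is.na(x)), n_subj, 100 * opts$max_missing_frac))
      next
    }
    groups <- split(x, grp)[GROUP_LEVELS]
    groups <- purrr::map(groups, ~ .x[!is.na(.x)])

    if (opts$outlier_filter) {
      for (g in names(groups)) {
        if (length(groups[[g]]) >= 3) {
          flt <- remove_outliers_2sd(groups[[g]])
          if (length(flt$removed)) {
            removed_log[[length(removed_log) + 1L]] <- tibble(
              feature = f, group = g, n_removed = length(flt$removed))
          }
          groups[[g]] <- flt$values
        }
      }
    }

    norm_p <- purrr::map(groups, function(g) ks_normality(g))
    lsd <- NULL

    for (i in seq_len(nrow(opts$contrasts))) {
      ga <- opts$contrasts$group_a[i]
      gb <- opts$contrasts$group_b[i]
      a <- groups[[ga]]; b <- groups[[gb]]
      flagged <- length(a) < opts$min_group || length(b) < opts$min_group
      if (length(a) < 2 || length(b) < 2) {
        exclusions[[length(exclusions) + 1L]] <- tibble(
          feature = f,
          reason = sprintf("contrast %s: fewer than 2 values per group",
                           opts$contrasts$contrast[i]))
        next
      }
      normal_a <- isTRUE(norm_p[[ga]]$too_small) ||
        (!is.na(norm_p[[ga]]$p_value) && norm_p[[ga]]$p_value > opts$alpha)
      normal_b <- isTRUE(norm_p[[gb]]$too_small) ||
        (!is.na(norm_p[[gb]]$p_value) && norm_p[[gb]]$p_value > opts$alpha)
      var_p <- tryCatch(var.test(a, b)$p.value, error = function(e) NA_real_)

      if (!normal_a || !normal_b) {
        test_used <- "mann_whitney"
        ht <- mann_whitney_u(a, b)
        statistic <- ht$U; dfree <- NA_real_; p_raw <- ht$p
      } else if (!is.na(var_p) && var_p <= opts$alpha) {
        test_used <- "welch_t"
        ht <- welch_t(a, b)
        statistic <- ht$t; dfree <- ht$df; p_raw <- ht$p
      } else {
        test_used <- "anova_lsd"
        if (is.null(lsd)) {
          usable <- groups[lengths(groups) >= 2]
          lsd <- anova_fisher_lsd(usable, contrasts = purrr::map(
            seq_len(nrow(opts$contrasts)),
            ~ c(opts$contrasts$group_a[.x], opts$contrasts$group_b[.x])))
        }
        row_i <- which(lsd$contrasts$group_a == ga & lsd$contrasts$group_b == gb)
        statistic <- lsd$contrasts$t[row_i]
        dfree <- lsd$contrasts$df[row_i]
        p_raw <- lsd$contrasts$p[row_i]
      }

      d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
      pwr <- if (is.na(d)) NA_real_ else posthoc_power(d, length(a), length(b),
                                                       alpha = opts$alpha)
      pct <- if (mean(a) != 0) 100 * (mean(b) - mean(a)) / mean(a) else NA_real_

      rows[[length(rows) + 1L]] <- tibble(
        feature = f,
        modality = meta$modality[match(f, meta$feature)],
        contrast = opts$contrasts$contrast[i],
        group_a = ga, group_b = gb,
        test_used = test_used, statistic = statistic, df = dfree,
        p_raw = p_raw, cohens_d = d, power_posthoc = pwr,
        percent_change = pct,
        n_a = length(a), n_b = length(b),
        normality_p_a = norm_p[[ga]]$p_value,
        normality_p_b = norm_p[[gb]]$p_value,
        variance_test_p = var_p,
        flagged_small = flagged
      )
    }
  }

  results <- if (length(rows)) bind_rows(rows) else tibble()
  if (nrow(results)) {
    # FDR families: one family per MRI metric modality, one for the cytokine
    # panel; a single-feature family (urinary p75) is left unadjusted.
    results$fdr_family <- results$modality
    results$q_decision <- FALSE
    for (fam in unique(results$fdr_family)) {
      idx <- which(results$fdr_family == fam)
      n_feat <- length(unique(results$feature[idx]))
      if (n_feat <= 1 && fam == "urinary_p75") {
        results$q_decision[idx] <- results$p_raw[idx] <= opts$alpha
      } else {
        results$q_decision[idx] <- bky_fdr(results$p_raw[idx], q = opts$q)$reject
      }
    }
  }

  structure(
    list(results = results,
         exclusions = if (length(exclusions)) bind_rows(exclusions) else
           tibble(feature = character(), reason = character()),
         removed = if (length(removed_log)) bind_rows(removed_log) else
           tibble(feature = character(), group = character(),
                  n_removed = integer()),
         options = opts),
    class = "feature_stats"
  )
}

#' @export
print.feature_stats <- function(x, ...) {
  cat("<feature_stats>", nrow(x$results), "contrast results,",
      nrow(x$exclusions), "exclusions,",
      sum(x$removed$n_removed), "outliers removed\n")
  sig <- dplyr::count(dplyr::filter(x$results, .data$q_decision),
                      .data$contrast)
  if (nrow(sig)) {
    cat("  FDR-rejected contrasts:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %-14s %d features\n", sig$contrast[i], sig$n[i]))
    }
  }
  invisible(x)
}

#' @rdname analyze_features
#' @param x A `feature_stats` object.
#' @param ... Unused.
#' @export
tidy.feature_stats <- function(x, ...) {
  x$results
}

#' @rdname analyze_features
#' @export
glance.feature_stats <- function(x, ...) {
  tibble(
    n_features = length(unique(x$results$feature)),
    n_contrasts = nrow(x$results),
    n_rejected = sum(x$results$q_decision),
    n_excluded = nrow(x$exclusions),
    n_outliers_removed = sum(x$removed$n_removed)
  )
}
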