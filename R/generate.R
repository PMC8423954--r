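#' Generate a synthetic 2x2 biomarker cohort
#'
#' Draws one subject-by-feature table for the four-group (genotype x
#' treatment) design described by a [cohort_config()]. Each feature's group
#' means are located by its standardized shifts (see [feature_spec()]) on a
#' common within-group SD of `baseline_mean * baseline_cv`; noise terms share
#' a compound-symmetric correlation `correlation_rho` within each modality
#' block (Gaussian copula) and are independent across modalities. Negative
#' draws for these positively supported assays are clipped to zero with a
#' warning; the clip count is kept in the `n_clipped` attribute.
#'
#' @param config A [cohort_config()].
#'
#' @return A tibble of class `biomarker_tbl` with columns `subject_id`,
#'   `genotype`, `treatment`, then one numeric column per feature. Feature
#'   metadata (modality, ROI, units) is attached as the `feature_meta`
#'   attribute and available via [feature_meta()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' dim(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$features
  p <- nrow(specs)
  sizes <- config$group_sizes

  chol_blocks <- modality_chol_blocks(specs, config$correlation_rho)

  rows <- with_preserved_seed(config$seed, {
    purrr::map(GROUP_LEVELS, function(g) {
      n <- sizes[[g]]
      z <- draw_correlated_z(n, specs, chol_blocks)
      sd_f <- specs$baseline_mean * specs$baseline_cv
      mu_f <- group_means(specs, g)
      vals <- if (config$noise == "gaussian") {
        sweep(sweep(z, 2, sd_f, `*`), 2, mu_f, `+`)
      } else {
        # moment-matched log-normal: same group mean and SD as the
        # gaussian parameterization
        if (any(mu_f <= 0)) {
          abort("lognormal noise requires positive group means for every feature")
        }
        sig2 <- log(1 + (sd_f / mu_f)^2)
        sweep(exp(sweep(z, 2, sqrt(sig2), `*`)), 2,
              mu_f / exp(sig2 / 2), `*`)
      }
      colnames(vals) <- specs$feature
      vals
    })
  })

  values <- do.call(rbind, rows)
  n_clipped <- 0L
  neg <- values < 0
  if (any(neg)) {
    n_clipped <- sum(neg)
    warn(sprintf("%d negative draw(s) clipped to 0 for positively supported features",
                 n_clipped))
    values[neg] <- 0
  }

  genotype <- rep(c("WT", "WT", "R6/2", "R6/2"), times = sizes)
  treatment <- rep(c("Veh", "C31", "Veh", "C31"), times = sizes)
  tbl <- tibble(
    subject_id = sprintf("m%03d", seq_len(sum(sizes))),
    genotype = factor(genotype, levels = c("WT", "R6/2")),
    treatment = factor(treatment, levels = c("Veh", "C31"))
  )
  tbl <- dplyr::bind_cols(tbl, as_tibble(values))
  new_biomarker_tbl(tbl,
                    feature_meta = specs[, c("feature", "modality", "roi", "units")],
                    n_clipped = n_clipped)
}

group_means <- function(specs, group) {
  sd_f <- specs$baseline_mean * specs$baseline_cv
  switch(group,
    "WT-Veh" = specs$baseline_mean,
    "WT-C31" = specs$baseline_mean + specs$d_wt_treatment * sd_f,
    "R6/2-Veh" = specs$baseline_mean + specs$d_genotype * sd_f,
    "R6/2-C31" = specs$baseline_mean +
      (specs$d_genotype + specs$d_treatment) * sd_f,
    abort(paste("unknown group:", group))
  )
}

# Cholesky factor of the compound-symmetric correlation for each modality
# block. CS with rho in [0,1) is positive definite, but we keep the guard so a
# failure names the offending block.
modality_chol_blocks <- function(specs, rho) {
  blocks <- split(seq_len(nrow(specs)), specs$modality)
  purrr::map(blocks, function(idx) {
    m <- length(idx)
    if (m == 1 || rho == 0) return(NULL)
    R <- matrix(rho, m, m)
    diag(R) <- 1
    ch <- tryCatch(chol(R), error = function(e) {
      abort(sprintf("correlation block for modality '%s' is not positive definite",
                    specs$modality[idx[1]]))
    })
    ch
  })
}

draw_correlated_z <- function(n, specs, chol_blocks) {
  p <- nrow(specs)
  z <- matrix(rnorm(n * p), n, p)
  blocks <- split(seq_len(p), specs$modality)
  for (mod in names(blocks)) {
    ch <- chol_blocks[[mod]]
    if (!is.null(ch)) {
      idx <- blocks[[mod]]
      z[, idx] <- z[, idx, drop = FALSE] %*% ch
    }
  }
  z
}

new_biomarker_tbl <- function(tbl, feature_meta, n_clipped = 0L,
                              contamination = NULL) {
  structure(
    tbl,
    feature_meta = feature_meta,
    n_clipped = n_clipped,
    contamination = contamination,
    class = c("biomarker_tbl", class(tibble()))
  )
}

#' Feature metadata of a biomarker table
#'
#' @param table A `biomarker_tbl` as returned by [generate_cohort()] or
#'   [read_biomarker_csv()].
#' @return A tibble with columns `feature`, `modality`, `roi`, `units`.
#' @export
feature_meta <- function(table) {
  meta <- attr(table, "feature_meta")
  if (is.null(meta)) abort("table carries no feature_meta attribute")
  as_tibble(meta)
}

#' Names of the feature columns of a biomarker table
#' @inheritParams feature_meta
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "genotype", "treatment"))
}

#' Inject outliers and below-detection values into a cohort
#'
#' Emulates the gross errors and assay-floor censoring that motivate the
#' a-priori 2-SD outlier filter and the exclusion of features measured near
#' the detection limit. A fraction `outlier_rate` of cells is displaced by
#' exactly `outlier_scale` within-group SDs (random sign); cells below a
#' feature's `detection_floor` are set to missing. Every perturbed cell is
#' recorded in the `contamination` attribute (subject, feature, kind,
#' original and new value) as ground truth for filter evaluation.
#'
#' @param table A `biomarker_tbl`.
#' @param config The [cohort_config()] carrying `outlier_rate`,
#'   `outlier_scale`, `detection_floor` and `seed` (a distinct child seed is
#'   derived so generation and contamination are independently reproducible).
#'
#' @return The contaminated `biomarker_tbl`; `attr(x, "contamination")` is a
#'   tibble of perturbed cells.
#' @export
inject_contamination <- function(table, config) {
  stopifnot(inherits(table, "biomarker_tbl"), inherits(config, "cohort_config"))
  feats <- feature_names(table)
  if (config$outlier_rate == 0 && is.null(config$detection_floor)) {
    attr(table, "contamination") <-
      tibble(subject_id = character(), feature = character(),
             kind = character(), original = numeric(), new = numeric())
    return(table)
  }

  grp <- group_label(table$genotype, table$treatment)
  vals <- as.matrix(table[, feats])
  log_rows <- list()

  seed <- derive_seeds(config$seed, 2L)[2L]
  vals <- with_preserved_seed(seed, {
    if (config$outlier_rate > 0) {
      hit <- matrix(runif(length(vals)) < config$outlier_rate,
                    nrow(vals), ncol(vals))
      sign_draw <- matrix(sample(c(-1, 1), length(vals), replace = TRUE),
                          nrow(vals), ncol(vals))
      for (j in seq_along(feats)) {
        sds <- unname(tapply(vals[, j], grp, sd)[grp])
        idx <- which(hit[, j])
        for (i in idx) {
          new_val <- unname(vals[i, j]) +
            sign_draw[i, j] * config$outlier_scale * sds[i]
          log_rows[[length(log_rows) + 1L]] <- tibble(
            subject_id = table$subject_id[i], feature = feats[j],
            kind = "outlier", original = unname(vals[i, j]), new = new_val)
          vals[i, j] <- new_val
        }
      }
    }
    vals
  })

  if (!is.null(config$detection_floor)) {
    for (f in names(config$detection_floor)) {
      j <- match(f, feats)
      floor_f <- config$detection_floor[[f]]
      idx <- which(!is.na(vals[, j]) & vals[, j] < floor_f)
      for (i in idx) {
        log_rows[[length(log_rows) + 1L]] <- tibble(
          subject_id = table$subject_id[i], feature = f,
          kind = "below_floor", original = unname(vals[i, j]), new = NA_real_)
      }
      vals[idx, j] <- NA_real_
    }
  }

  table[, feats] <- as_tibble(vals)
  attr(table, "contamination") <- if (length(log_rows)) {
    bind_rows(log_rows)
  } else {
    tibble(subject_id = character(), feature = character(),
           kind = character(), original = numeric(), new = numeric())
  }
  table
}
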