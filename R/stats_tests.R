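#' Single-pass 2-SD outlier filter
#'
#' Removes values lying more than two standard deviations from the sample
#' mean, with mean and SD computed once from the full input (a-priori
#' criterion, no iteration). Order of the survivors is preserved. A
#' zero-variance sample is returned unchanged.
#'
#' @param values Numeric vector, length >= 3; `NA`s are kept out of the
#'   mean/SD and never flagged.
#' @return A list with `values` (filtered sample) and `removed` (integer
#'   indices into the input).
#' @export
#' @examples
#' remove_outliers_2sd(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 10))
remove_outliers_2sd <- function(values) {
  stopifnot(is.numeric(values), sum(!is.na(values)) >= 3)
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    return(list(values = values, removed = integer()))
  }
  out <- which(!is.na(values) & abs(values - m) > 2 * s)
  list(values = if (length(out)) values[-out] else values, removed = out)
}

# Cache of Monte-Carlo Lilliefors null distributions, keyed by sample size.
.ks_null_cache <- new.env(parent = emptyenv())

ks_null_quantiles <- function(n, nsim = 10000L, seed = 20240117L) {
  key <- sprintf("n%d_s%d", n, nsim)
  if (!is.null(.ks_null_cache[[key]])) return(.ks_null_cache[[key]])
  stats <- with_preserved_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      x <- rnorm(n)
      lilliefors_stat(x)
    }, numeric(1))
  })
  .ks_null_cache[[key]] <- sort(stats)
  .ks_null_cache[[key]]
}

# Kolmogorov-Smirnov distance of a sample to the normal with its own
# estimated mean and SD (the composite-normality statistic).
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  Fz <- pnorm(z)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  max(abs(emp_hi - Fz), abs(Fz - emp_lo))
}

#' Composite-normality test (Kolmogorov-Smirnov with estimated parameters)
#'
#' The naive KS test is anticonservative when the normal's mean and SD are
#' estimated from the same sample; the null distribution here is therefore
#' simulated (Lilliefors-style) with >= 10^4 Monte-Carlo draws per sample
#' size, under a fixed internal seed so identical input always yields an
#' identical p-value. Samples with fewer than 5 values are too small to test
#' and are flagged as treated-normal.
#'
#' @param values Numeric sample.
#' @param nsim Number of null draws (default 10^4).
#' @return A list with `statistic` (the KS distance), `p_value`, and
#'   `too_small` (TRUE when n < 5, in which case `p_value` is `NA` and the
#'   sample should be treated as normal).
#' @export
ks_normality <- function(values, nsim = 10000L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5) {
    return(list(statistic = NA_real_, p_value = NA_real_, too_small = TRUE))
  }
  if (sd(values) == 0) {
    # degenerate; maximally non-normal
    return(list(statistic = 1, p_value = 0, too_small = FALSE))
  }
  D <- lilliefors_stat(values)
  null <- ks_null_quantiles(n, nsim = nsim)
  p <- (sum(null >= D) + 1) / (length(null) + 1)
  list(statistic = D, p_value = p, too_small = FALSE)
}

#' One-way ANOVA with Fisher's LSD planned contrasts
#'
#' Computes the omnibus one-way ANOVA over all groups, then tests each
#' planned contrast with the least-significant-difference t statistic
#' `t = (m_a - m_b) / sqrt(MSE * (1/n_a + 1/n_b))` on the pooled error
#' degrees of freedom `N - k`. Planned contrasts are reported regardless of
#' the omnibus result. With exactly two groups the LSD p-value equals the
#' pooled-variance two-sample t-test.
#'
#' @param groups Named list of numeric samples (>= 2 groups, each n >= 2).
#' @param contrasts List of two-element character vectors
#'   `c(group_a, group_b)` naming entries of `groups`.
#' @return A list with `omnibus` (tibble: F, df1, df2, p) and `contrasts`
#'   (tibble: group_a, group_b, estimate, t, df, p).
#' @export
#' @examples
#' anova_fisher_lsd(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8)),
#'                  contrasts = list(c("g1", "g3")))
anova_fisher_lsd <- function(groups, contrasts) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  groups <- purrr::map(groups, ~ .x[!is.na(.x)])
  ns <- lengths(groups)
  if (any(ns < 2)) abort("each group needs n >= 2")
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_err <- N - k
  mse <- sse / df_err
  if (mse == 0) abort("zero within-group mean square: LSD undefined")
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  Fstat <- (ssb / (k - 1)) / mse
  omnibus <- tibble(F = Fstat, df1 = k - 1, df2 = df_err,
                    p = stats::pf(Fstat, k - 1, df_err, lower.tail = FALSE))
  res <- purrr::map_dfr(contrasts, function(ct) {
    a <- ct[[1]]; b <- ct[[2]]
    if (!a %in% names(groups) || !b %in% names(groups)) {
      abort(sprintf("contrast names unknown group: %s vs %s", a, b))
    }
    est <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tval <- est / se
    tibble(group_a = a, group_b = b, estimate = est, t = tval, df = df_err,
           p = 2 * pt(-abs(tval), df_err))
  })
  list(omnibus = omnibus, contrasts = res)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom
#' (wrapper over [stats::t.test()] returning a flat result).
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    abort("both samples have zero variance: Welch statistic undefined")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The null distribution is exact when the smaller
#' sample has n <= 8 and the pooled data are tie-free; otherwise a
#' tie-corrected normal approximation (with continuity correction) is used.
#'
#' @param a,b Numeric samples, each n >= 3.
#' @return A list with `U` (count for the first sample), `p`, and `exact`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 3, length(b) >= 3)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 8 && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = unname(ht$p.value), exact = use_exact)
}

#' Two-stage adaptive step-up FDR (Benjamini-Krieger-Yekutieli)
#'
#' The two-stage linear step-up procedure: stage 1 runs Benjamini-Hochberg at
#' `q' = q / (1 + q)` giving `r1` rejections; if `r1 = 0` nothing is
#' rejected, if `r1 = m` everything is; otherwise the number of true nulls is
#' estimated as `m - r1` and stage 2 reruns BH at `q' * m / (m - r1)`. The
#' adaptive procedure rejects at least as much as plain BH at the same `q`
#' whenever stage 1 is informative.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; `NA`s are not
#'   allowed.
#' @param q Target false discovery rate (default 0.05).
#' @return A list with `reject` (logical vector), `r1` (stage-1 rejection
#'   count), and `m0_hat` (estimated number of true nulls).
#' @export
bky_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(list(reject = logical(), r1 = 0L, m0_hat = 0L))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  q1 <- q / (1 + q)
  r1 <- bh_reject_count(p_values, q1)
  if (r1 == 0L) {
    return(list(reject = rep(FALSE, m), r1 = 0L, m0_hat = m))
  }
  if (r1 == m) {
    return(list(reject = rep(TRUE, m), r1 = m, m0_hat = 0L))
  }
  m0_hat <- m - r1
  q2 <- q1 * m / m0_hat
  k2 <- bh_reject_count(p_values, q2)
  ord <- order(p_values)
  reject <- rep(FALSE, m)
  if (k2 > 0) reject[ord[seq_len(k2)]] <- TRUE
  list(reject = reject, r1 = r1, m0_hat = m0_hat)
}

# Number of BH step-up rejections at level q.
bh_reject_count <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= q * seq_len(m) / m)
  if (length(ok)) max(ok) else 0L
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, with the pooled variance weighted by
#' group degrees of freedom. The sign follows the first-minus-second
#' convention, so swapping the samples flips the sign.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return Signed effect size (numeric scalar).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) abort("zero pooled SD: Cohen's d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Post-hoc power of the two-sample t-test
#'
#' Power of the two-sided pooled-variance t-test for a standardized effect
#' `d`, via the noncentral t distribution: noncentrality
#' `ncp = d * sqrt(n_a * n_b / (n_a + n_b))` on `n_a + n_b - 2` degrees of
#' freedom. At `d = 0` the power equals `alpha`.
#'
#' @param d Standardized effect size (Cohen's d).
#' @param n_a,n_b Group sizes (each >= 2).
#' @param alpha Two-sided significance level, in (0, 1); default 0.05.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' posthoc_power(2, 12, 14)
posthoc_power <- function(d, n_a, n_b, alpha = 0.05) {
  stopifnot(n_a >= 2, n_b >= 2)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  df <- n_a + n_b - 2
  ncp <- d * sqrt(n_a * n_b / (n_a + n_b))
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp = ncp) + pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Paired numeric vectors (n >= 3, finite, nonzero variance).
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 3, all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

#' Proportional (brain-size-normalized) ROI volume
#'
#' Divides an ROI volume by total brain volume to separate regional from
#' global atrophy.
#'
#' @param roi_volume,total_brain_volume Volumes in mm^3, both positive.
#' @return A list with `ratio` and `percent`.
#' @export
proportional_volume <- function(roi_volume, total_brain_volume) {
  if (any(roi_volume <= 0) || any(total_brain_volume <= 0)) {
    abort("volumes must be positive")
  }
  ratio <- roi_volume / total_brain_volume
  list(ratio = ratio, percent = 100 * ratio)
}
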