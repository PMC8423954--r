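# Independent oracles used to cross-check package implementations.

# Plain BH step-up, coded as an explicit loop over the sorted p-values.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0L
  for (i in seq_len(m)) {
    if (p[ord[i]] <= q * i / m) k_max <- i
  }
  reject <- rep(FALSE, m)
  if (k_max > 0) reject[ord[seq_len(k_max)]] <- TRUE
  reject
}

# Two-stage adaptive BH, looped, no vectorized shortcuts; independent of the
# package's bky_fdr.
oracle_two_stage_bh <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(oracle_bh_reject(p, q1))
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  oracle_bh_reject(p, q1 * m / (m - r1))
}

# Exact two-sided Mann-Whitney p by enumerating all choose(na+nb, na)
# assignments of the pooled ranks (tie-free inputs only, small n).
oracle_mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">"))
  }
  obs <- u_stat(seq_len(na))
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, u_stat)
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# Monte-Carlo power of the two-sided pooled-variance t-test.
oracle_power_mc <- function(d, n_a, n_b, alpha = 0.05, nsim = 1e5, seed = 99) {
  set.seed(seed)
  xa <- matrix(rnorm(nsim * n_a, mean = d), nsim, n_a)
  xb <- matrix(rnorm(nsim * n_b), nsim, n_b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  tcrit <- qt(1 - alpha / 2, n_a + n_b - 2)
  mean(abs(tstat) > tcrit)
}
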