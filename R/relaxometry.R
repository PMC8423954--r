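#' Default multi-echo acquisition grid
#'
#' Eight gradient echoes starting at 3.5 ms with 5 ms spacing.
#'
#' @return Numeric vector of echo times in ms.
#' @export
default_echo_grid <- function() 3.5 + 5 * (0:7)

#' Fit R2* by log-linear regression of a multi-echo decay
#'
#' Mono-exponential transverse decay `S(TE) = S0 * exp(-R2* * TE)` is fitted
#' by ordinary least squares of `log(signal)` on echo time; the slope is
#' `-R2*` (converted from 1/ms to 1/s) and the intercept `log(S0)`.
#' Non-positive signals cannot enter the log fit and are dropped (flooring
#' them instead would bias the slope); at least three positive echoes must
#' remain.
#'
#' @param echo_times Echo times in ms, strictly increasing, length >= 3.
#' @param signals Signal magnitudes (arbitrary units), same length.
#' @param roi Optional ROI label carried through to the result.
#' @return A tibble with one row: `roi`, `r2star` (1/s), `s0`, `fit_r2`
#'   (R^2 of the log-linear fit), `n_echoes_used`, `n_dropped`.
#' @export
#' @examples
#' te <- default_echo_grid()
#' fit_r2star_loglinear(te, 100 * exp(-0.02 * te))
fit_r2star_loglinear <- function(echo_times, signals, roi = NA_character_) {
  stopifnot(length(echo_times) == length(signals), length(echo_times) >= 3)
  if (any(diff(echo_times) <= 0)) abort("echo_times must be strictly increasing")
  keep <- which(!is.na(signals) & signals > 0)
  n_dropped <- length(signals) - length(keep)
  if (length(keep) < 3) {
    abort(sprintf("only %d positive signal(s): need >= 3 for the log-linear fit",
                  length(keep)))
  }
  te <- echo_times[keep]
  y <- log(signals[keep])
  if (sd(y) == 0) {
    return(tibble(roi = roi, r2star = 0, s0 = exp(y[1]), fit_r2 = 1,
                  n_echoes_used = length(keep), n_dropped = n_dropped))
  }
  fit <- lm(y ~ te)
  slope <- unname(coef(fit)[2])
  r2star <- -slope * 1000  # 1/ms -> 1/s
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble(roi = roi, r2star = r2star, s0 = exp(unname(coef(fit)[1])),
         fit_r2 = 1 - ss_res / ss_tot,
         n_echoes_used = length(keep), n_dropped = n_dropped)
}

#' ROI-volume-corrected R2*
#'
#' Divides an R2* rate by the ROI volume to express susceptibility-related
#' signal decay per unit tissue volume (an iron-accumulation-per-volume
#' proxy). Homogeneous of degree -1 in volume: shrinking the ROI at constant
#' raw R2* increases the corrected value, which is how a raw R2* decrease can
#' coexist with a volume-corrected increase in an atrophic brain.
#'
#' @param r2star R2* in 1/s.
#' @param roi_volume ROI volume in mm^3, positive.
#' @return Corrected R2* in 1/(s mm^3).
#' @export
volume_corrected_r2star <- function(r2star, roi_volume) {
  if (any(roi_volume <= 0)) abort("roi_volume must be positive")
  r2star / roi_volume
}

#' Simulate a noisy multi-echo decay
#'
#' @param r2star True decay rate in 1/s (>= 0).
#' @param s0 Signal at TE = 0.
#' @param echo_grid Echo times in ms (default [default_echo_grid()]).
#' @param noise_sd Additive Gaussian noise SD in signal units (default 0).
#' @param seed Optional seed for reproducible noise.
#' @return A tibble with columns `echo_time_ms` and `signal`. Negative noisy
#'   draws are clipped to a small positive floor (`1e-6 * s0`) with the count
#'   in the `n_clipped` attribute.
#' @export
simulate_decay <- function(r2star, s0, echo_grid = default_echo_grid(),
                           noise_sd = 0, seed = NULL) {
  stopifnot(r2star >= 0, s0 > 0)
  clean <- s0 * exp(-r2star * echo_grid / 1000)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) {
      with_preserved_seed(seed, rnorm(length(echo_grid), sd = noise_sd))
    } else {
      rnorm(length(echo_grid), sd = noise_sd)
    }
  } else {
    rep(0, length(echo_grid))
  }
  sig <- clean + noise
  floor_val <- 1e-6 * s0
  n_clipped <- sum(sig < floor_val)
  sig[sig < floor_val] <- floor_val
  out <- tibble(echo_time_ms = echo_grid, signal = sig)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Fit R2* for every ROI of a long-format multi-echo table
#'
#' @param series A data frame with columns `roi`, `echo_time_ms`, `signal`
#'   (e.g. read from CSV).
#' @return A tibble with one [fit_r2star_loglinear()] row per ROI.
#' @export
fit_r2star_table <- function(series) {
  stopifnot(all(c("roi", "echo_time_ms", "signal") %in% names(series)))
  series |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(~ {
      ord <- order(.x$echo_time_ms)
      fit_r2star_loglinear(.x$echo_time_ms[ord], .x$signal[ord])[, -1]
    }) |>
    dplyr::ungroup()
}
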