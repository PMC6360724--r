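# Zero-lag low-pass Butterworth filtering and Winter-style residual analysis.

#' Zero-lag low-pass Butterworth filter
#'
#' Forward+backward passes of an order/2 Butterworth low-pass (net `order`,
#' default 4th), giving zero phase lag and DC gain 1. No cutoff-frequency
#' correction is applied for the dual pass, so the net amplitude at the cutoff
#' is 0.5 for `order = 4`. Edges are handled by odd (anti-symmetric)
#' reflection padding long enough for the start-up transient to decay
#' (at least `3 * order` samples, growing as `rate / cutoff`).
#'
#' @param x Numeric vector (one signal).
#' @param rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; must lie in (0, rate/2).
#' @param order Net filter order (even); `order/2` per pass.
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass_zero_lag <- function(x, rate, cutoff, order = 4) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz)", call. = FALSE)
  if (order %% 2 != 0 || order < 2)
    stop("order must be a positive even integer", call. = FALSE)
  n <- length(x)
  # the start-up transient decays over several filter time constants, so the
  # pad must grow as the cutoff falls relative to the sampling rate
  pad <- max(3L * order, ceiling(6 * rate / cutoff))
  if (n <= 3L * order || n <= pad)
    stop("signal too short (", n, " samples) for order-", order,
         " zero-lag filtering", call. = FALSE)
  bf <- signal::butter(order / 2, 2 * cutoff / rate, type = "low")
  # odd reflection about the end points suppresses edge transients
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Filter all marker trajectories of a trial
#'
#' Applies [lowpass_zero_lag()] per marker per axis. Trials with gaps in any
#' marker are rejected rather than interpolated.
#'
#' @param trial A [trial()] object.
#' @param cutoff Cutoff frequency, Hz (study default 26).
#' @param order Net filter order.
#' @return A [trial()] object with filtered coordinates.
#' @export
filter_trial <- function(trial, cutoff = 26, order = 4) {
  if (any(trial$gaps))
    stop("cannot filter a trial with flagged gaps (",
         sum(trial$gaps), " marker-frames)", call. = FALSE)
  out <- trial
  for (m in seq_along(trial$markers))
    for (ax in 1:3)
      out$data[, m, ax] <- lowpass_zero_lag(trial$data[, m, ax],
                                            trial$rate, cutoff, order)
  out
}

#' Residual analysis for cutoff selection
#'
#' Winter-style residual analysis: the RMS residual between the raw signal
#' and its low-pass filtered version is evaluated over a grid of candidate
#' cutoffs; a straight line is fitted to the high-frequency tail of the
#' residual curve (by default the upper half of the grid) and extrapolated to
#' 0 Hz to estimate the noise floor; the chosen cutoff is the smallest grid
#' frequency whose residual does not exceed that intercept.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @param grid Candidate cutoffs (Hz), strictly inside (0, rate/2).
#' @param order Net filter order passed to [lowpass_zero_lag()].
#' @param tail_fraction Fraction of the grid (from the top) used for the
#'   linear noise fit; at least 3 points are required.
#' @return An object of class `"residual_curve"`: list with `cutoffs`,
#'   `residuals` (mm), `noise_intercept` (mm), `chosen_cutoff` (Hz).
#' @export
residual_analysis <- function(x, rate, grid = 1:50, order = 4,
                              tail_fraction = 0.5) {
  grid <- sort(unique(grid))
  if (any(grid <= 0 | grid >= rate / 2))
    stop("residual-analysis grid must lie inside (0, Nyquist)", call. = FALSE)
  res <- vapply(grid, function(fc) rms(x - lowpass_zero_lag(x, rate, fc, order)),
                numeric(1))
  ntail <- max(3L, ceiling(tail_fraction * length(grid)))
  if (ntail > length(grid))
    stop("analysis error: fewer than 3 tail points for the noise fit",
         call. = FALSE)
  idx <- seq.int(length(grid) - ntail + 1L, length(grid))
  fit <- stats::lm.fit(cbind(1, grid[idx]), res[idx])
  intercept <- max(0, fit$coefficients[1])
  ok <- which(res <= intercept)
  chosen <- if (length(ok)) grid[min(ok)] else grid[length(grid)]
  structure(list(cutoffs = grid, residuals = res,
                 noise_intercept = unname(intercept),
                 chosen_cutoff = chosen),
            class = "residual_curve")
}

#' @export
print.residual_curve <- function(x, ...) {
  cat("<residual_curve>", length(x$cutoffs), "cutoffs; noise intercept",
      sprintf("%.3f", x$noise_intercept), "mm; chosen cutoff",
      x$chosen_cutoff, "Hz\n")
  invisible(x)
}
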