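#' Peak-based rhythm statistics
#'
#' Estimates period, peak phase and amplitude of a sampled time series by
#' peak analysis, a self-contained replacement for external online
#' rhythm-analysis services. Candidate peaks are strict local maxima above the series
#' midrange; candidates closer together than `min_separation_h` are merged
#' (highest wins) and each surviving peak time is refined by a least-squares
#' quadratic fit through the points within `refine_window_h` of the maximum
#' (at least the three bracketing points). The period is the mean successive
#' peak-to-peak interval, the phase is the first post-`t0` peak time modulo
#' the period, and the amplitude is half the peak-to-trough span.
#'
#' @param series Data frame with columns `time_h`, `value` (strictly
#'   increasing times), e.g. from [trajectory_series()].
#' @param min_cycles Minimum number of cycles the series must cover
#'   (default 3) at `expected_period_h`.
#' @param expected_period_h Nominal period used only for the coverage
#'   precondition (default 24).
#' @param min_separation_h Minimum spacing between distinct peaks
#'   (default 6).
#' @param refine_window_h Half-width of the quadratic refinement window
#'   (default 0.75).
#' @return An object of class `rhythm_stats`: list with `period_h`,
#'   `phase_h`, `amplitude`, `n_peaks_used`, `peak_times_h`.
#'   Fewer than two peaks signal arrhythmia and raise an error of class
#'   `rhythm_undetectable`.
#' @examples
#' tt <- seq(0, 120, by = 0.05)
#' s <- data.frame(time_h = tt, value = sin(2 * pi * tt / 24))
#' estimate_period(s)
#' @export
estimate_period <- function(series, min_cycles = 3, expected_period_h = 24,
                            min_separation_h = 6, refine_window_h = 0.75) {
  series <- check_series(series)
  tt <- series$time_h
  y <- series$value
  span <- tt[length(tt)] - tt[1]
  if (span < min_cycles * expected_period_h)
    stop(sprintf("series covers %.3g h; need >= %g cycles of %g h",
                 span, min_cycles, expected_period_h), call. = FALSE)
  if (length(tt) < 8 * min_cycles)
    stop("need at least 8 points per expected cycle", call. = FALSE)

  ## densely sampled series are lightly smoothed (running mean spanning
  ## ~T/12) before peak detection so sampling noise cannot split a crest;
  ## amplitude is still reported from the raw values
  ys <- y
  half <- 0L
  spacing <- stats::median(diff(tt))
  if (spacing < expected_period_h / 48) {
    k <- 2 * floor(expected_period_h / 24 / spacing) + 1
    if (k >= 3) {
      ys <- running_mean(y, k)
      half <- (k - 1) / 2
    }
  }

  mid <- (max(ys) + min(ys)) / 2
  n <- length(ys)
  cand <- which(ys[-c(1, 2)] < ys[-c(1, n)] &
                  ys[-c(n - 1, n)] < ys[-c(1, n)]) + 1
  cand <- cand[ys[cand] > mid]
  # drop candidates whose smoothing window is truncated by the boundary
  cand <- cand[cand > half & cand <= n - half]
  ## merge candidates closer than min_separation_h, keeping the highest
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && tt[i] - tt[peaks[length(peaks)]] < min_separation_h) {
      if (ys[i] > ys[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else peaks <- c(peaks, i)
  }
  if (length(peaks) < 2)
    stop(structure(class = c("rhythm_undetectable", "error", "condition"),
                   list(message = "fewer than 2 peaks: rhythm undetectable",
                        call = NULL)))

  peak_times <- vapply(peaks, function(i)
    refine_peak(tt, ys, i, refine_window_h), numeric(1))
  period <- mean(diff(peak_times))
  structure(list(period_h = period,
                 phase_h = peak_times[1] %% period,
                 amplitude = (max(y) - min(y)) / 2,
                 n_peaks_used = length(peaks),
                 peak_times_h = peak_times),
            class = "rhythm_stats")
}

## centered running mean with shrinking windows at the edges
running_mean <- function(y, k) {
  n <- length(y)
  half <- (k - 1) / 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

refine_peak <- function(tt, y, i, window_h) {
  sel <- which(abs(tt - tt[i]) <= window_h)
  sel <- union(sel, max(1, i - 1):min(length(tt), i + 1))
  if (length(sel) < 3) return(tt[i])
  fit <- stats::lm.fit(cbind(1, tt[sel] - tt[i], (tt[sel] - tt[i])^2), y[sel])
  a <- fit$coefficients[3]
  b <- fit$coefficients[2]
  if (!is.finite(a) || a >= 0) return(tt[i])
  vertex <- -b / (2 * a)
  ## never move outside the refinement window
  tt[i] + max(-window_h, min(window_h, vertex))
}

#' First peak time of a series within a window
#'
#' Locates the first prominent local maximum (above the series midrange)
#' inside `window_h`, the quantity compared across photoperiods when
#' measuring the first-cycle peak delay after a transfer (e.g. constant
#' light versus the entraining long day).
#'
#' @param series Data frame with columns `time_h`, `value`.
#' @param window_h Length-2 search window in hours (default `c(1, 28)`,
#'   skipping the switch instant itself).
#' @return Peak time in hours, or an error if no prominent peak exists.
#' @export
first_peak_time <- function(series, window_h = c(1, 28)) {
  series <- check_series(series)
  sel <- series$time_h >= window_h[1] & series$time_h <= window_h[2]
  tt <- series$time_h[sel]
  y <- series$value[sel]
  n <- length(y)
  if (n < 3) stop("window too short", call. = FALSE)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1
  i <- i[y[i] > (max(y) + min(y)) / 2]
  if (!length(i)) stop("no prominent peak in the window", call. = FALSE)
  tt[i[1]]
}

#' @export
print.rhythm_stats <- function(x, ...) {
  cat(sprintf(
    "Rhythm: period %.2f h, phase %.2f h, amplitude %.3g (%d peaks)\n",
    x$period_h, x$phase_h, x$amplitude, x$n_peaks_used))
  invisible(x)
}

check_series <- function(series) {
  if (!is.data.frame(series) || !all(c("time_h", "value") %in% names(series)))
    stop("a time series is a data frame with columns time_h, value",
         call. = FALSE)
  if (nrow(series) == 0) stop("empty time series", call. = FALSE)
  if (is.unsorted(series$time_h, strictly = TRUE))
    stop("time_h must be strictly increasing", call. = FALSE)
  series
}

#' Sum-of-squares error between matched series
#'
#' The discrepancy measure used for curve fitting:
#' \eqn{\sum_i (y_i - \tilde y_i)^2} over a shared time grid. Note this is a
#' sum, not a mean; `normalized = TRUE` divides by the number of points.
#'
#' @param sim,obs Data frames with columns `time_h`, `value` on identical
#'   grids.
#' @param normalized Divide by the number of points (default `FALSE`, the
#'   printed convention).
#' @return Non-negative scalar.
#' @export
mse <- function(sim, obs, normalized = FALSE) {
  sim <- check_series(sim); obs <- check_series(obs)
  if (nrow(sim) != nrow(obs) ||
      max(abs(sim$time_h - obs$time_h)) > 1e-8)
    stop("sim and obs must share the same time grid", call. = FALSE)
  s <- sum((sim$value - obs$value)^2)
  if (normalized) s / nrow(sim) else s
}

#' Simple cost over the photosynthetic genes
#'
#' \eqn{\delta = \sum_{i \in G} \sum_t (y_{it} - \bar y_{it})^2} where `G`
#' is the photosynthetic gene set (Lhcb1, RbcS1, atpA by default).
#'
#' @param sim,obs Named lists of time-series data frames.
#' @param genes Character vector of series names to sum over.
#' @return Non-negative scalar.
#' @export
cost_simple <- function(sim, obs, genes = c("Lhcb1", "RbcS1", "atpA")) {
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  missing <- setdiff(genes, intersect(names(sim), names(obs)))
  if (length(missing))
    stop("series missing from sim or obs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(vapply(genes, function(g) mse(sim[[g]], obs[[g]]), numeric(1)))
}

#' Extended cost with phase and period penalties
#'
#' \eqn{\delta' = \delta_{SSE} + \delta_\phi + \delta_{PI}}: the
#' sum-of-squares term over the extended gene set `G'` (photosynthetic genes
#' plus the four clock components), plus the summed squared peak-time
#' (phase) differences and squared period differences from peak analysis.
#' Phase differences are wrapped to half a period before squaring, so a
#' shift by exactly one period contributes nothing. A series too short or
#' too arrhythmic for [estimate_period()] contributes only to the SSE term
#' (with a warning), mirroring the loss of rhythm seen under the short
#' skeleton photoperiod.
#'
#' @param sim,obs Named lists of time-series data frames on shared grids.
#' @param genes Series names to include (default the extended set).
#' @param ... Passed to [estimate_period()].
#' @return An object of class `cost_breakdown`: list with `sse`,
#'   `phase_err`, `period_err`, `total` (= their sum).
#' @export
cost_optimal <- function(sim, obs,
                         genes = c("Lhcb1", "RbcS1", "atpA",
                                   "CL", "P97", "P51", "EL"), ...) {
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  missing <- setdiff(genes, intersect(names(sim), names(obs)))
  if (length(missing))
    stop("series missing from sim or obs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sse <- 0; phase_err <- 0; period_err <- 0
  for (g in genes) {
    sse <- sse + mse(sim[[g]], obs[[g]])
    rs <- tryCatch(estimate_period(sim[[g]], ...), error = function(e) NULL)
    ro <- tryCatch(estimate_period(obs[[g]], ...), error = function(e) NULL)
    if (is.null(rs) || is.null(ro)) {
      warning("series '", g, "' not rhythmic enough for phase/period terms; ",
              "SSE only", call. = FALSE)
      next
    }
    T0 <- ro$period_h
    dphi <- (ro$phase_h - rs$phase_h + T0 / 2) %% T0 - T0 / 2
    phase_err <- phase_err + dphi^2
    period_err <- period_err + (rs$period_h - ro$period_h)^2
  }
  structure(list(sse = sse, phase_err = phase_err, period_err = period_err,
                 total = sse + phase_err + period_err),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "Cost: total %.4g = SSE %.4g + phase %.4g + period %.4g\n",
    x$total, x$sse, x$phase_err, x$period_err))
  invisible(x)
}
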