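#' Relative expression by the 2^-ddCt method
#'
#' Relative quantification of RT-qPCR expression against a reference gene
#' and a calibrator sample:
#' \eqn{\Delta\Delta C_t = (C_t^{target} - C_t^{ref}) -
#' (C_t^{target,cal} - C_t^{ref,cal})} and relative expression
#' \eqn{2^{-\Delta\Delta C_t}}.
#'
#' @param ct_target,ct_reference Cycle thresholds of the sample.
#' @param ct_target_cal,ct_reference_cal Cycle thresholds of the calibrator.
#' @return Positive relative expression; 1 when sample and calibrator agree.
#' @examples
#' ddct_expression(24, 20, 25, 20)  # ddCt = -1 -> 2
#' @export
ddct_expression <- function(ct_target, ct_reference,
                            ct_target_cal, ct_reference_cal) {
  vals <- c(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}

#' Stomatal aperture from guard-cell half-axes
#'
#' Elliptical aperture area \eqn{c = \pi a b} with `a` half the stomatal
#' length and `b` half the width, both in micrometres.
#'
#' @param a,b Half-length and half-width (um, > 0); vectorised.
#' @return Aperture area in um^2.
#' @export
stomatal_aperture <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("half-axes must be positive", call. = FALSE)
  pi * a * b
}

#' Generate a study-shaped synthetic expression dataset
#'
#' Emulates the study's RT-qPCR design: per gene, time point and replicate a
#' noisy relative-expression value, on the photoperiod's sampling grid
#' (every 3 h, or every 1.5 h under the short skeleton photoperiod), with
#' three biological replicates by default. Noise is multiplicative
#' log-normal (fold-change error), so the noiseless limit reproduces the
#' truth exactly. The underlying truth per gene is either a model trajectory
#' variable (when `truth` is supplied) or a parametric cosine
#' `baseline + amplitude * cos(2*pi*(t - phase_h)/period_h)`.
#'
#' @param genes Named list describing each gene's waveform: either a state
#'   variable name (character, looked up in `truth`) or a list with
#'   `period_h`, `phase_h`, `amplitude`, `baseline`.
#' @param schedule Schedule name controlling the sampling grid
#'   (default `"12L12D"`).
#' @param truth Optional `clock_trajectory` providing model-based waveforms.
#' @param noise_sd Log-normal sdlog of the multiplicative noise
#'   (default 0.1).
#' @param n_replicates Biological replicates per sample (default 3).
#' @param days Days covered by the grid (default 1).
#' @param seed Integer seed; generation is a pure function of
#'   (configuration, seed).
#' @return Data frame with columns `time_h`, `gene`, `replicate`, `value`.
#' @export
generate_expression_dataset <- function(genes, schedule = "12L12D",
                                        truth = NULL, noise_sd = 0.1,
                                        n_replicates = 3, days = 1,
                                        seed = 1) {
  if (length(genes) == 0 || is.null(names(genes)))
    stop("genes must be a non-empty named list", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  step <- if (identical(schedule, "3L3D")) 1.5 else 3
  grid <- seq(0, 24 * days, by = step)

  truth_at <- function(wf) {
    if (is.character(wf)) {
      if (is.null(truth))
        stop("a trajectory `truth` is required for model-based waveforms",
             call. = FALSE)
      s <- trajectory_series(truth, wf)
      idx <- match(round(grid / truth$dt), round(s$time_h / truth$dt))
      if (any(is.na(idx)))
        stop("sampling grid not covered by the trajectory", call. = FALSE)
      s$value[idx]
    } else if (is.list(wf)) {
      req <- c("period_h", "phase_h", "amplitude", "baseline")
      if (!all(req %in% names(wf)))
        stop("parametric waveform needs ", paste(req, collapse = ", "),
             call. = FALSE)
      wf$baseline +
        wf$amplitude * cos(2 * pi * (grid - wf$phase_h) / wf$period_h)
    } else stop("unknown gene waveform specification", call. = FALSE)
  }

  set.seed(seed)
  rows <- lapply(names(genes), function(g) {
    mu <- truth_at(genes[[g]])
    if (any(mu < 0))
      stop("waveform for ", g, " goes negative; expression truth must be >= 0",
           call. = FALSE)
    do.call(rbind, lapply(seq_len(n_replicates), function(r)
      data.frame(time_h = grid, gene = g, replicate = r,
                 value = mu * exp(stats::rnorm(length(mu), 0, noise_sd)))))
  })
  out <- do.call(rbind, rows)
  out[order(out$gene, out$time_h, out$replicate), , drop = FALSE]
}

#' Summarise replicates to mean and standard error
#'
#' @param data Long data frame from [generate_expression_dataset()] (or the
#'   same layout read from disk).
#' @return Data frame with columns `time_h`, `gene`, `mean`, `se`, `n`.
#' @export
summarize_replicates <- function(data) {
  req <- c("time_h", "gene", "value")
  if (!all(req %in% names(data)))
    stop("need columns time_h, gene, value", call. = FALSE)
  agg <- stats::aggregate(value ~ gene + time_h, data = data, function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  out <- data.frame(time_h = agg$time_h, gene = agg$gene,
                    mean = agg$value[, "mean"], se = agg$value[, "se"],
                    n = as.integer(agg$value[, "n"]))
  out$se[is.na(out$se)] <- 0
  out[order(out$gene, out$time_h), , drop = FALSE]
}

#' Generate a study-shaped synthetic stomatal-aperture table
#'
#' Emulates the layout of the packaged stomatal-aperture table: per
#' photoperiod and sampling time, the mean and standard error of three noisy
#' pseudo-replicates around a rhythmic truth (a 24 h cosine peaking at ZT6
#' by default, the mid-light maximum seen in the measured data).
#'
#' @param photoperiods Schedule names (columns of the emulated table).
#' @param baseline,amplitude,peak_h Cosine truth parameters (um^2 / hours).
#' @param noise_sd Multiplicative log-normal noise sdlog (default 0.02).
#' @param n_replicates Pseudo-replicates per cell (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `time_h`, `photoperiod`, `mean`, `se`,
#'   `n` — the same layout the packaged table loads into, so readers are
#'   shared.
#' @export
generate_stomatal_dataset <- function(photoperiods = c("12L12D", "6L6D",
                                                       "24L", "3L3D"),
                                      baseline = 46, amplitude = 12,
                                      peak_h = 6, noise_sd = 0.02,
                                      n_replicates = 3, seed = 1) {
  set.seed(seed)
  rows <- lapply(photoperiods, function(ph) {
    step <- if (identical(ph, "3L3D")) 1.5 else 3
    grid <- seq(0, 24, by = step)
    mu <- baseline + amplitude * cos(2 * pi * (grid - peak_h) / 24)
    reps <- matrix(mu, nrow = n_replicates, ncol = length(mu), byrow = TRUE) *
      exp(matrix(stats::rnorm(n_replicates * length(mu), 0, noise_sd),
                 nrow = n_replicates))
    se <- apply(reps, 2, stats::sd) / sqrt(n_replicates)
    se[is.na(se)] <- 0
    data.frame(time_h = grid, photoperiod = ph,
               mean = colMeans(reps), se = se, n = n_replicates)
  })
  do.call(rbind, rows)
}
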