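#' Read and write time-series CSV files
#'
#' `read_timeseries_csv` accepts either long form (`time_h`, optional
#' grouping columns such as `gene`/`replicate`, and `value`) or wide form
#' (`time_h` plus one numeric column per series). Validation is strict:
#' a missing or empty file, non-numeric cells, or (for wide form)
#' unsorted/duplicated times are errors, never silent coercions.
#'
#' @param path CSV path.
#' @return Data frame as stored.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("empty or unreadable time-series file: ", path,
                        call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0)
    stop("empty time-series file: ", path, call. = FALSE)
  if (!"time_h" %in% names(df))
    stop("time-series CSV must have a time_h column", call. = FALSE)
  if (!is.numeric(df$time_h))
    stop("non-numeric time_h values in ", path, call. = FALSE)
  value_cols <- setdiff(names(df), c("time_h", "gene", "photoperiod",
                                     "replicate", "letters"))
  bad <- value_cols[!vapply(df[value_cols], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric value column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  long <- any(c("gene", "photoperiod", "replicate") %in% names(df))
  if (!long) {
    dup <- which(duplicated(df$time_h))
    if (length(dup))
      stop("duplicated time_h at row(s) ", paste(dup, collapse = ", "),
           call. = FALSE)
    if (is.unsorted(df$time_h))
      stop("time_h must be sorted increasing", call. = FALSE)
  }
  df
}

#' @rdname read_timeseries_csv
#' @param data Data frame to write.
#' @export
write_timeseries_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged stomatal-aperture table
#'
#' Loads the measured stomatal apertures of tea leaves under the four
#' photoperiods (mean ± standard error of three replicates, um^2, with the
#' published multiple-comparison letters kept as opaque annotations). The
#' 1.5 h rows exist only for the short skeleton photoperiod 3L3D, matching
#' the sampling design.
#'
#' @return Data frame with columns `time_h`, `photoperiod`, `mean`, `se`,
#'   `n`, `letters`.
#' @examples
#' tab <- load_stomatal_fixture()
#' subset(tab, photoperiod == "12L12D" & time_h == 6)
#' @export
load_stomatal_fixture <- function() {
  path <- system.file("extdata", "stomatal_aperture_table.csv",
                      package = "circaphoto")
  if (!nzchar(path)) stop("packaged stomatal table not found", call. = FALSE)
  df <- read_timeseries_csv(path)
  req <- c("time_h", "photoperiod", "mean", "se", "n", "letters")
  if (!all(req %in% names(df)))
    stop("packaged stomatal table is malformed", call. = FALSE)
  df
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study workflow on synthetic data: (1) simulate the basal
#' model under the training photoperiod (24L) and generate noisy observed
#' photosynthetic-parameter series from it; (2) estimate the 20 output-map
#' parameters by cost minimisation; (3) predict clock and photosynthetic
#' dynamics under all four photoperiods by changing only the light input;
#' (4) run rhythm statistics on every gene series; (5) write trajectories
#' (CSV), fitted parameters and rhythm summaries (JSON) to `out_dir`.
#' Fully reproducible under a fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param params Basal parameter set.
#' @param seed Integer seed for the synthetic observations and the fit.
#' @param noise_sd Multiplicative noise on the synthetic observations.
#' @param n_starts Multi-start count for the fit.
#' @param post_days Days simulated per photoperiod.
#' @param dt RK4 step (hours).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(out_dir, params = default_params(), seed = 1,
                         noise_sd = 0.1, n_starts = 10, post_days = 3,
                         dt = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## 1. synthetic 24L observations of the photosynthetic parameters
  train <- entrain_then_switch(params, target = "24L", post_days = post_days,
                               dt = dt)
  true_out <- simulate_photoparams(train, params[names(default_output_params())])
  grid <- seq(0, 24 * post_days, by = 3)
  set.seed(seed)
  obs <- lapply(true_out, function(s) {
    idx <- match(round(grid / dt), round(s$time_h / dt))
    mu <- s$value[idx]
    data.frame(time_h = grid,
               value = mu * exp(stats::rnorm(length(mu), 0, noise_sd)))
  })

  ## 2. output-parameter estimation (kinetics frozen)
  fit <- fit_output_params(obs, params = params, schedule = "24L",
                           n_starts = n_starts, seed = seed, dt = dt)

  ## 3-4. prediction under all photoperiods + rhythm statistics
  fitted_params <- params
  fitted_params[names(coef(fit))] <- coef(fit)
  trajs <- predict_under_photoperiods(fitted_params, post_days = post_days,
                                      dt = dt)
  gene_vars <- c(CL = "MCL", P97 = "MP97", P51 = "MP51", EL = "MEL",
                 Lhcb1 = "M_Lhcb1", RbcS1 = "M_RbcS1", atpA = "M_atpA")
  rhythms <- lapply(trajs, function(tr) {
    lapply(gene_vars, function(v) {
      rs <- tryCatch(
        estimate_period(trajectory_series(tr, v),
                        min_cycles = min(3, floor(post_days * 24 / 24))),
        error = function(e) NULL)
      if (is.null(rs)) list(rhythmic = FALSE)
      else list(rhythmic = TRUE, period_h = rs$period_h,
                phase_h = rs$phase_h, amplitude = rs$amplitude,
                n_peaks_used = rs$n_peaks_used)
    })
  })

  ## 5. artifacts
  for (nm in names(trajs))
    write_timeseries_csv(as.data.frame(trajs[[nm]]),
                         file.path(out_dir, paste0("trajectory_", nm, ".csv")))
  summary <- list(
    package_version = as.character(utils::packageVersion("circaphoto")),
    seed = seed, noise_sd = noise_sd, n_starts = n_starts,
    post_days = post_days, dt = dt,
    fitted_output_params = as.list(coef(fit)),
    fit_cost = fit$cost, fit_converged = fit$converged,
    rhythms = rhythms)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
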