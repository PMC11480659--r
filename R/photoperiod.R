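#' Build a photoperiod schedule
#'
#' A photoperiod schedule is a piecewise-constant binary light forcing
#' \eqn{L(t)} over one repeating cycle, with darkness defined as
#' \eqn{D(t) = 1 - L(t)}. The four experimental regimes are available as
#' presets: the entraining long day `"12L12D"`, constant light `"24L"`, and
#' the two skeleton photoperiods `"6L6D"` (6 h on / 6 h off) and `"3L3D"`
#' (3 h on / 3 h off), all on a 24 h cycle starting with lights-on at ZT0
#' (09:00 clock time in the experimental design).
#'
#' Blocks are half-open intervals `[start_h, end_h)` and must tile
#' `[0, cycle_h)` exactly, with no gaps or overlaps.
#'
#' @param preset_or_blocks Either a preset name (`"12L12D"`, `"24L"`,
#'   `"6L6D"`, `"3L3D"`) or a data frame with columns `start_h`, `end_h`,
#'   `is_light` describing explicit blocks.
#' @param cycle_h Cycle length in hours (default 24; ignored size-checked
#'   against explicit blocks).
#' @param name Optional label; defaults to the preset name.
#' @return An object of class `photoperiod_schedule` with elements `name`,
#'   `cycle_h` and `blocks`.
#' @examples
#' sched <- build_schedule("6L6D")
#' light_at(sched, c(0, 5.9, 6, 17.9, 18))
#' duty_cycle(sched)
#' @export
build_schedule <- function(preset_or_blocks, cycle_h = 24, name = NULL) {
  if (!is.finite(cycle_h) || cycle_h <= 0)
    stop("cycle_h must be a positive number of hours", call. = FALSE)

  if (is.character(preset_or_blocks) && length(preset_or_blocks) == 1) {
    preset <- preset_or_blocks
    blocks <- switch(preset,
      "12L12D" = block_df(c(0, 12), c(12, 24), c(TRUE, FALSE)),
      "24L"    = block_df(0, 24, TRUE),
      "6L6D"   = block_df(c(0, 6, 12, 18), c(6, 12, 18, 24),
                          c(TRUE, FALSE, TRUE, FALSE)),
      "3L3D"   = block_df(seq(0, 21, by = 3), seq(3, 24, by = 3),
                          rep(c(TRUE, FALSE), 4)),
      stop("unknown photoperiod preset: ", preset, call. = FALSE)
    )
    cycle_h <- 24
    if (is.null(name)) name <- preset
  } else {
    blocks <- as.data.frame(preset_or_blocks)
    req <- c("start_h", "end_h", "is_light")
    if (!all(req %in% names(blocks)))
      stop("explicit blocks need columns start_h, end_h, is_light", call. = FALSE)
    blocks <- blocks[order(blocks$start_h), req]
    blocks$is_light <- as.logical(blocks$is_light)
    if (is.null(name)) name <- "custom"
  }

  validate_blocks(blocks, cycle_h)
  structure(list(name = name, cycle_h = cycle_h, blocks = blocks),
            class = "photoperiod_schedule")
}

block_df <- function(start, end, light) {
  data.frame(start_h = start, end_h = end, is_light = light)
}

validate_blocks <- function(blocks, cycle_h) {
  if (nrow(blocks) == 0)
    stop("schedule must contain at least one block", call. = FALSE)
  if (any(blocks$end_h <= blocks$start_h))
    stop("every block needs end_h > start_h", call. = FALSE)
  bounds_ok <- isTRUE(all.equal(blocks$start_h[1], 0)) &&
    isTRUE(all.equal(blocks$end_h[nrow(blocks)], cycle_h))
  joins_ok <- nrow(blocks) < 2 ||
    isTRUE(all.equal(blocks$end_h[-nrow(blocks)], blocks$start_h[-1]))
  if (!bounds_ok || !joins_ok)
    stop("blocks must tile [0, cycle_h) exactly with no gaps or overlaps",
         call. = FALSE)
  invisible(NULL)
}

#' Evaluate the light forcing of a schedule
#'
#' `light_at` returns \eqn{L(t) \in \{0, 1\}} for any finite time, wrapping
#' `t` modulo the cycle length; `dark_at` returns \eqn{D(t) = 1 - L(t)}.
#'
#' @param schedule A [build_schedule()] object.
#' @param t Time(s) in hours since ZT0; any finite real, vectorised.
#' @return Integer vector of 0/1 values.
#' @export
light_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "photoperiod_schedule"))
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  tm <- t %% schedule$cycle_h
  b <- schedule$blocks
  idx <- findInterval(tm, b$start_h)
  as.integer(b$is_light[idx])
}

#' @rdname light_at
#' @export
dark_at <- function(schedule, t) 1L - light_at(schedule, t)

#' @rdname light_at
#' @export
duty_cycle <- function(schedule) {
  b <- schedule$blocks
  sum((b$end_h - b$start_h)[b$is_light]) / schedule$cycle_h
}

#' @export
print.photoperiod_schedule <- function(x, ...) {
  cat(sprintf("Photoperiod schedule '%s' (cycle %g h, light fraction %.3g)\n",
              x$name, x$cycle_h, duty_cycle(x)))
  b <- x$blocks
  for (i in seq_len(nrow(b)))
    cat(sprintf("  [%5.2f, %5.2f) %s\n", b$start_h[i], b$end_h[i],
                if (b$is_light[i]) "light" else "dark"))
  invisible(x)
}

#' Read or write a schedule as a YAML configuration
#'
#' Serialises a schedule to a YAML file with fields `name`, `cycle_h` and
#' `blocks` (a list of `start_h`/`end_h`/`is_light` records), and reads the
#' same format back, re-validating the tiling invariant.
#'
#' @param schedule A schedule object.
#' @param path File path.
#' @return `read_schedule_yaml` returns a `photoperiod_schedule`;
#'   `write_schedule_yaml` returns `path` invisibly.
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "photoperiod_schedule"))
  b <- schedule$blocks
  obj <- list(name = schedule$name, cycle_h = schedule$cycle_h,
              blocks = lapply(seq_len(nrow(b)), function(i)
                list(start_h = b$start_h[i], end_h = b$end_h[i],
                     is_light = b$is_light[i])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  blocks <- do.call(rbind, lapply(obj$blocks, function(bl)
    data.frame(start_h = bl$start_h, end_h = bl$end_h,
               is_light = bl$is_light)))
  build_schedule(blocks, cycle_h = obj$cycle_h, name = obj$name)
}
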