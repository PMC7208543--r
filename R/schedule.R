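#' Stimulation schedules
#'
#' A stimulation schedule maps each dynamic (one image per TR) to the
#' stimulating current delivered while it was acquired. It is a tibble with
#' columns `dynamic_index` (0-based, dense), `current_mA`, `level_index` and
#' `repeat_index`, plus a `step_mA` attribute holding the nominal current
#' step between levels.
#'
#' @param entries A data frame with columns `dynamic_index`, `current_mA`,
#'   `level_index`, `repeat_index`.
#' @param step_mA Nominal current step between consecutive levels (mA).
#' @return A tibble of class `stim_schedule`.
#' @examples
#' plan_fine_schedule(12, n_levels = 4)
#' @export
stim_schedule <- function(entries, step_mA = NA_real_) {
  need <- c("dynamic_index", "current_mA", "level_index", "repeat_index")
  if (!all(need %in% names(entries))) {
    stop_format(paste("schedule needs columns:", paste(need, collapse = ", ")))
  }
  x <- as_tibble(entries)[need]
  x$dynamic_index <- as.integer(x$dynamic_index)
  x$level_index <- as.integer(x$level_index)
  x$repeat_index <- as.integer(x$repeat_index)
  x$current_mA <- as.numeric(x$current_mA)
  x <- dplyr::arrange(x, .data$dynamic_index)
  if (nrow(x) < 1L) stop_format("schedule must have at least one entry")
  if (!identical(x$dynamic_index, seq_len(nrow(x)) - 1L)) {
    stop_format("dynamic_index must be dense and 0-based (0, 1, 2, ...)")
  }
  if (any(x$current_mA < 0)) stop_format("currents must be non-negative")
  bad <- dplyr::group_by(x, .data$level_index) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$current_mA) == 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    stop_consistency(sprintf(
      "current varies within level(s): %s",
      paste(bad$level_index, collapse = ", ")))
  }
  structure(x, step_mA = as.numeric(step_mA),
            class = c("stim_schedule", class(x)))
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d dynamics, %d levels, step %.3g mA\n",
              nrow(x), dplyr::n_distinct(x$level_index),
              attr(x, "step_mA")))
  NextMethod()
}

#' @rdname stim_schedule
#' @param schedule A `stim_schedule`.
#' @return `schedule_step()` returns the nominal step in mA; if the attribute
#'   is missing it is inferred as the median absolute difference between
#'   consecutive level currents.
#' @export
schedule_step <- function(schedule) {
  s <- attr(schedule, "step_mA")
  if (!is.null(s) && is.finite(s)) return(s)
  lv <- dplyr::distinct(as_tibble(schedule), .data$level_index, .data$current_mA)
  if (nrow(lv) < 2L) return(NA_real_)
  stats::median(abs(diff(lv$current_mA[order(lv$level_index)])))
}

#' Read and write stimulation schedule CSV
#'
#' CSV dialect: comma separated, dot decimal, mandatory header with columns
#' `dynamic_index,current_mA,level_index,repeat_index`. The nominal step is
#' inferred from the level currents on load.
#'
#' @param path Path to a CSV file.
#' @return `load_schedule()` returns a [stim_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
load_schedule <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sched <- stim_schedule(x)
  attr(sched, "step_mA") <- schedule_step(sched)
  sched
}

#' @rdname load_schedule
#' @param schedule A [stim_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Plan a coarse-grain ascending current ramp
#'
#' The coarse scan ramps the stimulation current up, one dynamic per current
#' level, until clear contrast appears between stimulated and non-stimulated
#' muscle. Typical steps are 0.1-0.5 mA; steps outside that range are allowed
#' but flagged with a warning.
#'
#' @param start_mA Current of the first dynamic (mA).
#' @param step_mA Current increment per dynamic (mA).
#' @param n_dynamics Number of dynamics (= number of levels).
#' @return A [stim_schedule()] with one repeat per level.
#' @examples
#' plan_coarse_schedule(8, 0.1, 60)
#' @export
plan_coarse_schedule <- function(start_mA, step_mA, n_dynamics) {
  if (step_mA <= 0) stop_parameter("`step_mA` must be positive")
  if (n_dynamics < 1L) stop_parameter("`n_dynamics` must be at least 1")
  if (step_mA < 0.1 || step_mA > 0.5) {
    rlang::warn(sprintf(
      "coarse ramp step %.3g mA is outside the usual 0.1-0.5 mA range", step_mA),
      class = "mumri_parameter_warning")
  }
  idx <- seq_len(n_dynamics) - 1L
  stim_schedule(
    tibble(dynamic_index = idx,
           current_mA = start_mA + step_mA * idx,
           level_index = idx,
           repeat_index = 0L),
    step_mA = step_mA)
}

#' Plan a fine-grain descending staircase
#'
#' The fine scan starts at `i_max_mA` (five coarse steps above the inflection
#' point) and descends in small steps, each current level held for several
#' consecutive dynamics so that probabilistic firing near a unit's threshold
#' is observed as alternation. The defaults (0.01 mA steps, 5 repeats per
#' level) match the published acquisition.
#'
#' @param i_max_mA Starting (highest) current in mA.
#' @param step_mA Current decrement between levels; default 0.01 mA.
#' @param repeats Consecutive dynamics per level; default 5.
#' @param n_levels Number of descending levels.
#' @return A [stim_schedule()] with `n_levels * repeats` dynamics.
#' @examples
#' sched <- plan_fine_schedule(12.0, n_levels = 216)
#' nrow(sched)          # 1080 dynamics
#' min(sched$current_mA) # 9.85 mA
#' @export
plan_fine_schedule <- function(i_max_mA, step_mA = 0.01, repeats = 5L,
                               n_levels) {
  if (step_mA <= 0) stop_parameter("`step_mA` must be positive")
  if (repeats < 1L) stop_parameter("`repeats` must be at least 1")
  if (n_levels < 1L) stop_parameter("`n_levels` must be at least 1")
  currents <- i_max_mA - step_mA * (seq_len(n_levels) - 1L)
  if (any(currents <= 0)) {
    stop_parameter("staircase reaches a non-positive current; reduce `n_levels`")
  }
  lvl <- rep(seq_len(n_levels) - 1L, each = repeats)
  stim_schedule(
    tibble(dynamic_index = seq_along(lvl) - 1L,
           current_mA = rep(currents, each = repeats),
           level_index = lvl,
           repeat_index = rep(seq_len(repeats) - 1L, times = n_levels)),
    step_mA = step_mA)
}
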