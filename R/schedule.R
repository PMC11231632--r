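#' Experimental phase schedule
#'
#' Defines the three-phase lysimeter protocol: a well-watered pre-treatment
#' with nightly irrigation to pot capacity, a drought phase with irrigation
#' withheld, and a rewatering phase with nightly irrigation restored. The
#' drought phase ends early for an individual plant once its pre-dawn soil
#' water content falls below `drought_stop_swc` percent, after which nightly
#' refill resumes for that plant.
#'
#' @param pre_days,drought_days,rewater_days Number of days in each phase
#'   (each at least 1).
#' @param sampling_interval Load-cell sampling interval in minutes; must
#'   divide 1440. The default 3 min gives 480 samples per plant per day.
#' @param drought_stop_swc Per-plant drought termination threshold, percent
#'   of pot-capacity soil water content, strictly between 0 and 100.
#' @return An object of class `phase_schedule`: a list with the validated
#'   fields plus `total_days` and `samples_per_day`.
#' @examples
#' phase_schedule(9, 11, 9)     # 29-day screening protocol
#' phase_schedule(11, 15, 29)   # 55-day replicated protocol
#' @export
phase_schedule <- function(pre_days, drought_days, rewater_days,
                           sampling_interval = 3, drought_stop_swc = 15) {
  stopifnot(
    length(pre_days) == 1, length(drought_days) == 1, length(rewater_days) == 1,
    pre_days >= 1, drought_days >= 1, rewater_days >= 1,
    pre_days == as.integer(pre_days), drought_days == as.integer(drought_days),
    rewater_days == as.integer(rewater_days)
  )
  if (sampling_interval <= 0 || 1440 %% sampling_interval != 0) {
    stop("`sampling_interval` must be a positive divisor of 1440 minutes")
  }
  if (drought_stop_swc <= 0 || drought_stop_swc >= 100) {
    stop("`drought_stop_swc` must lie strictly between 0 and 100")
  }
  out <- list(
    pre_days = as.integer(pre_days),
    drought_days = as.integer(drought_days),
    rewater_days = as.integer(rewater_days),
    sampling_interval = sampling_interval,
    drought_stop_swc = drought_stop_swc,
    total_days = as.integer(pre_days + drought_days + rewater_days),
    samples_per_day = as.integer(1440 / sampling_interval)
  )
  class(out) <- "phase_schedule"
  out
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf(
    "<phase_schedule> pre %d d | drought %d d (stop < %g%% SWC) | rewater %d d; %d samples/day\n",
    x$pre_days, x$drought_days, x$drought_stop_swc, x$rewater_days,
    x$samples_per_day
  ))
  invisible(x)
}

#' Phase label for each experiment day
#'
#' @param schedule A [phase_schedule()].
#' @param day Integer day index (1-based) or vector thereof.
#' @return Character vector with values `"pre"`, `"drought"`, `"rewater"`.
#' @export
phase_of_day <- function(schedule, day) {
  stopifnot(inherits(schedule, "phase_schedule"))
  out <- rep(NA_character_, length(day))
  out[day <= schedule$pre_days] <- "pre"
  dr <- day > schedule$pre_days & day <= schedule$pre_days + schedule$drought_days
  out[dr] <- "drought"
  out[day > schedule$pre_days + schedule$drought_days &
        day <= schedule$total_days] <- "rewater"
  out
}

#' Day indices belonging to one phase
#'
#' @inheritParams phase_of_day
#' @param phase One of `"pre"`, `"drought"`, `"rewater"`.
#' @return Integer vector of day indices.
#' @export
phase_days <- function(schedule, phase = c("pre", "drought", "rewater")) {
  phase <- match.arg(phase)
  p <- schedule$pre_days
  d <- schedule$drought_days
  switch(phase,
    pre = seq_len(p),
    drought = p + seq_len(d),
    rewater = p + d + seq_len(schedule$rewater_days)
  )
}
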