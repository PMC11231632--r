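#' Detect irrigation events from weight jumps
#'
#' Finds between-sample weight increases larger than `jump_threshold` and
#' merges runs of consecutive jump samples into single events (an event's
#' volume is the total observed increase across the run). Used when a raw
#' export carries no irrigation log; simulated series carry a log and the
#' detector is validated against it.
#'
#' @param series A `plant_series` or a data frame with `time_min` and
#'   `weight_g` columns (at least 2 rows, strictly increasing timestamps).
#' @param jump_threshold Minimum between-sample increase (g) to call a jump.
#' @return Tibble with `time_min` (last sample before the increase),
#'   `volume_g`, and `detected = TRUE`.
#' @export
detect_irrigation_events <- function(series, jump_threshold = 20) {
  d <- if (inherits(series, "plant_series")) series$data else series
  stopifnot(nrow(d) >= 2, jump_threshold > 0)
  if (any(diff(d$time_min) <= 0)) stop("timestamps must be strictly increasing")
  dw <- diff(d$weight_g)
  jump <- !is.na(dw) & dw > jump_threshold
  if (!any(jump)) {
    return(tibble::tibble(time_min = numeric(0), volume_g = numeric(0),
                          detected = logical(0)))
  }
  r <- rle(jump)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ji <- which(r$values)
  tibble::tibble(
    time_min = d$time_min[starts[ji]],
    volume_g = vapply(ji, function(k) sum(dw[starts[k]:ends[k]]), numeric(1)),
    detected = TRUE
  )
}
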