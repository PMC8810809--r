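#' Postprandial glucose and mbNIR time series for one person
#'
#' Simulates a monitoring session: glucose sits at `baseline` and each meal
#' event adds a rise that decays exponentially back to baseline (a
#' first-order stand-in for the insulin response). Event magnitudes default
#' to +20 mg/dL for `"cake"` and a uniform draw in [25, 30] mg/dL for
#' `"noodle"`; the rise ramps up linearly over `rise_minutes` and then
#' decays at rate `decay_rate`. The three noiseless NIR channels are derived
#' from the person's transmittance curve at every time point.
#'
#' @param person One-row tibble from [generate_population()].
#' @param events Data frame with columns `time` (minutes, sorted
#'   increasing) and `event_type` (`"cake"` or `"noodle"`); may be empty.
#' @param duration Session length in minutes.
#' @param config The [optical_config()] used for `person`.
#' @param baseline Baseline glucose (mg/dL).
#' @param decay_rate Exponential decay rate of each event's rise (1/min);
#'   0 makes rises permanent.
#' @param rise_minutes Minutes over which an event's rise ramps in.
#' @param step Sampling interval (minutes).
#' @param event_magnitudes Named list mapping event types to either a single
#'   rise (mg/dL) or a `c(min, max)` range sampled uniformly.
#'
#' @return A tibble `time_min, glucose, nir_1, nir_2, nir_3`.
#' @export
#'
#' @examples
#' cfg <- optical_config(seed = 4)
#' p <- generate_population(1, cfg)
#' ev <- data.frame(time = 60, event_type = "cake")
#' ts <- meal_timeseries(p, ev, duration = 180, config = cfg)
#' max(ts$glucose) - ts$glucose[1]
meal_timeseries <- function(person, events, duration,
                            config = optical_config(),
                            baseline = 95, decay_rate = 0.02,
                            rise_minutes = 20, step = 1,
                            event_magnitudes = list(
                              cake = 20, noodle = c(25, 30)
                            )) {
  stopifnot(inherits(config, "optical_config"), nrow(person) == 1L)
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    if (!all(c("time", "event_type") %in% names(events))) {
      abort("`events` needs columns `time` and `event_type`.")
    }
    if (is.unsorted(events$time)) abort("`events` must be sorted by time.")
    unknown <- setdiff(unique(events$event_type), names(event_magnitudes))
    if (length(unknown) > 0) {
      abort(paste0("Unknown event type(s): ", paste(unknown, collapse = ", ")))
    }
  }

  set.seed(config$seed + 2000003L)
  time_min <- seq(0, duration, by = step)
  glucose <- rep(baseline, length(time_min))
  for (i in seq_len(nrow(events))) {
    mag <- event_magnitudes[[events$event_type[i]]]
    rise <- if (length(mag) == 2L) runif(1, mag[1], mag[2]) else mag[1]
    dt <- time_min - events$time[i]
    ramp <- pmin(pmax(dt / rise_minutes, 0), 1)
    resp <- rise * ramp * exp(-decay_rate * pmax(dt - rise_minutes, 0))
    glucose <- glucose + resp
  }

  nir <- transmittance_all_bands(person, glucose, config)
  bind_cols(tibble(time_min = time_min, glucose = glucose), as_tibble(nir))
}

#' Write a monitoring time series as CSV
#'
#' @param ts Tibble from [meal_timeseries()] (columns `time_min, glucose,
#'   nir_1, nir_2, nir_3`, plus any prediction columns).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  write.csv(ts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
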