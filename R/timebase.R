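# Event-anchored representation of raw measurement streams: a fully imputed
# per-minute grid for the final hour, hourly aggregates for the 12-hour
# lookback, and a single multivariable representative per channel.
#
# Grid convention: the minute grid runs t = -59 ... 0 inclusive (60 slots).
# Slot t = 0 holds the multivariable representative and is excluded from the
# time-series feature block, which therefore contributes 59 minute-level
# elements per channel. Hourly bin h (h = 1 most recent) covers
# t in [-60h, -60(h-1)-1]; the most recent bin overlaps the minute-resolution
# hour, which is tolerated and documented.

#' Two-resolution windowing specification
#'
#' @param minute_window_min length of the high-resolution window (minutes).
#' @param minute_resolution_min grid step inside the minute window (minutes).
#' @param hour_window_h length of the low-resolution lookback (hours).
#' @param hour_resolution_min width of each low-resolution bin (minutes).
#' @param hourly_includes_minute_window if `TRUE` (default) the hourly
#'   lookback ends at t = -1 and its most recent bin overlaps the
#'   minute-resolution hour; if `FALSE` the hourly bins start where the
#'   minute window ends.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(minute_window_min = 60, minute_resolution_min = 1,
                        hour_window_h = 12, hour_resolution_min = 60,
                        hourly_includes_minute_window = TRUE) {
  if (minute_window_min %% minute_resolution_min != 0)
    stop("minute_window_min must be divisible by minute_resolution_min")
  if ((hour_window_h * 60) %% hour_resolution_min != 0)
    stop("hour window must be divisible by hour_resolution_min")
  if (minute_window_min > hour_window_h * 60)
    stop("minute window cannot exceed the hourly lookback")
  structure(list(minute_window_min = minute_window_min,
                 minute_resolution_min = minute_resolution_min,
                 hour_window_h = hour_window_h,
                 hour_resolution_min = hour_resolution_min,
                 hourly_includes_minute_window =
                   isTRUE(hourly_includes_minute_window)),
            class = "window_spec")
}

# start of the hourly lookback relative to the event: 0 when the hourly
# window overlaps the minute-resolution hour, minute_window otherwise
.hourly_offset <- function(spec) {
  if (spec$hourly_includes_minute_window) 0L else spec$minute_window_min
}

#' Normal-value table
#'
#' Predefined per-channel values imputed when a grid slot has no prior
#' observation to carry forward. The defaults are broadly normal pediatric
#' values and are implementation defaults, overridable per channel, e.g.
#' `normal_values(hr = 90)`.
#'
#' @param ... named channel overrides.
#' @return named numeric vector.
#' @export
normal_values <- function(...) {
  defaults <- c(hr = 100, spo2 = 0.98, sbp = 100, dbp = 60,
                nibp_sbp = 100, nibp_dbp = 60, hgb = 12)
  o <- c(...)
  if (length(o)) {
    if (is.null(names(o)) || any(names(o) == ""))
      stop("normal-value overrides must be named")
    defaults[names(o)] <- o
  }
  if (any(defaults <= 0)) stop("normal values must be within physiologic bounds (> 0)")
  defaults
}

.normal_for <- function(normal, channel) {
  if (!channel %in% names(normal))
    stop("no normal value configured for channel: ", channel)
  normal[[channel]]
}

#' Re-express a measurement stream relative to the reference event
#'
#' Timestamps become minutes relative to the event (<= 0 before it);
#' observations after the reference are dropped, so no future value can leak
#' into any downstream representation.
#'
#' @param series data frame with `timestamp_min`, `value`.
#' @param reference_time_min the event time in record minutes.
#' @return data frame with `rel_time_min` (<= 0, strictly increasing), `value`.
#' @export
align_to_reference <- function(series, reference_time_min) {
  stopifnot(is.data.frame(series), all(c("timestamp_min", "value") %in% names(series)))
  if (nrow(series) > 0 && reference_time_min < min(series$timestamp_min)) {
    warning("reference precedes first observation; returning empty series")
    return(data.frame(rel_time_min = integer(0), value = numeric(0)))
  }
  rel <- series$timestamp_min - reference_time_min
  keep <- rel <= 0
  data.frame(rel_time_min = rel[keep], value = series$value[keep])
}

# Carry-forward of an aligned series onto arbitrary grid times. Lookback is
# unlimited within the record; the normal value fills slots with no prior
# observation. Flags record provenance per slot.
.carry_forward <- function(aligned, times, normal_value) {
  if (nrow(aligned) == 0) {
    return(list(values = rep(normal_value, length(times)),
                flags = rep("normal", length(times))))
  }
  idx <- findInterval(times, aligned$rel_time_min)
  values <- ifelse(idx == 0, normal_value, aligned$value[pmax(idx, 1L)])
  flags <- rep("carried", length(times))
  flags[idx == 0] <- "normal"
  exact <- idx > 0 & aligned$rel_time_min[pmax(idx, 1L)] == times
  flags[exact] <- "observed"
  list(values = values, flags = flags)
}

#' Impute an aligned series onto the event-anchored minute grid
#'
#' For each grid time t in `-(W-1) ... 0` the value is the last observation at
#' time <= t (carry-forward, unlimited lookback), or the channel's normal
#' value when no prior observation exists. Provenance flags
#' (`observed` / `carried` / `normal`) are recorded per slot. Slot t = 0 is
#' the multivariable-representative slot.
#'
#' @param aligned output of [align_to_reference()].
#' @param spec a [window_spec()].
#' @param normal a [normal_values()] table.
#' @param channel channel name (used for the normal-value lookup).
#' @return object of class `grid_series`: `channel`, `rel_times`, `values`,
#'   `flags`.
#' @export
to_minute_grid <- function(aligned, spec = window_spec(), normal = normal_values(),
                           channel) {
  nv <- .normal_for(normal, channel)
  times <- seq(-(spec$minute_window_min - spec$minute_resolution_min), 0,
               by = spec$minute_resolution_min)
  cf <- .carry_forward(aligned, times, nv)
  structure(list(channel = channel, rel_times = times, values = cf$values,
                 flags = cf$flags),
            class = "grid_series")
}

#' Hourly aggregates over the 12-hour lookback
#'
#' Bin h (h = 1 most recent) averages the carried-forward minute grid over
#' t in `[-60h, -60(h-1)-1]`; `coverage` counts native (non-imputed)
#' observations in each bin. Bins with zero native observations take the mean
#' of the imputed grid, which may be the normal value.
#'
#' @inheritParams to_minute_grid
#' @return object of class `hourly_series`: `channel`, `hour_index` (1..H),
#'   `values`, `coverage`.
#' @export
hourly_aggregate <- function(aligned, spec = window_spec(), normal = normal_values(),
                             channel) {
  nv <- .normal_for(normal, channel)
  res <- spec$hour_resolution_min
  total <- spec$hour_window_h * 60
  off <- .hourly_offset(spec)
  times <- seq(-(total + off), -(1 + off))
  cf <- .carry_forward(aligned, times, nv)
  bin <- ceiling(-(times + off) / res)    # 1 = most recent
  h <- seq_len(total / res)
  values <- as.numeric(tapply(cf$values, bin, mean)[as.character(h)])
  native <- aligned$rel_time_min[aligned$rel_time_min >= -(total + off) &
                                   aligned$rel_time_min <= -(1 + off)]
  coverage <- as.integer(tabulate(ceiling(-(native + off) / res), nbins = length(h)))
  structure(list(channel = channel, hour_index = h, values = values,
                 coverage = coverage),
            class = "hourly_series")
}

#' Multivariable representative of a channel
#'
#' The latest observation taken at or before the reference event; the
#' channel's predefined normal value (flagged) when the aligned series is
#' empty.
#'
#' @inheritParams to_minute_grid
#' @return list with `value` and `provenance` (`"observed"` or `"normal"`).
#' @export
multivariable_representative <- function(aligned, normal = normal_values(), channel) {
  if (nrow(aligned) == 0)
    return(list(value = .normal_for(normal, channel), provenance = "normal"))
  list(value = aligned$value[which.max(aligned$rel_time_min)],
       provenance = "observed")
}

#' @export
print.grid_series <- function(x, ...) {
  cat(sprintf("<grid_series> %s: %d slots t = %d..%d (%d observed, %d carried, %d normal)\n",
              x$channel, length(x$values), min(x$rel_times), max(x$rel_times),
              sum(x$flags == "observed"), sum(x$flags == "carried"),
              sum(x$flags == "normal")))
  invisible(x)
}
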