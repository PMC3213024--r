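# Synthetic PICU cohort: labelled arrest/control episodes whose vital signs
# follow a progressive-shock trajectory (slow insidious drift over hours, with
# an accelerated deterioration inside a short terminal window before the
# event) on top of stationary AR(1) monitor noise.

#' Channels emitted at per-minute resolution by the simulator
#' @keywords internal
.minute_channels <- c("hr", "spo2", "sbp", "dbp")

#' All continuous channels (per-minute plus irregularly sampled noninvasive BP)
#' @keywords internal
.continuous_channels <- c("hr", "spo2", "sbp", "dbp", "nibp_sbp", "nibp_dbp")

#' Shock-trajectory simulation parameters
#'
#' Parameters of the progressive-shock generative model. Each monitored
#' channel fluctuates around a pediatric baseline with stationary AR(1)
#' noise. Arrest cases additionally drift from a per-case random shock onset
#' (`slow_drift`, units/hour) and accelerate inside the terminal window
#' (`terminal_drift`, units/minute): blood pressures and oxygen saturation
#' fall while heart rate rises. Noninvasive blood pressure is a sparse copy
#' of the arterial pressure plus independent measurement noise, sampled at a
#' per-case fixed interval drawn from `nibp_interval_choices`.
#'
#' Drift magnitudes are model assumptions chosen to be physiologically
#' plausible for compensated-to-uncompensated pediatric shock; they are
#' documented defaults, not literature estimates.
#'
#' @param baseline named numeric, per-channel baseline mean: `hr` (bpm),
#'   `sbp`/`dbp` (mmHg), `spo2` (fraction in (0,1]).
#' @param noise_sd named numeric, stationary noise SD per channel (same units).
#' @param ar1 lag-1 autocorrelation of the noise process, in `[0, 1)`.
#' @param shock_onset_hours length-2 numeric `(lo, hi)`: the per-case shock
#'   onset is drawn Uniform(lo, hi) hours before the event. Bounds must lie in
#'   `(0, 12]`.
#' @param slow_drift named numeric, drift in units/hour applied from shock
#'   onset (arrest cases only).
#' @param terminal_window_min length of the terminal acceleration window in
#'   minutes (at most 60).
#' @param terminal_drift named numeric, additional drift in units/minute
#'   accumulated inside the terminal window.
#' @param nibp_interval_choices integer set of candidate noninvasive-BP
#'   sampling intervals (minutes); one is drawn per case.
#' @param nibp_noise_sd SD (mmHg) of independent cuff noise added to the
#'   arterial pressure when forming the noninvasive channels.
#' @param dropout_prob per-minute probability that a continuous observation is
#'   missing, in `[0, 1)`.
#' @param hgb_mean,hgb_sd mean and SD (g/dL) of the single hemoglobin lab.
#' @param mv_matched logical; if `TRUE`, each arrest case's baseline is
#'   shifted down by its own total expected drift at the event, so the
#'   *expected value at the reference time* equals the control baseline.
#'   This designed experimental mode removes last-value (multivariable)
#'   separation while preserving trajectory (trend) separation.
#' @return an object of class `shock_params`.
#' @export
shock_params <- function(baseline = c(hr = 120, sbp = 95, dbp = 55, spo2 = 0.97),
                         noise_sd = c(hr = 4, sbp = 3, dbp = 2.5, spo2 = 0.01),
                         ar1 = 0.8,
                         shock_onset_hours = c(2, 8),
                         slow_drift = c(hr = 4, sbp = -3, dbp = -2, spo2 = -0.002),
                         terminal_window_min = 15,
                         terminal_drift = c(hr = 1.5, sbp = -1.5, dbp = -1, spo2 = -0.004),
                         nibp_interval_choices = c(5, 15, 30, 60),
                         nibp_noise_sd = 4,
                         dropout_prob = 0.03,
                         hgb_mean = 11.5,
                         hgb_sd = 1.8,
                         mv_matched = FALSE) {
  for (nm in .minute_channels) {
    if (!nm %in% names(baseline)) stop("baseline missing channel: ", nm)
    if (!nm %in% names(noise_sd)) stop("noise_sd missing channel: ", nm)
    if (!nm %in% names(slow_drift)) stop("slow_drift missing channel: ", nm)
    if (!nm %in% names(terminal_drift)) stop("terminal_drift missing channel: ", nm)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  if (length(shock_onset_hours) != 2 || any(shock_onset_hours <= 0) ||
      any(shock_onset_hours > 12) || shock_onset_hours[1] > shock_onset_hours[2])
    stop("shock_onset_hours must be bounds (lo <= hi) within (0, 12]")
  if (terminal_window_min > 60 || terminal_window_min < 0)
    stop("terminal_window_min must be in [0, 60]")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)")
  if (hgb_sd < 0 || nibp_noise_sd < 0) stop("lab/cuff noise SDs must be >= 0")
  structure(list(baseline = baseline, noise_sd = noise_sd, ar1 = ar1,
                 shock_onset_hours = shock_onset_hours, slow_drift = slow_drift,
                 terminal_window_min = terminal_window_min,
                 terminal_drift = terminal_drift,
                 nibp_interval_choices = as.integer(nibp_interval_choices),
                 nibp_noise_sd = nibp_noise_sd, dropout_prob = dropout_prob,
                 hgb_mean = hgb_mean, hgb_sd = hgb_sd, mv_matched = mv_matched),
            class = "shock_params")
}

#' Cohort simulation configuration
#'
#' @param n_arrest,n_control numbers of arrest and control cases (>= 1 each).
#'   Balanced 1:1 cohorts are the default study design; the class ratio is
#'   config-driven for prevalence-realistic experiments.
#' @param record_hours hours of monitoring to emit per case; must be >= 13 so
#'   the full 12-hour lookback plus the final hour is always covered.
#' @param seed integer master seed; per-case sub-seeds are derived
#'   deterministically from it.
#' @param params a [shock_params()] object.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_arrest, n_control, record_hours = 14, seed = 1,
                          params = shock_params()) {
  if (n_arrest < 1 || n_control < 1) stop("n_arrest and n_control must be >= 1")
  if (record_hours < 13) stop("insufficient pre-event coverage: record_hours must be >= 13")
  stopifnot(inherits(params, "shock_params"))
  structure(list(n_arrest = as.integer(n_arrest), n_control = as.integer(n_control),
                 record_hours = record_hours, seed = as.integer(seed),
                 params = params),
            class = "cohort_config")
}

# Deterministic per-case sub-seed: stable integer hash of (seed, index),
# kept strictly below 2^31. Exact in double arithmetic (< 2^53).
.case_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + as.double(i) * 1299721) %% 2147483629)
}

# clip to physiologic hard bounds; returns value and count of clipped points
.clip_channel <- function(v, channel) {
  lo <- switch(channel, spo2 = 0.01, 1)
  hi <- switch(channel, spo2 = 1, Inf)
  clipped <- sum(v < lo | v > hi)
  list(value = pmin(pmax(v, lo), hi), clipped = clipped)
}

#' Simulate one monitored episode
#'
#' Generates per-minute heart rate, oxygen saturation and arterial
#' systolic/diastolic pressure channels (AR(1) noise around baseline, with
#' progressive-shock drift for arrest cases), an irregularly sampled
#' noninvasive blood-pressure channel pair, one pre-window hemoglobin lab,
#' demographics, and a reference event time: the end of the record for arrest
#' cases, or a random interior time with at least 13 h of prior monitoring for
#' controls, so both classes are windowed identically.
#'
#' Timestamps are integer minutes `0 ... record_hours*60`. Per-minute values
#' may be missing with probability `dropout_prob`. Values are clipped to
#' physiologic hard bounds (HR and pressures > 0, SpO2 in (0,1]); clip counts
#' are kept in the returned record (`$clipped`).
#'
#' @param label `"arrest"` or `"control"`.
#' @param params a [shock_params()] object.
#' @param record_hours hours of monitoring (>= 13).
#' @param seed integer seed; identical inputs yield identical records.
#' @return a `case_record`: list with `case_id`, `label`,
#'   `reference_time_min`, `age_months`, `weight_kg`, `hgb_g_dl`,
#'   `hgb_time_min`, `channels` (named list of data frames with
#'   `timestamp_min`, `value`), and `clipped`.
#' @export
simulate_case <- function(label, params = shock_params(), record_hours = 14,
                          seed = 1) {
  label <- match.arg(label, c("arrest", "control"))
  if (record_hours < 13) stop("insufficient pre-event coverage: record_hours must be >= 13")
  withr::with_seed(as.integer(seed), {
    t_end <- round(record_hours * 60)
    ts <- 0:t_end
    n <- length(ts)
    is_arrest <- label == "arrest"
    if (is_arrest) {
      ref <- t_end
      onset_h <- stats::runif(1, params$shock_onset_hours[1], params$shock_onset_hours[2])
    } else {
      ref <- if (t_end == 780L) 780L else sample(780:t_end, 1)
      onset_h <- NA_real_
    }

    raw <- list()           # pre-dropout minute series, reused for NIBP
    channels <- list()
    clipped <- integer(0)
    for (ch in .minute_channels) {
      drift <- numeric(n)
      base <- params$baseline[[ch]]
      if (is_arrest) {
        hrs_before <- (ref - ts) / 60
        drift <- params$slow_drift[[ch]] * pmax(0, onset_h - hrs_before)
        mins_before <- ref - ts
        in_term <- mins_before < params$terminal_window_min & mins_before >= 0
        drift[in_term] <- drift[in_term] +
          params$terminal_drift[[ch]] * (params$terminal_window_min - mins_before[in_term])
        if (isTRUE(params$mv_matched)) {
          base <- base - (params$slow_drift[[ch]] * onset_h +
                          params$terminal_drift[[ch]] * params$terminal_window_min)
        }
      }
      sd_ch <- params$noise_sd[[ch]]
      init <- stats::rnorm(1, 0, sd_ch)
      innov <- stats::rnorm(n, 0, sd_ch * sqrt(1 - params$ar1^2))
      noise <- as.numeric(stats::filter(innov, params$ar1, method = "recursive",
                                        init = init))
      cl <- .clip_channel(base + drift + noise, ch)
      raw[[ch]] <- cl$value
      clipped[[ch]] <- cl$clipped
      keep <- if (params$dropout_prob > 0) stats::runif(n) >= params$dropout_prob else rep(TRUE, n)
      channels[[ch]] <- data.frame(timestamp_min = ts[keep], value = cl$value[keep])
    }

    # noninvasive BP: sparse copy of arterial pressure + independent cuff noise
    interval <- if (length(params$nibp_interval_choices) == 1L)
      params$nibp_interval_choices else sample(params$nibp_interval_choices, 1)
    offset <- if (interval > 1L) sample(0:(interval - 1L), 1) else 0L
    nibp_ts <- seq(offset, t_end, by = interval)
    idx <- match(nibp_ts, ts)
    for (pair in c(sbp = "nibp_sbp", dbp = "nibp_dbp")) {
      src <- names(which(c(sbp = "nibp_sbp", dbp = "nibp_dbp") == pair))
      cl <- .clip_channel(raw[[src]][idx] + stats::rnorm(length(idx), 0, params$nibp_noise_sd),
                          src)
      clipped[[pair]] <- cl$clipped
      channels[[pair]] <- data.frame(timestamp_min = nibp_ts, value = cl$value)
    }

    hgb_time <- sample(0:min(30L, t_end), 1)
    hgb <- max(3, stats::rnorm(1, params$hgb_mean, params$hgb_sd))
    age_months <- sample(1:216, 1)
    weight_kg <- max(2, round(3 + 0.25 * age_months + stats::rnorm(1, 0, 2), 1))

    structure(list(case_id = sprintf("%s_seed%d", label, as.integer(seed)),
                   label = label,
                   reference_time_min = as.integer(ref),
                   age_months = as.integer(age_months),
                   weight_kg = weight_kg,
                   hgb_g_dl = hgb,
                   hgb_time_min = as.integer(hgb_time),
                   channels = channels,
                   clipped = clipped),
              class = "case_record")
  })
}

#' Simulate a labelled cohort
#'
#' Each case is simulated with an independent sub-seed derived
#' deterministically from `config$seed`, so two runs with the same
#' configuration produce identical cohorts. Arrest cases come first; case ids
#' are `arrest_###` / `control_###`.
#'
#' @param config a [cohort_config()] object.
#' @return list of `case_record`, class `arrest_cohort`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- c(rep("arrest", config$n_arrest), rep("control", config$n_control))
  cases <- vector("list", length(labels))
  n_by <- c(arrest = 0L, control = 0L)
  for (i in seq_along(labels)) {
    cs <- simulate_case(labels[i], config$params, config$record_hours,
                        .case_seed(config$seed, i))
    n_by[[labels[i]]] <- n_by[[labels[i]]] + 1L
    cs$case_id <- sprintf("%s_%03d", labels[i], n_by[[labels[i]]])
    cases[[i]] <- cs
  }
  structure(cases, class = "arrest_cohort")
}

.cases_columns <- c("case_id", "label", "reference_time_min", "age_months",
                    "weight_kg", "hgb_g_dl", "hgb_time_min")

#' Write / read a cohort as CSV
#'
#' Serializes a cohort to two plain-text files under `path`:
#' `cases.csv` (one row per case: id, label, reference time, demographics,
#' hemoglobin lab, and per-channel clip counts) and `measurements.csv`
#' (one row per observation: `case_id`, `channel`, `timestamp_min`, `value`).
#' Values are written with 17 significant digits so the round trip is
#' lossless: `read_cohort(write_cohort(x)) == x`.
#'
#' @param cases an `arrest_cohort` (or plain list of `case_record`).
#' @param path directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cases, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cases, function(cs) {
    row <- data.frame(case_id = cs$case_id, label = cs$label,
                      reference_time_min = cs$reference_time_min,
                      age_months = cs$age_months,
                      weight_kg = .num17(cs$weight_kg),
                      hgb_g_dl = .num17(cs$hgb_g_dl),
                      hgb_time_min = cs$hgb_time_min)
    for (ch in names(cs$clipped)) row[[paste0("clipped_", ch)]] <- cs$clipped[[ch]]
    row
  }))
  meas <- data.table::rbindlist(lapply(cases, function(cs) {
    data.table::rbindlist(lapply(names(cs$channels), function(ch) {
      data.table::data.table(case_id = cs$case_id, channel = ch,
                             timestamp_min = cs$channels[[ch]]$timestamp_min,
                             value = .num17(cs$channels[[ch]]$value))
    }))
  }))
  data.table::fwrite(meta, file.path(path, "cases.csv"))
  data.table::fwrite(meas, file.path(path, "measurements.csv"))
  invisible(path)
}

# full-precision decimal representation (round-trips IEEE doubles)
.num17 <- function(x) sprintf("%.17g", x)

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  meta_f <- file.path(path, "cases.csv")
  meas_f <- file.path(path, "measurements.csv")
  if (!file.exists(meta_f) || !file.exists(meas_f))
    stop("cohort directory must contain cases.csv and measurements.csv")
  meta <- data.table::fread(meta_f, colClasses = list(character = c("case_id", "label")))
  meas <- data.table::fread(meas_f,
                            colClasses = list(character = c("case_id", "channel", "value")))
  missing_cols <- setdiff(.cases_columns, names(meta))
  if (length(missing_cols))
    stop("cases.csv missing column(s): ", paste(missing_cols, collapse = ", "))
  vals <- suppressWarnings(as.numeric(meas$value))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("measurements.csv row ", bad, ": non-numeric value ",
         dQuote(meas$value[bad]), " in column 'value'")
  }
  meas$value <- vals
  clip_cols <- grep("^clipped_", names(meta), value = TRUE)
  cases <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    rows <- meas[meas$case_id == m$case_id, ]
    channels <- list()
    for (ch in intersect(c(.continuous_channels, unique(rows$channel)), unique(rows$channel))) {
      sub <- rows[rows$channel == ch, ]
      channels[[ch]] <- data.frame(timestamp_min = as.integer(sub$timestamp_min),
                                   value = sub$value)
    }
    clipped <- as.integer(unlist(m[, clip_cols, with = FALSE]))
    names(clipped) <- sub("^clipped_", "", clip_cols)
    structure(list(case_id = m$case_id, label = m$label,
                   reference_time_min = as.integer(m$reference_time_min),
                   age_months = as.integer(m$age_months),
                   weight_kg = as.numeric(m$weight_kg),
                   hgb_g_dl = as.numeric(m$hgb_g_dl),
                   hgb_time_min = as.integer(m$hgb_time_min),
                   channels = channels, clipped = clipped),
              class = "case_record")
  })
  structure(cases, class = "arrest_cohort")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s (%s), reference t = %d min\n", x$case_id,
              x$label, x$reference_time_min))
  for (ch in names(x$channels))
    cat(sprintf("  %-9s %5d obs\n", ch, nrow(x$channels[[ch]])))
  invisible(x)
}

#' @export
print.arrest_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<arrest_cohort> %d cases (%d arrest / %d control)\n",
              length(x), sum(labs == "arrest"), sum(labs == "control")))
  invisible(x)
}
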