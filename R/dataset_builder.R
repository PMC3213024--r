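# Assembles class-tagged feature matrices from case records, instantiates
# the five modeling subsets, and performs the stratified 33% holdout
# partition.
#
# Feature accounting (asserted at build time) for C continuous channels,
# L latent channels and D demographics/labs:
#   |MV| = C + L + D          one multivariable representative per variable
#   |TS| = 71 C               59 minute slots (t = -59..-1) + 12 hourly bins
#   |CLIN| = 71 L             latent channels in the same TS format
#   |TREND| = 22 (C + L)      per-channel trend block

#' Feature-engineering configuration
#'
#' The default channel roster is heart rate, oxygen saturation, arterial
#' systolic/diastolic pressure and noninvasive systolic/diastolic pressure
#' (continuous); pulse pressure, mean arterial pressure, shock index and
#' oxygen-delivery index (clinical latents); and age, weight and hemoglobin
#' (demographics/labs).
#'
#' @param continuous continuous channel names present in each case record.
#' @param latents clinical latent channels to derive (subset of
#'   `c("pp","map","si","odi")`).
#' @param demographics scalar per-case variables for the MV block.
#' @param window a [window_spec()].
#' @param normal a [normal_values()] table.
#' @param trend_windows trend windows in minutes.
#' @param trend_channels channels receiving a trend block (default: all
#'   continuous channels plus all latents).
#' @return object of class `feature_config`.
#' @export
feature_config <- function(continuous = c("hr", "spo2", "sbp", "dbp",
                                          "nibp_sbp", "nibp_dbp"),
                           latents = c("pp", "map", "si", "odi"),
                           demographics = c("age_months", "weight_kg", "hgb"),
                           window = window_spec(),
                           normal = normal_values(),
                           trend_windows = c(5, 10, 15, 60),
                           trend_channels = c(continuous, latents)) {
  stopifnot(inherits(window, "window_spec"))
  if (length(latents) && !"sbp" %in% continuous)
    stop("latent channels require the arterial pressure channels in the roster")
  structure(list(continuous = continuous, latents = latents,
                 demographics = demographics, window = window, normal = normal,
                 trend_windows = trend_windows, trend_channels = trend_channels),
            class = "feature_config")
}

# grid_series constructed from already-carried values (internal fast path)
.grid_from <- function(channel, times, values, flags) {
  structure(list(channel = channel, rel_times = times, values = values,
                 flags = flags), class = "grid_series")
}

#' Build the tagged feature vector for one case
#'
#' Emits, per the configured roster: the MV block (multivariable
#' representatives of continuous channels, clinical-latent representatives,
#' labs and demographics), the TS block (59 minute slots plus 12 hourly bins
#' per continuous channel), the CLIN block (latent channels in the same
#' format) and the TREND block (22 trend features per raw and latent
#' channel). Column naming is deterministic: `hr__m59 ... hr__m1`,
#' `hr__h1 ... hr__h12`, `hr__mv`, `sbp__slope5`, `si__mean60`,
#' `hr__ratio5_60`, ...
#'
#' @param case a `case_record`.
#' @param config a [feature_config()].
#' @param blocks which blocks to compute (subset of MV/TS/CLIN/TREND).
#' @return named numeric vector with attribute `tags` (named character,
#'   one of `"MV"`, `"TS"`, `"CLIN"`, `"TREND"` per feature).
#' @export
build_feature_vector <- function(case, config = feature_config(),
                                 blocks = c("MV", "TS", "CLIN", "TREND")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  spec <- config$window
  normal <- config$normal
  ref <- case$reference_time_min
  missing_ch <- setdiff(config$continuous, names(case$channels))
  if (length(missing_ch))
    stop("unconfigured or absent channel(s) in case ", case$case_id, ": ",
         paste(missing_ch, collapse = ", "))

  aligned <- lapply(case$channels[config$continuous], align_to_reference, ref)

  need_hourly <- any(c("TS", "CLIN") %in% blocks)
  need_minute <- any(c("TS", "CLIN", "TREND") %in% blocks)
  hr_off <- .hourly_offset(spec)
  total_min <- spec$hour_window_h * 60 + hr_off
  full_times <- if (need_hourly) seq(-total_min, 0) else
    seq(-(spec$minute_window_min - 1), 0)
  n_minute <- spec$minute_window_min
  minute_idx <- (length(full_times) - n_minute + 1):length(full_times)

  grids <- NULL
  if (need_minute) {
    grids <- lapply(config$continuous, function(ch) {
      cf <- .carry_forward(aligned[[ch]], full_times, .normal_for(normal, ch))
      .grid_from(ch, full_times, cf$values, cf$flags)
    })
    names(grids) <- config$continuous
  }

  latents <- NULL
  if (length(config$latents) && (need_minute || "MV" %in% blocks)) {
    if (need_minute)
      latents <- derive_latent_channels(grids, case$hgb_g_dl)[config$latents]
  }

  values <- numeric(0)
  tags <- character(0)
  add <- function(v, tag) {
    values <<- c(values, v)
    tags <<- c(tags, rep(tag, length(v)))
  }

  mv_reps <- vapply(config$continuous, function(ch)
    multivariable_representative(aligned[[ch]], normal, ch)$value, numeric(1))

  if ("MV" %in% blocks) {
    mv <- mv_reps
    names(mv) <- paste0(config$continuous, "__mv")
    add(mv, "MV")
    if (length(config$latents)) {
      pp0 <- as.numeric(pulse_pressure(mv_reps[["sbp"]], mv_reps[["dbp"]]))
      lat_mv <- c(pp = pp0,
                  map = mean_arterial_pressure(mv_reps[["sbp"]], mv_reps[["dbp"]]),
                  si = as.numeric(suppressWarnings(
                    shock_index(mv_reps[["hr"]], mv_reps[["sbp"]]))),
                  odi = oxygen_delivery_index(mv_reps[["hr"]], pp0,
                                              mv_reps[["spo2"]], case$hgb_g_dl))
      lat_mv <- lat_mv[config$latents]
      names(lat_mv) <- paste0(config$latents, "__mv")
      add(lat_mv, "MV")
    }
    demo <- c(age_months = as.numeric(case$age_months),
              weight_kg = as.numeric(case$weight_kg),
              hgb = as.numeric(case$hgb_g_dl))
    add(demo[config$demographics], "MV")
  }

  ts_block_for <- function(grid, ch, tag) {
    minute_vals <- grid$values[minute_idx]
    mins <- minute_vals[-n_minute]                   # t = -59 ... -1
    names(mins) <- paste0(ch, "__m", (n_minute - 1):1)
    add(mins, tag)
    pre <- grid$rel_times <= -(1 + hr_off)
    bin <- ceiling(-(grid$rel_times[pre] + hr_off) / spec$hour_resolution_min)
    nb <- spec$hour_window_h * 60 / spec$hour_resolution_min
    hv <- as.numeric(tapply(grid$values[pre], bin, mean)[as.character(seq_len(nb))])
    names(hv) <- paste0(ch, "__h", seq_len(nb))
    add(hv, tag)
  }

  if ("TS" %in% blocks)
    for (ch in config$continuous) ts_block_for(grids[[ch]], ch, "TS")
  if ("CLIN" %in% blocks)
    for (ch in config$latents) ts_block_for(latents[[ch]], ch, "CLIN")

  if ("TREND" %in% blocks) {
    for (ch in config$trend_channels) {
      g <- if (ch %in% config$continuous) grids[[ch]] else latents[[ch]]
      if (is.null(g)) stop("trend channel not available: ", ch)
      mg <- .grid_from(ch, g$rel_times[minute_idx], g$values[minute_idx],
                       g$flags[minute_idx])
      tb <- trend_feature_block(mg, config$trend_windows)
      v <- tb$values
      names(v) <- paste0(ch, "__", names(v))
      add(v, "TREND")
    }
  }

  names(tags) <- names(values)
  attr(values, "tags") <- tags
  values
}

#' Build the cohort feature matrix
#'
#' One row per case, columns named and tagged per
#' [build_feature_vector()]; the per-block column counts are asserted
#' against the roster ledger and echoed via `message()`.
#'
#' @param cases an `arrest_cohort` (or list of `case_record`).
#' @inheritParams build_feature_vector
#' @param quiet suppress the feature-count ledger message.
#' @return a `feature_matrix`: data frame with `case_id`, `label`, then
#'   numeric feature columns; attribute `tags` maps feature name -> block.
#' @export
build_feature_matrix <- function(cases, config = feature_config(),
                                 blocks = c("MV", "TS", "CLIN", "TREND"),
                                 quiet = FALSE) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  rows <- lapply(cases, build_feature_vector, config = config, blocks = blocks)
  tags <- attr(rows[[1]], "tags")
  mat <- do.call(rbind, lapply(rows, as.numeric))
  colnames(mat) <- names(rows[[1]])
  if (anyNA(mat) || any(!is.finite(mat)))
    stop("feature matrix contains missing or non-finite values")

  C <- length(config$continuous)
  L <- length(config$latents)
  D <- length(config$demographics)
  counts <- table(factor(tags, levels = c("MV", "TS", "CLIN", "TREND")))
  slots <- config$window$minute_window_min / config$window$minute_resolution_min
  bins <- config$window$hour_window_h * 60 / config$window$hour_resolution_min
  per_ch <- (slots - 1) + bins
  expected <- c(MV = if ("MV" %in% blocks) C + L + D else 0,
                TS = if ("TS" %in% blocks) per_ch * C else 0,
                CLIN = if ("CLIN" %in% blocks) per_ch * L else 0,
                TREND = if ("TREND" %in% blocks)
                  (4 * length(config$trend_windows) +
                     choose(length(config$trend_windows), 2)) *
                  length(config$trend_channels) else 0)
  if (!all(counts == expected))
    stop("feature-count ledger mismatch: got ",
         paste(names(counts), counts, sep = "=", collapse = " "),
         ", expected ", paste(names(expected), expected, sep = "=", collapse = " "))
  if (!quiet)
    message("feature ledger: ",
            paste(names(counts), counts, sep = "=", collapse = " "),
            " (total ", sum(counts), ")")

  out <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                    label = vapply(cases, `[[`, "", "label"),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  .as_feature_matrix(out, tags)
}

.as_feature_matrix <- function(df, tags) {
  attr(df, "tags") <- tags
  class(df) <- unique(c("feature_matrix", class(df)))
  df
}

#' Feature tags of a feature matrix
#' @param m a `feature_matrix`.
#' @return named character vector feature -> block tag.
#' @export
feature_tags <- function(m) attr(m, "tags")

#' Feature column names of a feature matrix
#' @param m a `feature_matrix`.
#' @export
feature_cols <- function(m) setdiff(names(m), c("case_id", "label"))

#' Select one of the five modeling subsets
#'
#' `MV` keeps the multivariable baseline only; `MV_TS` adds the raw
#' time-series elements; `MV_TS_CLIN` additionally adds the clinical latent
#' channels; `MV_TREND` adds the trend block to the baseline without the raw
#' series; `ALL` keeps every tag. The row set is unchanged.
#'
#' @param m a `feature_matrix`.
#' @param subset one of `"MV"`, `"MV_TS"`, `"MV_TS_CLIN"`, `"MV_TREND"`,
#'   `"ALL"`.
#' @return a `feature_matrix` restricted to the subset's tags.
#' @export
select_subset <- function(m, subset) {
  tag_map <- list(MV = "MV",
                  MV_TS = c("MV", "TS"),
                  MV_TS_CLIN = c("MV", "TS", "CLIN"),
                  MV_TREND = c("MV", "TREND"),
                  ALL = c("MV", "TS", "CLIN", "TREND"))
  if (!subset %in% names(tag_map)) stop("unknown subset id: ", subset)
  tags <- feature_tags(m)
  keep <- names(tags)[tags %in% tag_map[[subset]]]
  out <- m[, c("case_id", "label", keep), drop = FALSE]
  out <- .as_feature_matrix(out, tags[keep])
  if (inherits(m, "holdout_matrix")) class(out) <- unique(c("holdout_matrix", class(out)))
  out
}

#' Stratified train/holdout partition
#'
#' Randomly withholds `holdout_frac` of the cases as a validation set,
#' stratified by class label: the total holdout count is
#' `floor(n * frac + 0.5)`, allocated per class by largest remainder (ties
#' toward the larger class, then label order). The holdout partition is
#' returned with class `holdout_matrix` and is refused by the selection and
#' training operations, so it can only be scored.
#'
#' @param m a `feature_matrix` (>= 2 cases per class).
#' @param holdout_frac fraction withheld, in (0, 1); default 0.33.
#' @param seed integer seed; the split is reproducible.
#' @return list with `train` and `holdout` feature matrices.
#' @export
partition_holdout <- function(m, holdout_frac = 0.33, seed = 1) {
  if (holdout_frac <= 0 || holdout_frac >= 1)
    stop("holdout_frac must be in (0, 1)")
  tab <- table(m$label)
  if (length(tab) < 2 || any(tab < 2))
    stop("each class must have at least 2 cases")
  n_total <- nrow(m)
  n_hold <- floor(n_total * holdout_frac + 0.5)
  quota <- as.numeric(tab) * holdout_frac
  base <- floor(quota)
  rem <- n_hold - sum(base)
  frac_part <- quota - base
  ord <- order(-frac_part, -as.numeric(tab), names(tab))
  extra <- integer(length(tab))
  if (rem > 0) extra[ord[seq_len(rem)]] <- 1L
  per_class <- base + extra
  names(per_class) <- names(tab)

  hold_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(names(tab), function(cl) {
      idx <- which(m$label == cl)
      sample(idx, per_class[[cl]])
    }), use.names = FALSE)
  })
  hold_idx <- sort(hold_idx)
  tags <- feature_tags(m)
  train <- .as_feature_matrix(m[-hold_idx, , drop = FALSE], tags)
  holdout <- .as_feature_matrix(m[hold_idx, , drop = FALSE], tags)
  class(holdout) <- unique(c("holdout_matrix", class(holdout)))
  list(train = train, holdout = holdout)
}

#' Write a feature matrix as CSV with a tag sidecar
#'
#' Writes `<path>.csv` (first columns `case_id`, `label`) and
#' `<path>.tags.json` mapping each feature column to its block tag.
#'
#' @param m a `feature_matrix`.
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  data.table::fwrite(as.data.frame(m), paste0(path, ".csv"))
  jsonlite::write_json(as.list(feature_tags(m)), paste0(path, ".tags.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
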