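# Clinically relevant latent variables used at the bedside to assess shock,
# computed pointwise from the raw hemodynamic channels. All operations are
# vectorized and each latent value at grid time t depends only on inputs at
# time t (plus the scalar hemoglobin lab).

#' Pulse pressure (mmHg)
#'
#' Systolic minus diastolic blood pressure; proxy for stroke volume at fixed
#' vascular resistance. Non-positive results are flagged, not rejected —
#' monitor artifacts happen.
#'
#' @param sbp,dbp systolic / diastolic pressure (mmHg), scalars or vectors.
#' @return numeric `sbp - dbp`, with attribute `flagged` marking elements
#'   where `sbp <= dbp`.
#' @export
pulse_pressure <- function(sbp, dbp) {
  out <- sbp - dbp
  attr(out, "flagged") <- out <= 0
  out
}

#' Shock index (bpm/mmHg)
#'
#' Heart rate divided by systolic blood pressure; rises in progressive shock.
#' Points with `sbp <= 0` are set to `cap` with a warning and flagged.
#'
#' @param hr heart rate (bpm).
#' @param sbp systolic pressure (mmHg).
#' @param cap value substituted where `sbp <= 0` (default 10 bpm/mmHg).
#' @return numeric `hr / sbp` with attribute `flagged`.
#' @export
shock_index <- function(hr, sbp, cap = 10) {
  bad <- sbp <= 0
  out <- ifelse(bad, cap, hr / sbp)
  if (any(bad)) warning(sum(bad), " shock-index point(s) with sbp <= 0 capped at ", cap)
  attr(out, "flagged") <- bad
  out
}

#' Oxygen-delivery index
#'
#' Semiquantitative supply-side surrogate: heart rate x pulse pressure x
#' oxygen saturation (fraction) x hemoglobin. Saturation must be a fraction;
#' percent-scale inputs are rejected at the boundary.
#'
#' @param hr heart rate (bpm).
#' @param pp pulse pressure (mmHg).
#' @param spo2 oxygen saturation as a fraction in `[0, 1]`.
#' @param hgb hemoglobin (g/dL).
#' @return numeric index (bpm * mmHg * fraction * g/dL).
#' @export
oxygen_delivery_index <- function(hr, pp, spo2, hgb) {
  if (any(spo2 > 1.5)) stop("saturation must be a fraction")
  hr * pp * spo2 * hgb
}

#' Mean arterial pressure (mmHg)
#'
#' Standard perfusion-pressure summary `(sbp + 2 dbp) / 3` (diastole occupies
#' roughly two thirds of the cardiac cycle).
#'
#' @inheritParams pulse_pressure
#' @return numeric MAP.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  (sbp + 2 * dbp) / 3
}

# provenance for a derived slot: the worst provenance among its inputs
.combine_flags <- function(...) {
  rank <- c(observed = 1L, carried = 2L, normal = 3L)
  mats <- do.call(cbind, lapply(list(...), function(f) rank[f]))
  names(rank)[apply(mats, 1, max)]
}

#' Derive the clinical latent channels for one case
#'
#' Computes pulse pressure (`pp`), mean arterial pressure (`map`), shock
#' index (`si`) and oxygen-delivery index (`odi`) pointwise on the input
#' grids, with the sparse hemoglobin lab carried forward as a scalar
#' broadcast across the grid. Input grids must share the same `rel_times`.
#'
#' @param grids named list of `grid_series` containing at least `hr`, `sbp`,
#'   `dbp`, `spo2` (arterial pressures; saturation as a fraction).
#' @param hgb_g_dl scalar hemoglobin (g/dL).
#' @return named list of `grid_series` with channels `pp`, `map`, `si`,
#'   `odi`; slot flags are the worst provenance among the inputs feeding
#'   each slot.
#' @export
derive_latent_channels <- function(grids, hgb_g_dl) {
  for (ch in c("hr", "sbp", "dbp", "spo2")) {
    if (is.null(grids[[ch]]))
      stop("missing required input channel: ", ch)
  }
  times <- grids$hr$rel_times
  for (ch in c("sbp", "dbp", "spo2")) {
    if (!identical(grids[[ch]]$rel_times, times))
      stop("latent inputs must share the same grid times (channel ", ch, ")")
  }
  pp <- unclass(pulse_pressure(grids$sbp$values, grids$dbp$values))
  attr(pp, "flagged") <- NULL
  si <- suppressWarnings(shock_index(grids$hr$values, grids$sbp$values))
  attr(si, "flagged") <- NULL
  vals <- list(pp = pp,
               map = mean_arterial_pressure(grids$sbp$values, grids$dbp$values),
               si = si,
               odi = oxygen_delivery_index(grids$hr$values, pp,
                                           grids$spo2$values, hgb_g_dl))
  bp_flags <- .combine_flags(grids$sbp$flags, grids$dbp$flags)
  flags <- list(pp = bp_flags,
                map = bp_flags,
                si = .combine_flags(grids$hr$flags, grids$sbp$flags),
                odi = .combine_flags(grids$hr$flags, grids$sbp$flags,
                                     grids$dbp$flags, grids$spo2$flags))
  out <- lapply(names(vals), function(ch) {
    structure(list(channel = ch, rel_times = times, values = as.numeric(vals[[ch]]),
                   flags = flags[[ch]]),
              class = "grid_series")
  })
  names(out) <- names(vals)
  out
}
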