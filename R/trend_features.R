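# Trend features: per-window slope, intercept, mean and slope/mean for the
# 5-, 10-, 15- and 60-minute pre-event windows, plus the six between-window
# mean ratios. A W-minute window is the W most recent minute-grid slots,
# including the t = 0 slot, and the intercept is the fitted value at t = 0
# (the projected value at the event), which makes intercepts comparable
# across windows.

.window_tail <- function(grid, window_min) {
  n <- length(grid$values)
  if (window_min > n)
    stop("window (", window_min, ") exceeds grid length (", n, ")")
  grid$values[(n - window_min + 1):n]
}

#' Ordinary least-squares line over a pre-event window
#'
#' Fits `value ~ t` by OLS over the window's grid times
#' `t = -(W-1), ..., 0`; the slope is in channel units per minute and the
#' intercept is the fitted value at t = 0.
#'
#' @param grid a `grid_series` (complete, minute resolution).
#' @param window_min window length W in minutes (>= 2).
#' @return named numeric `c(slope, intercept)`.
#' @export
fit_window_line <- function(grid, window_min) {
  if (window_min < 2) stop("window too short for slope")
  v <- .window_tail(grid, window_min)
  t <- seq.int(-(window_min - 1), 0)
  tbar <- mean(t)
  vbar <- mean(v)
  slope <- sum((t - tbar) * (v - vbar)) / sum((t - tbar)^2)
  c(slope = slope, intercept = vbar - slope * tbar)
}

#' Mean over a pre-event window
#'
#' @inheritParams fit_window_line
#' @return arithmetic mean of the W most recent grid values.
#' @export
window_mean <- function(grid, window_min) {
  mean(.window_tail(grid, window_min))
}

#' Full trend-feature block for one channel
#'
#' Computes, for each window W in `windows`: `slopeW`, `interceptW`, `meanW`
#' and `slopemeanW` (slope divided by mean, 1/min), plus the between-window
#' mean ratios `ratioA_B = meanA / meanB` for every ordered pair of a shorter
#' window A and a longer window B — 22 named features for the default
#' windows. Any ratio whose denominator has magnitude below `eps` is set to 0
#' with its validity flag cleared, so the feature matrix stays rectangular.
#'
#' @param grid a `grid_series` covering at least `max(windows)` slots.
#' @param windows window lengths in minutes, ascending.
#' @param eps degenerate-denominator guard (default 1e-9).
#' @return object of class `trend_block`: list with `values` (named numeric)
#'   and `valid` (named logical).
#' @export
trend_feature_block <- function(grid, windows = c(5, 10, 15, 60), eps = 1e-9) {
  windows <- sort(windows)
  values <- numeric(0)
  valid <- logical(0)
  means <- numeric(length(windows))
  names(means) <- as.character(windows)
  for (i in seq_along(windows)) {
    W <- windows[i]
    line <- fit_window_line(grid, W)
    m <- window_mean(grid, W)
    means[i] <- m
    sm_ok <- abs(m) >= eps
    block <- c(line["slope"], line["intercept"], mean = m,
               slopemean = if (sm_ok) line[["slope"]] / m else 0)
    names(block) <- paste0(c("slope", "intercept", "mean", "slopemean"), W)
    values <- c(values, block)
    ok <- c(TRUE, TRUE, TRUE, sm_ok)
    names(ok) <- names(block)
    valid <- c(valid, ok)
  }
  pairs <- utils::combn(seq_along(windows), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- windows[pairs[1, k]]
    b <- windows[pairs[2, k]]
    nm <- sprintf("ratio%d_%d", a, b)
    ok <- abs(means[[as.character(b)]]) >= eps
    values[[nm]] <- if (ok) means[[as.character(a)]] / means[[as.character(b)]] else 0
    valid[[nm]] <- ok
  }
  structure(list(values = values, valid = valid), class = "trend_block")
}
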