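# Small builders used across the suite. All fixtures are generated in code.

make_series <- function(timestamp_min, value) {
  data.frame(timestamp_min = timestamp_min, value = value)
}

# grid_series ending at t = 0 with the given values, all observed
make_grid <- function(values, channel = "x") {
  n <- length(values)
  structure(list(channel = channel, rel_times = seq(-(n - 1), 0),
                 values = values, flags = rep("observed", n)),
            class = "grid_series")
}

# feature_matrix built directly from a numeric matrix (bypasses the
# featurizer) with uniform or supplied tags
make_matrix <- function(X, labels, tags = NULL) {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  tags <- tags %||% stats::setNames(rep("MV", ncol(X)), colnames(X))
  df <- data.frame(case_id = sprintf("case_%03d", seq_len(nrow(X))),
                   label = labels, X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "tags") <- tags
  class(df) <- c("feature_matrix", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gaussian two-class matrix: first `k` features shifted by `effect` SDs in
# the arrest class, the rest pure noise
make_signal_matrix <- function(n_per_class = 50, p = 50, k = 3, effect = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(stats::rnorm(n * p), n, p)
    labels <- rep(c("arrest", "control"), each = n_per_class)
    X[labels == "arrest", seq_len(k)] <- X[labels == "arrest", seq_len(k)] + effect
    make_matrix(X, labels)
  })
}

# deterministic noise-free case record: constant channels, useful for exact
# featurizer arithmetic
make_flat_case <- function(values = c(hr = 120, spo2 = 0.97, sbp = 95, dbp = 55),
                           t_end = 840, label = "control", hgb = 12) {
  ts <- 0:t_end
  channels <- lapply(values, function(v) make_series(ts, rep(v, length(ts))))
  channels$nibp_sbp <- make_series(ts, rep(values[["sbp"]], length(ts)))
  channels$nibp_dbp <- make_series(ts, rep(values[["dbp"]], length(ts)))
  structure(list(case_id = "flat_001", label = label,
                 reference_time_min = t_end, age_months = 24L,
                 weight_kg = 12, hgb_g_dl = hgb, hgb_time_min = 0L,
                 channels = channels,
                 clipped = stats::setNames(integer(6), names(channels))),
            class = "case_record")
}

quiet_matrix <- function(...) suppressMessages(build_feature_matrix(...))

noise_free_params <- function(...) {
  shock_params(noise_sd = c(hr = 0, sbp = 0, dbp = 0, spo2 = 0),
               nibp_noise_sd = 0, dropout_prob = 0, hgb_sd = 0, ...)
}

null_params <- function(...) {
  shock_params(slow_drift = c(hr = 0, sbp = 0, dbp = 0, spo2 = 0),
               terminal_drift = c(hr = 0, sbp = 0, dbp = 0, spo2 = 0), ...)
}
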