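# Event-anchored windowing, imputation and representatives

test_that("alignment re-expresses timestamps and drops future observations", {
  s <- make_series(c(100, 160), c(80, 82))
  a <- align_to_reference(s, 160)
  expect_equal(a$rel_time_min, c(-60, 0))

  a2 <- align_to_reference(make_series(c(100, 170), c(80, 82)), 160)
  expect_equal(a2$rel_time_min, -60)   # the post-event sample is gone

  # 13 h of per-minute data, reference at the end
  s3 <- make_series(0:780, rnorm(781))
  a3 <- align_to_reference(s3, 780)
  expect_equal(nrow(a3), 781)
  expect_equal(range(a3$rel_time_min), c(-780, 0))

  expect_warning(e <- align_to_reference(make_series(100, 5), 50),
                 "reference precedes")
  expect_equal(nrow(e), 0)
})

test_that("carry-forward imputation fills the minute grid as specified", {
  spec <- window_spec(minute_window_min = 10)
  nv <- normal_values(x = 100)
  a <- data.frame(rel_time_min = c(-7, -3), value = c(90, 84))
  g <- to_minute_grid(a, spec, nv, "x")
  expect_equal(g$values, c(100, 100, 90, 90, 90, 90, 84, 84, 84, 84))
  expect_equal(g$flags, c("normal", "normal", "observed", "carried", "carried",
                          "carried", "observed", "carried", "carried", "carried"))

  # no observations at all -> the normal value everywhere
  g0 <- to_minute_grid(data.frame(rel_time_min = numeric(0), value = numeric(0)),
                       spec, nv, "x")
  expect_equal(g0$values, rep(100, 10))
  expect_true(all(g0$flags == "normal"))

  # complete per-minute data is reproduced exactly, nothing carried
  v <- rnorm(60)
  full <- data.frame(rel_time_min = -59:0, value = v)
  gf <- to_minute_grid(full, window_spec(), nv, "x")
  expect_equal(gf$values, v)
  expect_true(all(gf$flags == "observed"))

  expect_error(to_minute_grid(a, spec, normal_values(), "unknown_channel"),
               "no normal value configured")
})

test_that("hourly aggregation averages the carried minute grid per bin", {
  nv <- normal_values(x = 100)
  # 60 native values all 70 in the most recent bin
  a <- data.frame(rel_time_min = -60:-1, value = rep(70, 60))
  h <- hourly_aggregate(a, window_spec(), nv, "x")
  expect_equal(h$values[1], 70)
  expect_equal(h$coverage[1], 60L)
  # earlier bins carry the last value forward... backward bins use normal
  expect_equal(h$values[12], 100)
  expect_equal(h$coverage[12], 0L)

  # arithmetic series: values 1..60 in the bin (value t maps to rel time -t)
  a2 <- data.frame(rel_time_min = -60:-1, value = 60:1)
  expect_equal(hourly_aggregate(a2, window_spec(), nv, "x")$values[1], 30.5)

  # brute-force averaging oracle on a complete 12-h record
  withr::with_seed(31, {
    v <- rnorm(721)
    full <- data.frame(rel_time_min = -720:0, value = v)
    h3 <- hourly_aggregate(full, window_spec(), nv, "x")
    oracle <- vapply(1:12, function(hh) {
      mean(v[full$rel_time_min >= -60 * hh & full$rel_time_min <= -60 * (hh - 1) - 1])
    }, numeric(1))
    expect_equal(h3$values, oracle)
    expect_equal(h3$coverage, rep(60L, 12))
  })
})

test_that("the hourly lookback can exclude the minute-resolution hour", {
  withr::with_seed(17, {
    v <- rnorm(781, 100, 10)
    a <- data.frame(rel_time_min = -780:0, value = v)
    spec <- window_spec(hourly_includes_minute_window = FALSE)
    h <- hourly_aggregate(a, spec, normal_values(x = 100), "x")
    oracle <- vapply(1:12, function(hh)
      mean(v[(-780:0) >= -60 * (hh + 1) & (-780:0) <= -60 * hh - 1]), numeric(1))
    expect_equal(h$values, oracle)
    expect_equal(h$coverage, rep(60L, 12))

    # the featurizer honors the same offset
    cs <- make_flat_case()
    fc <- feature_config(window = spec)
    vec <- build_feature_vector(cs, fc, blocks = c("MV", "TS"))
    expect_equal(unname(vec[["hr__h12"]]), 120)
    expect_length(grep("^hr__h", names(vec)), 12)
  })
})

test_that("the multivariable representative is the latest pre-event value", {
  a <- data.frame(rel_time_min = c(-7, -3), value = c(90, 84))
  r <- multivariable_representative(a, normal_values(x = 100), "x")
  expect_equal(r$value, 84)
  expect_equal(r$provenance, "observed")

  r0 <- multivariable_representative(data.frame(rel_time_min = numeric(0),
                                                value = numeric(0)),
                                     normal_values(x = 100), "x")
  expect_equal(r0$value, 100)
  expect_equal(r0$provenance, "normal")

  # cross-operation consistency: equals the t = 0 grid slot
  withr::with_seed(8, {
    s <- make_series(0:780, rnorm(781))
    a3 <- align_to_reference(s, 780)
    g <- to_minute_grid(a3, window_spec(), normal_values(x = 50), "x")
    expect_equal(multivariable_representative(a3, normal_values(x = 50), "x")$value,
                 g$values[g$rel_times == 0])
  })
})

test_that("perturbing post-reference observations never changes outputs", {
  withr::with_seed(99, {
    for (trial in 1:25) {
      n <- sample(50:200, 1)
      ts <- sort(sample(0:1000, n))
      v <- rnorm(n, 100, 10)
      ref <- sample(700:900, 1)
      s <- make_series(ts, v)
      v2 <- v
      future <- ts > ref
      v2[future] <- v2[future] + rnorm(sum(future), 0, 50)
      s2 <- make_series(c(ts, sample(setdiff((ref + 1):1200, ts), 3)),
                        c(v2, rnorm(3)))
      base <- align_to_reference(s, ref)
      pert <- align_to_reference(s2, ref)
      nv <- normal_values(x = 100)
      expect_equal(to_minute_grid(pert, window_spec(), nv, "x"),
                   to_minute_grid(base, window_spec(), nv, "x"))
      expect_equal(hourly_aggregate(pert, window_spec(), nv, "x"),
                   hourly_aggregate(base, window_spec(), nv, "x"))
      expect_equal(multivariable_representative(pert, nv, "x"),
                   multivariable_representative(base, nv, "x"))
    }
  })
})

test_that("grid completeness and idempotence hold on random inputs", {
  withr::with_seed(13, {
    for (trial in 1:20) {
      n <- sample(0:80, 1)
      a <- data.frame(rel_time_min = sort(sample(-800:0, n)),
                      value = rnorm(n, 90, 15))
      g <- to_minute_grid(a, window_spec(), normal_values(x = 90), "x")
      expect_length(g$values, 60)
      expect_false(anyNA(g$values))
      # idempotence: re-gridding the complete grid reproduces it
      g2 <- to_minute_grid(data.frame(rel_time_min = g$rel_times, value = g$values),
                           window_spec(), normal_values(x = 90), "x")
      expect_equal(g2$values, g$values)
    }
  })
})

test_that("window specification invariants are enforced", {
  expect_error(window_spec(minute_window_min = 61, minute_resolution_min = 2),
               "divisible")
  expect_error(window_spec(hour_resolution_min = 7), "divisible")
  expect_error(window_spec(minute_window_min = 800), "cannot exceed")
  expect_error(normal_values(hr = -5), "physiologic")
})
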