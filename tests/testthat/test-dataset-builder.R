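# Feature-matrix assembly, subsets, holdout partition

test_that("the feature vector honors the per-block accounting", {
  cs <- simulate_case("control", shock_params(dropout_prob = 0), seed = 21)
  v <- build_feature_vector(cs)
  tags <- attr(v, "tags")
  expect_equal(sum(tags == "TS"), 6 * (59 + 12))     # 426
  expect_equal(sum(tags == "MV"), 6 + 4 + 3)
  expect_equal(sum(tags == "CLIN"), 4 * 71)
  expect_equal(sum(tags == "TREND"), 22 * 10)
  expect_false(anyNA(v))

  # determinism
  expect_identical(build_feature_vector(cs), v)

  # naming convention spot checks
  expect_true(all(c("hr__m59", "hr__m1", "hr__h12", "sbp__mv", "si__mean60",
                    "sbp__slope5", "hr__ratio5_60", "age_months") %in% names(v)))
  # the t = 0 slot is the MV representative, not a TS element
  expect_false("hr__m0" %in% names(v))
})

test_that("a case with no observations falls back to the normal table", {
  empty <- make_flat_case()
  for (ch in names(empty$channels))
    empty$channels[[ch]] <- make_series(integer(0), numeric(0))
  suppressWarnings(v <- build_feature_vector(empty))
  nv <- normal_values()
  expect_equal(v[["hr__mv"]], nv[["hr"]])
  expect_equal(v[["sbp__mv"]], nv[["sbp"]])
  expect_equal(v[["spo2__mv"]], nv[["spo2"]])
  expect_false(anyNA(v))
  expect_length(v, 943)
})

test_that("flat cases produce exactly computable features", {
  v <- build_feature_vector(make_flat_case())
  expect_equal(v[["hr__mv"]], 120)
  expect_equal(v[["pp__mv"]], 40)
  expect_equal(v[["map__mv"]], (95 + 2 * 55) / 3)
  expect_equal(v[["si__mv"]], 120 / 95)
  expect_equal(v[["odi__mv"]], 120 * 40 * 0.97 * 12)
  expect_equal(v[["hr__h7"]], 120)
  expect_equal(v[["sbp__slope10"]], 0)
  expect_equal(v[["si__ratio5_60"]], 1)
})

test_that("a missing configured channel is a hard error", {
  cs <- make_flat_case()
  cs$channels$spo2 <- NULL
  expect_error(build_feature_vector(cs), "spo2")
})

test_that("subset selection filters by tag and conserves columns", {
  co <- simulate_cohort(cohort_config(3, 3, seed = 5))
  fm <- quiet_matrix(co)
  widths <- vapply(c("MV", "MV_TS", "MV_TS_CLIN", "MV_TREND", "ALL"),
                   function(s) length(feature_cols(select_subset(fm, s))),
                   numeric(1))
  expect_equal(unname(widths), c(13, 13 + 426, 13 + 426 + 284, 13 + 220, 943))
  expect_equal(widths[["ALL"]], sum(table(feature_tags(fm))))

  mv_trend <- select_subset(fm, "MV_TREND")
  expect_false(any(feature_tags(mv_trend) == "TS"))
  expect_equal(nrow(mv_trend), nrow(fm))
  expect_error(select_subset(fm, "TS_ONLY"), "unknown subset")

  # an MV-only build equals the MV subset of the full build
  fmv <- quiet_matrix(co, blocks = "MV")
  expect_equal(as.data.frame(select_subset(fm, "MV")), as.data.frame(fmv))
})

test_that("the holdout partition is stratified, seeded and disjoint", {
  X <- matrix(rnorm(100 * 4), 100)
  fm <- make_matrix(X, rep(c("arrest", "control"), each = 50))
  p <- partition_holdout(fm, 0.33, seed = 7)
  expect_equal(nrow(p$holdout), 33)
  expect_equal(nrow(p$train), 67)
  tab <- table(p$holdout$label)
  expect_true(all(sort(as.numeric(tab)) == c(16, 17)))
  expect_length(intersect(p$train$case_id, p$holdout$case_id), 0)
  expect_setequal(c(p$train$case_id, p$holdout$case_id), fm$case_id)

  p2 <- partition_holdout(fm, 0.33, seed = 7)
  expect_identical(p2$holdout$case_id, p$holdout$case_id)

  phalf <- partition_holdout(make_matrix(X[1:10, ], rep(c("arrest", "control"), 5)),
                             0.5, seed = 1)
  expect_equal(nrow(phalf$holdout), 5)
  expect_equal(nrow(phalf$train), 5)

  expect_error(partition_holdout(fm, 0), "holdout_frac")
  expect_error(partition_holdout(make_matrix(X[1:3, ],
                                             c("arrest", "control", "control")),
                                 0.33),
               "at least 2 cases")
})

test_that("class proportions in train and holdout differ by at most one case", {
  withr::with_seed(3, {
    for (trial in 1:10) {
      n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
      frac <- runif(1, 0.2, 0.5)
      fm <- make_matrix(matrix(rnorm((n1 + n0) * 2), n1 + n0),
                        c(rep("arrest", n1), rep("control", n0)))
      p <- partition_holdout(fm, frac, seed = trial)
      h <- table(factor(p$holdout$label, c("arrest", "control")))
      expect_lte(abs(h[["arrest"]] - n1 * frac), 1)
      expect_lte(abs(h[["control"]] - n0 * frac), 1)
      expect_equal(nrow(p$holdout), floor((n1 + n0) * frac + 0.5))
    }
  })
})

test_that("feature matrices round-trip through CSV with their tag sidecar", {
  co <- simulate_cohort(cohort_config(2, 2, seed = 1))
  fm <- quiet_matrix(co, blocks = c("MV", "TREND"))
  path <- file.path(tempdir(), "fm_out")
  write_feature_matrix(fm, path)
  back <- data.table::fread(paste0(path, ".csv"), data.table = FALSE)
  expect_equal(back$case_id, fm$case_id)
  expect_equal(names(back), names(fm))
  tags <- unlist(jsonlite::read_json(paste0(path, ".tags.json")))
  expect_equal(tags, feature_tags(fm))
})
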