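# The 79-feature catalogue: schema, elementary statistics, step detection,
# gait features, assembly and equivariance.

test_that("the feature schema is the documented 79-entry catalogue", {
  sc <- feature_schema()
  expect_identical(nrow(sc), 79L)
  expect_identical(anyDuplicated(sc$name), 0L)
  expect_identical(sc$number, 1:79)
  expect_identical(as.integer(table(sc$block)[c("tug", "sist", "walk", "turn", "stsi")]),
                   c(12L, 22L, 11L, 12L, 22L))
  # anchor the singleton features at their catalogue positions
  expect_identical(sc$name[13], "stand_duration")
  expect_identical(sc$name[35], "walk_duration")
  expect_identical(sc$name[36], "cadence")
  expect_identical(sc$name[37], "step_length")
  expect_identical(sc$name[38], "gait_speed")
  expect_identical(sc$name[58], "sit_duration")
  expect_identical(sc$name[79], "sd_stsi_AP")
})

test_that("rms, jerk and descriptive statistics match their definitions", {
  expect_identical(rms(c(0, 0, 0)), 0)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  expect_error(rms(numeric(0)), "empty")
  withr::local_seed(61)
  x <- rnorm(40)
  expect_equal(rms(x), sqrt(sum(x^2) / 40))

  # linear ramp with slope a per sample -> constant jerk a * fs
  a <- 0.7; fs <- 30
  ramp <- a * (0:20)
  expect_equal(jerk_series(ramp, fs), rep(a * fs, 21))
  expect_identical(jerk_series(rep(2, 10), fs), rep(0, 10))
  j <- jerk_series(x, fs)
  expect_equal(j[5], (x[6] - x[4]) * fs / 2)
  expect_equal(j[1], (x[2] - x[1]) * fs)
  expect_equal(max_jerk(x, fs), max(abs(j)))
  expect_equal(mean_jerk(x, fs), mean(abs(j)))
  expect_error(jerk_series(1, fs), "at least 2")

  d <- descriptive_block(c(1, 1, 1))
  expect_identical(c(d$range, d$sd, d$cv), c(0, 0, 0))
  d2 <- descriptive_block(c(1, 3))
  expect_equal(c(d2$range, d2$median, d2$sd), c(2, 2, sqrt(2)))
  d3 <- descriptive_block(x)
  expect_equal(d3$sd, sd(x))
  expect_equal(d3$cv, 100 * sd(x) / abs(mean(x)))
  # zero-mean segment with spread: CV flagged missing
  expect_true(is.na(descriptive_block(c(-1, 1, -1, 1))$cv))
})

test_that("step detection finds the generator's step schedule", {
  spec <- cohort_spec_community(n_subjects = 1, noise_sd = 0,
                                cadence_mean = 120, cadence_sd = 0)
  s <- generate_cohort(spec, seed = 71)[[1]]
  segs <- lapply(c("walk_out", "walk_back"), function(ph) {
    iv <- s$bounds[[ph]]
    s$recording$acc$V[(iv[1] + 1):iv[2]]
  })
  ev <- detect_steps(segs, s$recording$fs)
  # cadence 120 -> 0.5 s step interval, within one sample
  expect_lt(max(abs(ev$step_intervals - 0.5)), 1 / s$recording$fs + 1e-9)
  expect_error(detect_steps(rep(0, 60), 30), "fewer than 2")

  # doubling cadence halves the median step time
  spec2 <- cohort_spec_community(n_subjects = 1, noise_sd = 0,
                                 cadence_mean = 60, cadence_sd = 0)
  s2 <- generate_cohort(spec2, seed = 71)[[1]]
  iv <- s2$bounds$walk_out
  ev2 <- detect_steps(s2$recording$acc$V[(iv[1] + 1):iv[2]], s2$recording$fs)
  expect_equal(median(ev2$step_intervals) / median(ev$step_intervals), 2,
               tolerance = 0.1)
})

test_that("gait features follow their definitions and identities", {
  ev <- structure(list(events = list(seq(1, 361, by = 15)),
                       step_intervals = rep(0.5, 24),
                       stride_intervals = rep(1, 12), n_steps = 24L),
                  class = "tug_step_events")
  g <- gait_features(ev, walk_duration = 6, distance = 6)
  expect_equal(g$cadence, 120)
  expect_equal(g$gait_speed, 1)
  expect_equal(g$step_length, 0.5)
  expect_equal(g$cv_step_time, 0)
  expect_equal(g$stride_time, 1)

  # hand-computed CV for alternating intervals
  iv <- c(0.4, 0.6, 0.4, 0.6)
  ev2 <- structure(list(events = list(c(0, cumsum(iv * 30))),
                        step_intervals = iv,
                        stride_intervals = c(1, 1), n_steps = 4L),
                   class = "tug_step_events")
  g2 <- gait_features(ev2, walk_duration = 2, distance = 2)
  expect_equal(g2$cv_step_time, 100 * sd(iv) / mean(iv))
  expect_equal(g2$cv_stride_time, 0)

  # the speed identity is exact by construction
  for (g_i in list(g, g2))
    expect_equal(g_i$gait_speed, g_i$cadence / 60 * g_i$step_length,
                 tolerance = 1e-12)
  expect_error(gait_features(structure(list(step_intervals = 0.5,
                                            stride_intervals = numeric(0),
                                            n_steps = 1L),
                                       class = "tug_step_events"), 6, 6),
               "at least 3")
})

test_that("extract_features emits the complete keyed vector", {
  s <- tiny_cohort(1, seed = 81)[[1]]
  fv <- extract_features(s$recording, s$bounds)
  expect_length(fv, 79L)
  expect_identical(names(fv), feature_names())
  expect_false(anyNA(fv[c("stand_duration", "walk_duration", "cadence")]))
  # durations are exactly interval length / fs in annotated mode
  expect_identical(fv[["stand_duration"]],
                   diff(s$bounds$sist) / s$recording$fs)
  expect_identical(fv[["sit_duration"]],
                   diff(s$bounds$stsi) / s$recording$fs)
  expect_identical(fv[["walk_duration"]],
                   (diff(s$bounds$walk_out) + diff(s$bounds$walk_back)) /
                     s$recording$fs)
})

test_that("features are scale-equivariant as documented", {
  s <- tiny_cohort(1, seed = 83)[[1]]
  fv <- extract_features(s$recording, s$bounds)
  cc <- 3.7
  rec2 <- tug_recording(s$recording$subject_id, s$recording$fs,
                        lapply(s$recording$acc, function(x) cc * x))
  fv2 <- extract_features(rec2, s$bounds)
  sc <- feature_schema()
  scale_by_c <- sc$name[grepl("^(range|max|min|rms|sd|max_jerk|mean_jerk|median)_", sc$name)]
  invariant <- c("stand_duration", "sit_duration", "walk_duration", "cadence",
                 "step_length", "gait_speed", "step_time", "stride_time",
                 "cv_step_time", "cv_stride_time",
                 sc$name[grepl("^(pe_tug|cv_turn)", sc$name)])
  expect_equal(fv2[scale_by_c], cc * fv[scale_by_c], tolerance = 1e-10)
  expect_equal(fv2[invariant], fv[invariant], tolerance = 1e-10)
})

test_that("a failing block yields flagged missings plus a warning, never a short vector", {
  s <- tiny_cohort(1, seed = 85)[[1]]
  # collapse the walking bouts to a fraction of a second: step detection
  # cannot succeed, but the vector must stay complete
  b <- s$bounds
  short <- phase_bounds(b$sist, c(b$sist[2], b$sist[2] + 5),
                        c(b$sist[2] + 5, b$turn[2]), c(b$turn[2], b$turn[2] + 5),
                        b$stsi, n = s$recording$n)
  expect_warning(fv <- extract_features(s$recording, short), "failed")
  expect_length(fv, 79L)
  expect_true(anyNA(fv[c("cadence", "step_time")]))
})

test_that("group-mean stand_duration ratio tracks the generator effect", {
  spec <- cohort_spec_community(
    n_subjects = 100, fall_risk_fraction = 0.5,
    effects = list(stand_duration = 2.5, sit_duration = 1, gait_speed = 1,
                   cadence = 1))
  co <- generate_cohort(spec, seed = 87)
  cf <- cohort_features(co)
  risk <- vapply(co, function(s) s$truth$fall_risk, logical(1))
  ratio <- mean(cf$X[risk, "stand_duration"]) / mean(cf$X[!risk, "stand_duration"])
  expect_equal(ratio, 2.5, tolerance = 0.1 * 2.5)
})
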