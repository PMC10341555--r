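# Synthetic cohort generator: determinism, kinematic identities, effect
# shifts, label consistency, spectral content, disk round-trip.

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_spec_community(n_subjects = 3), seed = 1)
  b <- generate_cohort(cohort_spec_community(n_subjects = 3), seed = 1)
  expect_identical(lapply(a, function(s) s$recording$acc),
                   lapply(b, function(s) s$recording$acc))
  expect_identical(lapply(a, `[[`, "labels"), lapply(b, `[[`, "labels"))
  c2 <- generate_cohort(cohort_spec_community(n_subjects = 3), seed = 2)
  expect_false(identical(a[[1]]$recording$acc, c2[[1]]$recording$acc))
})

test_that("true gait speed follows the kinematic identity", {
  spec <- cohort_spec_community(n_subjects = 5, noise_sd = 0,
                                fall_risk_fraction = 0,
                                cadence_mean = 120, cadence_sd = 0,
                                step_length_mean = 0.5, step_length_sd = 0)
  co <- generate_cohort(spec, seed = 3)
  for (s in co) {
    expect_equal(s$truth$gait_speed, 1.0, tolerance = 1e-12)
    expect_equal(s$truth$gait_speed,
                 s$truth$cadence / 60 * s$truth$step_length, tolerance = 1e-12)
    # tug_seconds is the exact sum of the five phase durations
    expect_equal(s$labels$tug_seconds, sum(s$truth$phase_durations),
                 tolerance = 1e-12)
  }
})

test_that("the stand-duration effect shifts the fall-risk group as specified", {
  spec <- cohort_spec_community(
    n_subjects = 200, fall_risk_fraction = 0.5,
    effects = list(stand_duration = 2.5, sit_duration = 1, gait_speed = 1,
                   cadence = 1))
  co <- generate_cohort(spec, seed = 5)
  risk <- vapply(co, function(s) s$truth$fall_risk, logical(1))
  sist <- vapply(co, function(s) s$truth$phase_durations[["sist"]], numeric(1))
  ratio <- mean(sist[risk]) / mean(sist[!risk])
  expect_equal(ratio, 2.5, tolerance = 0.1 * 2.5)
})

test_that("increasing the stand effect strictly increases mean SiSt duration", {
  means <- vapply(c(1, 1.5, 2.5), function(k) {
    spec <- cohort_spec_community(
      n_subjects = 50, noise_sd = 0, fall_risk_fraction = 1,
      effects = list(stand_duration = k, sit_duration = 1, gait_speed = 1,
                     cadence = 1))
    co <- generate_cohort(spec, seed = 7)
    mean(vapply(co, function(s) s$truth$phase_durations[["sist"]], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the dominant walking V frequency equals cadence/60 within one DFT bin", {
  spec <- cohort_spec_community(n_subjects = 1, noise_sd = 0,
                                cadence_mean = 110, cadence_sd = 0)
  s <- generate_cohort(spec, seed = 9)[[1]]
  iv <- s$bounds$walk_out
  v <- s$recording$acc$V[(iv[1] + 1):iv[2]]
  n <- length(v)
  amp <- Mod(fft(v - mean(v)))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * s$recording$fs / n
  f_peak <- freqs[which.max(amp)]
  expect_lt(abs(f_peak - s$truth$cadence / 60), s$recording$fs / n)
})

test_that("labels are internally consistent and track the designed classes", {
  spec <- cohort_spec_community(
    n_subjects = 100, fall_risk_fraction = 0.5,
    effects = list(stand_duration = 2.5, sit_duration = 1.5, gait_speed = 0.8,
                   cadence = 0.9))
  co <- generate_cohort(spec, seed = 11)
  risk <- vapply(co, function(s) s$truth$fall_risk, logical(1))
  lab <- do.call(rbind, lapply(co, `[[`, "labels"))
  # stored labels are exactly make_labels of the stored scores
  re <- make_labels(lab$tug_seconds, lab$sfbbs_score)
  expect_identical(re, lab)
  # with shifts this large the designed classes dominate both labelings
  expect_gte(mean(lab$label_tug == as.integer(risk)), 0.8)
  expect_gte(mean(lab$label_sfbbs == as.integer(risk)), 0.8)
  # and the two labelings still disagree for some subjects (imperfect proxy)
  expect_gt(sum(lab$label_tug != lab$label_sfbbs), 0)
})

test_that("write_cohort emits 2n+1 files plus a manifest and round-trips", {
  co <- tiny_cohort(3, seed = 13)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  files <- setdiff(list.files(dir), "manifest.json")
  expect_length(files, 7L)  # 3 recordings + 3 annotations + labels.csv
  expect_true(file.exists(manifest))

  id <- co[[1]]$recording$subject_id
  back <- read_recording(file.path(dir, paste0(id, "_recording.csv")),
                         fs = 30, subject_id = id)
  expect_identical(back$acc, co[[1]]$recording$acc)
  expect_identical(read_annotations(file.path(dir, paste0(id, "_annotations.csv"))),
                   co[[1]]$bounds)

  empty <- structure(list(), class = "tug_cohort",
                     spec = cohort_spec_community(n_subjects = 1))
  dir2 <- withr::local_tempdir()
  write_cohort(empty, dir2)
  expect_setequal(list.files(dir2), c("labels.csv", "manifest.json"))
})
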