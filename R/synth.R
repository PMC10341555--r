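# Synthetic two-cohort TUG accelerometer generator.
#
# Each subject's trace is a phase-wise deterministic template plus Gaussian
# noise: smooth anterior-posterior (AP) + vertical (V) transients for the
# postural transitions, step-frequency oscillations during walking (ML sway
# at the stride frequency), and elevated ML variance plus a centripetal ML
# offset during the 180-degree turn. Signals are m/s^2 with gravity removed.

# smoothstep ramp up/down envelope on [0, 1), ramp fraction rf at each end
ramp_envelope <- function(n, rf) {
  t <- (seq_len(n) - 0.5) / n
  up <- pmin(pmax(t / rf, 0), 1)
  down <- pmin(pmax((1 - t) / rf, 0), 1)
  s <- function(u) u * u * (3 - 2 * u)  # smoothstep
  s(up) * s(down)
}

#' Specify a synthetic TUG cohort
#'
#' Defines the stated world of one simulated cohort: sample size, sampling
#' rate, phase-duration distributions, gait parameters, noise level and the
#' multiplicative effect shifts applied to fall-risk subjects. Walking-bout
#' durations are not drawn; they follow from cadence, step length and the
#' fixed 3 m walkway (each way), keeping gait speed, step length and walk
#' duration mutually consistent.
#'
#' @param n_subjects Number of subjects.
#' @param fs Sampling rate in Hz (30 for the community preset, 45 for stroke).
#' @param phase_means,phase_sds Named numeric vectors with entries `sist`,
#'   `turn`, `stsi`: mean/SD of the transition and turn durations in seconds.
#'   Per-subject draws are truncated below at 0.1 s.
#' @param cadence_mean,cadence_sd Cadence distribution, steps/min.
#' @param step_length_mean,step_length_sd Step length distribution, m.
#' @param distance_m One-way walkway length in m (default 3, the standard TUG).
#' @param noise_sd Additive white-noise SD in m/s^2.
#' @param sway_gain_ml Dimensionless gain on the walking ML sway amplitude.
#' @param fall_risk_fraction Probability that a subject is in the fall-risk
#'   group and receives the effect shifts.
#' @param effects Named list of multiplicative shifts for fall-risk subjects:
#'   `stand_duration`, `sit_duration`, `gait_speed` (acts through step
#'   length), `cadence`.
#' @param padding_s Seated padding before and after the trial, seconds.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param name Cohort tag carried into subject ids.
#' @return An object of class `tug_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 65, fs = 30,
                        phase_means = c(sist = 1.0, turn = 2.0, stsi = 1.3),
                        phase_sds = c(sist = 0.15, turn = 0.25, stsi = 0.15),
                        cadence_mean = 100, cadence_sd = 8,
                        step_length_mean = 0.48, step_length_sd = 0.04,
                        distance_m = 3, noise_sd = 0.25, sway_gain_ml = 1,
                        fall_risk_fraction = 0.2,
                        effects = list(stand_duration = 1.7, sit_duration = 1.3,
                                       gait_speed = 0.85, cadence = 0.95),
                        padding_s = 1, seed = 1L, name = "cohort") {
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be positive")
  for (ph in c("sist", "turn", "stsi")) {
    if (!is_scalar_num(phase_means[[ph]]) || phase_means[[ph]] <= 0)
      stopf("phase mean %s must be positive", ph)
    if (!is_scalar_num(phase_sds[[ph]]) || phase_sds[[ph]] < 0)
      stopf("phase sd %s must be >= 0", ph)
  }
  for (nm in c("cadence_mean", "step_length_mean", "distance_m"))
    if (get(nm) <= 0) stopf("%s must be positive", nm)
  for (nm in c("cadence_sd", "step_length_sd", "noise_sd", "sway_gain_ml", "padding_s"))
    if (get(nm) < 0) stopf("%s must be >= 0", nm)
  if (fall_risk_fraction < 0 || fall_risk_fraction > 1)
    stopf("fall_risk_fraction must be in [0, 1]")
  eff <- list(stand_duration = 1, sit_duration = 1, gait_speed = 1, cadence = 1)
  if (length(effects)) {
    bad <- setdiff(names(effects), names(eff))
    if (length(bad)) stopf("unknown effect(s): %s", paste(bad, collapse = ", "))
    eff[names(effects)] <- effects
  }
  if (any(unlist(eff) <= 0)) stopf("effects must be positive multipliers")
  structure(
    list(n_subjects = as.integer(n_subjects), fs = fs,
         phase_means = phase_means, phase_sds = phase_sds,
         cadence_mean = cadence_mean, cadence_sd = cadence_sd,
         step_length_mean = step_length_mean, step_length_sd = step_length_sd,
         distance_m = distance_m, noise_sd = noise_sd,
         sway_gain_ml = sway_gain_ml, fall_risk_fraction = fall_risk_fraction,
         effects = eff, padding_s = padding_s, seed = as.integer(seed),
         name = name),
    class = "tug_cohort_spec"
  )
}

#' Community-dwelling elderly cohort preset
#'
#' 65 subjects at 30 Hz; the fall-risk stand-duration shift (x1.7) matches
#' the ratio of the reported group means for this population.
#' @param ... Overrides passed to [cohort_spec()].
#' @export
cohort_spec_community <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 65, fs = 30, name = "community")
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

#' Stroke-survivor cohort preset
#'
#' 35 subjects at 45 Hz, slower transitions, higher noise, larger fall-risk
#' shifts (stand duration x2.8 per the reported group-mean ratio). Gait
#' defaults are calibrated so that both TUG label classes occur under the
#' fixed 12.47 s cutoff.
#' @param ... Overrides passed to [cohort_spec()].
#' @export
cohort_spec_stroke <- function(...) {
  args <- list(...)
  defaults <- list(
    n_subjects = 35, fs = 45,
    phase_means = c(sist = 1.27, turn = 2.0, stsi = 1.4),
    phase_sds = c(sist = 0.2, turn = 0.3, stsi = 0.2),
    cadence_mean = 100, cadence_sd = 10,
    step_length_mean = 0.5, step_length_sd = 0.05,
    noise_sd = 0.3, fall_risk_fraction = 0.35,
    effects = list(stand_duration = 2.8, sit_duration = 1.5,
                   gait_speed = 0.8, cadence = 0.9),
    name = "stroke")
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# Simulate the SFBBS score: a logistic latent impairment driven by the
# subject's applied effect shifts, plus noise, mapped onto the 0-28 scale.
# Healthy subjects score high (>= 23 almost always); shifted subjects drop
# below 23 with high but not perfect probability, so the TUG and SFBBS
# labelings agree imperfectly, as real cohorts do.
simulate_sfbbs <- function(applied_effects) {
  z <- sum(abs(log(unlist(applied_effects)))) + rnorm(1, 0, 0.15)
  latent <- stats::plogis(6 * (z - 0.5))
  max(0L, min(28L, 28L - as.integer(round(28 * latent))))
}

# Build one subject's noise-free template given the resolved parameters.
# Returns list(acc = list(ML, V, AP), bounds, n).
build_template <- function(fs, dur, cadence, pad_n) {
  f_step <- cadence / 60  # Hz
  n_ph <- vapply(PHASES, function(p) max(2L, as.integer(round(dur[[p]] * fs))),
                 integer(1))
  segs <- list()
  for (ph in PHASES) {
    n <- n_ph[[ph]]
    t <- (seq_len(n) - 1L) / fs
    ml <- v <- ap <- numeric(n)
    if (ph == "sist") {
      r <- ramp_envelope(n, 0.06)
      ap <- 3.0 * r
      v <- 1.8 * r
    } else if (ph == "stsi") {
      r <- ramp_envelope(n, 0.06)
      ap <- -3.0 * r
      v <- 1.2 * r
    } else if (ph %in% c("walk_out", "walk_back")) {
      v <- 1.5 * sin(2 * pi * f_step * t)
      ap <- 0.8 * sin(2 * pi * f_step * t + pi / 3)
      ml <- 0.4 * sin(2 * pi * (f_step / 2) * t)
    } else { # turn: elevated ML variance (x3 walking) + centripetal offset
      dc <- 1.2 * ramp_envelope(n, 0.08)
      ml <- dc + sqrt(3) * 0.4 * sin(2 * pi * f_step * t)
      v <- 1.0 * sin(2 * pi * f_step * t)
      ap <- 0.5 * sin(2 * pi * f_step * t + pi / 3)
    }
    segs[[ph]] <- cbind(ML = ml, V = v, AP = ap)
  }
  pad <- matrix(0, nrow = pad_n, ncol = 3,
                dimnames = list(NULL, AXES))
  full <- rbind(pad, do.call(rbind, segs[PHASES]), pad)
  offs <- pad_n + c(0L, cumsum(n_ph))
  bounds <- phase_bounds(
    sist = c(offs[1L], offs[2L]), walk_out = c(offs[2L], offs[3L]),
    turn = c(offs[3L], offs[4L]), walk_back = c(offs[4L], offs[5L]),
    stsi = c(offs[5L], offs[6L]), n = nrow(full))
  list(acc = list(ML = full[, "ML"], V = full[, "V"], AP = full[, "AP"]),
       bounds = bounds, n = nrow(full))
}

#' Generate a synthetic TUG cohort
#'
#' Deterministic given the seed. Each subject is drawn fall-risk with
#' probability `fall_risk_fraction` and, if so, receives the spec's
#' multiplicative effect shifts (longer transitions, shorter/slower steps).
#' Walking-bout durations are `distance_m / gait_speed` with
#' `gait_speed = cadence/60 * step_length`, so the generator's ground-truth
#' gait parameters are mutually consistent. The simulated TUG duration is
#' the exact sum of the five continuous phase durations; the SFBBS score is
#' simulated from a noisy logistic latent impairment (see the vignette).
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A list of class `tug_cohort`; each element has fields
#'   `recording` ([tug_recording()]), `bounds` (ground-truth
#'   [phase_bounds()]), `truth` (cadence, step length, gait speed, the five
#'   phase durations, fall-risk status) and `labels` (a row of
#'   [make_labels()] output).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "tug_cohort_spec"))
  subjects <- with_seed(seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      at_risk <- runif(1) < spec$fall_risk_fraction
      eff <- if (at_risk) spec$effects else
        list(stand_duration = 1, sit_duration = 1, gait_speed = 1, cadence = 1)
      draw <- function(m, s) max(0.1, rnorm(1, m, s))
      sist <- draw(spec$phase_means[["sist"]], spec$phase_sds[["sist"]]) *
        eff$stand_duration
      turn <- draw(spec$phase_means[["turn"]], spec$phase_sds[["turn"]])
      stsi <- draw(spec$phase_means[["stsi"]], spec$phase_sds[["stsi"]]) *
        eff$sit_duration
      cadence <- max(30, rnorm(1, spec$cadence_mean, spec$cadence_sd)) *
        eff$cadence
      step_len <- max(0.05, rnorm(1, spec$step_length_mean, spec$step_length_sd)) *
        eff$gait_speed
      speed <- cadence / 60 * step_len
      walk_each <- spec$distance_m / speed
      dur <- list(sist = sist, walk_out = walk_each, turn = turn,
                  walk_back = walk_each, stsi = stsi)
      tug_seconds <- sist + 2 * walk_each + turn + stsi
      sfbbs <- simulate_sfbbs(eff)

      tmpl <- build_template(spec$fs, dur, cadence,
                             pad_n = max(2L, round(spec$padding_s * spec$fs)))
      acc <- tmpl$acc
      # sway gain applies to the ML template (oscillation + turn offset),
      # not to the additive noise
      if (spec$sway_gain_ml != 1) acc$ML <- acc$ML * spec$sway_gain_ml
      if (spec$noise_sd > 0) {
        for (ax in AXES) acc[[ax]] <- acc[[ax]] + rnorm(tmpl$n, 0, spec$noise_sd)
      }
      rec <- tug_recording(sprintf("%s_%03d", spec$name, i), spec$fs, acc)
      labels <- make_labels(tug_seconds, sfbbs)
      list(
        recording = rec, bounds = tmpl$bounds,
        truth = list(cadence = cadence, step_length = step_len,
                     gait_speed = speed, phase_durations = unlist(dur),
                     fall_risk = at_risk),
        labels = labels
      )
    })
  })
  structure(subjects, class = "tug_cohort", spec = spec)
}

#' @export
print.tug_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  nf <- sum(vapply(x, function(s) s$truth$fall_risk, logical(1)))
  cat(sprintf("<tug_cohort> %s: %d subjects @ %g Hz (%d fall-risk by design)\n",
              spec$name, length(x), spec$fs, nf))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one recording CSV and one annotation CSV per subject, a
#' cohort-level `labels.csv` (subject_id, tug_seconds, sfbbs_score), and a
#' JSON manifest listing all files.
#'
#' @param cohort A `tug_cohort`.
#' @param directory Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "tug_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory %s", directory)
  files <- character(0)
  rows <- lapply(cohort, function(s) {
    id <- s$recording$subject_id
    rec_f <- file.path(directory, paste0(id, "_recording.csv"))
    ann_f <- file.path(directory, paste0(id, "_annotations.csv"))
    write_recording(s$recording, rec_f)
    write_annotations(s$bounds, ann_f)
    files <<- c(files, rec_f, ann_f)
    data.frame(subject_id = id, tug_seconds = s$labels$tug_seconds,
               sfbbs_score = s$labels$sfbbs_score)
  })
  labels_f <- file.path(directory, "labels.csv")
  lab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), tug_seconds = numeric(0),
               sfbbs_score = integer(0))
  write.csv(lab, labels_f, row.names = FALSE, quote = FALSE)
  files <- c(files, labels_f)
  spec <- attr(cohort, "spec")
  manifest <- file.path(directory, "manifest.json")
  jsonlite::write_json(
    list(cohort = spec$name, fs = spec$fs, n_subjects = length(cohort),
         files = basename(files)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
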