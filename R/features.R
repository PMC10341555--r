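# The 79-feature catalogue computed per subject from a segmented recording:
# full-TUG entropy block (12), sit-to-stand block (22), walk block (11),
# turn block (12), stand-to-sit block (22).

#' Feature schema
#'
#' The canonical 79-feature catalogue: feature number, key, block and axis.
#' Axis-resolved features expand over ML, V, AP in that order. Walk features
#' are computed on the concatenation of the two walking bouts (turn
#' excluded); durations are phase-interval lengths in seconds; CV features
#' are in percent.
#'
#' @return A data.frame with columns `number`, `name`, `block`, `axis`.
#' @export
feature_schema <- function() {
  ax3 <- function(stub) paste0(stub, "_", AXES)
  defs <- list(
    list("tug", ax3("mse_mean_tug")),
    list("tug", ax3("mse_sd_tug")),
    list("tug", ax3("mse_ci_tug")),
    list("tug", ax3("pe_tug")),
    list("sist", "stand_duration"),
    list("sist", ax3("range_sist")),
    list("sist", ax3("max_sist")),
    list("sist", ax3("rms_sist")),
    list("sist", ax3("max_jerk_sist")),
    list("sist", ax3("min_sist")),
    list("sist", ax3("mean_jerk_sist")),
    list("sist", ax3("sd_sist")),
    list("walk", c("walk_duration", "cadence", "step_length", "gait_speed",
                   "step_time", "stride_time", "cv_step_time", "cv_stride_time")),
    list("walk", ax3("rms_walk")),
    list("turn", ax3("cv_turn")),
    list("turn", ax3("median_turn")),
    list("turn", ax3("range_turn")),
    list("turn", ax3("rms_turn")),
    list("stsi", "sit_duration"),
    list("stsi", ax3("range_stsi")),
    list("stsi", ax3("rms_stsi")),
    list("stsi", ax3("min_stsi")),
    list("stsi", ax3("max_stsi")),
    list("stsi", ax3("max_jerk_stsi")),
    list("stsi", ax3("mean_jerk_stsi")),
    list("stsi", ax3("sd_stsi"))
  )
  name <- unlist(lapply(defs, `[[`, 2L))
  block <- unlist(lapply(defs, function(d) rep(d[[1L]], length(d[[2L]]))))
  axis <- ifelse(grepl("_(ML|V|AP)$", name), sub(".*_(ML|V|AP)$", "\\1", name), "")
  data.frame(number = seq_along(name), name = name, block = block, axis = axis,
             stringsAsFactors = FALSE)
}

#' Names of the 79 features in catalogue order
#' @export
feature_names <- function() feature_schema()$name

#' Root mean square of a segment
#' @param x Non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0L) stopf("rms of an empty segment")
  sqrt(mean(x^2))
}

#' Jerk series and summaries
#'
#' Jerk is the first time-derivative of acceleration, estimated with a
#' central first difference scaled by the sampling rate (one-sided at the
#' endpoints). Summaries are direction-agnostic: `max_jerk = max(|jerk|)`,
#' `mean_jerk = mean(|jerk|)`.
#'
#' @param x Numeric vector, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return `jerk_series`: numeric vector of the same length as `x`.
#' @export
jerk_series <- function(x, fs) {
  n <- length(x)
  if (n < 2L) stopf("jerk needs at least 2 samples")
  j <- numeric(n)
  j[1L] <- (x[2L] - x[1L]) * fs
  j[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) j[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  j
}

#' @rdname jerk_series
#' @export
max_jerk <- function(x, fs) max(abs(jerk_series(x, fs)))

#' @rdname jerk_series
#' @export
mean_jerk <- function(x, fs) mean(abs(jerk_series(x, fs)))

#' Descriptive statistics of a segment
#'
#' Range, max, min, median, sample SD, and CV (percent, `100 * sd/|mean|`).
#' The CV is 0 for a constant segment and flagged missing (`NA`) when the
#' mean is negligible relative to the SD (`|mean| < 1e-9 * sd`), where the
#' ratio would explode.
#'
#' @param x Non-empty numeric vector.
#' @return Named list with `range`, `max`, `min`, `median`, `sd`, `cv`.
#' @export
descriptive_block <- function(x) {
  if (length(x) == 0L) stopf("descriptive_block of an empty segment")
  s <- if (length(x) > 1L) sd(x) else 0
  m <- mean(x)
  cv <- if (s == 0) 0
        else if (abs(m) < 1e-9 * s) NA_real_
        else 100 * s / abs(m)
  list(range = max(x) - min(x), max = max(x), min = min(x),
       median = median(x), sd = s, cv = cv)
}

# Brick-wall FFT band-pass; deterministic, no external filter dependency.
bandpass_fft <- function(x, fs, lo = 0.5, hi = 3) {
  n <- length(x)
  if (n < 4L) return(x - mean(x))
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  xf <- fft(x)
  xf[freqs < lo | freqs > hi] <- 0
  Re(fft(xf, inverse = TRUE)) / n
}

#' Detect step events in the walking bouts
#'
#' Heel-strike proxies: local maxima of the 0.5-3 Hz band-passed vertical
#' signal, at least `min_sep` seconds apart and above 30% of the bout's
#' peak filtered amplitude. Each walking bout is processed separately so no
#' spurious interval spans the turn; step intervals are differences of
#' consecutive events within a bout.
#'
#' @param segments A numeric vector (one bout) or list of numeric vectors
#'   (one per bout), normally the vertical axis.
#' @param fs Sampling rate in Hz.
#' @param min_sep Minimum event separation in seconds (default 0.25).
#' @return A `tug_step_events` list: `events` (per-bout sample indices,
#'   1-based within bout), `step_intervals` (s), `stride_intervals` (s,
#'   non-overlapping sums of adjacent step-interval pairs starting at the
#'   first event of each bout), and `n_steps` (total number of step
#'   intervals).
#' @export
detect_steps <- function(segments, fs, min_sep = 0.25) {
  if (!is.list(segments)) segments <- list(segments)
  total_dur <- sum(vapply(segments, length, integer(1))) / fs
  if (total_dur < 1) stopf("walking data shorter than 1 s")
  events <- lapply(segments, function(x) {
    f <- bandpass_fft(x, fs)
    n <- length(f)
    if (n < 3L || max(abs(f)) == 0) return(integer(0))
    cand <- which(f[2:(n - 1L)] > f[1:(n - 2L)] & f[2:(n - 1L)] >= f[3:n]) + 1L
    cand <- cand[f[cand] > 0.3 * max(f)]
    if (length(cand) == 0L) return(integer(0))
    # greedy non-maximum suppression: keep highest peaks >= min_sep apart
    keep <- integer(0)
    for (i in cand[order(-f[cand], cand)]) {
      if (all(abs(i - keep) >= min_sep * fs)) keep <- c(keep, i)
    }
    sort(keep)
  })
  n_events <- sum(vapply(events, length, integer(1)))
  if (n_events < 2L) stopf("step detection failed: fewer than 2 step events")
  step_iv <- unlist(lapply(events, function(e) diff(e) / fs))
  stride_iv <- unlist(lapply(events, function(e) {
    iv <- diff(e) / fs
    k <- length(iv) %/% 2L
    if (k == 0L) return(numeric(0))
    vapply(seq_len(k), function(j) iv[2L * j - 1L] + iv[2L * j], numeric(1))
  }))
  structure(list(events = events, step_intervals = step_iv,
                 stride_intervals = stride_iv, n_steps = length(step_iv)),
            class = "tug_step_events")
}

#' Gait features from step events
#'
#' `step_time` is the mean step interval and `stride_time` the mean of the
#' non-overlapping sums of adjacent step intervals; `cadence = 60/step_time`
#' (steps/min); `gait_speed = distance/walk_duration`; `step_length =
#' distance/n_steps` with the number of steps taken as the effective count
#' `walk_duration/step_time` implied by the mean step interval (fencepost-
#' free, so `gait_speed = cadence/60 * step_length` holds as an exact
#' algebraic identity); CVs are `100 * sd/mean` of the respective interval
#' sequences.
#'
#' @param events A `tug_step_events` with at least 3 events (>= 2 step
#'   intervals), so stride statistics exist.
#' @param walk_duration Total walking time in seconds (both bouts).
#' @param distance Total walking distance in m (both bouts).
#' @return Named list with `walk_duration`, `cadence`, `step_length`,
#'   `gait_speed`, `step_time`, `stride_time`, `cv_step_time`,
#'   `cv_stride_time`.
#' @export
gait_features <- function(events, walk_duration, distance) {
  stopifnot(inherits(events, "tug_step_events"))
  if (events$n_steps < 2L)
    stopf("gait features need at least 3 step events (2 step intervals)")
  if (walk_duration <= 0 || distance <= 0)
    stopf("walk_duration and distance must be positive")
  st <- events$step_intervals
  sr <- events$stride_intervals
  cv <- function(v) if (length(v) < 2L) 0 else 100 * sd(v) / mean(v)
  step_time <- mean(st)
  n_steps_eff <- walk_duration / step_time
  list(
    walk_duration = walk_duration,
    cadence = 60 / step_time,
    step_length = distance / n_steps_eff,
    gait_speed = distance / walk_duration,
    step_time = step_time,
    stride_time = if (length(sr)) mean(sr) else 2 * step_time,
    cv_step_time = cv(st),
    cv_stride_time = cv(sr)
  )
}

#' Extract the 79-feature vector of a segmented recording
#'
#' Assembles all five blocks:
#' \itemize{
#'   \item full-TUG: MSE mean/SD/complexity index and permutation entropy
#'     per axis, computed on the trial span (sit-to-stand start through
#'     stand-to-sit end);
#'   \item sit-to-stand / stand-to-sit: the phase duration plus range, max,
#'     min, RMS, SD and jerk summaries per axis;
#'   \item walk: duration, cadence, step length, gait speed, step/stride
#'     time and their CVs from vertical-axis step detection on the two
#'     concatenated bouts, plus RMS per axis;
#'   \item turn: CV, median, range, RMS per axis.
#' }
#' A failing block yields `NA` for its features plus a warning, never a
#' silently truncated vector.
#'
#' @param rec A [tug_recording()].
#' @param bounds A [phase_bounds()] for `rec`.
#' @param mse,pe Entropy parameters ([mse_params()], [pe_params()]).
#' @param distance One-way walkway length in m (default 3; the walk block
#'   uses `2 * distance` as the total distance over both bouts).
#' @return A named numeric vector of class `tug_feature_vector` with
#'   exactly the 79 entries of [feature_schema()], possibly containing
#'   flagged `NA`s.
#' @export
extract_features <- function(rec, bounds, mse = mse_params(), pe = pe_params(),
                             distance = 3) {
  stopifnot(inherits(rec, "tug_recording"), inherits(bounds, "tug_phase_bounds"))
  if (bounds$stsi[2L] > rec$n) stopf("bounds extend beyond the recording")
  fv <- setNames(rep(NA_real_, 79L), feature_names())
  fs <- rec$fs
  fill_block <- function(expr, keys) {
    vals <- tryCatch(expr, error = function(e) {
      warnf("feature block {%s...} failed: %s", keys[1L], conditionMessage(e))
      NULL
    })
    if (!is.null(vals)) fv[keys] <<- unlist(vals)[keys]
  }

  # full-TUG entropy block on the trial span
  trial <- c(bounds$sist[1L] + 1L, bounds$stsi[2L])
  for (ax in AXES) {
    sig <- rec$acc[[ax]][trial[1L]:trial[2L]]
    keys <- paste0(c("mse_mean_tug_", "mse_sd_tug_", "mse_ci_tug_", "pe_tug_"), ax)
    fill_block({
      prof <- mse_profile(sig, mse)
      list(mse_mean = mse_mean(prof), mse_sd = mse_sd(prof),
           mse_ci = complexity_index(prof),
           pe = permutation_entropy(sig, pe)) |>
        setNames(keys)
    }, keys)
  }

  # transition blocks
  for (ph in c("sist", "stsi")) {
    dur_key <- if (ph == "sist") "stand_duration" else "sit_duration"
    fv[dur_key] <- phase_duration(bounds, ph, fs)
    for (ax in AXES) {
      keys <- paste0(c("range_", "max_", "min_", "rms_", "sd_",
                       "max_jerk_", "mean_jerk_"), ph, "_", ax)
      # stsi block has no median/cv; sist likewise
      keys <- intersect(keys, feature_names())
      fill_block({
        x <- phase_slice(rec, bounds, ph, ax)
        d <- descriptive_block(x)
        out <- c(d$range, d$max, d$min, rms(x), d$sd,
                 max_jerk(x, fs), mean_jerk(x, fs))
        setNames(as.list(out), paste0(c("range_", "max_", "min_", "rms_", "sd_",
                                        "max_jerk_", "mean_jerk_"), ph, "_", ax))
      }, keys)
    }
  }

  # walk block: concatenated bouts, turn excluded
  walk_keys <- c("walk_duration", "cadence", "step_length", "gait_speed",
                 "step_time", "stride_time", "cv_step_time", "cv_stride_time")
  fill_block({
    segs <- list(phase_slice(rec, bounds, "walk_out", "V"),
                 phase_slice(rec, bounds, "walk_back", "V"))
    ev <- detect_steps(segs, fs)
    wd <- phase_duration(bounds, "walk_out", fs) +
      phase_duration(bounds, "walk_back", fs)
    gait_features(ev, wd, 2 * distance)
  }, walk_keys)
  for (ax in AXES) {
    key <- paste0("rms_walk_", ax)
    fill_block({
      x <- c(phase_slice(rec, bounds, "walk_out", ax),
             phase_slice(rec, bounds, "walk_back", ax))
      setNames(list(rms(x)), key)
    }, key)
  }

  # turn block
  for (ax in AXES) {
    keys <- paste0(c("cv_turn_", "median_turn_", "range_turn_", "rms_turn_"), ax)
    fill_block({
      x <- phase_slice(rec, bounds, "turn", ax)
      d <- descriptive_block(x)
      setNames(list(d$cv, d$median, d$range, rms(x)), keys)
    }, keys)
  }

  structure(fv, class = c("tug_feature_vector", "numeric"),
            subject_id = rec$subject_id)
}

#' Feature matrix and labels for a whole cohort
#'
#' Runs [extract_features()] on every subject of a synthetic cohort using
#' its ground-truth bounds (annotated mode) and collects the clinical
#' labels, giving the inputs the ranking/classification pipeline expects.
#'
#' @param cohort A `tug_cohort` from [generate_cohort()].
#' @param mse,pe,distance Passed to [extract_features()].
#' @return List with `X` (n x 79 matrix, subjects in rows) and `labels`
#'   (data.frame from [make_labels()], one row per subject).
#' @export
cohort_features <- function(cohort, mse = mse_params(), pe = pe_params(),
                            distance = 3) {
  stopifnot(inherits(cohort, "tug_cohort"))
  X <- t(vapply(cohort, function(s)
    as.numeric(extract_features(s$recording, s$bounds, mse, pe, distance)),
    numeric(79L)))
  colnames(X) <- feature_names()
  rownames(X) <- vapply(cohort, function(s) s$recording$subject_id, character(1))
  labels <- do.call(rbind, lapply(cohort, function(s) s$labels))
  list(X = X, labels = labels)
}
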