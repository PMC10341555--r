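# TUG phase segmentation.
#
# The trial structure is sit-to-stand, walk out, 180-degree turn, walk back,
# stand-to-sit. Annotated mode trusts supplied boundaries; auto mode detects
# them from the signals: the two postural transitions as sustained
# anterior-posterior (AP) excursions from the seated baseline, the turn as
# the period of maximal short-window mediolateral (ML) variance between them.

# centered moving average, window w samples (forced odd)
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centered rolling variance about the local mean (robust to slow drifts)
rolling_var <- function(x, w) {
  hp <- x - moving_avg(x, w)
  moving_avg(hp^2, w)
}

# Find the first (or last) run of `x > thr` lasting >= min_len samples.
find_sustained_run <- function(x, thr, min_len, from_end = FALSE) {
  above <- x > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (length(ok) == 0L) return(NULL)
  i <- if (from_end) ok[length(ok)] else ok[1L]
  c(starts[i], ends[i])
}

# Expand from a peak to the half-amplitude crossings. 1-based inclusive.
expand_to_fraction <- function(x, peak_idx, frac, lo_lim, hi_lim) {
  thr <- frac * x[peak_idx]
  s <- peak_idx
  while (s > lo_lim && x[s - 1L] >= thr) s <- s - 1L
  e <- peak_idx
  while (e < hi_lim && x[e + 1L] >= thr) e <- e + 1L
  c(s, e)
}

#' Segment a TUG recording into its five phases
#'
#' In `annotated` mode the supplied boundaries are validated and returned
#' unchanged. In `auto` mode phases are detected from the signals:
#' \enumerate{
#'   \item the sit-to-stand is the first sustained AP excursion above the
#'     seated baseline (default 0.15 g for at least 0.25 s), with its
#'     boundaries refined to the half-amplitude crossings of the smoothed
#'     excursion envelope;
#'   \item the stand-to-sit is detected symmetrically at the trial end;
#'   \item the turn is the region of elevated short-window ML second moment
#'     about the walking baseline (turning adds sway variance plus a
#'     centripetal ML offset), thresholded midway between the walking floor
#'     and the turn plateau with one refinement pass;
#'   \item the walking bouts are the gaps between transition and turn.
#' }
#' Step oscillations are suppressed before envelope thresholding with a
#' centered moving average (default 0.3 s), which attenuates cadence-band
#' components while leaving the slow postural transients nearly intact.
#'
#' @param rec A [tug_recording()].
#' @param mode `"annotated"` or `"auto"`.
#' @param annotations A [phase_bounds()], required in annotated mode.
#' @param threshold AP excursion threshold in signal units; default 0.15 g
#'   expressed in m/s^2 (`0.15 * 9.80665`), matching the generator's units.
#' @param sustain Minimum suprathreshold duration in seconds (default 0.25).
#' @param smooth_win Envelope smoothing window in seconds (default 0.3).
#' @param var_win ML rolling-variance window in seconds (default 0.6).
#' @return A valid [phase_bounds()] (0-based half-open intervals).
#' @export
segment_phases <- function(rec, mode = c("annotated", "auto"), annotations = NULL,
                           threshold = 0.15 * 9.80665, sustain = 0.25,
                           smooth_win = 0.3, var_win = 0.6) {
  stopifnot(inherits(rec, "tug_recording"))
  mode <- match.arg(mode)
  if (mode == "annotated") {
    if (is.null(annotations)) stopf("annotated mode requires annotations")
    if (!inherits(annotations, "tug_phase_bounds"))
      stopf("annotations must be a tug_phase_bounds object")
    if (annotations$stsi[2L] > rec$n)
      stopf("annotations extend beyond the recording (n = %d)", rec$n)
    return(annotations)
  }

  fs <- rec$fs
  if (rec$n / fs < 3) stopf("segmentation failed: recording shorter than 3 s")
  ap <- rec$acc$AP
  n <- rec$n
  base_win <- max(2L, round(0.5 * fs))
  base_start <- mean(ap[seq_len(base_win)])
  base_end <- mean(ap[(n - base_win + 1L):n])

  sm_w <- round(smooth_win * fs)
  dev_start <- abs(moving_avg(ap - base_start, sm_w))
  dev_end <- abs(moving_avg(ap - base_end, sm_w))
  min_len <- max(1L, round(sustain * fs))

  run1 <- find_sustained_run(dev_start, threshold, min_len)
  if (is.null(run1)) stopf("segmentation failed: no sit-to-stand transient found")
  p1 <- run1[1L] - 1L + which.max(dev_start[run1[1L]:run1[2L]])
  sist <- expand_to_fraction(dev_start, p1, 0.5, 1L, n)

  run2 <- find_sustained_run(dev_end, threshold, min_len, from_end = TRUE)
  if (is.null(run2)) stopf("segmentation failed: no stand-to-sit transient found")
  p2 <- run2[1L] - 1L + which.max(dev_end[run2[1L]:run2[2L]])
  stsi <- expand_to_fraction(dev_end, p2, 0.5, 1L, n)

  if (stsi[1L] <= sist[2L] + 2L)
    stopf("segmentation failed: transitions overlap (no walking interval)")

  mid_lo <- sist[2L] + 1L
  mid_hi <- stsi[1L] - 1L
  # Short-window ML second moment about the walking baseline. Turning adds
  # both extra sway variance and a sustained centripetal ML offset, so the
  # second moment about the walking mean (not the local mean) separates the
  # turn from steady gait far more sharply than a locally centered variance.
  w_var <- round(var_win * fs)
  ml_mid <- rec$acc$ML[mid_lo:mid_hi]
  baseline_ml <- median(moving_avg(ml_mid, w_var))
  ml_var <- moving_avg((ml_mid - baseline_ml)^2, w_var)
  if (length(ml_var) < 4L) stopf("segmentation failed: walking interval too short")
  pk <- which.max(ml_var)
  # walking floor and turn plateau from robust quantiles (the turn occupies
  # a minority of the walking interval)
  floor_var <- quantile(ml_var, 0.3, names = FALSE)
  peak_var <- quantile(ml_var, 0.9, names = FALSE)
  expand <- function(thr) {
    s <- pk; while (s > 1L && ml_var[s - 1L] >= thr) s <- s - 1L
    e <- pk; while (e < length(ml_var) && ml_var[e + 1L] >= thr) e <- e + 1L
    c(s, e)
  }
  se <- expand(floor_var + 0.5 * (peak_var - floor_var))
  # one refinement pass: re-estimate plateau/floor from the provisional
  # interval, then re-expand at their midpoint (debiases the quantile
  # references, whose accuracy depends on the turn/walk duration ratio)
  inside <- seq(se[1L], se[2L])
  if (length(inside) >= 4L && length(inside) < length(ml_var) - 4L) {
    plateau <- median(ml_var[inside])
    floor2 <- median(ml_var[-inside])
    se <- expand((plateau + floor2) / 2)
  }
  turn <- c(mid_lo + se[1L] - 1L, mid_lo + se[2L] - 1L)

  if (turn[1L] <= mid_lo + 1L || turn[2L] >= mid_hi - 1L)
    stopf("segmentation failed: turn not separated from the transitions")

  # 1-based inclusive -> 0-based half-open
  out <- try(phase_bounds(
    sist = c(sist[1L] - 1L, sist[2L]),
    walk_out = c(sist[2L], turn[1L] - 1L),
    turn = c(turn[1L] - 1L, turn[2L]),
    walk_back = c(turn[2L], stsi[1L] - 1L),
    stsi = c(stsi[1L] - 1L, stsi[2L]),
    n = n
  ), silent = TRUE)
  if (inherits(out, "try-error"))
    stopf("segmentation failed: detected intervals violate phase ordering")
  out
}
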