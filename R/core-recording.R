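#' Construct a triaxial TUG accelerometer recording
#'
#' A recording holds one subject's waist-worn accelerometer trace during a
#' Timed-Up-and-Go trial: three equal-length acceleration series on the
#' mediolateral (ML), vertical (V) and anterior-posterior (AP) axes, sampled
#' at a fixed rate. Signals are treated unit-agnostically (the synthetic
#' generator emits m/s^2 with gravity removed); only jerk features depend on
#' the sampling rate.
#'
#' @param subject_id Opaque subject identifier (length-1 character).
#' @param fs Sampling rate in Hz; must be a positive finite number.
#' @param acc Named list with numeric components `ML`, `V`, `AP`, all finite
#'   and of identical length `n >= 2`.
#' @return An object of class `tug_recording` with fields `subject_id`, `fs`,
#'   `acc` (named list of the three axis series) and `n`.
#' @examples
#' rec <- tug_recording("s1", fs = 30,
#'                      acc = list(ML = rnorm(90), V = rnorm(90), AP = rnorm(90)))
#' rec$n / rec$fs  # duration in seconds
#' @export
tug_recording <- function(subject_id, fs, acc) {
  if (length(subject_id) != 1L) stopf("subject_id must be a single identifier")
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive finite number")
  if (!is.list(acc) || !setequal(names(acc), AXES))
    stopf("acc must be a named list with axes exactly {ML, V, AP}")
  acc <- acc[AXES]
  lens <- vapply(acc, length, integer(1))
  if (length(unique(lens)) != 1L)
    stopf("axis series have unequal lengths (%s)", paste(lens, collapse = ", "))
  n <- lens[[1L]]
  if (n < 2L) stopf("recording needs at least 2 samples per axis, got %d", n)
  for (ax in AXES) {
    if (!is.numeric(acc[[ax]])) stopf("axis %s is not numeric", ax)
    if (any(!is.finite(acc[[ax]]))) stopf("axis %s contains non-finite samples", ax)
    acc[[ax]] <- as.numeric(acc[[ax]])
  }
  structure(
    list(subject_id = as.character(subject_id), fs = as.numeric(fs),
         acc = acc, n = as.integer(n)),
    class = "tug_recording"
  )
}

#' @export
print.tug_recording <- function(x, ...) {
  cat(sprintf("<tug_recording> subject %s: %d samples/axis @ %g Hz (%.2f s)\n",
              x$subject_id, x$n, x$fs, x$n / x$fs))
  invisible(x)
}

#' Construct TUG phase boundaries
#'
#' Five half-open, 0-based sample-index intervals `[start, end)` delimiting
#' the sit-to-stand (`sist`), outbound walk (`walk_out`), turn (`turn`),
#' return walk (`walk_back`) and stand-to-sit (`stsi`) phases of a TUG trial.
#' Intervals must be non-empty, non-overlapping and in temporal order; they
#' need not cover the whole recording (pre- and post-trial sitting is
#' typically excluded).
#'
#' @param sist,walk_out,turn,walk_back,stsi Length-2 integer vectors
#'   `c(start, end)`, 0-based half-open.
#' @param n Optional recording length; when given, all indices are checked
#'   against `[0, n]`.
#' @return An object of class `tug_phase_bounds`: a named list of length-2
#'   integer vectors.
#' @export
phase_bounds <- function(sist, walk_out, turn, walk_back, stsi, n = NULL) {
  b <- list(sist = sist, walk_out = walk_out, turn = turn,
            walk_back = walk_back, stsi = stsi)
  for (ph in PHASES) {
    iv <- b[[ph]]
    if (length(iv) != 2L || !is.numeric(iv) || any(!is.finite(iv)) ||
        any(iv != floor(iv)))
      stopf("phase %s must be an integer c(start, end) pair", ph)
    if (iv[2L] <= iv[1L]) stopf("phase %s interval [%d, %d) is empty", ph, iv[1L], iv[2L])
    if (iv[1L] < 0) stopf("phase %s starts before sample 0", ph)
    b[[ph]] <- as.integer(iv)
  }
  for (i in seq_len(length(PHASES) - 1L)) {
    a <- b[[PHASES[i]]]; nx <- b[[PHASES[i + 1L]]]
    if (nx[1L] < a[2L])
      stopf("phases %s and %s overlap or are out of order", PHASES[i], PHASES[i + 1L])
  }
  if (!is.null(n) && b$stsi[2L] > n)
    stopf("phase stsi ends at %d, beyond recording length %d", b$stsi[2L], n)
  structure(b, class = "tug_phase_bounds")
}

#' @export
print.tug_phase_bounds <- function(x, ...) {
  cat("<tug_phase_bounds> [start, end) per phase:\n")
  for (ph in PHASES) cat(sprintf("  %-9s [%d, %d)\n", ph, x[[ph]][1L], x[[ph]][2L]))
  invisible(x)
}

# Extract one phase's samples for a given axis (0-based half-open bounds).
phase_slice <- function(rec, bounds, phase, axis) {
  iv <- bounds[[phase]]
  rec$acc[[axis]][(iv[1L] + 1L):iv[2L]]
}

phase_duration <- function(bounds, phase, fs) {
  iv <- bounds[[phase]]
  (iv[2L] - iv[1L]) / fs
}

#' Read a recording from a delimited text file
#'
#' Expects a headered CSV with columns `ML`, `V`, `AP` (an optional leading
#' `time` column is ignored), or any >= 3 numeric columns mapped to axes via
#' `axis_order` when the header does not name the axes.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz.
#' @param subject_id Identifier stored in the recording; defaults to the
#'   file name without extension.
#' @param axis_order Permutation of `c("ML","V","AP")` giving the meaning of
#'   the first three non-time columns when the header does not name them.
#' @return A [tug_recording()].
#' @export
read_recording <- function(path, fs, subject_id = NULL, axis_order = AXES) {
  if (!file.exists(path)) stopf("recording file not found: %s", path)
  if (!setequal(axis_order, AXES) || length(axis_order) != 3L)
    stopf("axis_order must be a permutation of {ML, V, AP}")
  df <- read.csv(path, check.names = FALSE)
  if ("time" %in% names(df)) df <- df[setdiff(names(df), "time")]
  if (all(AXES %in% names(df))) {
    df <- df[AXES]
  } else {
    if (ncol(df) < 3L)
      stopf("expected 3 acceleration columns, found %d in %s", ncol(df), path)
    df <- df[seq_len(3L)]
    names(df) <- axis_order
    df <- df[AXES]
  }
  if (nrow(df) < 2L) stopf("recording %s has fewer than 2 rows", path)
  for (ax in AXES) {
    col <- df[[ax]]
    if (!is.numeric(col)) stopf("non-numeric cell in axis column %s of %s", ax, path)
    if (any(!is.finite(col))) stopf("non-finite sample in axis column %s of %s", ax, path)
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  tug_recording(subject_id, fs, as.list(df))
}

#' Write a recording to CSV
#'
#' Writes columns `time,ML,V,AP` with full double precision so that
#' [read_recording()] round-trips bit-exactly.
#'
#' @param rec A [tug_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tug_recording"))
  df <- data.frame(time = (seq_len(rec$n) - 1L) / rec$fs,
                   ML = rec$acc$ML, V = rec$acc$V, AP = rec$acc$AP)
  # format() with digits=17 keeps doubles exact under read.csv
  out <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = TRUE), character(nrow(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read phase annotations from CSV
#'
#' @param path CSV with columns `phase,start,end` (0-based half-open indices),
#'   one row per phase.
#' @param n Optional recording length for bounds checking.
#' @return A [phase_bounds()].
#' @export
read_annotations <- function(path, n = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  df <- read.csv(path)
  if (!all(c("phase", "start", "end") %in% names(df)))
    stopf("annotations need columns phase,start,end")
  if (!setequal(df$phase, PHASES))
    stopf("annotations must name exactly the phases %s", paste(PHASES, collapse = ", "))
  rows <- df[match(PHASES, df$phase), ]
  args <- lapply(seq_len(5L), function(i) c(rows$start[i], rows$end[i]))
  names(args) <- PHASES
  do.call(phase_bounds, c(args, list(n = n)))
}

#' Write phase annotations to CSV
#' @param bounds A [phase_bounds()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(bounds, path) {
  stopifnot(inherits(bounds, "tug_phase_bounds"))
  df <- data.frame(phase = PHASES,
                   start = vapply(PHASES, function(p) bounds[[p]][1L], integer(1)),
                   end = vapply(PHASES, function(p) bounds[[p]][2L], integer(1)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
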