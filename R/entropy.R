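# Multiscale sample entropy and permutation entropy.
#
# Conventions (documented in the vignette): coarse-graining averages
# non-overlapping blocks; sample entropy uses Chebyshev distance with
# self-matches excluded; the multiscale tolerance r is fixed as a fraction
# of the SD of the original (scale-1) series across all scales; ordinal
# patterns break ties by temporal order; permutation entropy is in bits.

#' Multiscale-entropy parameters
#'
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the scale-1 series SD (default 0.15).
#' @param tau_max Maximum coarse-graining scale (default 5).
#' @return A `tug_mse_params` list.
#' @export
mse_params <- function(m = 2L, r = 0.15, tau_max = 5L) {
  if (!is_count(m)) stopf("m must be a positive integer")
  if (!is_scalar_num(r) || r <= 0) stopf("r must be > 0")
  if (!is_count(tau_max)) stopf("tau_max must be a positive integer")
  structure(list(m = as.integer(m), r = r, tau_max = as.integer(tau_max)),
            class = "tug_mse_params")
}

#' Permutation-entropy parameters
#'
#' @param D Embedding dimension (integer >= 2, default 3).
#' @param tau Embedding delay in samples (default 1).
#' @return A `tug_pe_params` list.
#' @export
pe_params <- function(D = 3L, tau = 1L) {
  if (!is_count(D) || D < 2) stopf("D must be an integer >= 2")
  if (!is_count(tau)) stopf("tau must be a positive integer")
  structure(list(D = as.integer(D), tau = as.integer(tau)),
            class = "tug_pe_params")
}

#' Coarse-grain a series
#'
#' Element `j` of the output is the mean of the `j`-th consecutive
#' non-overlapping block of `tau` samples; the output has `floor(N/tau)`
#' elements. `tau = 1` is the identity.
#'
#' @param series Numeric vector of length `N >= tau`.
#' @param tau Scale factor (positive integer `<= N`).
#' @return Numeric vector of length `floor(N/tau)`.
#' @export
coarse_grain <- function(series, tau) {
  if (!is_count(tau)) stopf("tau must be a positive integer")
  n <- length(series)
  if (tau > n) stopf("tau (%d) exceeds series length (%d)", tau, n)
  if (tau == 1L) return(as.numeric(series))
  nb <- n %/% tau
  colMeans(matrix(series[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `SampEn = -ln(C_{m+1}/C_m)`: the negative log conditional probability
#' that template pairs of length `m` within Chebyshev tolerance
#' `r_absolute` remain within tolerance when extended by one point.
#' Self-matches are excluded. A perfectly regular series gives 0; `+Inf` is
#' returned when no extended pair matches, and `NA` (a flagged missing
#' value, with a warning) when there are no length-`m` matches at all, so
#' that degenerate segments surface as missing features rather than as
#' infinities.
#'
#' @param series Numeric vector, length `> m + 1`.
#' @param m Template length.
#' @param r_absolute Tolerance in signal units (not a fraction of SD).
#' @return Non-negative scalar, `+Inf`, or `NA`.
#' @export
sample_entropy <- function(series, m = 2L, r_absolute) {
  if (!is_count(m)) stopf("m must be a positive integer")
  if (!is_scalar_num(r_absolute) || r_absolute <= 0) stopf("r_absolute must be > 0")
  n <- length(series)
  if (n <= m + 1L) stopf("series length (%d) must exceed m + 1 (%d)", n, m + 1L)
  if (any(!is.finite(series))) stopf("series contains non-finite values")
  counts <- sampen_counts(as.numeric(series), as.integer(m), r_absolute)
  if (counts[1L] == 0) {
    warnf("sample_entropy: no length-%d template matches; returning NA", m)
    return(NA_real_)
  }
  if (counts[2L] == 0) return(Inf)
  -log(counts[2L] / counts[1L])
}

#' Multiscale sample-entropy profile
#'
#' `SampEn` of the coarse-grained series at scales `1..tau_max`, with the
#' absolute tolerance fixed across all scales as the fraction `r` of the SD
#' of the original (scale-1) series.
#'
#' @param series Numeric vector.
#' @param params A [mse_params()].
#' @return Numeric vector of length `tau_max` (entries may be `Inf`/`NA`,
#'   see [sample_entropy()]).
#' @export
mse_profile <- function(series, params = mse_params()) {
  stopifnot(inherits(params, "tug_mse_params"))
  n <- length(series)
  if (n %/% params$tau_max <= params$m + 1L)
    stopf("series too short for tau_max = %d: floor(N/tau_max) must exceed m + 1",
          params$tau_max)
  s <- sd(series)
  if (!is.finite(s) || s == 0) {
    # constant series: every template matches at every scale
    return(rep(0, params$tau_max))
  }
  r_abs <- params$r * s
  vapply(seq_len(params$tau_max), function(tau)
    sample_entropy(coarse_grain(series, tau), params$m, r_abs), numeric(1))
}

#' Complexity index and profile summaries
#'
#' The complexity index is the sum of the sample-entropy profile over all
#' scales; `mse_mean`/`mse_sd` are its mean and (sample) SD. Non-finite
#' profile entries propagate as `NA` (flagged missing), never as an error.
#'
#' @param profile Numeric vector from [mse_profile()].
#' @return A scalar; `NA` if the profile has non-finite entries.
#' @export
complexity_index <- function(profile) {
  if (length(profile) == 0L) stopf("empty MSE profile")
  if (any(!is.finite(profile))) return(NA_real_)
  sum(profile)
}

#' @rdname complexity_index
#' @export
mse_mean <- function(profile) {
  if (length(profile) == 0L) stopf("empty MSE profile")
  if (any(!is.finite(profile))) return(NA_real_)
  mean(profile)
}

#' @rdname complexity_index
#' @export
mse_sd <- function(profile) {
  if (length(profile) == 0L) stopf("empty MSE profile")
  if (any(!is.finite(profile))) return(NA_real_)
  if (length(profile) == 1L) return(0)
  sd(profile)
}

# rank pattern of one embedding window: element i gets the rank of the i-th
# value (0-based, ascending); ties broken by temporal order of occurrence
rank_pattern <- function(w) {
  rank(w, ties.method = "first") - 1L
}

#' Ordinal-pattern distribution
#'
#' Embeds the series in windows of `D` points spaced `tau` apart (columns of
#' a `D x (T - (D-1) tau)` matrix), maps each window to its rank pattern and
#' returns relative frequencies over all `D!` patterns. Pattern names are
#' the rank vectors, e.g. `"0-2-1"` means the middle value is the largest.
#'
#' @param series Numeric vector of length `T >= D * tau`.
#' @param params A [pe_params()].
#' @return Named probability vector of length `D!` summing to 1.
#' @export
ordinal_distribution <- function(series, params = pe_params()) {
  stopifnot(inherits(params, "tug_pe_params"))
  D <- params$D; tau <- params$tau
  n <- length(series)
  n_win <- n - (D - 1L) * tau
  if (n_win < 1L || n < D * tau)
    stopf("series length (%d) too short for D = %d, tau = %d", n, D, tau)
  perms <- all_permutations(D)
  labels <- vapply(perms, function(p) paste(p, collapse = "-"), character(1))
  # vectorized rank patterns over all windows: rank of element i =
  # #(values below it) + #(equal values occurring earlier) (ties by
  # temporal order); windows are encoded in base D and tallied
  emb <- matrix(vapply(0:(D - 1L), function(d) series[seq_len(n_win) + d * tau],
                       numeric(n_win)), nrow = n_win, ncol = D)
  codes <- numeric(n_win)
  for (i in seq_len(D)) {
    rk <- numeric(n_win)
    for (j in seq_len(D)) {
      if (j == i) next
      rk <- rk + (emb[, j] < emb[, i]) + (emb[, j] == emb[, i] & j < i)
    }
    codes <- codes + rk * D^(i - 1L)
  }
  perm_codes <- vapply(perms, function(p) sum(p * D^(seq_len(D) - 1L)),
                       numeric(1))
  counts <- tabulate(match(codes, perm_codes), nbins = length(perms))
  setNames(counts / n_win, labels)
}

# all permutations of 0..(D-1), lexicographic
all_permutations <- function(D) {
  if (D == 1L) return(list(0L))
  sub <- all_permutations(D - 1L)
  out <- list()
  for (v in 0:(D - 1L)) {
    rest <- setdiff(0:(D - 1L), v)
    for (s in sub) out[[length(out) + 1L]] <- c(v, rest[s + 1L])
  }
  out
}

#' Permutation entropy (bits)
#'
#' Shannon entropy of the ordinal-pattern distribution:
#' `PE = -sum(p_i log2 p_i)` over patterns with `p_i > 0`. Bounded by
#' `[0, log2(D!)]`; 0 for strictly monotone series, and invariant under
#' strictly increasing transforms of the series.
#'
#' @inheritParams ordinal_distribution
#' @return Non-negative scalar in bits.
#' @export
permutation_entropy <- function(series, params = pe_params()) {
  p <- ordinal_distribution(series, params)
  p <- p[p > 0]
  -sum(p * log2(p))
}
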