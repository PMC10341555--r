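# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive quantities through different code paths than the
# package (explicit enumeration, vectorized pair scans) so agreement is
# evidence, not tautology.

# Brute-force sample entropy: explicit pairwise Chebyshev comparison over
# the N - m extensible templates, self-matches excluded.
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  cm <- 0; cm1 <- 0
  emb <- sapply(seq_len(m + 1L), function(k) x[(k):(nt + k - 1L)])
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(emb[i, 1:m] - emb[j, 1:m])) <= r) {
        cm <- cm + 1
        if (abs(emb[i, m + 1L] - emb[j, m + 1L]) <= r) cm1 <- cm1 + 1
      }
    }
  }
  if (cm == 0) return(NA_real_)
  if (cm1 == 0) return(Inf)
  -log(cm1 / cm)
}

# Ordinal-pattern distribution by literal window-by-window ranking.
ordinal_bruteforce <- function(x, D, tau) {
  n_win <- length(x) - (D - 1L) * tau
  keys <- vapply(seq_len(n_win), function(i)
    paste(rank(x[i + (0:(D - 1L)) * tau], ties.method = "first") - 1L,
          collapse = "-"),
    character(1))
  ref <- ordinal_distribution(x, pe_params(D, tau))  # for the level set only
  tab <- table(factor(keys, levels = names(ref)))
  setNames(as.numeric(tab) / n_win, names(ref))
}

# Literal transcription of the Relief-F update equations: min-max scaled
# features, Manhattan distances, k nearest hits/misses with ties to the
# lower index, hit updates subtracted and miss updates added with the
# prior factor, both divided by m * d_rq; zero-distance neighbors skipped.
# Mirrors the published update rule step by step with plain loops.
relieff_oracle <- function(X, y, k, m_iters, seed) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) max(col) - min(col))
  Xs <- X
  for (j in seq_len(p)) {
    Xs[, j] <- if (rng[j] > 0) (X[, j] - min(X[, j])) / rng[j] else 0
  }
  classes <- sort(unique(y))
  prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  draws <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    d <- sample.int(n, m_iters, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    d
  })
  W <- numeric(p)
  for (it in seq_len(m_iters)) {
    r <- draws[it]
    d <- vapply(seq_len(n), function(i) sum(abs(Xs[i, ] - Xs[r, ])), numeric(1))
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      cand <- which(y == cl)
      if (cl == y[r]) cand <- setdiff(cand, r)
      cand <- cand[order(d[cand], cand)]
      nbrs <- cand[seq_len(min(k, length(cand)))]
      for (q in nbrs) {
        if (d[q] == 0) next
        delta <- abs(Xs[r, ] - Xs[q, ])
        if (cl == y[r]) {
          W <- W - delta / (m_iters * d[q])
        } else {
          pr <- prior[ci] / (1 - prior[which(classes == y[r])])
          W <- W + pr * delta / (m_iters * d[q])
        }
      }
    }
  }
  unname(W)
}

# A small fast cohort for plumbing tests.
tiny_cohort <- function(n = 3, seed = 1, ...) {
  generate_cohort(cohort_spec_community(n_subjects = n, ...), seed = seed)
}
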