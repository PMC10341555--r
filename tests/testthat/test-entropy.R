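# Coarse-graining, sample entropy, multiscale profile, complexity index,
# ordinal patterns and permutation entropy.

test_that("coarse_grain matches the block-mean definition", {
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5, 6), 1), c(1, 2, 3, 4, 5, 6))
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_length(coarse_grain(1:7, 3), 2L)
  expect_error(coarse_grain(1:5, 6), "exceeds")
  expect_error(coarse_grain(1:5, 0), "positive integer")
})

test_that("coarse_grain length is floor(N/tau) for random N, tau", {
  withr::local_seed(21)
  for (i in 1:50) {
    n <- sample(2:400, 1)
    tau <- sample.int(n, 1)
    out <- coarse_grain(rnorm(n), tau)
    expect_length(out, n %/% tau)
  }
})

test_that("sample entropy handles regular, degenerate and infinite cases", {
  expect_identical(sample_entropy(rep(5, 8), 2, 0.1), 0)
  # C_m > 0 but no extensible match -> +Inf
  expect_identical(sample_entropy(c(0, 1, 0.01, 5), m = 1, r_absolute = 0.1), Inf)
  # no template matches at all -> flagged missing with a warning
  expect_warning(
    out <- sample_entropy(c(0, 10, 1, 20, 3, 40, 6), m = 2, r_absolute = 1e-6),
    "no length-2")
  expect_true(is.na(out))
  expect_error(sample_entropy(1:3, 2, 0.1), "exceed")
  expect_error(sample_entropy(1:10, 2, 0), "r_absolute")
})

test_that("sample entropy equals the brute-force enumerator", {
  x <- rep(c(1, 2), 4)
  expect_equal(sample_entropy(x, 2, 0.5 * sd(x)),
               sampen_bruteforce(x, 2, 0.5 * sd(x)), tolerance = 1e-12)
  withr::local_seed(31)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    m <- sample(1:3, 1)
    x <- switch(sample(3, 1), runif(n), rnorm(n), sin(seq_len(n) / 3) + rnorm(n, 0, .2))
    r <- runif(1, 0.1, 0.4) * sd(x)
    expect_equal(suppressWarnings(sample_entropy(x, m, r)),
                 sampen_bruteforce(x, m, r), tolerance = 1e-12)
  }
})

test_that("mse_profile composes coarse-graining and SampEn at fixed tolerance", {
  withr::local_seed(41)
  x <- rnorm(400)
  expect_equal(mse_profile(x, mse_params(tau_max = 1)),
               sample_entropy(x, 2, 0.15 * sd(x)))
  expect_identical(mse_profile(rep(3, 100), mse_params(tau_max = 4)), rep(0, 4))
  prof <- mse_profile(x, mse_params(m = 2, r = 0.2, tau_max = 5))
  oracle <- vapply(1:5, function(tau)
    sampen_bruteforce(coarse_grain(x, tau), 2, 0.2 * sd(x)), numeric(1))
  expect_equal(prof, oracle, tolerance = 1e-12)
  expect_error(mse_profile(rnorm(10), mse_params(tau_max = 5)), "too short")
})

test_that("complexity index and profile summaries", {
  expect_identical(complexity_index(c(0, 0, 0)), 0)
  expect_identical(mse_mean(c(0, 0, 0)), 0)
  expect_identical(mse_sd(c(0, 0, 0)), 0)
  expect_identical(complexity_index(1.3), 1.3)
  expect_identical(mse_sd(1.3), 0)
  withr::local_seed(43)
  prof <- runif(5)
  expect_equal(complexity_index(prof), sum(prof))
  expect_equal(complexity_index(prof), 5 * mse_mean(prof))
  # non-finite entries propagate as flagged missing, not errors
  expect_true(is.na(complexity_index(c(1, Inf))))
  expect_true(is.na(mse_mean(c(1, Inf))))
  expect_error(complexity_index(numeric(0)), "empty")
})

test_that("ordinal distribution reproduces the worked example's consistent entries", {
  p <- ordinal_distribution(c(8, 5, 4, 3, 11, 9, 1), pe_params(D = 3, tau = 1))
  expect_equal(sum(p), 1)
  expect_equal(p[["0-2-1"]], 1 / 5)
  expect_equal(p[["1-0-2"]], 1 / 5)
  expect_equal(p[["0-1-2"]], 0)
  expect_equal(p[["1-2-0"]], 0)
})

test_that("ordinal distribution equals brute-force enumeration", {
  withr::local_seed(47)
  for (i in 1:10) {
    x <- rnorm(sample(20:100, 1))
    D <- sample(2:4, 1); tau <- sample(1:3, 1)
    expect_equal(ordinal_distribution(x, pe_params(D, tau)),
                 ordinal_bruteforce(x, D, tau), tolerance = 1e-12)
  }
  # ties broken by temporal order: constant series -> ascending pattern
  p <- ordinal_distribution(rep(1, 10), pe_params(3, 1))
  expect_equal(p[["0-1-2"]], 1)
})

test_that("permutation entropy closed forms and bounds", {
  expect_identical(permutation_entropy(1:50, pe_params(3, 1)), 0)
  expect_identical(permutation_entropy(seq(0, 1, length.out = 20), pe_params(4, 2)), 0)
  # period-2 alternation with D = 2 (whole number of periods plus one
  # sample, so both patterns occur equally often): (1/2, 1/2), PE = 1 bit
  alt <- c(rep(c(1, 2), 10), 1)
  p2 <- ordinal_distribution(alt, pe_params(D = 2, tau = 1))
  expect_equal(as.numeric(p2[c("0-1", "1-0")]), c(1 / 2, 1 / 2))
  expect_identical(permutation_entropy(alt, pe_params(D = 2, tau = 1)), 1)
  withr::local_seed(53)
  for (i in 1:10) {
    x <- rnorm(200)
    pe <- permutation_entropy(x, pe_params(3, 1))
    expect_gte(pe, 0)
    expect_lte(pe, log2(factorial(3)))
    # invariance under strictly monotone increasing transforms
    expect_equal(permutation_entropy(exp(x / 2), pe_params(3, 1)), pe)
  }
})
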