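hand_sample <- function() {
  ranked_sample(c(0, 0, 1, 1), ranks = c(0.125, 0.375, 0.625, 0.875))
}

test_that("hand example: CI = 0.5, CCI = 1, cov = 0.125", {
  res <- concentration_index(hand_sample(), se_method = "none")
  expect_equal(res$mu, 0.5)
  expect_equal(res$cov, 0.125)
  expect_equal(res$ci, 0.5)
  expect_equal(res$cci, 1)
})

test_that("constant outcome gives CI 0; reversed outcome flips the sign", {
  ones <- ranked_sample(rep(1, 4), ranks = c(0.125, 0.375, 0.625, 0.875))
  expect_equal(suppressWarnings(concentration_index(ones,
                                                    se_method = "none"))$ci, 0)
  rev_ <- ranked_sample(c(1, 1, 0, 0), ranks = c(0.125, 0.375, 0.625, 0.875))
  expect_equal(concentration_index(rev_, se_method = "none")$ci, -0.5)
})

test_that("no users is an error; all users warns about the degenerate bound", {
  zero <- ranked_sample(rep(0, 4), ranks = c(0.125, 0.375, 0.625, 0.875))
  expect_error(concentration_index(zero, se_method = "none"), "undefined")
  ones <- ranked_sample(rep(1, 4), ranks = c(0.125, 0.375, 0.625, 0.875))
  expect_warning(concentration_index(ones, se_method = "none"), "degenerate")
})

test_that("both corrected-index identities hold to 1e-12 on random samples", {
  set.seed(31)
  for (k in 1:1000) {
    n <- sample(5:60, 1)
    h <- rbinom(n, 1, runif(1, 0.1, 0.9))
    h[1:2] <- c(0, 1)                   # keep both classes present
    w <- rexp(n) + 0.1
    s <- ranked_sample(h, ses = rnorm(n), weights = w)
    res <- concentration_index(s, se_method = "none")
    expect_equal(res$cci, 4 * res$mu * res$ci, tolerance = 1e-12)
    expect_equal(res$cci, 8 * wcov_test(h, s$r, s$w), tolerance = 1e-12)
  }
})

test_that("CI is scale invariant and antisymmetric under rank reversal", {
  set.seed(32)
  h <- rpois(50, 2) + 0.5       # non-binary positive outcome
  ses <- rnorm(50)
  w <- runif(50, 0.5, 2)
  s <- ranked_sample(h, ses = ses, weights = w)
  ci1 <- concentration_index(s, se_method = "none")$ci
  s2 <- ranked_sample(3.7 * h, ses = ses, weights = w)
  expect_equal(concentration_index(s2, se_method = "none")$ci, ci1,
               tolerance = 1e-12)
  s3 <- ranked_sample(h, ranks = 1 - s$r, weights = w)
  expect_equal(concentration_index(s3, se_method = "none")$ci, -ci1,
               tolerance = 1e-12)
})

test_that("curve hand example: area 0.25, curve index equals covariance index", {
  cc <- concentration_curve(hand_sample())
  expect_equal(cc$pop_share, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cc$outcome_share, c(0, 0, 0, 0.5, 1))
  expect_equal(attr(cc, "index"), 0.5)
  # constant outcome: the curve is the diagonal
  ones <- ranked_sample(rep(1, 4), ranks = c(0.125, 0.375, 0.625, 0.875))
  cd <- concentration_curve(ones)
  expect_equal(cd$pop_share, cd$outcome_share)
  expect_equal(attr(cd, "index"), 0)
})

test_that("curve and covariance forms agree within 2/n on random data", {
  set.seed(33)
  for (k in 1:100) {
    n <- 1000
    h <- rbinom(n, 1, runif(1, 0.05, 0.5))
    if (sum(h) == 0) h[1] <- 1
    w <- rexp(n) + 0.1
    s <- ranked_sample(h, ses = rnorm(n), weights = w)
    ci_cov <- concentration_index(s, se_method = "none")$ci
    ci_curve <- attr(concentration_curve(s), "index")
    expect_lt(abs(ci_cov - ci_curve), 2 / n)
  }
})

test_that("convenient SE covers the null at roughly nominal rate", {
  set.seed(34)
  reps <- 500
  n <- 2000
  hit <- logical(reps)
  for (b in 1:reps) {
    h <- rbinom(n, 1, 0.3)
    s <- ranked_sample(h, ses = rnorm(n))
    ci <- concentration_index(s, se_method = "convenient")
    hit[b] <- abs(ci$ci) <= 2 * ci$se_ci
  }
  expect_gte(mean(hit), 0.93)
})

test_that("bootstrap SE is deterministic given the seed and 0 when degenerate", {
  set.seed(35)
  h <- rbinom(300, 1, 0.4)
  s <- ranked_sample(h, ses = rlnorm(300))
  se1 <- ci_standard_error(s, "bootstrap", reps = 200, seed = 99)
  se2 <- ci_standard_error(s, "bootstrap", reps = 200, seed = 99)
  expect_identical(se1, se2)
  expect_gt(se1, 0)
  const <- ranked_sample(rep(1, 50), ses = rnorm(50))
  expect_equal(ci_standard_error(const, "bootstrap", reps = 100, seed = 1), 0)
  expect_error(ci_standard_error(s, "bootstrap", reps = 50), "reps >= 100")
  expect_error(ci_standard_error(ranked_sample(c(0, 1), ses = 1:2),
                                 "convenient"), "n >= 10")
})

test_that("bootstrap leaves the caller's RNG stream untouched", {
  set.seed(77)
  before <- .Random.seed
  h <- rbinom(200, 1, 0.4)
  s <- ranked_sample(h, ses = rnorm(200))
  after_draws <- .Random.seed
  invisible(ci_standard_error(s, "bootstrap", reps = 100, seed = 5))
  expect_identical(.Random.seed, after_draws)
  expect_false(identical(before, after_draws))
})
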