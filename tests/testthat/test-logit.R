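# Independent oracle: Newton-Raphson maximization of the Bernoulli
# log-likelihood written from scratch (no glm).
newton_logit <- function(X, y, w = rep(1, length(y)), tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(X, w * (y - p))
    H <- crossprod(X, X * (w * p * (1 - p)))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

test_that("closed-form cases: intercept-only and saturated 2x2", {
  # intercept-only model: alpha = log-odds of the outcome mean
  only <- fit_logit(data.frame(y = rep(c(1, 0), c(25, 75))), "y",
                    covariates = "1")
  expect_equal(unname(only$beta[1]), log(0.25 / 0.75), tolerance = 1e-8)
  # saturated 2x2 with cell counts a=30, b=70 (x=1), c=10, d=90 (x=0):
  # slope = log odds ratio of the contingency table
  tab <- data.frame(
    y = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
    x = c(rep(1, 100), rep(0, 100)))
  fit <- fit_logit(tab, "y", covariates = "x")
  expect_equal(unname(fit$beta["x"]), log((30 * 90) / (70 * 10)),
               tolerance = 1e-8)
  expect_equal(unname(fit$beta["(Intercept)"]), log(10 / 90),
               tolerance = 1e-8)
})

test_that("coefficients match a from-scratch Newton optimizer at small n", {
  set.seed(21)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  eta <- -0.5 + 0.8 * d$x1 - 0.6 * d$x2
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logit(d, "y", covariates = c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  expect_equal(unname(fit$beta), newton_logit(X, d$y), tolerance = 1e-8)
  # weighted version
  w <- runif(n, 0.5, 3)
  fitw <- fit_logit(d, "y", covariates = c("x1", "x2"), weights = w)
  expect_equal(unname(fitw$beta), newton_logit(X, d$y, w), tolerance = 1e-8)
})

test_that("score equations hold and fitted mean matches outcome mean", {
  set.seed(22)
  n <- 400
  d <- data.frame(x1 = rnorm(n), g = sample(c("a", "b", "c"), n, TRUE))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.5 * d$x1 + 0.4 * (d$g == "b")))
  w <- runif(n, 0.5, 2)
  fit <- fit_logit(d, "y", covariates = c("x1", "g"), weights = w)
  X <- build_design <- model.matrix(~ x1 + g, d)
  score <- crossprod(X, w * (d$y - fit$fitted))
  expect_lt(max(abs(score)), 1e-6)
  expect_equal(weighted.mean(fit$fitted, w), weighted.mean(d$y, w),
               tolerance = 1e-10)
  # fitted probabilities strictly inside (0,1)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("robust sandwich covariance equals the hand-built bread-meat-bread", {
  set.seed(23)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.3 + 0.7 * d$x))
  fit <- fit_logit(d, "y", covariates = "x")
  X <- cbind(1, d$x)
  p <- plogis(drop(X %*% fit$beta))
  A <- crossprod(X, X * (p * (1 - p)))        # observed information
  B <- crossprod(X * (d$y - p))               # outer product of scores
  V <- solve(A) %*% B %*% solve(A)
  expect_equal(unname(fit$cov), unname(V), tolerance = 1e-6)
})

test_that("parameter recovery within 3 robust SEs on simulated data", {
  set.seed(24)
  n <- 20000
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta <- c(-1, 0.5, -0.3)
  d$y <- rbinom(n, 1, plogis(beta[1] + beta[2] * d$x1 + beta[3] * d$x2))
  fit <- fit_logit(d, "y", covariates = c("x1", "x2"))
  expect_true(all(abs(fit$beta - beta) <= 3 * fit$se))
})

test_that("odds ratios are exp(beta) with delta-method SEs, round-tripping", {
  set.seed(25)
  d <- data.frame(x = rnorm(300))
  d$y <- rbinom(300, 1, plogis(0.2 + 0.5 * d$x))
  fit <- fit_logit(d, "y", covariates = "x")
  ors <- odds_ratios(fit)
  expect_equal(ors$or, unname(exp(fit$beta)))
  expect_equal(log(ors$or), unname(fit$beta), tolerance = 1e-12)
  expect_equal(ors$se, unname(exp(fit$beta) * fit$se))
  # numeric-vector method
  expect_equal(odds_ratios(0)$or, 1)
  expect_equal(odds_ratios(c(a = 0.3556))$or, exp(0.3556))
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(y = rep(c(0, 1), 25), x = rnorm(50))
  d$x2 <- d$x * 2                       # aliased
  expect_error(fit_logit(d, "y", covariates = c("x", "x2")),
               "rank deficient")
  sep <- data.frame(y = rep(c(0, 1), each = 25),
                    x = c(rnorm(25, -5), rnorm(25, 5)),
                    z = rnorm(50))
  expect_error(fit_logit(sep, "y", covariates = c("x", "z")), "separation")
  one <- data.frame(y = rep(1, 30), x = rnorm(30))
  expect_error(fit_logit(one, "y", covariates = "x"), "single class")
})

test_that("predict_prob evaluates the logistic link and honors overrides", {
  d <- data.frame(x = c(0, 0.5, 1), y = c(0, 1, 1))
  fit <- fit_logit(data.frame(x = rnorm(100),
                              y = rbinom(100, 1, 0.5)), "y",
                   covariates = "x")
  fit$beta <- c("(Intercept)" = 1, x = -2)
  expect_equal(predict_prob(fit, d), plogis(1 - 2 * d$x))
  # all-zero coefficients give 0.5 everywhere
  fit$beta[] <- 0
  expect_equal(predict_prob(fit, d), rep(0.5, 3))
  # scalar override pins the column
  fit$beta <- c("(Intercept)" = 1, x = -2)
  expect_equal(predict_prob(fit, d, overrides = list(x = 0.5)),
               rep(plogis(0), 3))
  expect_error(predict_prob(fit, d, overrides = list(nope = 1)),
               "unknown override")
})

test_that("'mean' overrides fix factor dummies at their proportions", {
  set.seed(26)
  n <- 500
  d <- data.frame(x = rnorm(n),
                  g = factor(sample(c("a", "b", "c"), n, TRUE)))
  d$y <- rbinom(n, 1, plogis(0.3 * d$x + 0.5 * (d$g == "b")))
  fit <- fit_logit(d, "y", covariates = c("x", "g"))
  p <- predict_prob(fit, d, overrides = list(g = "mean"))
  mm <- model.matrix(~ x + g, d)
  mm[, "gb"] <- mean(d$g == "b")
  mm[, "gc"] <- mean(d$g == "c")
  expect_equal(p, unname(plogis(drop(mm %*% fit$beta))))
  # overriding every covariate to its mean yields a constant vector
  pc <- predict_prob(fit, d, overrides = list(g = "mean", x = "mean"))
  expect_equal(diff(range(pc)), 0, tolerance = 1e-12)
})
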