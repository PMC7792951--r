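#' Concentration index and its correction for binary outcomes
#'
#' Computes the concentration index CI = (2/mu) * cov(h, r), where r are the
#' weighted fractional SES ranks and mu the weighted mean of the outcome,
#' together with the corrected index CCI = 4 * mu * CI = 8 * cov(h, r)
#' appropriate for binary outcomes (whose unadjusted CI is compressed toward
#' zero as the prevalence rises). Covariances are population-weighted
#' (divide by total weight), which makes the two printed forms of the
#' corrected index identical to machine precision and the curve-based index
#' agree up to discreteness.
#'
#' A positive index means use is concentrated among high-SES (pro-rich)
#' respondents, a negative one among low-SES (pro-poor) respondents.
#'
#' @param sample a [ranked_sample()]
#' @param se_method "convenient" (regression-based, the default),
#'   "bootstrap", or "none"
#' @param reps bootstrap replicates (>= 100) when `se_method = "bootstrap"`
#' @param seed bootstrap seed
#' @return an object of class `concentration_result` with fields `mu`, `ci`,
#'   `cci`, `se_ci`, `se_cci`, `n`, `method`, and the labels carried over
#'   from the sample
#' @seealso [concentration_curve()], [ci_standard_error()]
#' @examples
#' s <- ranked_sample(c(0, 0, 1, 1), ranks = c(0.125, 0.375, 0.625, 0.875))
#' concentration_index(s, se_method = "none")  # CI = 0.5, CCI = 1
#' @export
concentration_index <- function(sample,
                                se_method = c("convenient", "bootstrap", "none"),
                                reps = 500, seed = 1L) {
  stopifnot(inherits(sample, "ranked_sample"))
  se_method <- match.arg(se_method)
  h <- sample$h; r <- sample$r; w <- sample$w
  mu <- wmean(h, w)
  if (mu == 0)
    stop("undefined index: outcome mean is zero (no users in sample)",
         call. = FALSE)
  if (mu == 1 && all(h %in% c(0, 1)))
    warning("outcome mean is 1: the corrected index bound is degenerate")
  cv <- wcov(h, r, w)
  ci <- 2 * cv / mu
  cci <- 4 * mu * ci
  se_ci <- if (se_method == "none") NA_real_
           else ci_standard_error(sample, method = se_method,
                                  reps = reps, seed = seed)
  structure(list(mu = mu, ci = ci, cci = cci,
                 se_ci = se_ci, se_cci = 4 * mu * se_ci,
                 cov = cv, n = sample$n, method = "covariance",
                 rank_label = sample$label,
                 outcome_label = sample$outcome_label,
                 country = sample$country),
            class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat("concentration_result (", x$method, " form)\n", sep = "")
  if (!is.null(x$country)) cat("  country: ", x$country, "\n", sep = "")
  cat(sprintf("  mu = %.4f   n = %d   rank: %s\n", x$mu, x$n, x$rank_label))
  cat(sprintf("  CI  = %+.4f (SE %.4f) %s\n", x$ci, x$se_ci,
              signif_stars(x$ci, x$se_ci)))
  cat(sprintf("  CCI = %+.4f (SE %.4f)\n", x$cci, x$se_cci))
  invisible(x)
}

#' Concentration curve of an outcome against SES rank
#'
#' The cumulative share of the outcome plotted against the cumulative share
#' of the population, ordered poorest to richest: a Lorenz-type curve from
#' (0, 0) to (1, 1). Observations tied on rank move as one block. The
#' curve-based index, 1 - 2 * (area under the curve) by the trapezoid rule,
#' is the geometric counterpart of the covariance form and is exposed as the
#' `"index"` attribute.
#'
#' @param sample a [ranked_sample()]
#' @return a data frame with columns `pop_share` and `outcome_share`
#'   (first row (0, 0)), with attribute `"index"`
#' @export
concentration_curve <- function(sample) {
  stopifnot(inherits(sample, "ranked_sample"))
  h <- sample$h; r <- sample$r; w <- sample$w
  th <- sum(w * h)
  if (th == 0)
    stop("undefined curve: outcome mean is zero", call. = FALSE)
  o <- order(r)
  rs <- r[o]
  gid <- cumsum(c(TRUE, diff(rs) > 0))
  pw <- as.vector(rowsum(w[o], gid))
  hw <- as.vector(rowsum((w * h)[o], gid))
  p <- c(0, cumsum(pw) / sum(w))
  L <- c(0, cumsum(hw) / th)
  area <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  out <- data.frame(pop_share = p, outcome_share = L)
  attr(out, "index") <- 1 - 2 * area
  out
}

#' Standard error of a concentration index
#'
#' `"convenient"` runs the convenient regression
#' 2 * var(r) * (h_i / mu) = a + b * r_i (weighted), whose slope b is the
#' concentration index, and returns the heteroskedasticity-robust (HC1)
#' standard error of the slope. `"bootstrap"` resamples respondents i.i.d.
#' with replacement and recomputes the index in each replicate —
#' re-deriving the fractional ranks from the resampled SES values, since
#' ranking is part of the estimator — and returns the standard deviation
#' over replicates.
#'
#' @param sample a [ranked_sample()]; bootstrap requires it to carry the raw
#'   `ses` variable
#' @param method "convenient" or "bootstrap"
#' @param reps bootstrap replicates (>= 100)
#' @param seed bootstrap seed (the caller's RNG stream is left untouched)
#' @return scalar standard error
#' @export
ci_standard_error <- function(sample, method = c("convenient", "bootstrap"),
                              reps = 500, seed = 1L) {
  stopifnot(inherits(sample, "ranked_sample"))
  method <- match.arg(method)
  h <- sample$h; r <- sample$r; w <- sample$w
  if (method == "convenient") {
    if (sample$n < 10)
      stop("convenient SE needs n >= 10", call. = FALSE)
    mu <- wmean(h, w)
    if (mu == 0) stop("undefined index: outcome mean is zero", call. = FALSE)
    y <- 2 * wvar(r, w) * (h / mu)
    dat <- data.frame(y = y, r = r, w = w)
    fit <- stats::lm(y ~ r, data = dat, weights = w)
    sqrt(sandwich::vcovHC(fit, type = "HC1")["r", "r"])
  } else {
    if (reps < 100) stop("bootstrap needs reps >= 100", call. = FALSE)
    if (is.null(sample$ses))
      stop("bootstrap SE requires the raw SES variable in the sample",
           call. = FALSE)
    n <- sample$n
    stat <- function(idx) {
      hb <- h[idx]; wb <- w[idx]
      mub <- wmean(hb, wb)
      if (mub == 0) return(NA_real_)
      rb <- fractional_rank(sample$ses[idx], wb)
      2 * wcov(hb, rb, wb) / mub
    }
    cis <- with_seed(seed, {
      vapply(seq_len(reps),
             function(b) stat(sample.int(n, n, replace = TRUE)),
             numeric(1))
    })
    stats::sd(cis, na.rm = TRUE)
  }
}
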