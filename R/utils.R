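# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted mean
#' @param x numeric vector
#' @param w positive weights, same length as `x`
#' @return scalar weighted mean
#' @keywords internal
#' @noRd
wmean <- function(x, w) sum(w * x) / sum(w)

# Population-weighted covariance (divides by total weight, not total - 1).
# This convention makes CCI = 8*cov(h, r) an exact identity with
# CCI = 4*mu*CI and makes the concentration-curve area agree with the
# covariance form up to discreteness only.
wcov <- function(x, y, w) {
  tw <- sum(w)
  mx <- sum(w * x) / tw
  my <- sum(w * y) / tw
  sum(w * (x - mx) * (y - my)) / tw
}

wvar <- function(x, w) wcov(x, x, w)

check_weights <- function(w, n) {
  if (length(w) != n)
    stop("weights must have the same length as the data (", n, ")", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be strictly positive and finite", call. = FALSE)
  invisible(w)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Significance stars for a normal z-test
#'
#' Two-sided normal test of `est / se` against zero, starred at the
#' 1\% (`***`), 5\% (`**`) and 10\% (`*`) levels.
#'
#' @param est estimate(s)
#' @param se standard error(s)
#' @return character vector of stars ("" when p >= 0.10 or `se` is NA)
#' @export
signif_stars <- function(est, se) {
  p <- 2 * stats::pnorm(-abs(est / se))
  out <- ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
  out[!is.finite(p)] <- ""
  out
}

# Stable content hash of a (config-sized) R object, via its canonical JSON
# serialization and a rolling polynomial hash. Used for run manifests only.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE, null = "null"))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
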