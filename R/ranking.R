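#' Weighted fractional ranks of a socioeconomic variable
#'
#' Positions each observation at the midpoint of its cumulative-weight block
#' in the distribution of `ses`: after sorting ascending, the rank of
#' observation i is (cumulative weight before i + w_i / 2) / total weight.
#' Ties share the midpoint of their whole block, which is the average of the
#' ranks the tied observations would occupy under any tie-breaking order and
#' preserves the weighted mean of exactly 0.5. With equal weights and no
#' ties the ranks reduce to (2i - 1) / (2n). Output is in the original row
#' order; ranks are invariant to any strictly increasing transform of `ses`.
#'
#' @param ses numeric vector of the socioeconomic ranking variable
#'   (length >= 2, all finite)
#' @param weights optional strictly positive weights, same length
#' @return numeric vector of ranks in (0, 1)
#' @examples
#' fractional_rank(c(10, 20, 30, 40))       # 0.125 0.375 0.625 0.875
#' fractional_rank(c(5, 5, 9))              # 1/3 1/3 5/6
#' @export
fractional_rank <- function(ses, weights = NULL) {
  n <- length(ses)
  if (n < 2) stop("need at least 2 observations to rank", call. = FALSE)
  if (any(!is.finite(ses)))
    stop("non-finite values in the ranking variable", call. = FALSE)
  w <- weights %||% rep(1, n)
  check_weights(w, n)
  o <- order(ses)
  s <- ses[o]
  ws <- w[o]
  gid <- cumsum(c(TRUE, diff(s) > 0))     # tie blocks on the sorted vector
  gw <- as.vector(rowsum(ws, gid))
  rg <- (cumsum(gw) - gw / 2) / sum(ws)   # midpoint of each block
  r <- numeric(n)
  r[o] <- rg[gid]
  r
}

#' Pair a health outcome with fractional SES ranks
#'
#' The unit of analysis for concentration indices: outcome values h, ranks r
#' in (0, 1) with weighted mean 0.5, and normalized weights. Either supply
#' the raw `ses` variable (ranks are computed, and kept so bootstrap
#' replicates can re-rank) or pre-computed `ranks`.
#'
#' @param h numeric outcome vector (binary for care-use outcomes; any
#'   non-negative variable is accepted)
#' @param ses socioeconomic variable to rank on (ignored when `ranks` given)
#' @param weights optional positive weights
#' @param ranks optional pre-computed fractional ranks in (0, 1)
#' @param label name of the ranking variable
#' @param outcome_label,country optional labels carried into results
#' @return an object of class `ranked_sample`
#' @export
ranked_sample <- function(h, ses = NULL, weights = NULL, ranks = NULL,
                          label = "ses", outcome_label = NULL, country = NULL) {
  n <- length(h)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(h))) stop("non-finite outcome values", call. = FALSE)
  w <- weights %||% rep(1, n)
  check_weights(w, n)
  if (is.null(ranks)) {
    if (is.null(ses)) stop("supply either ses or ranks", call. = FALSE)
    r <- fractional_rank(ses, w)
  } else {
    if (length(ranks) != n) stop("ranks length mismatch", call. = FALSE)
    if (any(ranks <= 0 | ranks >= 1))
      stop("ranks must lie strictly inside (0, 1)", call. = FALSE)
    r <- ranks
  }
  structure(list(h = h, r = r, w = w / sum(w), ses = ses, n = n,
                 label = label, outcome_label = outcome_label,
                 country = country),
            class = "ranked_sample")
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat("ranked_sample: n = ", x$n, ", rank variable = ", x$label,
      ", mean outcome = ", format(wmean(x$h, x$w), digits = 4), "\n", sep = "")
  invisible(x)
}
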