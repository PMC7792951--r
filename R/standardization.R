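# Indirect need-standardization and horizontal inequity.

hi_core <- function(df, rm_, ocol, rank_col, engine, weights) {
  covs <- c(rm_$need, rm_$nonneed)
  fit <- if (engine == "logit")
    fit_logit(microdata(df, rm_, validate = FALSE), ocol, covariates = covs,
              weights = weights)
  else
    fit_lpm(microdata(df, rm_, validate = FALSE), ocol, covariates = covs,
            weights = weights)
  w <- fit$weights
  overrides <- stats::setNames(as.list(rep("mean", length(rm_$nonneed))),
                               rm_$nonneed)
  h_hat <- if (engine == "logit")
    predict_prob(fit, df, overrides = overrides, weights = w)
  else
    predict_lpm(fit, df, overrides = overrides, weights = w)
  h <- df[[ocol]]
  wn <- w / sum(w)
  hbar <- wmean(h, wn)
  mu_hat <- wmean(h_hat, wn)
  # recentering by mean(h_hat) keeps mean(h_std) = hbar exactly for both
  # engines; for the LPM mu_hat = hbar, so this is the textbook h - hhat + hbar
  h_std <- h - h_hat + mu_hat
  r <- fractional_rank(df[[rank_col]], wn)
  ci_actual <- 2 * wcov(h, r, wn) / hbar
  ci_need <- 2 * wcov(h_hat, r, wn) / mu_hat
  hi <- 2 * wcov(h_std, r, wn) / hbar     # = CI of standardized use
  list(fit = fit, h = h, h_hat = h_hat, h_std = h_std, r = r, w = wn,
       hbar = hbar, mu_hat = mu_hat,
       ci_actual = ci_actual, ci_need = ci_need,
       hi = hi, hi_alt = ci_actual - ci_need, n = length(h))
}

#' Indirect need-standardization and the horizontal inequity index
#'
#' Fits the utilization model on need plus non-need determinants, computes
#' the need-predicted use of each respondent (need variables at their
#' observed values, non-need variables fixed at sample means), forms the
#' standardized use h'_i = h_i - hhat_i + mean(hhat) — which preserves the
#' sample mean by construction (and reduces to h - hhat + hbar whenever the
#' predictions average to hbar, e.g. under the LPM engine) — and measures
#' the horizontal inequity index HI as
#' the concentration index of h' against the chosen SES ranks. A nonzero HI
#' means respondents with equal need use care differently by SES (positive:
#' pro-rich inequity).
#'
#' Two constructions are reported: `hi`, the index of standardized use,
#' which satisfies HI = CI(h) - (2/hbar) cov(hhat, r) exactly, and
#' `hi_alt` = CI(h) - CI(hhat) with CI(hhat) scaled by its own mean. Under
#' the linear-probability engine the two coincide to machine precision
#' (the mean of hhat equals hbar for OLS with an intercept); under the
#' logit engine they differ by the linearization error of the prediction.
#'
#' @param table a [microdata()] table with need and non-need roles bound
#' @param outcome `"formal"`, `"informal"` or a 0/1 column name
#' @param rank `"income"`, `"wealth"` or a numeric column name
#' @param engine prediction engine for need-expected use: `"logit"`
#'   (default) or `"lpm"` (linear probability model)
#' @param se_method `"convenient"` (default), `"bootstrap"` (re-fits the
#'   standardization model in every replicate) or `"none"`
#' @param reps bootstrap replicates (>= 100)
#' @param seed bootstrap seed
#' @param weights optional weight column name or numeric vector
#' @return an object of class `inequity_result` with fields `h_hat`,
#'   `h_std`, `hbar`, `ci_actual`, `ci_need`, `hi`, `hi_alt`, `se_hi`, `n`,
#'   `rank_label`, `outcome_label`, `country`, `engine`
#' @export
indirect_standardize <- function(table, outcome, rank = "income",
                                 engine = c("logit", "lpm"),
                                 se_method = c("convenient", "bootstrap", "none"),
                                 reps = 500, seed = 1L, weights = NULL) {
  engine <- match.arg(engine)
  se_method <- match.arg(se_method)
  rm_ <- role_map_of(table)
  if (is.null(rm_)) stop("table must carry a role_map", call. = FALSE)
  if (length(rm_$need) == 0 || length(rm_$nonneed) == 0)
    stop("need and nonneed role lists must be non-empty", call. = FALSE)
  ocol <- resolve_outcome(table, outcome)
  rank_col <- resolve_rank(table, rank)
  df <- as.data.frame(table)
  use_cols <- c(ocol, rm_$need, rm_$nonneed, rank_col, rm_$weight)
  keep <- stats::complete.cases(df[use_cols])
  df <- df[keep, , drop = FALSE]
  if (is.null(weights) && !is.null(rm_$weight)) weights <- rm_$weight
  core <- hi_core(df, rm_, ocol, rank_col, engine, weights)

  se_hi <- NA_real_
  if (se_method == "convenient") {
    s <- ranked_sample(core$h_std, ranks = core$r, weights = core$w,
                       label = rank_col)
    se_hi <- ci_standard_error(s, method = "convenient")
  } else if (se_method == "bootstrap") {
    if (reps < 100) stop("bootstrap needs reps >= 100", call. = FALSE)
    n <- nrow(df)
    his <- with_seed(seed, vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(hi_core(df[idx, , drop = FALSE], rm_, ocol, rank_col,
                       engine, weights)$hi,
               error = function(e) NA_real_)
    }, numeric(1)))
    se_hi <- stats::sd(his, na.rm = TRUE)
  }

  structure(list(h_hat = core$h_hat, h_std = core$h_std, hbar = core$hbar,
                 mu_hat = core$mu_hat,
                 ci_actual = core$ci_actual, ci_need = core$ci_need,
                 hi = core$hi, hi_alt = core$hi_alt, se_hi = se_hi,
                 n = core$n, rank_label = rank_col, outcome_label = ocol,
                 country = unique(as.character(df[[rm_$country]])),
                 engine = engine),
            class = "inequity_result")
}

#' @export
print.inequity_result <- function(x, ...) {
  cat("inequity_result (", x$engine, " engine)\n", sep = "")
  cat(sprintf("  outcome: %s   rank: %s   n = %d\n",
              x$outcome_label, x$rank_label, x$n))
  cat(sprintf("  CI(actual) = %+.4f   CI(need-predicted) = %+.4f\n",
              x$ci_actual, x$ci_need))
  cat(sprintf("  HI = %+.4f (SE %.4f) %s   [alt: %+.4f]\n",
              x$hi, x$se_hi, signif_stars(x$hi, x$se_hi), x$hi_alt))
  invisible(x)
}

cell_grid <- function(table, outcomes, ranks, per_country) {
  rm_ <- role_map_of(table)
  countries <- if (per_country)
    sort(unique(as.character(as.data.frame(table)[[rm_$country]])))
  else "pooled"
  expand.grid(country = countries, outcome = outcomes, rank = ranks,
              stringsAsFactors = FALSE)
}

subset_country <- function(table, country) {
  rm_ <- role_map_of(table)
  df <- as.data.frame(table)
  if (!identical(country, "pooled"))
    df <- df[as.character(df[[rm_$country]]) == country, , drop = FALSE]
  microdata(df, rm_, validate = FALSE)
}

#' Horizontal inequity by country, outcome and ranking variable
#'
#' One [indirect_standardize()] run per (country x outcome x ranking
#' variable) cell. Cells that cannot be estimated (e.g. a country with no
#' users of an outcome) are flagged in the `note` column and left NA; the
#' run continues.
#'
#' @inheritParams indirect_standardize
#' @param outcomes outcomes to tabulate (default formal and informal)
#' @param ranks ranking variables (default income and wealth)
#' @param per_country per-country cells (default) or one pooled row set
#' @return a data frame with columns country, outcome, rank, n, hi, se_hi,
#'   stars, ci_actual, ci_need, note
#' @export
horizontal_inequity_table <- function(table,
                                      outcomes = c("formal", "informal"),
                                      ranks = c("income", "wealth"),
                                      engine = c("logit", "lpm"),
                                      se_method = c("convenient", "bootstrap", "none"),
                                      reps = 500, seed = 1L,
                                      per_country = TRUE) {
  engine <- match.arg(engine)
  se_method <- match.arg(se_method)
  grid <- cell_grid(table, outcomes, ranks, per_country)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- tryCatch(
      indirect_standardize(subset_country(table, g$country), g$outcome,
                           rank = g$rank, engine = engine,
                           se_method = se_method, reps = reps, seed = seed),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(g, n = NA_integer_, hi = NA_real_, se_hi = NA_real_,
                 stars = "", ci_actual = NA_real_, ci_need = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(g, n = res$n, hi = res$hi, se_hi = res$se_hi,
                 stars = signif_stars(res$hi, res$se_hi),
                 ci_actual = res$ci_actual, ci_need = res$ci_need,
                 note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concentration of care use by country, outcome and ranking variable
#'
#' Raw (unstandardized) inequality: one [concentration_index()] per
#' (country x outcome x ranking variable) cell, reporting both CI and the
#' binary-outcome corrected CCI. Degenerate cells are flagged, not fatal.
#'
#' @inheritParams horizontal_inequity_table
#' @return a data frame with columns country, outcome, rank, n, mu, ci,
#'   se_ci, cci, se_cci, stars, note
#' @export
inequality_table <- function(table,
                             outcomes = c("formal", "informal"),
                             ranks = c("income", "wealth"),
                             se_method = c("convenient", "bootstrap", "none"),
                             reps = 500, seed = 1L, per_country = TRUE) {
  se_method <- match.arg(se_method)
  rm_ <- role_map_of(table)
  grid <- cell_grid(table, outcomes, ranks, per_country)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- tryCatch({
      sub <- as.data.frame(subset_country(table, g$country))
      ocol <- resolve_outcome(microdata(sub, rm_, validate = FALSE), g$outcome)
      rank_col <- resolve_rank(microdata(sub, rm_, validate = FALSE), g$rank)
      keep <- stats::complete.cases(sub[c(ocol, rank_col, rm_$weight)])
      sub <- sub[keep, , drop = FALSE]
      w <- if (!is.null(rm_$weight)) sub[[rm_$weight]] else NULL
      s <- ranked_sample(sub[[ocol]], ses = sub[[rank_col]], weights = w,
                         label = rank_col, outcome_label = ocol,
                         country = g$country)
      concentration_index(s, se_method = se_method, reps = reps, seed = seed)
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(g, n = NA_integer_, mu = NA_real_, ci = NA_real_,
                 se_ci = NA_real_, cci = NA_real_, se_cci = NA_real_,
                 stars = "", note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(g, n = res$n, mu = res$mu, ci = res$ci, se_ci = res$se_ci,
                 cci = res$cci, se_cci = res$se_cci,
                 stars = signif_stars(res$ci, res$se_ci), note = "",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
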