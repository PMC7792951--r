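# Binary-outcome utilization models. Maximum likelihood is delegated to
# stats::glm (IRLS); the robust covariance comes from the sandwich package.
# Prediction, including the design-column overrides used by indirect
# standardization, is done against the stored terms object here so fitted
# models stay small and self-contained.

resolve_outcome <- function(table, outcome) {
  rm_ <- role_map_of(table)
  if (!is.null(rm_)) {
    if (identical(outcome, "formal")) return(rm_$outcome_formal)
    if (identical(outcome, "informal")) return(rm_$outcome_informal)
  }
  if (!outcome %in% names(table))
    stop("unknown outcome column: ", outcome, call. = FALSE)
  outcome
}

resolve_rank <- function(table, rank) {
  rm_ <- role_map_of(table)
  if (!is.null(rm_)) {
    if (identical(rank, "income")) return(rm_$rank_income)
    if (identical(rank, "wealth")) return(rm_$rank_wealth)
  }
  if (!rank %in% names(table))
    stop("unknown ranking column: ", rank, call. = FALSE)
  rank
}

# Model matrix for a stored design, with optional overrides.
# Overrides with a numeric value replace a data column before expansion;
# the special value "mean" replaces every design column derived from that
# variable with its (weighted) sample mean — for factor variables this fixes
# each dummy at its sample proportion.
build_design <- function(design_info, data, overrides = NULL, weights = NULL) {
  tt <- design_info$terms
  vars <- all.vars(tt)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0)
    stop("table lacks model columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  labels <- attr(tt, "term.labels")
  mean_over <- character(0)
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!nm %in% vars)
      stop("unknown override column: ", nm, call. = FALSE)
    if (identical(v, "mean")) mean_over <- c(mean_over, nm)
    else data[[nm]] <- v
  }
  for (v in vars) {
    if (is.character(data[[v]]))
      data[[v]] <- factor(data[[v]],
                          levels = design_info$xlevels[[v]] %||%
                            sort(unique(data[[v]])))
    else if (is.factor(data[[v]]) && !is.null(design_info$xlevels[[v]]))
      data[[v]] <- factor(data[[v]], levels = design_info$xlevels[[v]])
  }
  mf <- stats::model.frame(tt, data, xlev = design_info$xlevels)
  mm <- stats::model.matrix(tt, mf, contrasts.arg = design_info$contrasts)
  if (length(mean_over) > 0) {
    asg <- attr(mm, "assign")
    w <- weights %||% rep(1, nrow(mm))
    for (nm in mean_over) {
      cols <- which(asg == match(nm, labels))
      for (jc in cols) mm[, jc] <- wmean(mm[, jc], w)
    }
  }
  mm
}

#' Fit a logistic utilization model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of a binary care outcome on the supplied covariates, with a
#' robust (sandwich) covariance matrix by default — the estimator whose
#' objective is reported as a log-pseudolikelihood. Character covariates are
#' expanded to dummies against their first factor level (set the factor
#' levels to choose reference categories). Rows with missing values in the
#' outcome or covariates are dropped (listwise deletion per model) and the
#' count recorded.
#'
#' @param table a [microdata()] object or plain data frame
#' @param outcome `"formal"`, `"informal"` (resolved through the role map)
#'   or a column name of a 0/1 variable
#' @param covariates character vector of covariate columns; defaults to the
#'   role map's need + non-need lists
#' @param weights optional frequency-style weights: a column name or a
#'   numeric vector (default: unweighted)
#' @param robust use the sandwich covariance (default) instead of the
#'   inverse Fisher information
#' @return an object of class `logit_fit` with elements `beta`, `cov`, `se`,
#'   `or`, `loglik` (log-pseudolikelihood), `n`, `n_dropped`, `fitted`,
#'   and `design_info`
#' @seealso [odds_ratios()], [predict_prob()]
#' @export
fit_logit <- function(table, outcome, covariates = NULL, weights = NULL,
                      robust = TRUE) {
  rm_ <- role_map_of(table)
  ocol <- resolve_outcome(table, outcome)
  if (is.null(covariates)) {
    if (is.null(rm_))
      stop("covariates must be given when the table has no role map",
           call. = FALSE)
    covariates <- c(rm_$need, rm_$nonneed)
  }
  df <- as.data.frame(table)
  cov_cols <- setdiff(covariates, "1")   # "1" = intercept-only model
  missing_cols <- setdiff(c(ocol, cov_cols), names(df))
  if (length(missing_cols) > 0)
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.character(weights) && length(weights) == 1) {
    if (!weights %in% names(df))
      stop("weight column not found: ", weights, call. = FALSE)
    w <- df[[weights]]
  } else if (is.numeric(weights)) {
    w <- weights
  } else w <- rep(1, nrow(df))
  keep <- stats::complete.cases(df[c(ocol, cov_cols)]) & !is.na(w)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  w <- w[keep]
  check_weights(w, nrow(df))
  y <- df[[ocol]]
  if (!all(y %in% c(0, 1)))
    stop("outcome '", ocol, "' must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome '", ocol, "' has a single class", call. = FALSE)
  for (v in cov_cols) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  # covariates with no variation in the estimation sample carry no
  # information and would only alias the intercept
  constant <- vapply(cov_cols, function(v)
    length(unique(df[[v]][!is.na(df[[v]])])) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant covariates: ",
            paste(cov_cols[constant], collapse = ", "))
    covariates <- setdiff(covariates, cov_cols[constant])
    if (length(covariates) == 0) covariates <- "1"
  }
  fml <- stats::reformulate(covariates, response = as.name(ocol))
  environment(fml) <- environment()
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df, weights = w,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged)
    stop("logistic fit did not converge within 100 iterations; ",
         "last deviance ", format(fit$deviance), call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("design matrix is rank deficient; aliased terms: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  p <- fit$fitted.values
  if (min(p) < 1e-12 || max(p) > 1 - 1e-12) {
    # fitted probabilities at machine 0/1: the likelihood is maximized on
    # the boundary, i.e. (quasi-)perfect separation; name the dominant term
    X <- stats::model.matrix(fit)
    contrib <- abs(beta[-1]) * apply(X[, -1, drop = FALSE], 2, stats::sd)
    stop("possible perfect separation involving: ",
         names(which.max(contrib)), call. = FALSE)
  }
  V <- if (robust) sandwich::sandwich(fit) else stats::vcov(fit)
  ll <- sum(w * (y * log(p) + (1 - y) * log1p(-p)))
  tt <- stats::delete.response(stats::terms(fit))
  attr(tt, ".Environment") <- baseenv()
  structure(list(
    beta = beta, cov = V, se = sqrt(diag(V)), or = exp(beta),
    loglik = ll, n = nrow(df), n_dropped = n_dropped, robust = robust,
    fitted = p, y = y, weights = w,
    design_info = list(terms = tt, xlevels = fit$xlevels,
                       contrasts = fit$contrasts,
                       covariates = covariates, outcome = ocol)),
    class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("logit_fit: ", x$design_info$outcome, " ~ ",
      paste(x$design_info$covariates, collapse = " + "), "\n", sep = "")
  tab <- data.frame(coef = x$beta, se = x$se, or = x$or,
                    stars = signif_stars(x$beta, x$se))
  print(round_df(tab, 4))
  cat(sprintf("Log pseudolikelihood: %.4f   n = %d (%d dropped)\n",
              x$loglik, x$n, x$n_dropped))
  invisible(x)
}

round_df <- function(d, digits) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- round(d[[j]], digits)
  d
}

#' Odds ratios with delta-method standard errors
#'
#' Because the logit model is nonlinear, coefficients are reported as odds
#' ratios exp(beta) — the multiplicative effect on the odds
#' p / (1 - p). The delta-method standard error is OR * SE(beta).
#'
#' @param fit a [fit_logit()] result, or a numeric coefficient vector
#' @param se optional standard errors when `fit` is a numeric vector
#' @param ... unused
#' @return a data frame with columns `term`, `or`, `se`
#' @export
odds_ratios <- function(fit, ...) UseMethod("odds_ratios")

#' @rdname odds_ratios
#' @export
odds_ratios.logit_fit <- function(fit, ...) {
  data.frame(term = names(fit$beta), or = exp(fit$beta),
             se = exp(fit$beta) * fit$se, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname odds_ratios
#' @export
odds_ratios.default <- function(fit, se = NULL, ...) {
  beta <- as.numeric(fit)
  or_ <- exp(beta)
  data.frame(term = names(fit) %||% paste0("b", seq_along(beta)),
             or = or_,
             se = if (is.null(se)) NA_real_ else or_ * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predicted probabilities from a fitted logit model
#'
#' Evaluates logistic(x_i' beta) on new data, optionally holding columns at
#' fixed values. An override value may be a scalar (imposed on the data
#' column before dummy expansion) or the string `"mean"`, which fixes every
#' design column derived from that variable at its (weighted) sample mean —
#' for categorical variables, the dummy proportions. This is the mechanism
#' indirect need-standardization uses to neutralize non-need variables.
#'
#' @param fit a [fit_logit()] result
#' @param table data to predict on
#' @param overrides named list, column -> value or "mean"
#' @param weights optional weights used for the "mean" overrides
#' @return numeric vector of probabilities in (0, 1)
#' @export
predict_prob <- function(fit, table, overrides = NULL, weights = NULL) {
  stopifnot(inherits(fit, "logit_fit"))
  mm <- build_design(fit$design_info, as.data.frame(table),
                     overrides = overrides, weights = weights)
  unname(stats::plogis(drop(mm %*% fit$beta)))
}

# Linear-probability counterpart used by the "lpm" standardization engine:
# same design handling, identity link, OLS coefficients.
fit_lpm <- function(table, outcome, covariates = NULL, weights = NULL) {
  rm_ <- role_map_of(table)
  ocol <- resolve_outcome(table, outcome)
  if (is.null(covariates)) covariates <- c(rm_$need, rm_$nonneed)
  df <- as.data.frame(table)
  if (is.character(weights) && length(weights) == 1) w <- df[[weights]]
  else if (is.numeric(weights)) w <- weights
  else w <- rep(1, nrow(df))
  keep <- stats::complete.cases(df[c(ocol, covariates)]) & !is.na(w)
  df <- df[keep, , drop = FALSE]
  w <- w[keep]
  for (v in covariates)
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  fml <- stats::reformulate(covariates, response = as.name(ocol))
  environment(fml) <- environment()
  fit <- stats::lm(fml, data = df, weights = w)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("design matrix is rank deficient; aliased terms: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  tt <- stats::delete.response(stats::terms(fit))
  attr(tt, ".Environment") <- baseenv()
  structure(list(
    beta = beta, n = nrow(df), weights = w,
    design_info = list(terms = tt, xlevels = fit$xlevels,
                       contrasts = fit$contrasts,
                       covariates = covariates, outcome = ocol)),
    class = "lpm_fit")
}

predict_lpm <- function(fit, table, overrides = NULL, weights = NULL) {
  mm <- build_design(fit$design_info, as.data.frame(table),
                     overrides = overrides, weights = weights)
  drop(mm %*% fit$beta)
}
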