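# Multi-country synthetic microdata with a known data-generating process.
#
# The generator emulates the structure of a SHARE-like cross-section of
# Europeans aged 50+: right-skewed, correlated household income and wealth;
# categorical age groups; over-dispersed ADL-limitation and chronic-disease
# counts; a self-assessed-health indicator whose log-odds decline with ADL
# limitations; and binary formal/informal care outcomes drawn from a
# logistic model over need and non-need determinants plus a direct SES
# effect that enters through the within-country fractional income rank --
# so the inequity it induces is exactly what the concentration-index
# machinery measures.

# Per-country calibration anchors (proportions, means, SDs) for ten European
# countries, loosely matched to published survey summaries for this
# population. educ1/2/3 are primary/secondary/tertiary shares.
share_country_stats <- function() {
  df <- read.table(header = TRUE, text = "
code informal formal female age_mean age_sd single educ1 educ2 educ3 nchild chhh hhsize urban saghs adl ncd
AT 0.410148 0.107383 0.590210 70.7449  9.2835 0.363665 0.233448 0.496392 0.270160 2.1064 0.002196 1.8817 0.507085 0.618136 0.2949 1.9206
DE 0.326139 0.073471 0.529102 68.1372  9.3417 0.245194 0.113247 0.564656 0.322096 1.9920 0.003687 1.9573 0.591251 0.569660 0.2499 2.0716
SE 0.241088 0.073350 0.538172 72.1986  8.8213 0.287465 0.338674 0.332077 0.329249 2.2164 0.001885 1.7908 0.621395 0.684889 0.1976 1.6510
ES 0.229379 0.090217 0.556886 71.5682 10.2876 0.276305 0.785714 0.105646 0.108640 2.5501 0.005560 2.2397 0.846242 0.551112 0.4134 2.0079
IT 0.202936 0.053239 0.547803 69.1585  9.6743 0.229411 0.688231 0.231398 0.080371 2.0571 0.008170 2.3449 0.657284 0.557960 0.2826 1.6410
FR 0.296752 0.114109 0.579745 69.6413 10.2909 0.348696 0.386598 0.370831 0.242571 2.3302 0.002426 1.8924 0.518461 0.624924 0.2674 1.8451
DK 0.380952 0.067636 0.541356 67.1915  9.6754 0.261194 0.166356 0.378731 0.454913 2.2384 0.004353 1.8955 0.754119 0.736629 0.1785 1.5917
GR 0.209694 0.048249 0.573544 69.6703  9.3476 0.285620 0.520237 0.298124 0.181639 1.8643 0.003620 2.1316 0.843353 0.668641 0.1612 1.9197
BE 0.275995 0.189184 0.553472 68.3192 10.2364 0.320008 0.365135 0.276942 0.357923 2.1507 0.004739 1.9825 0.671958 0.678137 0.3313 2.0387
CZ 0.451754 0.071810 0.599237 70.3550  8.5431 0.331345 0.380248 0.476861 0.142891 2.1155 0.002624 1.9854 0.711117 0.675573 0.3137 2.3447
", stringsAsFactors = FALSE)
  df
}

# Default generating coefficients for the two outcome models (log-odds
# scale), matching the magnitudes typical of utilization studies in this
# population. Intercepts are calibrated separately per country.
default_coef_formal <- function() c(
  female = 0.3556, age_66_80 = 0.5817, age_80p = 1.7870,
  saghs = -0.7566, adl = 0.4994, ncd = 0.1347,
  single = 0.6815, educ_secondary = -0.0919, educ_tertiary = 0.1363,
  nchild = 0.0028, chhh = -0.2824, hhsize = -0.1669, urban = 0.2344)

default_coef_informal <- function() c(
  female = 0.1415, age_66_80 = 0.0423, age_80p = 0.7107,
  saghs = -0.5225, adl = 0.4329, ncd = 0.1663,
  single = 0.5967, educ_secondary = 0.0244, educ_tertiary = -0.0372,
  nchild = 0.0836, chhh = -0.3232, hhsize = -0.1995, urban = -0.2925)

#' Specify one country block of a synthetic configuration
#'
#' Distributional parameters of one country's respondents. Outcome
#' intercepts are either given explicitly (`intercept_*`) or calibrated at
#' generation time by root-finding so that the realized expected prevalence
#' equals `prev_*`.
#'
#' @param code country label
#' @param n respondents to draw (>= 2)
#' @param prev_formal,prev_informal target marginal prevalences in (0, 1)
#' @param female_p,single_p,urban_p,chhh_p,saghs_p Bernoulli probabilities
#' @param age_mean,age_sd age distribution (normal, truncated to 50-104)
#' @param educ_p length-3 probabilities (primary, secondary, tertiary)
#' @param nchild_mean Poisson mean of the number of children
#' @param hhsize_mean mean household size (1 + Poisson(hhsize_mean - 1))
#' @param adl_mean,ncd_mean means of the ADL-limitation and chronic-disease
#'   counts (negative binomial; dispersion set at config level)
#' @param income_meanlog,income_sdlog,wealth_meanlog,wealth_sdlog log-normal
#'   parameters of household income and wealth
#' @param iw_cor income-wealth correlation on the log scale, in (-1, 1)
#' @param intercept_formal,intercept_informal explicit model intercepts;
#'   NA means "calibrate to the prevalence target"
#' @return a list of class `country_spec`
#' @export
country_spec <- function(code, n = 2000,
                         prev_formal = 0.09, prev_informal = 0.28,
                         female_p = 0.56, age_mean = 69.7, age_sd = 9.7,
                         single_p = 0.29, educ_p = c(0.4, 0.35, 0.25),
                         nchild_mean = 2.15, chhh_p = 0.004,
                         hhsize_mean = 2.03, urban_p = 0.68, saghs_p = 0.63,
                         adl_mean = 0.28, ncd_mean = 1.92,
                         income_meanlog = 10, income_sdlog = 0.7,
                         wealth_meanlog = 11.8, wealth_sdlog = 1.2,
                         iw_cor = 0.6,
                         intercept_formal = NA_real_,
                         intercept_informal = NA_real_) {
  probs <- c(prev_formal, prev_informal, female_p, single_p, urban_p,
             chhh_p, saghs_p, educ_p)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1] (country ", code, ")",
         call. = FALSE)
  if (abs(sum(educ_p) - 1) > 1e-8)
    stop("educ_p must sum to 1 (country ", code, ")", call. = FALSE)
  if (n < 2) stop("n must be >= 2 (country ", code, ")", call. = FALSE)
  if (abs(iw_cor) >= 1)
    stop("iw_cor must lie strictly inside (-1, 1)", call. = FALSE)
  if (min(adl_mean, ncd_mean, nchild_mean) < 0 || hhsize_mean < 1)
    stop("count means out of range (country ", code, ")", call. = FALSE)
  structure(list(code = code, n = n, prev_formal = prev_formal,
                 prev_informal = prev_informal, female_p = female_p,
                 age_mean = age_mean, age_sd = age_sd, single_p = single_p,
                 educ_p = educ_p, nchild_mean = nchild_mean, chhh_p = chhh_p,
                 hhsize_mean = hhsize_mean, urban_p = urban_p,
                 saghs_p = saghs_p, adl_mean = adl_mean, ncd_mean = ncd_mean,
                 income_meanlog = income_meanlog,
                 income_sdlog = income_sdlog,
                 wealth_meanlog = wealth_meanlog,
                 wealth_sdlog = wealth_sdlog, iw_cor = iw_cor,
                 intercept_formal = intercept_formal,
                 intercept_informal = intercept_informal),
            class = "country_spec")
}

#' Build a synthetic multi-country study configuration
#'
#' @param countries list of [country_spec()] blocks
#' @param coef_formal,coef_informal named generating coefficient vectors on
#'   the log-odds scale (see [default_share_like_config()] for the names)
#' @param delta_formal,delta_informal direct SES effects: log-odds change
#'   per unit of the within-country fractional income rank. Zero makes the
#'   outcome conditionally independent of SES given the covariates — the
#'   null for horizontal-inequity tests.
#' @param adl_size,ncd_size negative-binomial dispersion (size) of the two
#'   count variables; small size = heavy over-dispersion
#' @param saghs_adl_slope decline of the good-health log-odds per ADL
#'   limitation
#' @param seed master seed; each country draws from its own stream derived
#'   deterministically from the master seed and the country code, so adding
#'   a country does not perturb the others
#' @return a list of class `synthetic_config`
#' @export
synthetic_config <- function(countries,
                             coef_formal = default_coef_formal(),
                             coef_informal = default_coef_informal(),
                             delta_formal = 0.5, delta_informal = -1.0,
                             adl_size = 0.12, ncd_size = 4.9,
                             saghs_adl_slope = 0.8, seed = 1L) {
  if (!is.list(countries) || length(countries) == 0)
    stop("countries must be a non-empty list of country_spec", call. = FALSE)
  countries <- lapply(countries, function(cs) {
    if (!inherits(cs, "country_spec")) do.call(country_spec, cs) else cs
  })
  names(countries) <- vapply(countries, `[[`, character(1), "code")
  needed <- names(default_coef_formal())
  for (co in list(coef_formal, coef_informal))
    if (!all(needed %in% names(co)))
      stop("coefficient vector lacks terms: ",
           paste(setdiff(needed, names(co)), collapse = ", "), call. = FALSE)
  if (min(adl_size, ncd_size) <= 0)
    stop("dispersion sizes must be positive", call. = FALSE)
  structure(list(countries = countries,
                 coef_formal = coef_formal, coef_informal = coef_informal,
                 delta_formal = delta_formal, delta_informal = delta_informal,
                 adl_size = adl_size, ncd_size = ncd_size,
                 saghs_adl_slope = saghs_adl_slope,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default ten-country configuration
#'
#' Country blocks for AT, DE, SE, ES, IT, FR, DK, GR, BE and CZ with
#' prevalences and covariate means matched to published per-country
#' summaries of this survey population (informal-care prevalence ranging
#' roughly 0.20-0.45 across countries, formal care 0.05-0.19).
#'
#' @param n_per_country respondents per country
#' @param delta_formal,delta_informal direct SES effects (see
#'   [synthetic_config()]); the defaults induce the pro-rich formal /
#'   pro-poor informal pattern typical of European LTC data
#' @param seed master seed
#' @return a `synthetic_config`
#' @export
default_share_like_config <- function(n_per_country = 2000,
                                      delta_formal = 0.5,
                                      delta_informal = -1.0,
                                      seed = 1L) {
  st <- share_country_stats()
  countries <- lapply(seq_len(nrow(st)), function(i) {
    s <- st[i, ]
    country_spec(code = s$code, n = n_per_country,
                 prev_formal = s$formal, prev_informal = s$informal,
                 female_p = s$female, age_mean = s$age_mean,
                 age_sd = s$age_sd, single_p = s$single,
                 educ_p = c(s$educ1, s$educ2, s$educ3) /
                   (s$educ1 + s$educ2 + s$educ3),
                 nchild_mean = s$nchild, chhh_p = s$chhh,
                 hhsize_mean = s$hhsize, urban_p = s$urban,
                 saghs_p = s$saghs, adl_mean = s$adl, ncd_mean = s$ncd)
  })
  synthetic_config(countries, delta_formal = delta_formal,
                   delta_informal = delta_informal, seed = seed)
}

#' Default role map for generated tables
#' @return a [role_map()] matching the columns [generate_microdata()] emits
#' @export
synthetic_role_map <- function() {
  role_map(outcome_formal = "formal", outcome_informal = "informal",
           rank_income = "income", rank_wealth = "wealth",
           need = c("age_group", "female", "saghs", "adl", "ncd"),
           nonneed = c("single", "education", "nchild", "chhh",
                       "hhsize", "urban"),
           country = "country")
}

country_seed <- function(master, code) {
  h <- 0
  for (b in utf8ToInt(code)) h <- (h * 131 + b) %% 30269
  as.integer((as.numeric(master) * 30269 + h) %% 2147483646 + 1)
}

solve_intercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  stats::uniroot(f, interval = c(-30, 15), tol = 1e-12)$root
}

eta_from_coef <- function(co, d) {
  co[["female"]] * d$female +
    co[["age_66_80"]] * (d$age_group == "66-80") +
    co[["age_80p"]] * (d$age_group == "80+") +
    co[["saghs"]] * d$saghs + co[["adl"]] * d$adl + co[["ncd"]] * d$ncd +
    co[["single"]] * d$single +
    co[["educ_secondary"]] * (d$education == "secondary") +
    co[["educ_tertiary"]] * (d$education == "tertiary") +
    co[["nchild"]] * d$nchild + co[["chhh"]] * d$chhh +
    co[["hhsize"]] * d$hhsize + co[["urban"]] * d$urban
}

generate_country <- function(cs, config) {
  set.seed(country_seed(config$seed, cs$code))
  n <- cs$n
  # correlated log-normal income and wealth
  z1 <- stats::rnorm(n)
  z2 <- cs$iw_cor * z1 + sqrt(1 - cs$iw_cor^2) * stats::rnorm(n)
  income <- exp(cs$income_meanlog + cs$income_sdlog * z1)
  wealth <- exp(cs$wealth_meanlog + cs$wealth_sdlog * z2)
  age <- pmin(pmax(stats::rnorm(n, cs$age_mean, cs$age_sd), 50), 104)
  age_group <- cut(age, breaks = c(-Inf, 65, 80, Inf),
                   labels = c("50-65", "66-80", "80+"))
  female <- stats::rbinom(n, 1, cs$female_p)
  single <- stats::rbinom(n, 1, cs$single_p)
  education <- factor(sample(c("primary", "secondary", "tertiary"), n,
                             replace = TRUE, prob = cs$educ_p),
                      levels = c("primary", "secondary", "tertiary"))
  nchild <- stats::rpois(n, cs$nchild_mean)
  chhh <- stats::rbinom(n, 1, cs$chhh_p)
  hhsize <- 1 + stats::rpois(n, cs$hhsize_mean - 1)
  urban <- stats::rbinom(n, 1, cs$urban_p)
  adl <- stats::rnbinom(n, size = config$adl_size, mu = cs$adl_mean)
  ncd <- stats::rnbinom(n, size = config$ncd_size, mu = cs$ncd_mean)
  # good health declines with ADL limitations; level set to the country's
  # marginal good-health share on the realized ADL draws
  a_sag <- solve_intercept(-config$saghs_adl_slope * adl, cs$saghs_p)
  saghs <- stats::rbinom(n, 1, stats::plogis(a_sag -
                                             config$saghs_adl_slope * adl))
  d <- data.frame(country = cs$code, female, age, age_group, single,
                  education, nchild, chhh, hhsize, urban, saghs, adl, ncd,
                  income, wealth, stringsAsFactors = FALSE)
  r_inc <- fractional_rank(income)
  for (oc in c("formal", "informal")) {
    co <- config[[paste0("coef_", oc)]]
    delta <- config[[paste0("delta_", oc)]]
    eta <- eta_from_coef(co, d) + delta * r_inc
    a <- cs[[paste0("intercept_", oc)]]
    if (is.na(a)) a <- solve_intercept(eta, cs[[paste0("prev_", oc)]])
    d[[oc]] <- stats::rbinom(n, 1, stats::plogis(a + eta))
    attr(d, paste0("intercept_", oc)) <- a
  }
  d
}

#' Generate a synthetic multi-country microdata table
#'
#' Deterministic given the configuration seed. Each country is drawn from
#' its own RNG stream, so country blocks are reproducible independently of
#' which other countries are present. The solved per-country outcome
#' intercepts are attached as the `"intercepts"` attribute.
#'
#' @param config a [synthetic_config()]
#' @return a [microdata()] table bound to [synthetic_role_map()]
#' @export
generate_microdata <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  blocks <- lapply(config$countries, generate_country, config = config)
  intercepts <- lapply(blocks, function(b)
    c(formal = attr(b, "intercept_formal"),
      informal = attr(b, "intercept_informal")))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out <- microdata(out, synthetic_role_map())
  attr(out, "intercepts") <- intercepts
  out
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$countries <- lapply(x$countries, function(cs) {
    cs <- unclass(cs)
    cs$educ_p <- as.numeric(cs$educ_p)
    cs
  })
  x$coef_formal <- as.list(x$coef_formal)
  x$coef_informal <- as.list(x$coef_informal)
  x
}

list_to_config <- function(x) {
  countries <- lapply(x$countries, function(cs) {
    cs$educ_p <- as.numeric(unlist(cs$educ_p))
    do.call(country_spec, cs)
  })
  synthetic_config(countries,
                   coef_formal = unlist(x$coef_formal),
                   coef_informal = unlist(x$coef_informal),
                   delta_formal = x$delta_formal,
                   delta_informal = x$delta_informal,
                   adl_size = x$adl_size, ncd_size = x$ncd_size,
                   saghs_adl_slope = x$saghs_adl_slope,
                   seed = x$seed)
}

#' Write / read a synthetic configuration as YAML
#'
#' All generator parameters are emitted in a human-readable key-value file
#' that round-trips through [read_synthetic_config()].
#'
#' @param config a [synthetic_config()]
#' @param path file path
#' @return `path` (write) or the configuration (read)
#' @export
write_synthetic_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  list_to_config(yaml::read_yaml(path))
}
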