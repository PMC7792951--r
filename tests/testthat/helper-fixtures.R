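# Shared fixtures: tiny role-mapped tables and small synthetic configs.

toy_role_map <- function(weight = NULL) {
  role_map(outcome_formal = "fc", outcome_informal = "ic",
           rank_income = "inc", rank_wealth = "wlt",
           need = c("adl", "saghs"), nonneed = c("single", "urban"),
           country = "cty", weight = weight)
}

toy_table <- function(n = 8, weight = FALSE) {
  set.seed(42)
  d <- data.frame(
    fc = rep(c(0, 1), length.out = n),
    ic = rep(c(1, 0), length.out = n),
    inc = seq_len(n) * 100,
    wlt = rev(seq_len(n)) * 1000,
    adl = rpois(n, 0.5),
    saghs = rbinom(n, 1, 0.6),
    single = rbinom(n, 1, 0.3),
    urban = rbinom(n, 1, 0.7),
    cty = rep(c("AA", "BB"), each = n / 2))
  if (weight) d$wt <- runif(n, 0.5, 2)
  microdata(d, toy_role_map(if (weight) "wt"))
}

# Single-country configuration in which need is independent of SES and there
# is no direct SES effect: the null under which HI should center on zero.
null_config <- function(n = 5000, seed = 1L) {
  synthetic_config(
    list(country_spec(code = "XX", n = n)),
    delta_formal = 0, delta_informal = 0, seed = seed)
}

# Single-country configuration with known direct SES effects.
effect_config <- function(n = 5000, delta_formal = 0.5, delta_informal = -1,
                          seed = 1L) {
  synthetic_config(
    list(country_spec(code = "XX", n = n)),
    delta_formal = delta_formal, delta_informal = delta_informal, seed = seed)
}

# Map from generating-coefficient names to fitted glm term names, for
# parameter-recovery checks.
coef_term_map <- function() c(
  female = "female", age_66_80 = "age_group66-80", age_80p = "age_group80+",
  saghs = "saghs", adl = "adl", ncd = "ncd", single = "single",
  educ_secondary = "educationsecondary", educ_tertiary = "educationtertiary",
  nchild = "nchild", chhh = "chhh", hhsize = "hhsize", urban = "urban")

# Independent population-weighted covariance used as a brute-force oracle.
wcov_test <- function(x, y, w) {
  tw <- sum(w)
  mx <- sum(w * x) / tw
  my <- sum(w * y) / tw
  sum(w * (x - mx) * (y - my)) / tw
}
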