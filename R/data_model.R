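#' Variable-role map for long-term-care microdata
#'
#' Binds arbitrary column names of a respondent-level table to the roles the
#' analysis needs: the two binary care outcomes, the socioeconomic ranking
#' variables, the need and non-need determinants, the country label and an
#' optional survey weight. Column names are free; the role map is what welds
#' a file to the pipeline, so the package is not tied to any survey's naming.
#'
#' Need determinants are the health/demography variables a fair allocation
#' would respond to (age group, gender, self-assessed health, ADL limitations,
#' chronic conditions); non-need determinants are everything else entering the
#' utilization model (marital status, education, household composition,
#' urbanicity, ...).
#'
#' @param outcome_formal,outcome_informal column names of the 0/1 formal and
#'   informal care indicators
#' @param rank_income,rank_wealth column names of the two socioeconomic
#'   ranking variables (household income and household wealth)
#' @param need character vector of need-determinant columns
#' @param nonneed character vector of non-need-determinant columns
#' @param country column name of the country label
#' @param weight optional column name of a strictly positive survey weight
#' @return an object of class `role_map`
#' @seealso [microdata()], [read_microdata()]
#' @export
role_map <- function(outcome_formal, outcome_informal,
                     rank_income, rank_wealth,
                     need, nonneed, country, weight = NULL) {
  rm_ <- structure(list(
    outcome_formal  = outcome_formal,
    outcome_informal = outcome_informal,
    rank_income = rank_income,
    rank_wealth = rank_wealth,
    need = need,
    nonneed = nonneed,
    country = country,
    weight = weight
  ), class = "role_map")
  reserved <- c(outcome_formal, outcome_informal, rank_income, rank_wealth,
                country, weight)
  if (length(intersect(need, nonneed)) > 0)
    stop("need and nonneed lists must be disjoint; overlap: ",
         paste(intersect(need, nonneed), collapse = ", "), call. = FALSE)
  if (length(intersect(c(need, nonneed), reserved)) > 0)
    stop("need/nonneed lists must not contain outcome, rank, country or ",
         "weight columns: ",
         paste(intersect(c(need, nonneed), reserved), collapse = ", "),
         call. = FALSE)
  rm_
}

#' @export
print.role_map <- function(x, ...) {
  cat("role_map\n")
  cat("  outcomes: formal=", x$outcome_formal,
      ", informal=", x$outcome_informal, "\n", sep = "")
  cat("  ranks:    income=", x$rank_income,
      ", wealth=", x$rank_wealth, "\n", sep = "")
  cat("  need:     ", paste(x$need, collapse = ", "), "\n", sep = "")
  cat("  nonneed:  ", paste(x$nonneed, collapse = ", "), "\n", sep = "")
  cat("  country:  ", x$country,
      if (!is.null(x$weight)) paste0("   weight: ", x$weight), "\n", sep = "")
  invisible(x)
}

role_columns <- function(rm_) {
  c(rm_$outcome_formal, rm_$outcome_informal, rm_$rank_income, rm_$rank_wealth,
    rm_$need, rm_$nonneed, rm_$country, rm_$weight)
}

#' Construct a validated microdata table
#'
#' Attaches a [role_map()] to a respondent-level data frame and validates the
#' contract: every role column exists, outcomes are 0/1 (missing allowed),
#' ranking variables are numeric and weights, if present, are strictly
#' positive and finite.
#'
#' @param data a data frame, one row per respondent
#' @param role_map a [role_map()]
#' @param validate run validation (default TRUE)
#' @return the data frame with class `microdata` and the role map attached
#' @export
microdata <- function(data, role_map, validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  attr(data, "role_map") <- role_map
  class(data) <- c("microdata", "data.frame")
  if (validate) validate_microdata(data)
  data
}

#' Retrieve the role map attached to a microdata table
#' @param x a `microdata` object
#' @return the attached [role_map()]
#' @export
role_map_of <- function(x) attr(x, "role_map")

#' @rdname microdata
#' @param x a `microdata` object
#' @export
validate_microdata <- function(x) {
  rm_ <- role_map_of(x)
  if (is.null(rm_)) stop("no role_map attached", call. = FALSE)
  missing_cols <- setdiff(role_columns(rm_), names(x))
  if (length(missing_cols) > 0)
    stop("role columns absent from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (oc in c(rm_$outcome_formal, rm_$outcome_informal)) {
    v <- x[[oc]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad) > 0)
      stop("outcome column '", oc, "' must be 0/1; offending rows: ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) ", ...", call. = FALSE)
  }
  for (rc in c(rm_$rank_income, rm_$rank_wealth)) {
    if (!is.numeric(x[[rc]]))
      stop("ranking column '", rc, "' must be numeric", call. = FALSE)
  }
  if (!is.null(rm_$weight)) {
    w <- x[[rm_$weight]]
    if (any(!is.na(w) & (!is.finite(w) | w <= 0)))
      stop("weights in '", rm_$weight,
           "' must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read respondent-level microdata from a delimited file
#'
#' Reads a delimited text file with a header row, binds the supplied role
#' map and validates the result. The default missing-data policy is
#' `"keep"`: rows with missing values are retained and each estimator later
#' applies listwise deletion on the columns it actually uses. Under
#' `"drop"` any row with a missing value in a role column is removed at read
#' time (the count is reported via `message()`); `"error"` refuses files
#' containing missing role values.
#'
#' @param path path to a CSV/TSV file with header
#' @param role_map a [role_map()]
#' @param missing one of "keep", "drop", "error"
#' @param sep field separator; guessed from the extension when NULL
#' @return a validated [microdata()] table
#' @export
read_microdata <- function(path, role_map,
                           missing = c("keep", "drop", "error"),
                           sep = NULL) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- guess_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(role_columns(role_map), names(df))
  if (length(missing_cols) > 0)
    stop("role columns absent from '", path, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (missing != "keep") {
    cc <- stats::complete.cases(df[role_columns(role_map)])
    n_drop <- sum(!cc)
    if (missing == "error" && n_drop > 0)
      stop(n_drop, " rows have missing values in role columns", call. = FALSE)
    if (n_drop > 0) {
      message("read_microdata: dropped ", n_drop,
              " rows with missing role values")
      df <- df[cc, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  microdata(df, role_map)
}

#' Write a microdata table to a delimited file
#'
#' Round-trips with [read_microdata()]: reading a written file with the same
#' role map reproduces the table (factors come back as character columns).
#'
#' @param x a `microdata` object or plain data frame
#' @param path output path (.csv or .tsv)
#' @param sep field separator; guessed from the extension when NULL
#' @return `path`, invisibly
#' @export
write_microdata <- function(x, path, sep = NULL) {
  sep <- guess_sep(path, sep)
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

describe_block <- function(df, cols) {
  out <- list()
  n <- nrow(df)
  for (v in cols) {
    x <- df[[v]]
    if (is.numeric(x) || is.logical(x)) {
      x <- as.numeric(x)
      out[[length(out) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
        n = sum(!is.na(x)), stringsAsFactors = FALSE)
    } else {
      x <- as.factor(x)
      for (lv in levels(x)) {
        ind <- as.numeric(x == lv)
        out[[length(out) + 1L]] <- data.frame(
          variable = v, level = lv,
          mean = mean(ind, na.rm = TRUE), sd = stats::sd(ind, na.rm = TRUE),
          n = sum(!is.na(ind)), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Descriptive summary of a microdata table
#'
#' One row per variable (per country when `by_country = TRUE`) with mean and
#' sample standard deviation (n - 1 denominator). Means of 0/1 indicators are
#' proportions on \[0, 1\]; categorical variables are expanded into one
#' indicator row per level.
#'
#' @param table a `microdata` object
#' @param by_country split the summary by the country column
#' @param columns columns to summarize; defaults to every role column except
#'   country and weight
#' @return a data frame with columns country (optional), variable, level,
#'   mean, sd, n
#' @export
describe <- function(table, by_country = FALSE, columns = NULL) {
  if (nrow(table) == 0) stop("cannot describe an empty table", call. = FALSE)
  rm_ <- role_map_of(table)
  df <- as.data.frame(table)
  if (is.null(columns)) {
    if (is.null(rm_)) columns <- names(df)
    else columns <- setdiff(role_columns(rm_), c(rm_$country, rm_$weight))
  }
  if (!by_country) return(describe_block(df, columns))
  ccol <- rm_$country
  if (is.null(ccol)) stop("by_country requires a country role", call. = FALSE)
  blocks <- lapply(split(df, df[[ccol]]), describe_block, cols = columns)
  out <- do.call(rbind, Map(function(cn, b) cbind(country = cn, b),
                            names(blocks), blocks))
  rownames(out) <- NULL
  out
}
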