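# Validity-stage statistics: correlation / simple linear regression of
# vulnerability scores against an external outcome series, and
# method-agreement correlations between scoring variants.

# trim + casefold country names so outcome series join on spelling variants
normalize_country <- function(x, aliases = NULL) {
  key <- tolower(gsub("[^a-z0-9]+", " ", tolower(trimws(x))))
  key <- trimws(gsub(" +", " ", key))
  if (!is.null(aliases)) {
    idx <- match(key, names(aliases))
    key[!is.na(idx)] <- aliases[idx[!is.na(idx)]]
  }
  key
}

#' Correlation and simple regression between scores and an outcome
#'
#' Pearson correlation and ordinary least-squares regression of `y` on `x`,
#' with the two-sided p-value from the t distribution. Pairs with a missing
#' outcome are dropped and reported via the `n_dropped` field.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return List of class `validation_result`: `n`, `n_dropped`, `pearson_r`,
#'   `r_squared`, `slope`, `intercept`, `p_value`.
#' @export
#' @examples
#' correlate(1:10, -2 * (1:10) + 7)
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  r <- unname(ct$estimate)
  structure(
    list(n = length(x), n_dropped = n_dropped, pearson_r = r,
         r_squared = r^2, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), p_value = ct$p.value),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("n = %d (%d dropped), r = %.3f, R^2 = %.3f, y = %.3f + %.3f x, p = %.3g\n",
              x$n, x$n_dropped, x$pearson_r, x$r_squared, x$intercept,
              x$slope, x$p_value))
  invisible(x)
}

#' Validate scores against an outcome series
#'
#' Joins a per-country outcome series (e.g. the UHC service coverage index)
#' onto a score table by normalized country name and runs [correlate()].
#'
#' @param scores `vuln_scores` data.frame with `country` and `v_score`.
#' @param outcome data.frame with columns `country` and `outcome` (or the
#'   column named by `outcome_col`).
#' @param outcome_col name of the outcome column.
#' @param aliases optional named character vector of country-name aliases
#'   (normalized alias -> normalized canonical name).
#' @return A `validation_result`; countries without an outcome are dropped
#'   (counted in `n_dropped`).
#' @export
validate_scores <- function(scores, outcome, outcome_col = "outcome",
                            aliases = NULL) {
  stopifnot("country" %in% names(outcome), outcome_col %in% names(outcome))
  key_s <- normalize_country(scores$country, aliases)
  key_o <- normalize_country(outcome$country, aliases)
  y <- outcome[[outcome_col]][match(key_s, key_o)]
  correlate(scores$v_score, y)
}

#' Method-agreement correlations
#'
#' Pearson r and r-squared of every scoring-variant column against a base
#' column, reproducing the reference method-comparison table when fed its
#' printed score columns.
#'
#' @param score_table data.frame or matrix, countries x methods (>= 3
#'   countries, >= 2 methods); non-numeric columns (e.g. `country`) are
#'   ignored.
#' @param base name of the base method column (default: first numeric
#'   column).
#' @return data.frame with `method`, `r`, `r_squared`, one row per
#'   non-base method. Constant columns yield `NA` with a warning.
#' @export
method_agreement <- function(score_table, base = NULL) {
  df <- as.data.frame(score_table)
  num <- vapply(df, is.numeric, logical(1))
  df <- df[num]
  if (ncol(df) < 2) stop("need at least 2 method columns")
  if (nrow(df) < 3) stop("need at least 3 countries")
  if (is.null(base)) base <- names(df)[1]
  stopifnot(base %in% names(df))
  others <- setdiff(names(df), base)
  r <- vapply(others, function(m) {
    if (stats::var(df[[m]]) == 0 || stats::var(df[[base]]) == 0) {
      warning("constant column: ", m)
      return(NA_real_)
    }
    stats::cor(df[[base]], df[[m]])
  }, numeric(1))
  data.frame(method = others, r = unname(r), r_squared = unname(r)^2,
             stringsAsFactors = FALSE)
}
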