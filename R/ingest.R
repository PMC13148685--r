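# Reading country indicator tables and reconstructing ordinal levels from
# published weighted component scores.

.budget_synonyms <- c(
  "expansion" = "expansion", "expand" = "expansion",
  "expansionary" = "expansion",
  "stagnation" = "stagnation", "stagnant" = "stagnation",
  "contraction" = "contraction", "contract" = "contraction",
  "contracting" = "contraction"
)

.debt_synonyms <- c(
  "in_distress_or_very_high" = "in_distress_or_very_high",
  "in_debt_distress" = "in_distress_or_very_high",
  "in_distress" = "in_distress_or_very_high",
  "debt_distress" = "in_distress_or_very_high",
  "very_high" = "in_distress_or_very_high",
  "high" = "high",
  "moderate" = "moderate",
  "low_or_na" = "low_or_na", "low" = "low_or_na",
  "na" = "low_or_na", "n_a" = "low_or_na", "not_assessed" = "low_or_na",
  "none" = "low_or_na"
)

# lowercase snake-case normalization for category strings
normalize_category <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

.required_columns <- c("country", "che_per_capita_usd", "external_share_pct",
                       "budget_space", "debt_risk")

#' Read a country indicator table
#'
#' Reads a UTF-8 CSV of raw per-country indicators and returns validated
#' records. Expected columns: `country`, `che_per_capita_usd` (current health
#' expenditure per capita, US$), `external_share_pct` (external share of CHE,
#' 0-100), `budget_space` (expansion / stagnation / contraction),
#' `debt_risk` (in_distress_or_very_high / high / moderate / low_or_na) and
#' optionally `poverty_rate_pct`. Category strings are matched
#' case-insensitively against a synonym table (e.g. "In Debt Distress" and
#' "Very high" both map to `in_distress_or_very_high`; "N/A" maps to
#' `low_or_na`).
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping expected column
#'   names to the names used in the file, e.g.
#'   `c(country = "Country Name")`.
#' @return A data.frame of validated records with normalized categories and
#'   one row per input row.
#' @export
read_country_indicators <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        encoding = "UTF-8")
  if (nrow(df) == 0) stop("no records in ", path)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stop("mapped column not found in file: ", src)
      names(df)[names(df) == src] <- std
    }
  }
  missing <- setdiff(.required_columns, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  validate_indicator_records(df)
}

#' Validate raw indicator records
#'
#' Applies the range and category checks of [read_country_indicators()] to an
#' in-memory data.frame. Errors name the offending country, field and row.
#'
#' @param df data.frame with the indicator columns.
#' @return The validated data.frame with normalized category columns.
#' @export
validate_indicator_records <- function(df) {
  problems <- character(0)
  note <- function(row, country, msg) {
    problems <<- c(problems, sprintf("row %d (%s): %s", row, country, msg))
  }
  df$country <- trimws(as.character(df$country))
  df$che_per_capita_usd <- as.numeric(df$che_per_capita_usd)
  df$external_share_pct <- as.numeric(df$external_share_pct)
  bs <- normalize_category(df$budget_space)
  dr <- normalize_category(df$debt_risk)
  for (i in seq_len(nrow(df))) {
    ctry <- df$country[i]
    if (!nzchar(ctry)) note(i, "?", "empty country name")
    che <- df$che_per_capita_usd[i]
    if (is.na(che) || che < 0)
      note(i, ctry, "che_per_capita_usd must be a non-negative number")
    ext <- df$external_share_pct[i]
    if (is.na(ext) || ext < 0 || ext > 100)
      note(i, ctry, sprintf("external_share_pct out of [0, 100]: %s", ext))
    if (!bs[i] %in% names(.budget_synonyms))
      note(i, ctry, sprintf("unknown budget_space category '%s'",
                            df$budget_space[i]))
    if (!dr[i] %in% names(.debt_synonyms))
      note(i, ctry, sprintf("unknown debt_risk category '%s'",
                            df$debt_risk[i]))
  }
  if ("poverty_rate_pct" %in% names(df)) {
    pov <- as.numeric(df$poverty_rate_pct)
    bad <- which(!is.na(pov) & (pov < 0 | pov > 100))
    for (i in bad) note(i, df$country[i], "poverty_rate_pct out of [0, 100]")
    df$poverty_rate_pct <- pov
  }
  if (length(problems))
    stop("invalid indicator record(s):\n  ",
         paste(problems, collapse = "\n  "))
  df$budget_space <- unname(.budget_synonyms[bs])
  df$debt_risk <- unname(.debt_synonyms[dr])
  df
}

#' Recover ordinal levels from weighted component scores
#'
#' Inverts the component-score computation `score = level / denominator x
#' weight`: given a matrix of (2-decimal, printed) weighted component scores
#' and the weights, recovers the integer exposure levels. A recovered level is
#' accepted when re-rounding it through the forward computation lands within
#' +/-0.005 of the printed value (the printed table's 2-decimal precision);
#' otherwise the cell is flagged as inconsistent.
#'
#' @param weighted_components numeric matrix (countries x factors) of
#'   weighted component scores.
#' @param weights numeric vector of per-factor weights (all > 0), or a
#'   [weight_vector] object.
#' @param norm_denominators integer vector of per-factor normalizing
#'   denominators.
#' @param countries optional character vector of country names (defaults to
#'   rownames).
#' @param factor_names optional character vector of factor names.
#' @param max_levels optional integer vector; defaults to the maximum
#'   recovered level per factor.
#' @return An [ordinal_dataset]. Inconsistent cells raise an error naming
#'   country and factor.
#' @export
#' @examples
#' backout_levels(rbind(Malawi = c(32.10, 30.70, 5.07, 23.68)),
#'                weights = c(32.10, 30.70, 7.60, 29.60),
#'                norm_denominators = c(4, 5, 3, 5))
backout_levels <- function(weighted_components, weights, norm_denominators,
                           countries = rownames(weighted_components),
                           factor_names = colnames(weighted_components),
                           max_levels = NULL) {
  if (inherits(weights, "weight_vector")) weights <- weights$weights
  weighted_components <- as.matrix(weighted_components)
  k <- ncol(weighted_components)
  if (length(weights) != k || length(norm_denominators) != k)
    stop("weights and norm_denominators must match the number of factor columns")
  if (any(weights <= 0)) stop("all weights must be > 0")
  if (is.null(factor_names)) factor_names <- paste0("f", seq_len(k))
  if (is.null(countries)) countries <- paste0("row", seq_len(nrow(weighted_components)))

  implied <- sweep(sweep(weighted_components, 2, weights, "/"),
                   2, norm_denominators, "*")
  lev <- round(implied)
  # forward-check at printed precision
  forward <- sweep(sweep(lev, 2, norm_denominators, "/"), 2, weights, "*")
  ok <- abs(weighted_components - round_half_up(forward, 2)) <= 0.005 + 1e-9
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    msgs <- apply(bad, 1, function(idx)
      sprintf("%s / %s: printed %.2f implies level %.4f, not an integer at 2-dp tolerance",
              countries[idx[1]], factor_names[idx[2]],
              weighted_components[idx[1], idx[2]], implied[idx[1], idx[2]]))
    stop("inconsistent weighted component(s):\n  ",
         paste(msgs, collapse = "\n  "))
  }
  if (is.null(max_levels)) max_levels <- apply(lev, 2, max)
  ordinal_dataset(countries, lev, factor_names, max_levels, norm_denominators)
}
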