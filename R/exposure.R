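# Ordinal exposure-level assignment for the four health-financing and
# macro-fiscal factors. Higher level = higher propensity to vulnerability.
# All numeric bands are half-open, lower-inclusive on the risk-increasing
# side, so e.g. CHE of exactly US$85 falls in the [85, 180) band (level 2).

#' Exposure level from current health expenditure per capita
#'
#' Lower health spending per person means higher exposure: `< 55` US$ maps to
#' level 4, `[55, 85)` to 3, `[85, 180)` to 2 and `>= 180` to 1. The default
#' cut-points are the fixed reference values (20th/40th/60th percentiles of
#' the 2022 WHO African Region distribution); pass `cuts` to re-band another
#' dataset, e.g. `quantile(x, c(.2, .4, .6))`.
#'
#' @param che_per_capita numeric vector, US$ per person per year (>= 0).
#' @param cuts increasing numeric vector of three cut-points.
#' @return Integer levels in 1-4.
#' @export
#' @examples
#' level_from_che(c(40, 91, 726.9))
level_from_che <- function(che_per_capita, cuts = default_bands()$che_cuts) {
  if (any(is.na(che_per_capita)) || any(che_per_capita < 0))
    stop("che_per_capita must be non-negative")
  stopifnot(length(cuts) == 3, !is.unsorted(cuts, strictly = TRUE))
  # number of cut-points at or below the value: 0 -> level 4 ... 3 -> level 1
  as.integer(4L - findInterval(che_per_capita, cuts))
}

#' Exposure level from foreign aid dependency
#'
#' Share of current health expenditure financed from external sources, in
#' percent. `[0, 10)` maps to level 1, `[10, 15)` to 2, `[15, 25)` to 3,
#' `[25, 45)` to 4 and `>= 45` to 5.
#'
#' @param external_share numeric vector of percentages in `[0, 100]`.
#' @param cuts increasing numeric vector of four cut-points.
#' @return Integer levels in 1-5.
#' @export
#' @examples
#' level_from_fad(c(6.8, 12, 64.7))
level_from_fad <- function(external_share, cuts = default_bands()$fad_cuts) {
  if (any(is.na(external_share)) ||
      any(external_share < 0 | external_share > 100))
    stop("external_share must lie in [0, 100]")
  stopifnot(length(cuts) == 4, !is.unsorted(cuts, strictly = TRUE))
  as.integer(1L + findInterval(external_share, cuts))
}

#' Exposure level from budget space potential
#'
#' Projected trajectory of real general government expenditure per capita:
#' contraction maps to level 3, stagnation to 2, expansion to 1.
#'
#' @param budget_space character vector of categories (synonyms accepted,
#'   case-insensitive).
#' @return Integer levels in 1-3.
#' @export
level_from_bsp <- function(budget_space) {
  key <- normalize_category(budget_space)
  canon <- .budget_synonyms[key]
  if (any(is.na(canon)))
    stop("unknown budget_space category: ",
         paste(unique(budget_space[is.na(canon)]), collapse = ", "))
  unname(default_bands()$bsp_map[canon])
}

#' Exposure level from capacity to borrow
#'
#' Debt-distress risk per the IMF/World Bank debt sustainability analysis,
#' read as the inverse of the capacity to borrow: countries already in debt
#' distress or at very high risk map to level 4, high risk to 3, moderate to
#' 2, and low / not assessed to 1.
#'
#' @param debt_risk character vector of categories (synonyms accepted,
#'   case-insensitive; "N/A" maps to `low_or_na`).
#' @return Integer levels in 1-4.
#' @export
level_from_ctb <- function(debt_risk) {
  key <- normalize_category(debt_risk)
  canon <- .debt_synonyms[key]
  if (any(is.na(canon)))
    stop("unknown debt_risk category: ",
         paste(unique(debt_risk[is.na(canon)]), collapse = ", "))
  unname(default_bands()$ctb_map[canon])
}

#' Exposure level from multidimensional poverty prevalence
#'
#' Quintile banding of the supplied poverty column into levels 1-5 (higher
#' poverty, higher exposure). The banding rule for this optional fifth factor
#' is a package choice — no reference banding exists — so scores using it are
#' flagged as non-reproducing in the pipeline outputs.
#'
#' @param poverty_rate numeric vector of percentages in `[0, 100]`.
#' @return Integer levels in 1-5.
#' @export
level_from_poverty <- function(poverty_rate) {
  if (any(is.na(poverty_rate)) ||
      any(poverty_rate < 0 | poverty_rate > 100))
    stop("poverty_rate must lie in [0, 100]")
  q <- stats::quantile(poverty_rate, probs = c(.2, .4, .6, .8), names = FALSE,
                       type = 7)
  as.integer(1L + findInterval(poverty_rate, unique(q)))
}

#' Build exposure profiles from indicator records
#'
#' Applies the four banding rules to each validated record and returns the
#' per-country exposure profile. When a `poverty_rate_pct` column is present
#' and `include_poverty = TRUE`, a quintile-banded `poverty_level` is added.
#'
#' @param records data.frame from [read_country_indicators()] (or one
#'   structured like it).
#' @param bands banding configuration, see [default_bands()].
#' @param include_poverty add the optional poverty factor if the column is
#'   present.
#' @return data.frame with `country`, `che_level`, `fad_level`, `bsp_level`,
#'   `ctb_level` (and optionally `poverty_level`).
#' @export
#' @examples
#' rec <- data.frame(country = "Malawi", che_per_capita_usd = 40,
#'                   external_share_pct = 64.7, budget_space = "stagnation",
#'                   debt_risk = "in_distress_or_very_high")
#' build_profiles(rec)
build_profiles <- function(records, bands = default_bands(),
                           include_poverty = TRUE) {
  records <- validate_indicator_records(records)
  out <- data.frame(
    country = records$country,
    che_level = level_from_che(records$che_per_capita_usd, bands$che_cuts),
    fad_level = level_from_fad(records$external_share_pct, bands$fad_cuts),
    bsp_level = level_from_bsp(records$budget_space),
    ctb_level = level_from_ctb(records$debt_risk),
    stringsAsFactors = FALSE
  )
  if (include_poverty && "poverty_rate_pct" %in% names(records) &&
      !anyNA(records$poverty_rate_pct)) {
    out$poverty_level <- level_from_poverty(records$poverty_rate_pct)
  }
  out
}

#' Convert exposure profiles to an ordinal dataset
#'
#' @param profiles data.frame from [build_profiles()].
#' @param mode scoring convention, see [vuln_factors()].
#' @return An [ordinal_dataset] over the four factors (plus poverty when
#'   present, with `max_level = denominator = 5`).
#' @export
profiles_to_dataset <- function(profiles, mode = c("reproduction",
                                                   "eq1_literal")) {
  mode <- match.arg(mode)
  spec <- vuln_factors(mode)
  cols <- paste0(spec$name, "_level")
  stopifnot(all(cols %in% names(profiles)))
  lev <- as.matrix(profiles[, cols])
  names_out <- spec$name
  maxl <- spec$max_level
  dens <- spec$denominator
  if ("poverty_level" %in% names(profiles)) {
    lev <- cbind(lev, profiles$poverty_level)
    names_out <- c(names_out, "poverty")
    maxl <- c(maxl, 5L)
    dens <- c(dens, 5L)
  }
  ordinal_dataset(profiles$country, lev, names_out, maxl, dens)
}
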