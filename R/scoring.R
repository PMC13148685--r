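# Vulnerability score aggregation: weighted sum of normalized exposure
# levels on a 0-100 scale, archetype categorization, and the summary
# statistics and counts of the reference report.

#' Weighted component score for one factor
#'
#' `score = level / denominator * weight`. The component can never exceed
#' its factor's weight (levels are capped at the denominator).
#'
#' @param level integer level(s) of exposure.
#' @param denominator normalizing denominator (>= max level).
#' @param weight factor weight in percent.
#' @return Numeric weighted score(s), unrounded.
#' @export
#' @examples
#' component_score(4, 4, 32.10)  # 32.10
#' component_score(2, 3, 7.60)   # 5.0667 -> prints as 5.07
component_score <- function(level, denominator, weight) {
  if (any(level < 1 | level > denominator))
    stop("level out of range 1..", denominator)
  level / denominator * weight
}

#' Archetype from a vulnerability score
#'
#' `[0, 40)` is Low, `[40, 59.5)` Moderate, `[59.5, 73]` High and `> 73`
#' Very High. The boundary conventions (40 -> Moderate, 59.5 -> High, 73 ->
#' High) are the ones consistent with all 47 reference labels.
#'
#' @param v_score numeric score(s) in `[0, 100]`.
#' @param thresholds increasing numeric vector `c(low_upper, moderate_upper,
#'   high_upper)`.
#' @return Factor with levels Low, Moderate, High, Very High.
#' @export
#' @examples
#' categorize(c(59.18, 59.83, 73, 73.35))
categorize <- function(v_score, thresholds = c(40, 59.5, 73)) {
  if (any(is.na(v_score)) || any(v_score < 0 | v_score > 100))
    stop("v_score must lie in [0, 100]")
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds, strictly = TRUE))
  labs <- c("Low", "Moderate", "High", "Very High")
  # 40 and 59.5 are lower-inclusive; 73 belongs to High (upper-inclusive),
  # the only convention consistent with all 47 reference labels
  idx <- ifelse(v_score < thresholds[1], 1L,
         ifelse(v_score < thresholds[2], 2L,
         ifelse(v_score <= thresholds[3], 3L, 4L)))
  factor(labs[idx], levels = labs)
}

#' Vulnerability scores for an ordinal dataset
#'
#' For each country, each factor's level is divided by its normalizing
#' denominator, multiplied by the factor's weight, and the weighted
#' components are summed into the overall 0-100 vulnerability score.
#' Reproduction mode (the default, set through the dataset's denominators)
#' normalizes capacity-to-borrow by 5; see [vuln_factors()].
#'
#' @param data an [ordinal_dataset] (its `norm_denominators` define the
#'   aggregation mode).
#' @param weights a [weight_vector] covering the same factors, or a numeric
#'   vector in dataset factor order.
#' @param thresholds archetype thresholds, see [categorize()].
#' @return data.frame of class `vuln_scores`: `country`, one
#'   `<factor>_score` column per factor (unrounded), `v_score`, `archetype`.
#' @export
vulnerability_scores <- function(data, weights, thresholds = c(40, 59.5, 73)) {
  stopifnot(inherits(data, "ordinal_dataset"))
  if (inherits(weights, "weight_vector")) {
    if (!identical(weights$factor_names, data$factor_names)) {
      if (!setequal(weights$factor_names, data$factor_names))
        stop("weights cover factors (", paste(weights$factor_names, collapse = ", "),
             ") but data has (", paste(data$factor_names, collapse = ", "), ")")
      weights <- weights$weights[match(data$factor_names, weights$factor_names)]
    } else {
      weights <- weights$weights
    }
  }
  if (length(weights) != length(data$factor_names))
    stop("one weight per factor required")
  comp <- sweep(sweep(data$levels, 2, data$norm_denominators, "/"),
                2, weights, "*")
  v <- rowSums(comp)
  out <- data.frame(country = data$countries, comp, v_score = v,
                    archetype = categorize(v, thresholds),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1 + seq_along(data$factor_names)] <-
    paste0(data$factor_names, "_score")
  class(out) <- c("vuln_scores", "data.frame")
  out
}

#' Summary statistics for a set of vulnerability results
#'
#' Per-column mean / minimum / maximum (2 decimals), archetype counts and
#' per-factor level frequency tables.
#'
#' @param scores a `vuln_scores` data.frame from [vulnerability_scores()].
#' @param data optional [ordinal_dataset] backing `scores`; required for the
#'   level frequency tables.
#' @return List with `stats` (data.frame mean/min/max per score column),
#'   `archetype_counts` (named integer vector), and `level_counts` (list of
#'   per-factor frequency tables) when `data` is given.
#' @export
summarize_scores <- function(scores, data = NULL) {
  stopifnot(nrow(scores) >= 1)
  num_cols <- c(grep("_score$", names(scores), value = TRUE), "v_score")
  num_cols <- unique(num_cols)
  stats_df <- data.frame(
    column = num_cols,
    mean = round_half_up(vapply(scores[num_cols], mean, numeric(1)), 2),
    min = round_half_up(vapply(scores[num_cols], min, numeric(1)), 2),
    max = round_half_up(vapply(scores[num_cols], max, numeric(1)), 2),
    stringsAsFactors = FALSE
  )
  counts <- table(scores$archetype)
  out <- list(stats = stats_df,
              archetype_counts = stats::setNames(as.integer(counts),
                                                 names(counts)))
  if (!is.null(data)) {
    out$level_counts <- lapply(seq_along(data$factor_names), function(j) {
      tab <- table(factor(data$levels[, j], levels = 1:data$max_levels[j]))
      stats::setNames(as.integer(tab), names(tab))
    })
    names(out$level_counts) <- data$factor_names
  }
  out
}

#' Round a score table for reporting
#'
#' Reference tables print weighted components and totals at two decimals,
#' rounding halves away from zero. Internal arithmetic stays unrounded; use
#' this only at the reporting boundary.
#'
#' @param scores a `vuln_scores` data.frame.
#' @param digits decimal places.
#' @return The data.frame with numeric columns rounded.
#' @export
round_scores <- function(scores, digits = 2) {
  num <- vapply(scores, is.numeric, logical(1))
  scores[num] <- lapply(scores[num], round_half_up, digits = digits)
  scores
}
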