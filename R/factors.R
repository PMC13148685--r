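#' Default factor specification
#'
#' The four factors of exposure, their maximum attainable ordinal level and
#' the normalizing denominator used when aggregating. In reproduction mode
#' the capacity-to-borrow level is normalized by 5 even though its maximum
#' level is 4: every published weighted CTB component equals level/5 x weight,
#' so this is the convention the reference results were computed under. The
#' literal aggregation formula (denominator 4 for CTB) is available as mode
#' `"eq1_literal"` in the scoring functions.
#'
#' @param mode `"reproduction"` (default) or `"eq1_literal"`; only the CTB
#'   denominator differs.
#' @return A data.frame with columns `name`, `max_level`, `denominator`.
#' @export
#' @examples
#' vuln_factors()
vuln_factors <- function(mode = c("reproduction", "eq1_literal")) {
  mode <- match.arg(mode)
  data.frame(
    name = c("che", "fad", "bsp", "ctb"),
    max_level = c(4L, 5L, 3L, 4L),
    denominator = c(4L, 5L, 3L, if (mode == "reproduction") 5L else 4L),
    stringsAsFactors = FALSE
  )
}

#' Default exposure banding configuration
#'
#' Cut-points and category maps that translate raw indicators into ordinal
#' levels of exposure. Numeric bands are half-open, lower-inclusive on the
#' risk-increasing side. Defaults are the reference analysis values:
#' CHE per capita cut-points US$ 55 / 85 / 180 (the 20th/40th/60th
#' percentiles of the 2022 regional distribution), foreign aid dependency
#' cut-points 10 / 15 / 25 / 45 percent.
#'
#' @return A list with elements `che_cuts`, `fad_cuts`, `bsp_map`, `ctb_map`.
#' @export
default_bands <- function() {
  list(
    che_cuts = c(55, 85, 180),
    fad_cuts = c(10, 15, 25, 45),
    bsp_map = c(expansion = 1L, stagnation = 2L, contraction = 3L),
    ctb_map = c(low_or_na = 1L, moderate = 2L, high = 3L,
                in_distress_or_very_high = 4L)
  )
}

#' Construct an ordinal dataset
#'
#' Container for a countries x factors matrix of ordinal exposure levels plus
#' the per-factor maximum level and normalizing denominator.
#'
#' @param countries character vector of country names.
#' @param levels integer matrix, `length(countries)` rows, one column per
#'   factor; every entry must lie in `1:max_levels[j]`.
#' @param factor_names character vector of factor names.
#' @param max_levels integer vector, maximum attainable level per factor.
#' @param norm_denominators integer vector, normalizing denominator per
#'   factor (must be >= `max_levels`).
#' @return An object of class `ordinal_dataset`.
#' @export
ordinal_dataset <- function(countries, levels, factor_names, max_levels,
                            norm_denominators = max_levels) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  k <- length(factor_names)
  if (length(max_levels) != k || length(norm_denominators) != k)
    stop("factor_names, max_levels and norm_denominators must have equal length")
  if (ncol(levels) != k)
    stop("levels must have one column per factor")
  if (nrow(levels) != length(countries))
    stop("levels must have one row per country")
  for (j in seq_len(k)) {
    bad <- which(levels[, j] < 1L | levels[, j] > max_levels[j] |
                   is.na(levels[, j]))
    if (length(bad))
      stop(sprintf("factor '%s': level out of 1..%d for country %s",
                   factor_names[j], max_levels[j],
                   paste(countries[bad], collapse = ", ")))
  }
  colnames(levels) <- factor_names
  rownames(levels) <- NULL
  structure(
    list(countries = as.character(countries), levels = levels,
         factor_names = as.character(factor_names),
         max_levels = as.integer(max_levels),
         norm_denominators = as.integer(norm_denominators)),
    class = "ordinal_dataset"
  )
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("<ordinal_dataset: %d countries x %d factors (%s)>\n",
              length(x$countries), length(x$factor_names),
              paste(x$factor_names, collapse = ", ")))
  invisible(x)
}
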