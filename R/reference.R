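# Accessors for the packaged 47-country WHO African Region reference
# assessment, shipped as plain-text CSV and reconstructed into ordinal
# levels at run time.

.ref_path <- function(file) {
  system.file("extdata", file, package = "hfvuln", mustWork = TRUE)
}

#' Published weighted component scores for the 47 reference countries
#'
#' The per-country weighted component scores (2 decimals) of the reference
#' assessment, with the published overall score and archetype label for
#' cross-checking.
#'
#' @return data.frame with `country`, `che_component`, `fad_component`,
#'   `bsp_component`, `ctb_component`, `published_total`,
#'   `published_archetype`.
#' @export
afro47_components <- function() {
  utils::read.csv(.ref_path("afro47_weighted_components.csv"),
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Published factor weights of the reference assessment
#'
#' CHE per capita 32.10, foreign aid dependency 30.70, budget space
#' potential 7.60, capacity to borrow 29.60 (percent, polychoric-PCA
#' derived).
#'
#' @return A [weight_vector] with method `"user"`.
#' @export
afro47_weights <- function() {
  weight_vector(c("che", "fad", "bsp", "ctb"),
                c(32.10, 30.70, 7.60, 29.60), method = "user")
}

#' Reference ordinal exposure levels, reconstructed
#'
#' Recovers the 47 x 4 integer exposure levels by inverting the published
#' weighted component scores with the published weights (reproduction-mode
#' denominators 4, 5, 3, 5).
#'
#' @return An [ordinal_dataset].
#' @export
afro47_levels <- function() {
  comp <- afro47_components()
  m <- as.matrix(comp[, c("che_component", "fad_component",
                          "bsp_component", "ctb_component")])
  backout_levels(m, afro47_weights(), norm_denominators = c(4L, 5L, 3L, 5L),
                 countries = comp$country,
                 factor_names = c("che", "fad", "bsp", "ctb"),
                 max_levels = c(4L, 5L, 3L, 4L))
}

#' Published scores under the alternative weighting methods
#'
#' The reference method-comparison table: overall vulnerability score per
#' country under polychoric PCA, exploratory factor analysis, entropy
#' weighting, equal ("unweighted") weighting, and the unweighted variant
#' with poverty included as a fifth factor.
#'
#' @return data.frame with `country` and one numeric column per method.
#' @export
afro47_method_scores <- function() {
  utils::read.csv(.ref_path("afro47_method_scores.csv"),
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}
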