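# End-to-end pipeline: indicators (or levels) CSV -> profiles -> weights ->
# scores -> summary (+ optional validation), written to an output
# directory. The configuration is a plain list, optionally loaded from YAML.

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [run_pipeline()]'s `config`.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the vulnerability-scoring pipeline
#'
#' Reads input, assigns exposure levels, derives (or loads) weights, scores
#' every country, and writes: `results.csv` (levels, unrounded component
#' scores, total, archetype; input order), `results_ranked.csv` (rounded to
#' 2 decimals, sorted by descending score), `weights.json` (with
#' diagnostics), `summary.csv` (mean/min/max, archetype counts, level
#' frequencies) and, when an outcome file is configured,
#' `validation.json`.
#'
#' Configuration keys: one of `indicators_csv` (raw indicators, see
#' [read_country_indicators()]) or `levels_csv` (columns `country`,
#' `che_level`, `fad_level`, `bsp_level`, `ctb_level`); `weights_method`
#' (`"polychoric_pca"`, `"efa"`, `"entropy"`, `"equal"`) or `weights_file`
#' (CSV `factor,weight` or JSON, used verbatim); `mode` (`"reproduction"`
#' default or `"eq1_literal"`); `category_thresholds` (default 40, 59.5,
#' 73); `outcome_csv` + `outcome_col` (optional); `output_dir`; `seed`
#' (optional, only relevant for stochastic extensions).
#'
#' @param config list or path to a YAML file.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `profiles`, `data`, `weights`, `scores`,
#'   `summary` and (optionally) `validation`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  mode <- config$mode %||% "reproduction"
  thresholds <- config$category_thresholds %||% c(40, 59.5, 73)
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  # --- input stage -----------------------------------------------------
  if (!is.null(config$indicators_csv)) {
    records <- read_country_indicators(config$indicators_csv,
                                       config$column_map)
    say("ingest: %d indicator records", nrow(records))
    profiles <- build_profiles(records)
    data <- profiles_to_dataset(profiles, mode)
  } else if (!is.null(config$levels_csv)) {
    profiles <- utils::read.csv(config$levels_csv, stringsAsFactors = FALSE,
                                encoding = "UTF-8")
    say("ingest: %d level records", nrow(profiles))
    data <- profiles_to_dataset(profiles, mode)
  } else {
    stop("config must provide indicators_csv or levels_csv")
  }

  # --- weighting stage -------------------------------------------------
  if (!is.null(config$weights_file)) {
    weights <- read_weights(config$weights_file)
    say("weights: loaded from %s (%s)", config$weights_file, weights$method)
  } else {
    method <- config$weights_method %||% "polychoric_pca"
    weights <- derive_weights(data, method)
    say("weights: derived by %s", method)
  }

  # --- scoring stage ---------------------------------------------------
  scores <- vulnerability_scores(data, weights, thresholds)
  say("scoring: %d countries scored (%s mode)", nrow(scores), mode)
  summary <- summarize_scores(scores, data)

  utils::write.csv(cbind(as.data.frame(data$levels),
                         scores)[, c("country", colnames(data$levels),
                                     setdiff(names(scores), "country"))],
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  ranked <- round_scores(scores)[order(-scores$v_score, scores$country), ]
  utils::write.csv(ranked, file.path(out_dir, "results_ranked.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(factor_names = weights$factor_names, weights = weights$weights,
         method = weights$method, diagnostics = weights$diagnostics),
    file.path(out_dir, "weights.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_summary_csv(summary, file.path(out_dir, "summary.csv"))

  out <- list(profiles = profiles, data = data, weights = weights,
              scores = scores, summary = summary)

  # --- validation stage (optional) ------------------------------------
  if (!is.null(config$outcome_csv)) {
    outcome <- utils::read.csv(config$outcome_csv, stringsAsFactors = FALSE,
                               encoding = "UTF-8")
    val <- validate_scores(scores, outcome,
                           outcome_col = config$outcome_col %||% "outcome")
    say("validation: n = %d, r = %.3f, R^2 = %.3f", val$n, val$pearson_r,
        val$r_squared)
    jsonlite::write_json(unclass(val), file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$validation <- val
  }
  say("pipeline: outputs written to %s", out_dir)
  invisible(out)
}

#' Read a weight vector from CSV or JSON
#'
#' CSV needs columns `factor,weight`; JSON needs fields `factor_names` and
#' `weights` (and optionally `method`).
#'
#' @param path file path.
#' @return A [weight_vector] with method `"user"` unless the file declares
#'   one.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(weight_vector(j$factor_names, j$weights, j$method %||% "user"))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("factor", "weight") %in% names(df)))
  weight_vector(df$factor, df$weight, "user")
}

# long-format summary CSV: section,name,value
write_summary_csv <- function(summary, path) {
  rows <- list()
  s <- summary$stats
  for (i in seq_len(nrow(s))) {
    rows[[length(rows) + 1]] <- data.frame(
      section = "stats", name = paste0(s$column[i], c("_mean", "_min", "_max")),
      value = c(s$mean[i], s$min[i], s$max[i]))
  }
  rows[[length(rows) + 1]] <- data.frame(
    section = "archetype_counts", name = names(summary$archetype_counts),
    value = as.numeric(summary$archetype_counts))
  if (!is.null(summary$level_counts)) {
    for (f in names(summary$level_counts)) {
      lc <- summary$level_counts[[f]]
      rows[[length(rows) + 1]] <- data.frame(
        section = "level_counts", name = paste0(f, "_level_", names(lc)),
        value = as.numeric(lc))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
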