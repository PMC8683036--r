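# End-to-end pipeline glue: scores -> feature table -> PCA + reduction ->
# indices -> corroboration -> species-level hypothesis tests.

#' Run the full ARDI analysis pipeline
#'
#' Validates the panel, averages raters and rescales to probabilities,
#' standardizes all six features for a correlation-matrix PCA, runs the
#' stopping-rule battery and Jolliffe B2 elimination, builds the index
#' table (ARDI, reappearance, SCI), attaches PC1 scores, classifies call
#' names, computes the index-label correlation and putative-musical
#' summary, and (when covariates are supplied) the species-level
#' hypothesis battery.
#'
#' @param panel a `score_panel`.
#' @param metadata vocalization metadata.
#' @param covariates optional species covariate table.
#' @param config an [ardi_config()].
#' @return list of class `ardi_analysis` with components
#'   `validation`, `feature_table`, `reliability`, `pca`,
#'   `stopping_rules`, `reduction`, `index_table`, `classification`,
#'   `label_correlation`, `musical_summary`, `rankings`,
#'   `context_summary`, `species_summary`, `hypothesis_tests`.
#' @export
run_ardi_pipeline <- function(panel, metadata, covariates = NULL,
                              config = ardi_config()) {
  validation <- validate_panel(panel)
  if (nrow(validation) > 0) {
    warning(nrow(validation), " panel validation issue(s); see $validation",
      call. = FALSE
    )
  }
  ft <- rescale_probabilities(average_raters(panel))
  reliability <- reliability_report(panel)
  std <- standardize_features(ft)
  pca <- run_pca(std)
  stopping <- stopping_rule_report(pca, config)
  reduction <- jolliffe_b2_eliminate(std, config$jolliffe_cutoff)
  index_table <- build_index_table(ft, metadata, config$clamp_reappearance)
  index_table <- attach_pc1_scores(pca, index_table)
  classification <- classify_call_names(metadata, config$musical_keywords)
  label_cor <- index_label_correlation(index_table, classification)
  musical_summary <- summarize_putative_musical(ft, index_table)
  rankings <- ranking_table(index_table, metadata)
  ctx <- context_summaries(index_table, classification)
  species_summary <- species_max_index(index_table, metadata, covariates)
  hypo <- if (!is.null(covariates)) run_hypothesis_battery(species_summary) else NULL
  structure(
    list(
      validation = validation,
      feature_table = ft,
      reliability = reliability,
      pca = pca,
      stopping_rules = stopping,
      reduction = reduction,
      index_table = index_table,
      classification = classification,
      label_correlation = label_cor,
      musical_summary = musical_summary,
      rankings = rankings,
      context_summary = ctx,
      species_summary = species_summary,
      hypothesis_tests = hypo,
      config = config
    ),
    class = "ardi_analysis"
  )
}

#' @export
print.ardi_analysis <- function(x, ...) {
  cat("<ardi_analysis>\n")
  cat("  vocalizations:", nrow(x$index_table), "\n")
  cat("  species:      ", nrow(x$species_summary), "\n")
  cat(
    "  B2 retained:  ",
    paste(x$reduction$retained, collapse = ", "), "\n"
  )
  cat(
    "  index-label r:", signif(x$label_correlation$statistic, 3),
    "(", x$label_correlation$test, ")\n"
  )
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the standard CSVs: `feature_table.csv`, `reliability.csv`,
#' `pca_loadings.csv`, `pca_eigenvalues.csv`, `stopping_rules.csv`,
#' `reduction_trace.csv`, `indices.csv`, `classification.csv`,
#' `rankings.csv`, `context_summary.csv`, `species_summary.csv`, and
#' `tests.csv` when hypothesis tests were run.
#'
#' @param analysis an `ardi_analysis`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_pipeline_outputs <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(tab, name) {
    if (is.null(tab) || nrow(as.data.frame(tab)) == 0) {
      return(invisible(NULL))
    }
    path <- file.path(dir, name)
    write_table(as.data.frame(tab), path)
    files <<- c(files, path)
  }
  emit(analysis$feature_table, "feature_table.csv")
  emit(analysis$reliability, "reliability.csv")
  loadings <- data.frame(
    variable = rownames(analysis$pca$loadings),
    analysis$pca$loadings,
    check.names = FALSE
  )
  emit(loadings, "pca_loadings.csv")
  emit(
    data.frame(
      component = seq_along(analysis$pca$eigenvalues),
      eigenvalue = analysis$pca$eigenvalues,
      variance_fraction = analysis$pca$variance_fractions
    ),
    "pca_eigenvalues.csv"
  )
  emit(analysis$stopping_rules, "stopping_rules.csv")
  emit(analysis$reduction$trace, "reduction_trace.csv")
  emit(analysis$index_table, "indices.csv")
  emit(analysis$classification, "classification.csv")
  emit(analysis$rankings, "rankings.csv")
  emit(analysis$context_summary, "context_summary.csv")
  emit(analysis$species_summary, "species_summary.csv")
  emit(analysis$hypothesis_tests, "tests.csv")
  invisible(files)
}
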