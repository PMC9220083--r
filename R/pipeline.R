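#' Run the full chemotyping analysis end-to-end
#'
#' Orchestrates the whole pipeline on a synthetic study (or a pre-generated
#' one): quality screening, then for each spectral region derivative + EMSC
#' preprocessing, replicate averaging, five-medium block assembly, consensus
#' PCA and projection of all replicate spectra onto the rich-medium (BHI)
#' block scores; then the wide-region EMSC preprocessing and a genus-wise
#' correlation-loading analysis; and the growth-score summary. Returns a run
#' manifest with the per-stage sample counts and every fitted artifact. The
#' run is a deterministic function of the config seed.
#'
#' @param config A [synthetic_config()] defining the study, or a
#'   `synthetic_study` already generated.
#' @param qc A [qc_config()].
#' @param regions Regions to model (default: the four biochemical regions).
#' @param n_components Components per CPCA model.
#' @param project_medium Block to project replicate spectra onto.
#' @param correlation_genera Genera for the correlation analysis (default:
#'   all genera present after QC).
#' @param temperature_coding Passed to [genus_correlation_analysis()].
#' @return A list of class `ftir_run`: `counts` (stage-count tibble),
#'   `qc_fail`, `models` (named list of `cpca_model`), `projections` (named
#'   list of score tibbles on `project_medium`), `dropped` (per region),
#'   `correlations` (named list of `correlation_loadings`),
#'   `growth_summary`, and `config`.
#' @export
run_full <- function(config = synthetic_config(),
                     qc = qc_config(),
                     regions = c("lipid", "protein", "mixed",
                                 "polysaccharide"),
                     n_components = 2,
                     project_medium = "BHI",
                     correlation_genera = NULL,
                     temperature_coding = "dummy") {
  study <- if (inherits(config, "synthetic_study")) config
           else generate_dataset(config)
  screened <- quality_check(study$spectra, qc)
  counts <- tibble::tibble(
    stage = c("generated", "qc_pass", "qc_fail"),
    n = c(n_spectra(study$spectra), n_spectra(screened$pass),
          nrow(screened$fail))
  )
  models <- list(); projections <- list(); dropped <- list()
  for (r in regions) {
    prep <- preprocess_for_multiblock(screened$pass, r)
    avg <- average_replicates(prep)
    mb <- assemble_blocks(avg, study$truth$config$media)
    models[[r]] <- fit_cpca(mb, n_components = n_components)
    projections[[r]] <- project_block(models[[r]], project_medium, prep)
    dropped[[r]] <- mb$dropped
    counts <- dplyr::bind_rows(counts, tibble::tibble(
      stage = paste0(r, c("_averaged", "_retained", "_dropped")),
      n = c(n_spectra(avg), nrow(mb$keys), nrow(mb$dropped))
    ))
  }
  corr_prep <- preprocess_for_correlation(screened$pass)
  genera <- correlation_genera %||% sort(unique(corr_prep$meta$genus))
  correlations <- list()
  for (g in genera) {
    correlations[[g]] <- genus_correlation_analysis(
      corr_prep, g, temperature_coding = temperature_coding)
  }
  growth_summary <- summarize_growth(score_growth(study$growth))
  structure(list(
    counts = counts,
    qc_fail = screened$fail,
    models = models,
    projections = projections,
    dropped = dropped,
    correlations = correlations,
    growth_summary = growth_summary,
    run_id = study$run_id,
    config = study$truth$config
  ), class = "ftir_run")
}

#' @export
print.ftir_run <- function(x, ...) {
  cat("<ftir_run> ", x$run_id, "\n", sep = "")
  cat("  regions modelled: ", paste(names(x$models), collapse = ", "), "\n",
      sep = "")
  print(x$counts, n = nrow(x$counts))
  invisible(x)
}
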