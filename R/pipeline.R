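#' Configuration for a full pipeline run
#'
#' Exactly one of `input` (paths to `counts.tsv`, `probes.tsv`,
#' `samples.tsv`, optionally `ihc.tsv`) or `params` (a [sim_params()]
#' object, in which case a cohort is simulated) must be supplied.
#'
#' @param input named list of paths: `counts`, `probes`, `samples`, and
#'   optionally `ihc`.
#' @param params a `"sim_params"` object for a simulated run.
#' @param out_dir output directory.
#' @param seed integer seed (overrides `params$seed` for simulated runs).
#' @param subtract_igg IgG subtraction for the main normalization branch.
#' @param housekeeping `"auto"` or a housekeeping probe id.
#' @param analyses character vector of analysis toggles, any of
#'   `"paired_tests"`, `"size_association"`, `"surgery_comparison"`,
#'   `"phospho_correlation"`, `"concordance"`, `"clustering"`,
#'   `"dilution_qc"`.
#' @param ihc_mapping mapping tibble for the concordance analysis.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, params = NULL, out_dir,
                            seed = 1L, subtract_igg = TRUE,
                            housekeeping = "auto",
                            analyses = c("paired_tests", "size_association",
                                         "surgery_comparison",
                                         "phospho_correlation", "concordance",
                                         "clustering"),
                            ihc_mapping = default_ihc_mapping()) {
  if (is.null(input) == is.null(params)) {
    stop("supply exactly one of `input` (paths) or `params` (simulation)",
         call. = FALSE)
  }
  if (!is.null(input)) {
    need <- c("counts", "probes", "samples")
    if (!all(need %in% names(input))) {
      stop("`input` must name paths: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  known <- c("paired_tests", "size_association", "surgery_comparison",
             "phospho_correlation", "concordance", "clustering",
             "dilution_qc")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analysis toggle(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(input = input, params = params, out_dir = out_dir,
                 seed = as.integer(seed), subtract_igg = subtract_igg,
                 housekeeping = housekeeping, analyses = analyses,
                 ihc_mapping = ihc_mapping),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates: input (read or simulate) -> normalization (always both IgG
#' branches when the concordance analysis is enabled, so the IHC comparison
#' never silently reuses the wrong matrix) -> the enabled analyses ->
#' clustering -> a deterministic output tree with per-stage logging and a
#' JSON manifest (config, seed, package version) sufficient to reproduce
#' the run. Any stage failure leaves a `FAILED` marker file naming the
#' stage, retains partial outputs, and re-raises the error.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default `TRUE`).
#' @return named list of result tibbles, invisibly; outputs under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- "setup"
  results <- list()
  run <- function() {
    if (!is.null(config$params)) {
      stage <<- "simulate"
      cohort <- generate_cohort(config$params, seed = config$seed)
      dataset <- cohort$dataset
      ihc <- cohort$ihc
      say("simulate: %d probes x %d lanes, seed %d",
          nrow(dataset$counts), ncol(dataset$counts), config$seed)
    } else {
      stage <<- "read"
      dataset <- read_dataset(config$input$counts, config$input$probes,
                              config$input$samples)
      ihc <- if (!is.null(config$input$ihc)) read_ihc(config$input$ihc)
      say("read: %d probes x %d lanes", nrow(dataset$counts),
          ncol(dataset$counts))
    }
    stage <<- "normalize"
    norm <- run_normalization(dataset, subtract_igg = config$subtract_igg,
                              housekeeping = config$housekeeping)
    say("normalize: %d/%d endogenous probes retained (%d undetected), %d zero imputations",
        nrow(norm$expr),
        sum(dataset$probes$probe_class == "endogenous"),
        length(norm$report$undetected_probes),
        nrow(norm$report$zero_imputation_log))
    write_matrix(norm$expr, file.path(out, "normalized.tsv"))
    write_table(norm$report$housekeeping_cv_table,
                file.path(out, "housekeeping_cv.tsv"))
    write_table(tibble(lane_id = names(norm$report$lane_scaling_factors),
                       scaling_factor = norm$report$lane_scaling_factors,
                       negative_background = norm$report$negative_background,
                       igg_background = norm$report$igg_background),
                file.path(out, "normalization_report.tsv"))
    write_table(norm$report$zero_imputation_log,
                file.path(out, "zero_imputations.tsv"))
    results$normalization <<- norm
    norm_no_igg <- NULL
    if ("concordance" %in% config$analyses) {
      norm_no_igg <- run_normalization(dataset, subtract_igg = FALSE,
                                       housekeeping = config$housekeeping)
      write_matrix(norm_no_igg$expr, file.path(out, "normalized_no_igg.tsv"))
    }
    samples <- dataset$samples
    probes <- dataset$probes
    has_pairs <- all(c("core", "excision") %in% samples$specimen)
    if ("paired_tests" %in% config$analyses && has_pairs) {
      stage <<- "paired_tests"
      results$paired_tests <<- paired_protein_tests(norm$expr, samples, probes)
      write_table(results$paired_tests, file.path(out, "paired_tests.tsv"))
      say("paired_tests: %d proteins, %d pairs", nrow(results$paired_tests),
          results$paired_tests$n_pairs[1])
    }
    diffs <- if (has_pairs) difference_matrix(norm$expr, samples)
    if (!is.null(diffs)) {
      write_table(diffs, file.path(out, "differences.tsv"))
    }
    if ("size_association" %in% config$analyses && !is.null(diffs) &&
        any(!is.na(samples$tumour_size_mm))) {
      stage <<- "size_association"
      results$size_association <<- size_association(diffs, samples)
      write_table(results$size_association,
                  file.path(out, "size_association.tsv"))
      say("size_association: %d proteins", nrow(results$size_association))
    }
    if ("surgery_comparison" %in% config$analyses && !is.null(diffs) &&
        all(c("lumpectomy", "mastectomy") %in% samples$surgery)) {
      stage <<- "surgery_comparison"
      results$surgery_comparison <<- surgery_comparison(diffs, samples)
      write_table(results$surgery_comparison,
                  file.path(out, "surgery_comparison.tsv"))
      say("surgery_comparison: %d proteins", nrow(results$surgery_comparison))
    }
    if ("phospho_correlation" %in% config$analyses && !is.null(diffs)) {
      stage <<- "phospho_correlation"
      pc <- phospho_nonphospho_correlation(diffs, probes)
      results$phospho_correlation <<- pc
      write_table(pc$mean_correlation,
                  file.path(out, "phospho_mean_correlation.tsv"))
      write_table(pc$per_nonphospho,
                  file.path(out, "phospho_per_nonphospho.tsv"))
      say("phospho_correlation: rho = %.3f", pc$mean_correlation$rho)
    }
    if ("concordance" %in% config$analyses && !is.null(ihc) &&
        nrow(ihc) > 0) {
      stage <<- "concordance"
      results$concordance <<- ihc_concordance(norm_no_igg$expr, ihc, samples,
                                              mapping = config$ihc_mapping)
      write_table(results$concordance, file.path(out, "concordance.tsv"))
      say("concordance: %d protein-strata", nrow(results$concordance))
    }
    if ("clustering" %in% config$analyses) {
      stage <<- "clustering"
      cl <- two_way_cluster(norm$expr)
      results$clustering <<- cl
      write_matrix(cl$scaled, file.path(out, "scaled_matrix.tsv"))
      write_table(tidy(cl), file.path(out, "cluster_labels.tsv"))
      write_newick(cl$rows, file.path(out, "protein_tree.nwk"))
      write_newick(cl$cols, file.path(out, "lane_tree.nwk"))
      say("clustering: 2-cut lane groups %s",
          paste(table(cl$cols$k2), collapse = "/"))
    }
    if ("dilution_qc" %in% config$analyses &&
        any(!is.na(samples$dilution_tag))) {
      stage <<- "dilution_qc"
      endo <- probes$probe_id[probes$probe_class == "endogenous"]
      qc <- dilution_replicate_check(
        unclass(dataset$counts)[endo, , drop = FALSE], samples)
      results$dilution_qc <<- qc
      write_table(qc, file.path(out, "dilution_qc.tsv"))
      say("dilution_qc: %d/%d samples pass", sum(qc$pass), nrow(qc))
    }
    stage <<- "manifest"
    manifest <- list(
      package = "phosphodrift",
      version = as.character(packageVersion("phosphodrift")),
      seed = config$seed,
      subtract_igg = config$subtract_igg,
      housekeeping = config$housekeeping,
      analyses = config$analyses,
      input = config$input,
      simulated = !is.null(config$params),
      sim_params = if (!is.null(config$params)) {
        p <- config$params
        p$proteins <- as.data.frame(p$proteins)
        unclass(p)
      }
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  status <- tryCatch({
    run()
    0L
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    writeLines(log_lines, log_path)
    stop(sprintf("pipeline stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  writeLines(log_lines, log_path)
  invisible(results)
}
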