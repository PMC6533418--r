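#' Resolve each (patient, specimen) to one canonical lane
#'
#' When dilution replicates exist, the replicate carrying the canonical
#' dilution tag (default `"10x"`) is used for analysis; other replicates
#' feed only the dilution QC. Lanes without a dilution tag are canonical by
#' default.
#'
#' @param samples lane metadata tibble.
#' @param canonical_tag dilution tag marking the analysis replicate.
#' @return the metadata filtered to one lane per (patient, specimen).
#' @export
canonical_lanes <- function(samples, canonical_tag = "10x") {
  keep <- samples |>
    dplyr::filter(is.na(.data$dilution_tag) |
                    .data$dilution_tag == canonical_tag)
  dup <- keep |>
    dplyr::count(.data$patient_id, .data$specimen) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("multiple canonical lanes for: ",
         paste(paste0(dup$patient_id, "/", dup$specimen), collapse = ", "),
         call. = FALSE)
  }
  keep
}

#' Per-patient log2 expression differences (excision minus core)
#'
#' The paired difference statistic: for every patient with both specimen
#' types, `difference = log2(excision) - log2(core)` per protein. Patients
#' missing either specimen are dropped (and recorded in the
#' `dropped_patients` attribute).
#'
#' @param expr log2 `npx_matrix` (endogenous probes x lanes).
#' @param samples lane metadata tibble.
#' @param canonical_tag see [canonical_lanes()].
#' @return tibble with columns `protein`, `patient_id`, `difference`.
#' @export
difference_matrix <- function(expr, samples, canonical_tag = "10x") {
  check_stage(expr, "log2", "difference_matrix")
  meta <- canonical_lanes(samples, canonical_tag) |>
    dplyr::filter(.data$lane_id %in% colnames(expr))
  wide <- meta |>
    dplyr::select("patient_id", "specimen", "lane_id") |>
    tidyr::pivot_wider(names_from = "specimen", values_from = "lane_id")
  if (!all(c("core", "excision") %in% names(wide))) {
    stop("no patient has both core and excision lanes", call. = FALSE)
  }
  complete <- wide |>
    dplyr::filter(!is.na(.data$core) & !is.na(.data$excision))
  if (nrow(complete) == 0) stop("no complete core/excision pairs",
                                call. = FALSE)
  dropped <- setdiff(wide$patient_id, complete$patient_id)
  values <- unclass(expr)
  diffs <- values[, complete$excision, drop = FALSE] -
    values[, complete$core, drop = FALSE]
  colnames(diffs) <- complete$patient_id
  out <- tibble(
    protein = rep(rownames(diffs), times = ncol(diffs)),
    patient_id = rep(colnames(diffs), each = nrow(diffs)),
    difference = as.vector(diffs)
  )
  attr(out, "dropped_patients") <- dropped
  out
}

#' Paired core-vs-excision tests per protein
#'
#' For each protein: a Wilcoxon signed-rank test on the paired log2 values
#' (core as "before", excision as "after"), the mean percent change on the
#' linear scale, and counts of pairs past fold-change thresholds. Percent
#' change defaults to the mean over pairs of `100 * (excision/core - 1)`
#' computed on linear-scale values; `percent_change = "ratio_of_means"`
#' instead reports `100 * (mean(excision)/mean(core) - 1)`. Threshold counts
#' use strict inequalities on the per-pair linear ratio: >50% reduction is
#' ratio < 0.5, >75% reduction is ratio < 0.25, >100% increase is ratio > 2.
#'
#' @param expr log2 `npx_matrix`.
#' @param samples lane metadata tibble.
#' @param probes optional probe annotation (supplies `is_phospho`).
#' @param percent_change `"mean_of_pair_ratios"` (default) or
#'   `"ratio_of_means"`.
#' @param adjust_p add a Benjamini-Hochberg adjusted p-value column
#'   (default `FALSE`; no multiple-testing correction otherwise).
#' @param canonical_tag see [canonical_lanes()].
#' @return tibble, one row per protein: `protein`, `is_phospho`, `n_pairs`,
#'   `mean_percent_change`, `n_over_50pct_reduction`,
#'   `n_over_75pct_reduction`, `n_over_100pct_increase`, `statistic`,
#'   `p_value`, `method` (and `p_adjusted` if requested).
#' @export
paired_protein_tests <- function(expr, samples, probes = NULL,
                                 percent_change = c("mean_of_pair_ratios",
                                                    "ratio_of_means"),
                                 adjust_p = FALSE, canonical_tag = "10x") {
  percent_change <- match.arg(percent_change)
  diffs <- difference_matrix(expr, samples, canonical_tag)
  meta <- canonical_lanes(samples, canonical_tag)
  patients <- unique(diffs$patient_id)
  core_lane <- meta$lane_id[match(paste(patients, "core"),
                                  paste(meta$patient_id, meta$specimen))]
  exc_lane <- meta$lane_id[match(paste(patients, "excision"),
                                 paste(meta$patient_id, meta$specimen))]
  if (length(patients) < 6) {
    stop("need at least 6 complete pairs, got ", length(patients),
         call. = FALSE)
  }
  values <- unclass(expr)
  phospho_of <- function(p) {
    if (is.null(probes)) return(NA)
    probes$is_phospho[match(p, probes$probe_id)]
  }
  rows <- purrr::map(rownames(values), function(p) {
    core <- values[p, core_lane]
    exc <- values[p, exc_lane]
    ratio <- 2^(exc - core)
    mpc <- if (percent_change == "mean_of_pair_ratios") {
      mean(100 * (ratio - 1))
    } else {
      100 * (mean(2^exc) / mean(2^core) - 1)
    }
    wt <- wilcoxon_signed_rank(core, exc)
    tibble(
      protein = p,
      is_phospho = phospho_of(p),
      n_pairs = length(patients),
      mean_percent_change = mpc,
      n_over_50pct_reduction = sum(ratio < 0.5),
      n_over_75pct_reduction = sum(ratio < 0.25),
      n_over_100pct_increase = sum(ratio > 2),
      statistic = wt$statistic,
      p_value = wt$p_value,
      method = wt$method
    )
  })
  out <- dplyr::bind_rows(rows)
  if (isTRUE(adjust_p)) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Correlation of the paired difference with tumour size
#'
#' Spearman correlation, per protein, of the log2 excision-minus-core
#' difference against tumour size. Patients without a recorded size are
#' excluded listwise; proteins left with fewer than 3 patients are flagged
#' (`method = "insufficient_n"`) rather than dropped.
#'
#' @param diffs difference tibble from [difference_matrix()].
#' @param samples lane metadata tibble.
#' @return tibble: `protein`, `rho`, `p_value`, `n`, `method`.
#' @export
size_association <- function(diffs, samples) {
  sizes <- samples |>
    dplyr::distinct(.data$patient_id, .data$tumour_size_mm) |>
    dplyr::filter(!is.na(.data$tumour_size_mm))
  if (nrow(sizes) == 0) stop("no patient has a tumour size", call. = FALSE)
  joined <- dplyr::inner_join(diffs, sizes, by = "patient_id")
  joined |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        return(tibble(rho = NA_real_, p_value = NA_real_, n = nrow(d),
                      method = "insufficient_n"))
      }
      spearman_test(d$difference, d$tumour_size_mm) |>
        dplyr::select("rho", "p_value", "n", "method")
    }) |>
    dplyr::ungroup()
}

#' Compare paired differences between surgery types
#'
#' Mann-Whitney U test, per protein, of the per-patient differences grouped
#' by surgery type (mastectomy as the first group). Patients with unknown
#' surgery are excluded listwise.
#'
#' @param diffs difference tibble from [difference_matrix()].
#' @param samples lane metadata tibble.
#' @return tibble: `protein`, `statistic`, `p_value`, `n_mastectomy`,
#'   `n_lumpectomy`, `method`.
#' @export
surgery_comparison <- function(diffs, samples) {
  surgery <- samples |>
    dplyr::distinct(.data$patient_id, .data$surgery) |>
    dplyr::filter(.data$surgery %in% c("lumpectomy", "mastectomy"))
  joined <- dplyr::inner_join(diffs, surgery, by = "patient_id")
  counts <- joined |> dplyr::distinct(.data$patient_id, .data$surgery) |>
    dplyr::count(.data$surgery)
  for (grp in c("lumpectomy", "mastectomy")) {
    if (!grp %in% counts$surgery) {
      stop("surgery group '", grp, "' is empty (group sizes: ",
           paste(paste0(counts$surgery, "=", counts$n), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  joined |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(d, key) {
      mw <- mann_whitney_u(d$difference[d$surgery == "mastectomy"],
                           d$difference[d$surgery == "lumpectomy"])
      tibble(statistic = mw$statistic, p_value = mw$p_value,
             n_mastectomy = mw$n_a, n_lumpectomy = mw$n_b,
             method = mw$method)
    }) |>
    dplyr::ungroup()
}

#' Correlation between phospho and non-phospho mean differences
#'
#' Per patient, the mean paired difference over all phosphoproteins and over
#' all non-phosphoproteins; returns the Spearman correlation between those
#' two patient vectors, plus the correlation of the mean phospho difference
#' against each individual non-phospho protein's difference.
#'
#' @param diffs difference tibble from [difference_matrix()].
#' @param probes probe annotation tibble (supplies `is_phospho`).
#' @return list with `mean_correlation` (one-row tibble) and
#'   `per_nonphospho` (tibble, one row per non-phospho protein).
#' @export
phospho_nonphospho_correlation <- function(diffs, probes) {
  ann <- probes |>
    dplyr::filter(.data$probe_class == "endogenous") |>
    dplyr::select(protein = "probe_id", "is_phospho")
  d <- dplyr::inner_join(diffs, ann, by = "protein")
  n_ph <- dplyr::n_distinct(d$protein[d$is_phospho])
  n_np <- dplyr::n_distinct(d$protein[!d$is_phospho])
  if (n_ph < 2 || n_np < 2) {
    stop("need >= 2 phospho and >= 2 non-phospho proteins (got ",
         n_ph, " and ", n_np, ")", call. = FALSE)
  }
  means <- d |>
    dplyr::group_by(.data$patient_id, .data$is_phospho) |>
    dplyr::summarise(mean_diff = mean(.data$difference), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "is_phospho", values_from = "mean_diff",
                       names_prefix = "phospho_")
  mean_correlation <- spearman_test(means$phospho_TRUE, means$phospho_FALSE)
  phospho_mean <- setNames(means$phospho_TRUE, means$patient_id)
  per_nonphospho <- d |>
    dplyr::filter(!.data$is_phospho) |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(dd, key) {
      spearman_test(phospho_mean[dd$patient_id], dd$difference) |>
        dplyr::select("rho", "p_value", "n", "method")
    }) |>
    dplyr::ungroup()
  list(mean_correlation = mean_correlation, per_nonphospho = per_nonphospho)
}

#' Default mapping between IHC proteins and panel targets
#'
#' The five markers with both read-outs: Ki67, PgR, HER2, pAKT, pERK1/2.
#'
#' @return tibble with columns `protein` (IHC name) and `target` (panel
#'   target name).
#' @export
default_ihc_mapping <- function() {
  tibble(protein = c("Ki67", "PgR", "HER2", "pAKT", "pERK1/2"),
         target = c("Ki67", "PgR", "HER2", "pAKT", "pERK1/2"))
}

#' Concordance between panel expression and IHC scores
#'
#' For each mapped protein, the Spearman correlation between log2 panel
#' expression and the IHC score, pooled over both specimen types and within
#' each specimen type separately. The expression matrix should come from the
#' normalization branch without IgG subtraction. Ordinal IHC scales (HER2
#' 0-3+) enter as mid-ranks. Unmapped IHC proteins are skipped and listed in
#' the `skipped` attribute.
#'
#' @param expr log2 `npx_matrix` from `run_normalization(...,
#'   subtract_igg = FALSE)`.
#' @param ihc IHC record tibble from [read_ihc()].
#' @param samples lane metadata tibble.
#' @param mapping tibble with columns `protein`, `target`
#'   (default [default_ihc_mapping()]).
#' @param canonical_tag see [canonical_lanes()].
#' @return tibble: `protein`, `target`, `stratum`
#'   (pooled/core/excision), `rho`, `p_value`, `n`, `method`.
#' @export
ihc_concordance <- function(expr, ihc, samples,
                            mapping = default_ihc_mapping(),
                            canonical_tag = "10x") {
  check_stage(expr, "log2", "ihc_concordance")
  meta <- canonical_lanes(samples, canonical_tag)
  skipped <- setdiff(unique(ihc$protein), mapping$protein)
  values <- unclass(expr)
  rows <- purrr::pmap(mapping, function(protein, target) {
    if (!target %in% rownames(values)) {
      return(NULL)
    }
    scores <- ihc |> dplyr::filter(.data$protein == !!protein)
    matched <- scores |>
      dplyr::inner_join(meta, by = c("patient_id", "specimen")) |>
      dplyr::mutate(expression = values[target, .data$lane_id])
    strata <- list(pooled = matched,
                   core = matched[matched$specimen == "core", ],
                   excision = matched[matched$specimen == "excision", ])
    purrr::imap(strata, function(d, nm) {
      res <- if (nrow(d) < 3) {
        tibble(rho = NA_real_, p_value = NA_real_, n = nrow(d),
               method = "insufficient_n")
      } else {
        spearman_test(d$expression, d$value) |>
          dplyr::select("rho", "p_value", "n", "method")
      }
      dplyr::bind_cols(tibble(protein = protein, target = target,
                              stratum = nm), res)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}
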