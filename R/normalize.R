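#' Geometric mean
#'
#' `exp(mean(log(values)))`. All values must be strictly positive; control
#' probes that may legitimately contain zeros are pre-offset by the caller
#' (see [background_correct()]).
#'
#' @param values positive numeric vector, length >= 1.
#' @return positive scalar.
#' @examples
#' geometric_mean(c(2, 4, 8, 16, 32, 64)) # 2^3.5
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0) stop("geometric_mean of empty input", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("geometric_mean requires strictly positive finite values",
         call. = FALSE)
  }
  exp(mean(log(values)))
}

# geometric mean with zeros replaced by `offset` (background control probes)
geometric_mean_offset <- function(values, offset = 0.5) {
  values[values == 0] <- offset
  geometric_mean(values)
}

probe_ids_of_class <- function(probes, cls) {
  probes$probe_id[probes$probe_class %in% cls]
}

#' Positive-control (ERCC) lane normalization
#'
#' Scales every lane so the spike-in positive-control ladder has the same
#' geometric mean in all lanes, absorbing hybridization-efficiency
#' differences. Lane `l` with positive-control geometric mean `g_l` is
#' multiplied by `f_l = G / g_l`, where `G` is the geometric mean of the
#' `g_l` over lanes — so the factors themselves have geometric mean 1 and
#' the reference is a cohort-level constant that cancels from all downstream
#' log-ratio statistics.
#'
#' @param raw `npx_matrix` at stage `"raw"`.
#' @param probes probe annotation tibble.
#' @return list with `counts` (stage `"positive_normalized"`) and
#'   `lane_scaling_factors` (named numeric).
#' @export
positive_control_normalize <- function(raw, probes) {
  check_stage(raw, "raw", "positive_control_normalize")
  pos <- probe_ids_of_class(probes, "positive")
  if (length(pos) == 0) stop("no positive-control probes", call. = FALSE)
  pos_counts <- unclass(raw)[pos, , drop = FALSE]
  zero_lane <- colnames(raw)[colSums(pos_counts <= 0) > 0]
  if (length(zero_lane)) {
    stop("zero positive-control count (assay failure) in lane(s): ",
         paste(zero_lane, collapse = ", "), call. = FALSE)
  }
  g <- apply(pos_counts, 2, geometric_mean)
  G <- geometric_mean(g)
  f <- G / g
  out <- sweep(unclass(raw), 2, f, `*`)
  list(counts = restage(out, raw, "positive_normalized"),
       lane_scaling_factors = f)
}

#' Background correction by negative-probe and IgG subtraction
#'
#' Per lane, the geometric mean of the ERCC negative-control probes is
#' subtracted from every endogenous and housekeeping count (floored at
#' zero). If `subtract_igg` is `TRUE`, the geometric mean of the IgG
#' non-specific controls — themselves first negative-subtracted and floored
#' — is then subtracted likewise. For the background geometric means, zero
#' control counts are replaced by 0.5 so the background stays estimable.
#' Control probe rows are carried through unmodified for reporting. The IHC
#' comparison branch of the pipeline re-runs this stage with
#' `subtract_igg = FALSE`.
#'
#' @param m `npx_matrix` at stage `"positive_normalized"`.
#' @param probes probe annotation tibble.
#' @param subtract_igg subtract the IgG background after the negative-probe
#'   background (default `TRUE`).
#' @return list with `counts` (stage `"background_corrected"`),
#'   `negative_background` and `igg_background` (named per-lane numerics;
#'   the latter all-zero when `subtract_igg = FALSE`).
#' @export
background_correct <- function(m, probes, subtract_igg = TRUE) {
  check_stage(m, "positive_normalized", "background_correct")
  negs <- probe_ids_of_class(probes, "negative")
  if (length(negs) == 0) stop("no negative-control probes", call. = FALSE)
  target_rows <- probe_ids_of_class(probes, c("endogenous", "housekeeping"))
  values <- unclass(m)
  b_neg <- apply(values[negs, , drop = FALSE], 2, geometric_mean_offset)
  out <- values
  out[target_rows, ] <- pmax(
    sweep(values[target_rows, , drop = FALSE], 2, b_neg, `-`), 0)
  b_igg <- setNames(numeric(ncol(values)), colnames(values))
  if (isTRUE(subtract_igg)) {
    iggs <- probe_ids_of_class(probes, "igg")
    if (length(iggs) == 0) {
      stop("subtract_igg = TRUE but no IgG probes", call. = FALSE)
    }
    igg_corr <- pmax(sweep(values[iggs, , drop = FALSE], 2, b_neg, `-`), 0)
    b_igg <- apply(igg_corr, 2, geometric_mean_offset)
    out[target_rows, ] <- pmax(
      sweep(out[target_rows, , drop = FALSE], 2, b_igg, `-`), 0)
  }
  list(counts = restage(out, m, "background_corrected"),
       negative_background = b_neg, igg_background = b_igg)
}

#' Select the housekeeping probe with the lowest variation
#'
#' Among the housekeeping-class candidates, returns the probe whose log2
#' counts have the smallest coefficient of variation across lanes (the
#' operationalization of "lowest variation across the studied samples"),
#' together with the full CV table. Ties break by probe id.
#'
#' @param m `npx_matrix` at stage `"background_corrected"`.
#' @param probes probe annotation tibble.
#' @return list with `probe_id` and `cv_table` (tibble: probe_id, cv).
#' @export
select_housekeeping <- function(m, probes) {
  check_stage(m, "background_corrected", "select_housekeeping")
  hk <- probe_ids_of_class(probes, "housekeeping")
  if (length(hk) == 0) stop("no housekeeping probes", call. = FALSE)
  values <- unclass(m)[hk, , drop = FALSE]
  if (any(values <= 0)) {
    bad <- hk[rowSums(values <= 0) > 0]
    stop("housekeeping probe(s) with zero counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lv <- log2(values)
  cv <- apply(lv, 1, function(x) if (mean(x) == 0) Inf else sd(x) / abs(mean(x)))
  if (ncol(values) == 1) cv[] <- 0
  tab <- tibble(probe_id = hk, cv = as.numeric(cv)) |>
    dplyr::arrange(.data$cv, .data$probe_id)
  list(probe_id = tab$probe_id[1], cv_table = tab)
}

#' Housekeeping (sample-input) normalization
#'
#' Divides every endogenous (and housekeeping) count in lane `l` by
#' `hk(l) / G_hk`, where `G_hk` is the geometric mean of the housekeeping
#' counts over lanes, so the housekeeping probe becomes constant across
#' lanes and input-amount differences cancel. Control probes pass through
#' unmodified.
#'
#' @param m `npx_matrix` at stage `"background_corrected"`.
#' @param hk probe id of the housekeeping probe to normalize to.
#' @return `npx_matrix` at stage `"housekeeping_normalized"`.
#' @export
housekeeping_normalize <- function(m, hk) {
  check_stage(m, "background_corrected", "housekeeping_normalize")
  values <- unclass(m)
  if (!hk %in% rownames(values)) {
    stop("housekeeping probe not in matrix: ", hk, call. = FALSE)
  }
  hkc <- values[hk, ]
  if (any(hkc <= 0)) {
    stop("housekeeping probe '", hk, "' has zero counts in lane(s): ",
         paste(colnames(values)[hkc <= 0], collapse = ", "), call. = FALSE)
  }
  ratio <- hkc / geometric_mean(hkc)
  # all rows are scaled; control probes have no role after this stage
  out <- sweep(values, 2, ratio, `/`)
  restage(out, m, "housekeeping_normalized")
}

#' Flag endogenous probes never detected above IgG background
#'
#' An endogenous probe is undetected when its count is below the lane's
#' geometric mean of IgG counts in every lane. Undetected probes are
#' excluded from downstream statistics. The comparison is made on counts
#' that have not had the IgG level subtracted from them (raw or
#' positive-normalized), since background correction removes the very level
#' being compared against.
#'
#' @param m `npx_matrix` at stage `"raw"` or `"positive_normalized"`.
#' @param probes probe annotation tibble.
#' @return character vector of undetected endogenous probe ids.
#' @export
detect_above_background <- function(m, probes) {
  check_stage(m, c("raw", "positive_normalized"), "detect_above_background")
  iggs <- probe_ids_of_class(probes, "igg")
  if (length(iggs) == 0) stop("no IgG probes", call. = FALSE)
  endo <- probe_ids_of_class(probes, "endogenous")
  values <- unclass(m)
  igg_gm <- apply(values[iggs, , drop = FALSE], 2, geometric_mean_offset)
  below <- sweep(values[endo, , drop = FALSE], 2, igg_gm, `<`)
  endo[rowSums(below) == ncol(values)]
}

#' Half-minimum zero imputation and log2 transform
#'
#' For each endogenous probe, zeros are replaced by half the smallest
#' strictly positive value of that probe across all lanes, then the matrix
#' is log2 transformed. A probe with no positive value anywhere cannot be
#' imputed and raises an error (such probes should have been excluded as
#' undetected).
#'
#' @param m `npx_matrix` at stage `"housekeeping_normalized"`, endogenous
#'   probes only.
#' @return list with `expr` (`npx_matrix`, stage `"log2"`) and
#'   `imputation_log` (tibble: probe_id, lane_id, imputed_value).
#' @export
impute_and_log <- function(m) {
  check_stage(m, "housekeeping_normalized", "impute_and_log")
  values <- unclass(m)
  all_zero <- rownames(values)[apply(values, 1, function(x) all(x == 0))]
  if (length(all_zero)) {
    stop("probe(s) with all-zero values cannot be imputed: ",
         paste(all_zero, collapse = ", "), call. = FALSE)
  }
  log_rows <- list()
  for (p in rownames(values)) {
    z <- values[p, ] == 0
    if (any(z)) {
      half_min <- min(values[p, values[p, ] > 0]) / 2
      values[p, z] <- half_min
      log_rows[[p]] <- tibble(probe_id = p,
                              lane_id = colnames(values)[z],
                              imputed_value = half_min)
    }
  }
  imputation_log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble(probe_id = character(), lane_id = character(),
           imputed_value = numeric())
  list(expr = restage(log2(values), m, "log2"), imputation_log = imputation_log)
}

#' Run the full normalization chain
#'
#' Composes, in order: positive-control lane scaling, background correction
#' (negative probes, then optionally IgG), housekeeping selection and
#' normalization, exclusion of endogenous probes never detected above IgG
#' background, and half-minimum imputation with log2 transform. The returned
#' expression matrix contains the detected endogenous probes only.
#'
#' @param dataset an `"npx_dataset"` from [read_dataset()] or
#'   [npx_dataset()].
#' @param subtract_igg subtract IgG background (default `TRUE`; the IHC
#'   concordance analysis uses `FALSE`).
#' @param housekeeping `"auto"` (lowest-CV candidate) or a housekeeping
#'   probe id.
#' @return object of class `"npx_normalization"`: list with `expr`
#'   (log2 `npx_matrix`), `report` (lane scaling factors, backgrounds,
#'   housekeeping choice and CV table, imputation log, undetected probes,
#'   options), and `stages` (the intermediate matrices).
#' @export
run_normalization <- function(dataset, subtract_igg = TRUE,
                              housekeeping = "auto") {
  stopifnot(inherits(dataset, "npx_dataset"))
  probes <- dataset$probes
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("normalization stage '%s': %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }
  pn <- step("positive_control_normalize",
             positive_control_normalize(dataset$counts, probes))
  bg <- step("background_correct",
             background_correct(pn$counts, probes, subtract_igg = subtract_igg))
  if (identical(housekeeping, "auto")) {
    hk_sel <- step("select_housekeeping",
                   select_housekeeping(bg$counts, probes))
  } else {
    if (!housekeeping %in% probe_ids_of_class(probes, "housekeeping")) {
      stop("normalization stage 'select_housekeeping': '", housekeeping,
           "' is not a housekeeping-class probe", call. = FALSE)
    }
    hk_sel <- list(probe_id = housekeeping,
                   cv_table = tibble(probe_id = housekeeping, cv = NA_real_))
  }
  hn <- step("housekeeping_normalize",
             housekeeping_normalize(bg$counts, hk_sel$probe_id))
  undetected <- step("detect_above_background",
                     detect_above_background(pn$counts, probes))
  endo <- setdiff(probe_ids_of_class(probes, "endogenous"), undetected)
  if (length(endo) == 0) {
    stop("normalization stage 'detect_above_background': ",
         "no endogenous probe detected above background", call. = FALSE)
  }
  endo_vals <- unclass(hn)[endo, , drop = FALSE]
  endo_m <- count_matrix(endo_vals, "housekeeping_normalized")
  il <- step("impute_and_log", impute_and_log(endo_m))
  report <- list(
    lane_scaling_factors = pn$lane_scaling_factors,
    negative_background = bg$negative_background,
    igg_background = bg$igg_background,
    housekeeping_choice = hk_sel$probe_id,
    housekeeping_cv_table = hk_sel$cv_table,
    zero_imputation_log = il$imputation_log,
    undetected_probes = undetected,
    options = list(subtract_igg = subtract_igg, housekeeping = housekeeping)
  )
  structure(
    list(expr = il$expr, report = report,
         stages = list(positive_normalized = pn$counts,
                       background_corrected = bg$counts,
                       housekeeping_normalized = hn)),
    class = "npx_normalization"
  )
}

#' @export
print.npx_normalization <- function(x, ...) {
  cat("<npx_normalization>\n")
  cat(sprintf("  %d probes x %d lanes (log2)\n", nrow(x$expr), ncol(x$expr)))
  cat(sprintf("  housekeeping: %s | IgG subtracted: %s\n",
              x$report$housekeeping_choice, x$report$options$subtract_igg))
  cat(sprintf("  undetected probes excluded: %s\n",
              if (length(x$report$undetected_probes))
                paste(x$report$undetected_probes, collapse = ", ") else "none"))
  cat(sprintf("  zero imputations: %d\n", nrow(x$report$zero_imputation_log)))
  invisible(x)
}

#' Tidy and summarize a normalization result
#'
#' `tidy()` returns the normalized expression in long format; `glance()`
#' returns a one-row summary.
#'
#' @param x an `"npx_normalization"` object.
#' @param ... unused.
#' @export
tidy.npx_normalization <- function(x, ...) {
  tidy(x$expr) |>
    dplyr::rename(log2_expression = "value") |>
    dplyr::select(-"stage")
}

#' @rdname tidy.npx_normalization
#' @export
glance.npx_normalization <- function(x, ...) {
  tibble(
    n_probes = nrow(x$expr),
    n_lanes = ncol(x$expr),
    housekeeping = x$report$housekeeping_choice,
    subtract_igg = x$report$options$subtract_igg,
    n_undetected = length(x$report$undetected_probes),
    n_imputed = nrow(x$report$zero_imputation_log)
  )
}
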