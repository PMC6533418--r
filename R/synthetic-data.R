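#' Default 26-protein panel for simulated cohorts
#'
#' Thirteen phosphoproteins and thirteen non-phosphorylated proteins with
#' per-protein fixation-effect targets. `target_reduction` is the expected
#' mean linear reduction of excision relative to core signal (phospho decay
#' under delayed fixation); `target_increase` is the expected mean linear
#' increase (stress-response induction). Targets are anchored to the net
#' effects reported for this assay class (for example pAKT 59.5 percent mean
#' reduction, pan-KRT more than doubling in most pairs); proteins reported
#' non-significant get a small 10 percent reduction. The decay/stress rate
#' constants that realise these targets under a given delay distribution are
#' solved by [sim_params()]. `pEGFR` emulates a probe with essentially no
#' target in the tissue: near-zero abundance and below-IgG nonspecific
#' binding (`igg_binding` 0.1), so it is flagged undetected.
#'
#' @return tibble with columns `name`, `is_phospho`, `baseline` (median
#'   abundance, arbitrary units), `target_reduction`, `target_increase`,
#'   `igg_binding`.
#' @export
default_protein_panel <- function() {
  tibble::tribble(
    ~name,      ~is_phospho, ~baseline, ~target_reduction, ~target_increase,
    "pERK1/2",  TRUE,  150, 0.650, 0,
    "pAKT",     TRUE,  200, 0.595, 0,
    "p4EBP1",   TRUE,  300, 0.542, 0,
    "pGSK3B",   TRUE,  100, 0.800, 0,
    "pRPS6",    TRUE,  400, 0.400, 0,
    "pAMPKa",   TRUE,  120, 0.551, 0,
    "pMEK1/2",  TRUE,  180, 0.263, 0,
    "pPRAS40",  TRUE,  250, 0.341, 0,
    "pTSC2",    TRUE,   80, 0.100, 0,
    "pPDK1",    TRUE,  140, 0.100, 0,
    "pRAF1",    TRUE,  160, 0.100, 0,
    "pH3",      TRUE,  500, 0.100, 0,
    "pEGFR",    TRUE, 0.02, 0.000, 0,
    "Ki67",     FALSE,  60, 0, 0,
    "PgR",      FALSE,  90, 0, 0,
    "HER2",     FALSE, 220, 0, 0,
    "pan-KRT",  FALSE, 600, 0, 1.200,
    "4EBP1",    FALSE, 350, 0, 0.870,
    "ERK1/2",   FALSE, 280, 0, 0.695,
    "MET",      FALSE, 130, 0, 0.279,
    "GSK3B",    FALSE, 110, 0, 0,
    "pan-AKT",  FALSE, 240, 0, 0,
    "TSC2",     FALSE,  70, 0, 0,
    "MEK1/2",   FALSE, 190, 0, 0,
    "RPS6",     FALSE, 450, 0, 0,
    "RAF1",     FALSE, 100, 0, 0
  ) |>
    dplyr::mutate(igg_binding = ifelse(.data$name == "pEGFR", 0.1, 1))
}

#' Simulation parameters for a paired-specimen cohort
#'
#' Defines the study conditions the generator emulates: 16 patients with
#' paired core-cut and excision specimens, a log-normal tumour-size
#' distribution (median 33.5 mm), surgery assignment by size (mastectomy
#' above 30 mm, roughly half the cohort), and a fixation-delay model in
#' which formalin penetrates tissue at about 1 mm/h. Core-cuts fix almost
#' immediately (`core_delay_h`). The default `"size_proportional"` model
#' sets the excision fixation delay to half the tumour size divided by the
#' penetration rate — larger specimens fix more slowly, reproducing the
#' observed pattern of greater immunoreactivity loss in larger tumours and
#' hence in mastectomy specimens. The alternative `"surgery"` model caps
#' the half-thickness of sliced mastectomy specimens at
#' `mastectomy_slice_half_mm` and adds `overnight_offset_h` for unsliced
#' lumpectomies; `"constant"` fixes the delay at `constant_delay_h` for
#' every patient (a no-size-coupling control).
#'
#' Per-protein decay rates `lambda` (per hour) and stress gains `gamma` are
#' solved so that the expected mean linear reduction/increase over the
#' delay distribution equals each protein's target (see
#' [lability_for_mean_reduction()]). Supplying a panel that already has
#' `lambda`/`gamma` columns skips the solve.
#'
#' Measurement layers: endogenous counts are negative binomial around
#' `count_scale * abundance * lane_effect * input_amount` plus nonspecific
#' background; ERCC positive-control counts follow a spike ladder scaled by
#' the lane effect only; negative probes measure lane background; IgG probes
#' scale with input. IHC read-outs are a saturating (Hill) transform of the
#' same specimen-level latent abundance plus Gaussian noise, clipped to the
#' scale bounds.
#'
#' @param n_patients number of patients (paired lanes; default 16).
#' @param proteins protein panel tibble (default [default_protein_panel()]).
#' @param tumour_size_median_mm,tumour_size_sdlog log-normal tumour size
#'   distribution (defaults 33.5 mm, 0.6 — giving an IQR close to 20-45 mm).
#' @param tumour_size_range_mm truncation bounds of the size distribution
#'   (default 15-100 mm, the clinically plausible range for excised primary
#'   tumours).
#' @param mastectomy_size_threshold_mm surgery assignment threshold
#'   (default 30).
#' @param delay_model `"surgery"`, `"size_proportional"`, or `"constant"`.
#' @param core_delay_h core-cut fixation delay in hours (default 0.05).
#' @param excision_handling_offset_h handling time from devascularization to
#'   fixative equilibration, added to every excision delay under the
#'   size-dependent models (default 3 h; applies to excised specimens only,
#'   cores being fixed at the time of the procedure).
#' @param penetration_rate_mm_per_h formalin penetration rate (default 1).
#' @param mastectomy_slice_half_mm half-thickness of sliced mastectomy
#'   tissue (default 5).
#' @param overnight_offset_h extra delay for unsliced lumpectomies
#'   (default 16).
#' @param constant_delay_h delay for `delay_model = "constant"` (default 5).
#' @param stress_tau_h time constant of the saturating stress response
#'   (default 6).
#' @param abundance_sdlog between-patient abundance spread on the log scale
#'   (default 0.2; the cohort this emulates is biologically homogeneous —
#'   all ER-positive primaries — and its observed near-perfect specimen
#'   clustering implies the fixation artifact dominates patient-level
#'   profile variation).
#' @param lane_effect_sd,input_amount_sd log-scale SDs of the
#'   hybridization-efficiency and sample-input nuisance factors
#'   (defaults 0.15, 0.3).
#' @param count_scale counts per abundance unit (default 20).
#' @param count_dispersion negative-binomial dispersion (default 0.01,
#'   about a 10 percent technical CV at high counts; 0 gives deterministic
#'   counts equal to their means).
#' @param positive_ladder ERCC positive spike counts (6 values).
#' @param negative_probe_means ERCC negative probe mean counts (6 values).
#' @param igg_levels IgG probe nonspecific levels (2 values).
#' @param housekeeping_level latent abundance of the Histone H3 probe
#'   (default 100).
#' @param ihc_proteins names of panel proteins with an IHC read-out.
#' @param ihc_noise_frac IHC noise SD as a fraction of the scale maximum
#'   (default 0.08).
#' @param ihc_hill Hill coefficient of the IHC saturating transform
#'   (default 1).
#' @param seed integer seed making [generate_cohort()] deterministic.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_patients = 16,
                       proteins = default_protein_panel(),
                       tumour_size_median_mm = 33.5,
                       tumour_size_sdlog = 0.6,
                       tumour_size_range_mm = c(15, 100),
                       mastectomy_size_threshold_mm = 30,
                       delay_model = c("size_proportional", "surgery",
                                       "constant"),
                       core_delay_h = 0.05,
                       excision_handling_offset_h = 3,
                       penetration_rate_mm_per_h = 1,
                       mastectomy_slice_half_mm = 5,
                       overnight_offset_h = 16,
                       constant_delay_h = 5,
                       stress_tau_h = 6,
                       abundance_sdlog = 0.2,
                       lane_effect_sd = 0.15,
                       input_amount_sd = 0.3,
                       count_scale = 20,
                       count_dispersion = 0.01,
                       positive_ladder = c(32, 128, 512, 2048, 8192, 32768),
                       negative_probe_means = c(10, 12, 14, 16, 18, 22),
                       igg_levels = c(60, 60),
                       housekeeping_level = 100,
                       ihc_proteins = c("Ki67", "PgR", "HER2", "pAKT",
                                        "pERK1/2"),
                       ihc_noise_frac = 0.08,
                       ihc_hill = 1,
                       seed = 1L) {
  delay_model <- match.arg(delay_model)
  stopifnot(
    n_patients >= 1, tumour_size_median_mm > 0, tumour_size_sdlog >= 0,
    length(tumour_size_range_mm) == 2, tumour_size_range_mm[1] > 0,
    tumour_size_range_mm[1] < tumour_size_range_mm[2],
    penetration_rate_mm_per_h > 0, core_delay_h >= 0, overnight_offset_h >= 0,
    excision_handling_offset_h >= 0,
    constant_delay_h >= 0, stress_tau_h > 0, abundance_sdlog >= 0,
    lane_effect_sd >= 0, input_amount_sd >= 0, count_scale > 0,
    count_dispersion >= 0, all(positive_ladder > 0),
    all(negative_probe_means >= 0), all(igg_levels >= 0),
    housekeeping_level > 0, ihc_noise_frac >= 0, ihc_hill > 0
  )
  proteins <- as_tibble(proteins)
  need <- c("name", "is_phospho", "baseline", "target_reduction",
            "target_increase")
  stopifnot(all(need %in% names(proteins)),
            all(proteins$baseline > 0),
            all(proteins$target_reduction >= 0),
            all(proteins$target_reduction < 1),
            all(proteins$target_increase >= 0))
  if (!"igg_binding" %in% names(proteins)) proteins$igg_binding <- 1
  p <- structure(
    list(n_patients = as.integer(n_patients), proteins = proteins,
         tumour_size_median_mm = tumour_size_median_mm,
         tumour_size_sdlog = tumour_size_sdlog,
         tumour_size_range_mm = tumour_size_range_mm,
         mastectomy_size_threshold_mm = mastectomy_size_threshold_mm,
         delay_model = delay_model, core_delay_h = core_delay_h,
         excision_handling_offset_h = excision_handling_offset_h,
         penetration_rate_mm_per_h = penetration_rate_mm_per_h,
         mastectomy_slice_half_mm = mastectomy_slice_half_mm,
         overnight_offset_h = overnight_offset_h,
         constant_delay_h = constant_delay_h, stress_tau_h = stress_tau_h,
         abundance_sdlog = abundance_sdlog, lane_effect_sd = lane_effect_sd,
         input_amount_sd = input_amount_sd, count_scale = count_scale,
         count_dispersion = count_dispersion,
         positive_ladder = positive_ladder,
         negative_probe_means = negative_probe_means,
         igg_levels = igg_levels, housekeeping_level = housekeeping_level,
         ihc_proteins = ihc_proteins, ihc_noise_frac = ihc_noise_frac,
         ihc_hill = ihc_hill, seed = as.integer(seed)),
    class = "sim_params"
  )
  if (!"lambda" %in% names(proteins)) proteins$lambda <- NA_real_
  if (!"gamma" %in% names(proteins)) proteins$gamma <- NA_real_
  miss_g <- is.na(proteins$gamma)
  proteins$gamma[miss_g] <- vapply(
    proteins$target_increase[miss_g], stress_gain_for_mean_increase,
    numeric(1), params = p)
  miss_l <- is.na(proteins$lambda)
  proteins$lambda[miss_l] <- vapply(
    seq_len(nrow(proteins))[miss_l],
    function(i) lability_for_mean_reduction(proteins$target_reduction[i], p,
                                            gamma = proteins$gamma[i]),
    numeric(1))
  p$proteins <- proteins
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  %d patients, %d proteins (%d phospho), delay model '%s'\n",
              x$n_patients, nrow(x$proteins), sum(x$proteins$is_phospho),
              x$delay_model))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# truncated log-normal draws by inverse-CDF
rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  if (sdlog == 0) return(rep(exp(meanlog), n))
  plo <- plnorm(lower, meanlog, sdlog)
  phi <- plnorm(upper, meanlog, sdlog)
  qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

# deterministic quadrature grid over the excision-delay distribution:
# tumour sizes at equally spaced quantiles of the truncated size
# distribution, mapped through the delay rule
delay_grid <- function(params, n_grid = 401) {
  meanlog <- log(params$tumour_size_median_mm)
  sdlog <- params$tumour_size_sdlog
  plo <- plnorm(params$tumour_size_range_mm[1], meanlog, sdlog)
  phi <- plnorm(params$tumour_size_range_mm[2], meanlog, sdlog)
  sizes <- qlnorm(plo + stats::ppoints(n_grid) * (phi - plo), meanlog, sdlog)
  excision_delay(sizes, params)
}

# excision fixation delay (hours) as a function of tumour size; all excised
# specimens additionally accrue the handling offset (devascularization to
# fixative equilibration), which cores - fixed at the time of the procedure -
# do not
excision_delay <- function(size_mm, params) {
  handling <- params$excision_handling_offset_h
  switch(params$delay_model,
    surgery = {
      mast <- size_mm > params$mastectomy_size_threshold_mm
      half <- ifelse(mast, pmin(size_mm / 2, params$mastectomy_slice_half_mm),
                     size_mm / 2)
      offset <- ifelse(mast, 0, params$overnight_offset_h)
      half / params$penetration_rate_mm_per_h + offset + handling
    },
    size_proportional = (size_mm / 2) / params$penetration_rate_mm_per_h +
      handling,
    constant = rep(params$constant_delay_h, length(size_mm))
  )
}

# linear excision/core signal ratio after delay d
decay_ratio <- function(d, lambda, gamma, tau) {
  exp(-lambda * d) * (1 + gamma * (1 - exp(-d / tau)))
}

#' Expected mean linear reduction under the delay distribution
#'
#' `1 - E[exp(-lambda D) (1 + gamma (1 - exp(-D / tau)))]` with the
#' expectation taken over the excision-delay distribution implied by the
#' parameters (deterministic quantile quadrature over the tumour-size
#' distribution). Negative values are expected mean increases.
#'
#' @param lambda decay rate per hour.
#' @param params a `"sim_params"` object (or the argument list of one).
#' @param gamma stress gain (default 0).
#' @return expected mean linear reduction (fraction).
#' @export
expected_mean_reduction <- function(lambda, params, gamma = 0) {
  d <- delay_grid(params)
  1 - mean(decay_ratio(d, lambda, gamma, params$stress_tau_h))
}

#' Solve the decay rate giving a target expected mean reduction
#'
#' Inverts [expected_mean_reduction()] in `lambda` by root finding, holding
#' `gamma` fixed.
#'
#' @param reduction target expected mean linear reduction in `[0, 1)`.
#' @param params a `"sim_params"` object.
#' @param gamma stress gain held fixed (default 0).
#' @return decay rate lambda (per hour).
#' @export
lability_for_mean_reduction <- function(reduction, params, gamma = 0) {
  stopifnot(reduction >= 0, reduction < 1)
  if (reduction == 0 && gamma == 0) return(0)
  if (reduction == 0) return(0)
  f <- function(l) expected_mean_reduction(l, params, gamma) - reduction
  uniroot(f, c(0, 100), tol = 1e-10)$root
}

#' Solve the stress gain giving a target expected mean increase
#'
#' With no decay, the expected mean linear increase is
#' `gamma * E[1 - exp(-D / tau)]`; this returns `gamma` for a target
#' increase.
#'
#' @param increase target expected mean linear increase (>= 0).
#' @param params a `"sim_params"` object.
#' @return stress gain gamma.
#' @export
stress_gain_for_mean_increase <- function(increase, params) {
  if (increase == 0) return(0)
  d <- delay_grid(params)
  increase / mean(1 - exp(-d / params$stress_tau_h))
}

# control probe annotation shared by cohort and dilution generators
control_probes <- function() {
  tibble(
    probe_id = c(paste0("POS_", LETTERS[1:6]), paste0("NEG_", LETTERS[1:6]),
                 "IgG_rabbit", "IgG_mouse", "HistoneH3"),
    target = c(paste0("ERCC positive ", LETTERS[1:6]),
               paste0("ERCC negative ", LETTERS[1:6]),
               "rabbit IgG", "mouse IgG", "Histone H3"),
    probe_class = c(rep("positive", 6), rep("negative", 6), rep("igg", 2),
                    "housekeeping"),
    is_phospho = NA
  )
}

# negative-binomial (or deterministic, when dispersion = 0) counts
draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(mu)
  rnbinom(length(mu), mu = mu, size = 1 / dispersion) * 1.0
}

# expected count matrix for a set of lanes given per-lane latent abundances
# (proteins x lanes), lane effects and input amounts
expected_counts <- function(abund, lane_eff, input, params) {
  pr <- params$proteins
  gm_neg <- geometric_mean_offset(params$negative_probe_means)
  gm_igg <- geometric_mean_offset(params$igg_levels)
  n_lane <- length(lane_eff)
  endo <- sweep(params$count_scale * sweep(abund, 2, input, `*`), 2,
                lane_eff, `*`) +
    outer(pr$igg_binding, lane_eff * input * gm_igg) +
    outer(rep(1, nrow(pr)), lane_eff * gm_neg)
  pos <- outer(params$positive_ladder, lane_eff)
  neg <- outer(params$negative_probe_means, lane_eff)
  igg <- outer(params$igg_levels, input * lane_eff) +
    outer(rep(1, length(params$igg_levels)), lane_eff * gm_neg)
  hk <- matrix(params$count_scale * params$housekeeping_level *
                 lane_eff * input +
                 lane_eff * input * gm_igg + lane_eff * gm_neg,
               nrow = 1)
  out <- rbind(endo, pos, neg, igg, hk)
  rownames(out) <- c(pr$name, control_probes()$probe_id)
  out
}

#' Generate a paired core/excision cohort
#'
#' Draws, in a documented order under one seeded stream (tumour sizes,
#' patient-by-protein core abundances, lane effects, input amounts, counts,
#' IHC noise), a full synthetic cohort: a raw count matrix over the panel
#' and control probes, lane metadata, IHC records for the mapped proteins,
#' and the latent truth needed for parameter-recovery tests. Excision
#' abundance is `core * exp(-lambda * d) * (1 + gamma * (1 - exp(-d / tau)))`
#' with `d` the patient's excision fixation delay.
#'
#' @param params a `"sim_params"` object.
#' @param seed optional override of `params$seed`.
#' @return list of class `"npx_cohort"`: `dataset` (an `"npx_dataset"`),
#'   `ihc` (tibble), `truth` (list: `patients` tibble with size, surgery,
#'   delay; `core_abundance`, `excision_abundance` matrices;
#'   `true_mean_reduction` named vector; `lane_effects`, `input_amounts`),
#'   and `params`.
#' @export
generate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  withr::with_seed(seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(params) {
  np <- params$n_patients
  pr <- params$proteins
  patients <- sprintf("P%02d", seq_len(np))
  sizes <- rtrunc_lnorm(np, meanlog = log(params$tumour_size_median_mm),
                        sdlog = params$tumour_size_sdlog,
                        lower = params$tumour_size_range_mm[1],
                        upper = params$tumour_size_range_mm[2])
  surgery <- ifelse(sizes > params$mastectomy_size_threshold_mm,
                    "mastectomy", "lumpectomy")
  d_exc <- excision_delay(sizes, params)
  # core abundance: patient-by-protein log-normal around each baseline,
  # negligibly decayed by the core delay
  a0 <- matrix(rlnorm(nrow(pr) * np, meanlog = rep(log(pr$baseline), np),
                      sdlog = params$abundance_sdlog),
               nrow = nrow(pr), ncol = np,
               dimnames = list(pr$name, patients))
  core_factor <- decay_ratio(params$core_delay_h, pr$lambda, pr$gamma,
                             params$stress_tau_h)
  core_ab <- a0 * core_factor
  exc_factor <- outer(seq_len(nrow(pr)), seq_len(np),
                      function(i, j) decay_ratio(d_exc[j], pr$lambda[i],
                                                 pr$gamma[i],
                                                 params$stress_tau_h))
  exc_ab <- core_ab * exc_factor
  lanes <- sprintf("L%02d", seq_len(2 * np))
  core_lanes <- lanes[2 * seq_len(np) - 1]
  exc_lanes <- lanes[2 * seq_len(np)]
  lane_eff <- exp(rnorm(2 * np, 0, params$lane_effect_sd))
  input <- exp(rnorm(2 * np, 0, params$input_amount_sd))
  names(lane_eff) <- names(input) <- lanes
  abund <- matrix(0, nrow(pr), 2 * np, dimnames = list(pr$name, lanes))
  abund[, core_lanes] <- core_ab
  abund[, exc_lanes] <- exc_ab
  mu <- expected_counts(abund, lane_eff, input, params)
  counts <- matrix(draw_counts(mu, params$count_dispersion), nrow(mu),
                   ncol(mu), dimnames = dimnames(mu))
  samples <- tibble(
    lane_id = lanes,
    patient_id = rep(patients, each = 2),
    specimen = rep(c("core", "excision"), np),
    surgery = rep(surgery, each = 2),
    tumour_size_mm = rep(sizes, each = 2),
    dilution_tag = NA_character_
  )
  probes <- dplyr::bind_rows(
    tibble(probe_id = pr$name, target = pr$name, probe_class = "endogenous",
           is_phospho = pr$is_phospho),
    control_probes()
  )
  ihc <- generate_ihc(params, core_ab, exc_ab, patients)
  truth <- list(
    patients = tibble(patient_id = patients, tumour_size_mm = sizes,
                      surgery = surgery, core_delay_h = params$core_delay_h,
                      excision_delay_h = d_exc),
    core_abundance = core_ab,
    excision_abundance = exc_ab,
    true_mean_reduction = setNames(1 - rowMeans(exc_ab / core_ab), pr$name),
    lane_effects = lane_eff,
    input_amounts = input
  )
  structure(list(dataset = npx_dataset(counts, probes, samples), ihc = ihc,
                 truth = truth, params = params),
            class = "npx_cohort")
}

# IHC read-outs: saturating Hill transform of specimen-level abundance
generate_ihc <- function(params, core_ab, exc_ab, patients) {
  scales <- c(Ki67 = "percent_positive", HER2 = "ordinal_0_to_3")
  maxima <- c(h_score = 300, percent_positive = 100, ordinal_0_to_3 = 3)
  rows <- list()
  for (protein in params$ihc_proteins) {
    if (!protein %in% rownames(core_ab)) {
      stop("IHC protein not in panel: ", protein, call. = FALSE)
    }
    scale <- if (protein %in% names(scales)) scales[[protein]] else "h_score"
    mx <- maxima[[scale]]
    k <- params$proteins$baseline[match(protein, params$proteins$name)]
    h <- params$ihc_hill
    for (spec in c("core", "excision")) {
      ab <- if (spec == "core") core_ab[protein, ] else exc_ab[protein, ]
      val <- mx * ab^h / (ab^h + k^h) +
        rnorm(length(ab), 0, params$ihc_noise_frac * mx)
      val <- pmin(pmax(val, 0), mx)
      if (scale == "ordinal_0_to_3") val <- round(val)
      rows[[paste(protein, spec)]] <- tibble(
        patient_id = patients, specimen = spec, protein = protein,
        scale = scale, value = val)
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a dilution-series QC dataset
#'
#' Replicate lanes for `n_samples` single specimens run at several
#' dilutions. Expected counts are expressed relative to the canonical
#' reference dilution (`count_scale` is calibrated at `reference_dilution`),
#' so a lane at dilution `f` has all expected counts — endogenous and
#' controls — scaled by `reference_dilution / f` before count noise, and
#' each lane is tagged (`"5x"`, `"10x"`, ...) in the metadata. Mirroring
#' the optimization experiment this emulates, the samples alternate
#' core-cut and excision specimens (excisions carry the fixation-delay
#' artifact), unless `specimen_mix = FALSE`.
#'
#' @param params a `"sim_params"` object.
#' @param n_samples number of distinct samples (default 6).
#' @param dilutions dilution factors, at least two (default `c(5, 10, 20)`).
#' @param reference_dilution dilution at which `count_scale` is defined
#'   (default 10, the canonical analysis dilution).
#' @param specimen_mix alternate core/excision sample types (default
#'   `TRUE`).
#' @param sample_abundance_sdlog between-sample abundance spread of the QC
#'   specimens (default 0.4: assay-optimization samples span routine FFPE
#'   material, biologically more diverse than the matched study cohort).
#' @param seed optional override of `params$seed`.
#' @return list of class `"npx_cohort"` (no `ihc`): `dataset`, `truth`
#'   (sample abundances), `params`.
#' @export
generate_dilution_series <- function(params, n_samples = 6,
                                     dilutions = c(5, 10, 20),
                                     reference_dilution = 10,
                                     specimen_mix = TRUE,
                                     sample_abundance_sdlog = 0.4,
                                     seed = NULL) {
  stopifnot(inherits(params, "sim_params"), reference_dilution > 0)
  if (length(dilutions) < 2) stop("need at least 2 dilution factors",
                                  call. = FALSE)
  if (any(dilutions <= 0)) stop("dilution factors must be positive",
                                call. = FALSE)
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  withr::with_seed(seed, {
    pr <- params$proteins
    sample_ids <- sprintf("D%02d", seq_len(n_samples))
    specimen <- if (specimen_mix) {
      rep(c("core", "excision"), length.out = n_samples)
    } else {
      rep("core", n_samples)
    }
    sizes <- rtrunc_lnorm(n_samples,
                          meanlog = log(params$tumour_size_median_mm),
                          sdlog = params$tumour_size_sdlog,
                          lower = params$tumour_size_range_mm[1],
                          upper = params$tumour_size_range_mm[2])
    delays <- ifelse(specimen == "excision", excision_delay(sizes, params),
                     params$core_delay_h)
    ab <- matrix(rlnorm(nrow(pr) * n_samples,
                        meanlog = rep(log(pr$baseline), n_samples),
                        sdlog = sample_abundance_sdlog),
                 nrow = nrow(pr), dimnames = list(pr$name, sample_ids))
    decay <- outer(seq_len(nrow(pr)), seq_len(n_samples),
                   function(i, j) decay_ratio(delays[j], pr$lambda[i],
                                              pr$gamma[i],
                                              params$stress_tau_h))
    ab <- ab * decay
    n_lane <- n_samples * length(dilutions)
    lane_id <- sprintf("DL%02d", seq_len(n_lane))
    sample_of <- rep(sample_ids, each = length(dilutions))
    dil <- rep(dilutions, n_samples)
    lane_eff <- exp(rnorm(n_lane, 0, params$lane_effect_sd))
    # replicates are dilutions of one cleaved-tag lysate: the input amount
    # is a property of the sample, shared across its dilution lanes
    input_sample <- exp(rnorm(n_samples, 0, params$input_amount_sd))
    input <- rep(input_sample, each = length(dilutions))
    names(lane_eff) <- names(input) <- lane_id
    mu <- expected_counts(ab[, sample_of, drop = FALSE], lane_eff, input,
                          params)
    colnames(mu) <- lane_id
    mu <- sweep(mu, 2, reference_dilution / dil, `*`)
    counts <- matrix(draw_counts(mu, params$count_dispersion), nrow(mu),
                     ncol(mu), dimnames = dimnames(mu))
    samples <- tibble(
      lane_id = lane_id, patient_id = sample_of,
      specimen = rep(specimen, each = length(dilutions)),
      surgery = "unknown", tumour_size_mm = NA_real_,
      dilution_tag = paste0(dil, "x")
    )
    probes <- dplyr::bind_rows(
      tibble(probe_id = pr$name, target = pr$name,
             probe_class = "endogenous", is_phospho = pr$is_phospho),
      control_probes()
    )
    structure(list(dataset = npx_dataset(counts, probes, samples),
                   truth = list(abundance = ab), params = params),
              class = "npx_cohort")
  })
}

#' Write a cohort to disk in the package's interchange format
#'
#' Writes `counts.tsv`, `probes.tsv`, `samples.tsv`, and (when present)
#' `ihc.tsv` and `truth.tsv` (the per-patient latent delays) to a directory.
#'
#' @param cohort an `"npx_cohort"` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "npx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$dataset$counts, file.path(dir, "counts.tsv"))
  write_table(cohort$dataset$probes, file.path(dir, "probes.tsv"))
  write_table(cohort$dataset$samples, file.path(dir, "samples.tsv"))
  if (!is.null(cohort$ihc)) write_table(cohort$ihc, file.path(dir, "ihc.tsv"))
  if (!is.null(cohort$truth$patients)) {
    write_table(cohort$truth$patients, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}
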