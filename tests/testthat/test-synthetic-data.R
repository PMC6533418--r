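read_ihc_roundtrip <- function(ihc) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(ihc, path)
  read_ihc(path)
}

test_that("cohorts are deterministic for a fixed seed and well-formed", {
  p <- sim_params(seed = 13)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(unclass(a$dataset$counts), unclass(b$dataset$counts))
  expect_identical(a$ihc, b$ihc)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(p, seed = 14)
  expect_false(identical(unclass(a$dataset$counts),
                         unclass(c2$dataset$counts)))

  # dimensions: 26 endogenous + 6 + 6 + 2 + 1 controls, 2 lanes per patient
  expect_equal(dim(a$dataset$counts), c(41, 32))
  expect_true(all(unclass(a$dataset$counts) >= 0))
  pos <- a$dataset$probes$probe_id[a$dataset$probes$probe_class == "positive"]
  expect_true(all(unclass(a$dataset$counts)[pos, ] > 0))
  # IHC defaults: 5 proteins, both specimens per patient, within bounds
  expect_equal(nrow(a$ihc), 5 * 2 * 16)
  expect_equal(nrow(read_ihc_roundtrip(a$ihc)), 160)
})

test_that("null construction gives identical specimens after normalization", {
  panel <- default_protein_panel()
  panel$target_reduction <- 0
  panel$target_increase <- 0
  p <- sim_params(proteins = panel, lane_effect_sd = 0, input_amount_sd = 0,
                  count_dispersion = 0, seed = 3)
  co <- generate_cohort(p)
  expect_equal(co$truth$core_abundance, co$truth$excision_abundance)
  norm <- run_normalization(co$dataset)
  diffs <- difference_matrix(norm$expr, co$dataset$samples)
  expect_equal(diffs$difference, rep(0, nrow(diffs)), tolerance = 1e-9)
})

test_that("noise-free normalization recovers latent abundances exactly", {
  p <- sim_params(lane_effect_sd = 0, input_amount_sd = 0,
                  count_dispersion = 0, seed = 5)
  co <- generate_cohort(p)
  norm <- run_normalization(co$dataset)
  # latent abundance per lane, in lane order
  sm <- co$dataset$samples
  lane_ab <- sapply(seq_len(nrow(sm)), function(i) {
    ab <- if (sm$specimen[i] == "core") co$truth$core_abundance else
      co$truth$excision_abundance
    ab[, sm$patient_id[i]]
  })
  colnames(lane_ab) <- sm$lane_id
  for (pr in rownames(norm$expr)) {
    delta <- unclass(norm$expr)[pr, ] - log2(lane_ab[pr, ])
    expect_equal(max(delta) - min(delta), 0, tolerance = 1e-6)
  }
})

test_that("latent truth obeys the decay/stress construction", {
  p <- sim_params(seed = 7)
  co <- generate_cohort(p)
  pr <- p$proteins
  d <- co$truth$patients$excision_delay_h
  for (i in seq_len(nrow(pr))) {
    expected <- co$truth$core_abundance[pr$name[i], ] *
      exp(-pr$lambda[i] * d) *
      (1 + pr$gamma[i] * (1 - exp(-d / p$stress_tau_h)))
    expect_equal(unname(co$truth$excision_abundance[pr$name[i], ]),
                 unname(expected), tolerance = 1e-12)
  }
  # lambda = gamma = 0 reduces to equal specimens
  null_rows <- pr$lambda == 0 & pr$gamma == 0
  expect_equal(co$truth$true_mean_reduction[pr$name[null_rows]],
               setNames(rep(0, sum(null_rows)), pr$name[null_rows]))
})

test_that("effect calibration inverts the delay-distribution expectation", {
  p <- sim_params()
  for (r in c(0.25, 0.5, 0.75)) {
    lam <- lability_for_mean_reduction(r, p)
    expect_equal(expected_mean_reduction(lam, p), r, tolerance = 1e-8)
  }
  expect_equal(lability_for_mean_reduction(0, p), 0)
  g <- stress_gain_for_mean_increase(0.87, p)
  expect_equal(expected_mean_reduction(0, p, gamma = g), -0.87,
               tolerance = 1e-8)
  # default panel lambdas realise their paper-anchored targets in expectation
  pr <- p$proteins
  realized <- mapply(function(l, g) expected_mean_reduction(l, p, g),
                     pr$lambda, pr$gamma)
  target <- pr$target_reduction - pr$target_increase
  expect_equal(unname(realized), unname(target), tolerance = 1e-6)
})

test_that("monte-carlo mean reduction tracks the calibrated expectation", {
  # a pAKT-like protein set to exp(-lambda * delay) averaging 0.4 should
  # realise a ~60% mean linear reduction across cohorts
  p0 <- sim_params()
  lam <- lability_for_mean_reduction(0.6, p0)
  panel <- default_protein_panel()
  panel$lambda <- lam
  panel$gamma <- 0
  panel$lambda[panel$name == "pEGFR"] <- 0
  p <- sim_params(proteins = panel)
  red <- sapply(1:200, function(s) {
    co <- generate_cohort(p, seed = 40000 + s)
    mean(co$truth$true_mean_reduction[setdiff(names(
      co$truth$true_mean_reduction), "pEGFR")])
  })
  expect_lt(abs(mean(red) - 0.6), 0.10)
})

test_that("dilution series scales counts by the dilution factor", {
  p <- sim_params(lane_effect_sd = 0, input_amount_sd = 0,
                  count_dispersion = 0, seed = 11)
  dd <- generate_dilution_series(p, n_samples = 2, dilutions = c(1, 2),
                                 reference_dilution = 1)
  m <- unclass(dd$dataset$counts)
  sm <- dd$dataset$samples
  for (sid in unique(sm$patient_id)) {
    l1 <- sm$lane_id[sm$patient_id == sid & sm$dilution_tag == "1x"]
    l2 <- sm$lane_id[sm$patient_id == sid & sm$dilution_tag == "2x"]
    expect_equal(m[, l2], m[, l1] / 2, tolerance = 1e-12)
  }
  expect_error(generate_dilution_series(p, dilutions = 10), "2 dilution")
  expect_error(generate_dilution_series(p, dilutions = c(-1, 2)), "positive")
})

test_that("delay models couple delay to size as configured", {
  p_size <- sim_params(delay_model = "size_proportional")
  co <- generate_cohort(p_size, seed = 17)
  tr <- co$truth$patients
  expect_equal(tr$excision_delay_h,
               tr$tumour_size_mm / 2 + p_size$excision_handling_offset_h)
  p_const <- sim_params(delay_model = "constant", constant_delay_h = 4)
  co2 <- generate_cohort(p_const, seed = 17)
  expect_equal(unique(co2$truth$patients$excision_delay_h), 4)
  p_surg <- sim_params(delay_model = "surgery")
  co3 <- generate_cohort(p_surg, seed = 17)
  tr3 <- co3$truth$patients
  mast <- tr3$surgery == "mastectomy"
  expect_true(all(tr3$excision_delay_h[mast] <=
                    5 + p_surg$excision_handling_offset_h + 1e-9))
  expect_true(all(tr3$excision_delay_h[!mast] >=
                    p_surg$overnight_offset_h))
})

test_that("invalid parameters fail before any sampling", {
  expect_error(sim_params(penetration_rate_mm_per_h = 0))
  expect_error(sim_params(count_dispersion = -1))
  expect_error(sim_params(positive_ladder = c(0, 1)))
  panel <- default_protein_panel()
  panel$target_reduction[1] <- 1.2
  expect_error(sim_params(proteins = panel))
})
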