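# small paired cohort built directly at the log2 stage
paired_expr <- function(core, excision, proteins = NULL) {
  n <- ncol(core)
  if (is.null(proteins)) proteins <- rownames(core)
  lanes <- c(paste0("c", seq_len(n)), paste0("x", seq_len(n)))
  m <- cbind(core, excision)
  dimnames(m) <- list(proteins, lanes)
  samples <- tibble::tibble(
    lane_id = lanes,
    patient_id = rep(sprintf("P%02d", seq_len(n)), 2),
    specimen = rep(c("core", "excision"), each = n),
    surgery = rep(rep(c("lumpectomy", "mastectomy"), length.out = n), 2),
    tumour_size_mm = rep(seq(20, by = 5, length.out = n), 2),
    dilution_tag = NA_character_)
  list(expr = count_matrix(m, "log2"), samples = samples)
}

test_that("difference matrix is excision minus core and antisymmetric", {
  core <- matrix(c(3, 1), 1, 2)
  exc <- matrix(c(1, 1), 1, 2)
  rownames(core) <- rownames(exc) <- "A"
  d <- paired_expr(core, exc)
  diffs <- difference_matrix(d$expr, d$samples)
  expect_equal(diffs$difference, c(-2, 0))

  # swapping specimen labels negates every value
  swapped <- d$samples
  swapped$specimen <- ifelse(swapped$specimen == "core", "excision", "core")
  diffs_sw <- difference_matrix(d$expr, swapped)
  expect_equal(diffs_sw$difference, -diffs$difference)

  # a patient missing its excision is excluded and recorded
  incomplete <- d$samples[-4, ]
  m <- unclass(d$expr)[, -4, drop = FALSE]
  diffs2 <- difference_matrix(count_matrix(m, "log2"), incomplete)
  expect_equal(unique(diffs2$patient_id), "P01")
  expect_equal(attr(diffs2, "dropped_patients"), "P02")
})

test_that("paired tests report linear-scale percent change and counts", {
  # six pairs, every excision at exactly half the core level
  core <- rbind(A = c(3, 5, 4, 6, 2, 7), B = c(1, 2, 3, 4, 5, 6))
  exc <- core + log2(0.5)
  d <- paired_expr(core, exc)
  res <- paired_protein_tests(d$expr, d$samples)
  expect_equal(res$mean_percent_change, c(-50, -50))
  # strict inequality: ratio exactly 0.5 is not "> 50% reduction"
  expect_equal(res$n_over_50pct_reduction, c(0L, 0L))

  # ratios all 0.4: mean -60%, 6/6 past the threshold, p = 2/2^6
  exc2 <- core + log2(0.4)
  d2 <- paired_expr(core, exc2)
  res2 <- paired_protein_tests(d2$expr, d2$samples)
  expect_equal(res2$mean_percent_change, c(-60, -60))
  expect_equal(res2$n_over_50pct_reduction, c(6L, 6L))
  expect_equal(res2$p_value, rep(2 / 64, 2))

  # identity: zero change, all counts zero
  d3 <- paired_expr(core, core)
  res3 <- paired_protein_tests(d3$expr, d3$samples)
  expect_equal(res3$mean_percent_change, c(0, 0))
  expect_equal(res3$n_over_50pct_reduction + res3$n_over_75pct_reduction +
                 res3$n_over_100pct_increase, c(0L, 0L))
  expect_equal(res3$method, rep("degenerate", 2))

  # reporting alternative: percent change of the mean levels
  res4 <- paired_protein_tests(d2$expr, d2$samples,
                               percent_change = "ratio_of_means")
  expect_equal(res4$mean_percent_change, c(-60, -60))
})

test_that("size association and surgery comparison follow the metadata", {
  # differences strictly decreasing in size -> rho = -1
  core <- rbind(A = rep(5, 8))
  exc <- rbind(A = 5 - seq(0.1, 0.8, by = 0.1))
  d <- paired_expr(core, exc)
  diffs <- difference_matrix(d$expr, d$samples)
  sa <- size_association(diffs, d$samples)
  expect_equal(sa$rho, -1)

  # fewer than 3 sized patients is flagged, not an error
  sm <- d$samples
  sm$tumour_size_mm[sm$patient_id %in% sprintf("P%02d", 3:8)] <- NA
  sa2 <- size_association(diffs, sm)
  expect_equal(sa2$method, "insufficient_n")

  # all mastectomy differences below all lumpectomy differences
  sm2 <- d$samples
  mast <- sm2$surgery[match(diffs$patient_id, sm2$patient_id)] == "mastectomy"
  expect_equal(
    surgery_comparison(diffs, sm2)$p_value,
    mann_whitney_u(diffs$difference[mast], diffs$difference[!mast])$p_value)

  # identical groups give p = 1
  exc_same <- rbind(A = rep(4, 8))
  dd <- paired_expr(core, exc_same)
  expect_equal(surgery_comparison(difference_matrix(dd$expr, dd$samples),
                                  dd$samples)$p_value, 1)

  # unknown-surgery patients are excluded listwise
  sm3 <- d$samples
  sm3$surgery[sm3$patient_id == "P01"] <- "unknown"
  res <- surgery_comparison(diffs, sm3)
  expect_equal(res$n_mastectomy + res$n_lumpectomy, 7L)
})

test_that("phospho/non-phospho mean differences correlate as constructed", {
  probes <- tibble::tibble(
    probe_id = c("ph1", "ph2", "np1", "np2"), target = probe_id,
    probe_class = "endogenous", is_phospho = c(TRUE, TRUE, FALSE, FALSE))
  core <- matrix(5, 4, 6, dimnames = list(probes$probe_id, NULL))
  delta <- seq(-0.5, 0.5, length.out = 6)
  exc <- core + rbind(delta, delta, delta, delta)
  d <- paired_expr(core, exc, probes$probe_id)
  diffs <- difference_matrix(d$expr, d$samples)
  res <- phospho_nonphospho_correlation(diffs, probes)
  expect_equal(res$mean_correlation$rho, 1)
  expect_equal(res$per_nonphospho$rho, c(1, 1))

  # single patient cannot support a correlation
  one <- diffs[diffs$patient_id == "P01", ]
  expect_error(phospho_nonphospho_correlation(one, probes), "n >= 3")

  # fewer than 2 proteins per group is an error
  expect_error(phospho_nonphospho_correlation(diffs, probes[c(1, 3, 4), ]),
               ">= 2 phospho")
})

test_that("concordance strata behave under constructed IHC read-outs", {
  core <- rbind(pAKT = seq(1, 4, length.out = 8),
                Ki67 = seq(2, 5, length.out = 8))
  exc <- core - 1
  d <- paired_expr(core, exc)
  # IHC as a strictly increasing transform of expression -> rho = 1 pooled
  values <- unclass(d$expr)
  mk_ihc <- function(target, scale, mx) {
    tibble::tibble(
      patient_id = rep(sprintf("P%02d", 1:8), 2),
      specimen = rep(c("core", "excision"), each = 8),
      protein = target, scale = scale,
      value = mx * (1 / (1 + exp(-as.vector(values[target, ])))))
  }
  ihc <- dplyr::bind_rows(mk_ihc("pAKT", "h_score", 300),
                          mk_ihc("Ki67", "percent_positive", 100))
  res <- ihc_concordance(d$expr, ihc, d$samples,
                         mapping = tibble::tibble(
                           protein = c("pAKT", "Ki67"),
                           target = c("pAKT", "Ki67")))
  expect_equal(res$rho[res$stratum == "pooled"], c(1, 1))
  expect_equal(res$n[res$stratum == "pooled"], c(16L, 16L))
  expect_equal(res$n[res$stratum == "core"], c(8L, 8L))

  # unmapped IHC proteins are skipped and reported
  ihc2 <- dplyr::bind_rows(ihc, tibble::tibble(
    patient_id = "P01", specimen = "core", protein = "HER2",
    scale = "ordinal_0_to_3", value = 2))
  res2 <- ihc_concordance(d$expr, ihc2, d$samples,
                          mapping = tibble::tibble(protein = "pAKT",
                                                   target = "pAKT"))
  expect_true("HER2" %in% attr(res2, "skipped"))
})

test_that("canonical lane resolution prefers the tagged dilution", {
  sm <- tibble::tibble(
    lane_id = c("a", "b", "c"), patient_id = "P01", specimen = "core",
    surgery = "unknown", tumour_size_mm = NA_real_,
    dilution_tag = c("5x", "10x", "20x"))
  expect_equal(canonical_lanes(sm)$lane_id, "b")
  sm$dilution_tag <- c("10x", "10x", "20x")
  expect_error(canonical_lanes(sm), "multiple canonical")
})
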