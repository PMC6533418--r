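test_that("geometric_mean satisfies definition and scale equivariance", {
  expect_equal(geometric_mean(c(7, 7, 7)), 7)
  expect_equal(geometric_mean(c(1, 4)), 2)
  expect_equal(geometric_mean(c(2, 4, 8, 16, 32, 64)), 2^3.5)
  expect_equal(geometric_mean(3 * c(2, 9, 5)), 3 * geometric_mean(c(2, 9, 5)))
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(1, 0, 2)), "positive")
})

make_matrix <- function(m, stage = "raw") count_matrix(m, stage)

test_that("positive-control normalization equalizes lane geomeans", {
  # two lanes with positive geomeans 10 and 40 -> G = 20, factors (2, 0.5)
  m <- rbind(E = c(100, 100), P1 = c(5, 20), P2 = c(20, 80))
  colnames(m) <- c("l1", "l2")
  probes <- tibble::tibble(
    probe_id = c("E", "P1", "P2"), target = probe_id,
    probe_class = c("endogenous", "positive", "positive"), is_phospho = NA)
  res <- positive_control_normalize(make_matrix(m), probes)
  expect_equal(unname(res$lane_scaling_factors), c(2, 0.5))
  expect_equal(unclass(res$counts)["E", ], c(l1 = 200, l2 = 50))
  expect_equal(geometric_mean(res$lane_scaling_factors), 1)

  # identical lanes -> factors 1, counts unchanged
  m2 <- m
  m2[, 2] <- m2[, 1]
  res2 <- positive_control_normalize(make_matrix(m2), probes)
  expect_equal(unname(res2$lane_scaling_factors), c(1, 1))
  expect_equal(vals(res2$counts), m2)

  # single lane -> factor 1
  res3 <- positive_control_normalize(make_matrix(m[, 1, drop = FALSE]),
                                     probes)
  expect_equal(unname(res3$lane_scaling_factors), 1)

  # zero positive count names the lane
  m4 <- m
  m4["P1", "l2"] <- 0
  expect_error(positive_control_normalize(make_matrix(m4), probes), "l2")
})

test_that("background correction subtracts negatives then IgG, flooring at 0", {
  m <- rbind(E1 = c(100, 8), E2 = c(100, 100),
             N1 = c(10, 10), N2 = c(10, 10),
             I1 = c(15, 15), I2 = c(15, 15))
  colnames(m) <- c("l1", "l2")
  probes <- tibble::tibble(
    probe_id = rownames(m), target = rownames(m),
    probe_class = c("endogenous", "endogenous", "negative", "negative",
                    "igg", "igg"),
    is_phospho = NA)
  pm <- make_matrix(m, "positive_normalized")
  res <- background_correct(pm, probes, subtract_igg = TRUE)
  # b_neg = 10; IgG corrected to 5 -> b_igg = 5; 100 - 10 - 5 = 85
  expect_equal(unclass(res$counts)["E2", ], c(l1 = 85, l2 = 85))
  # 8 - 10 floors at 0 before IgG subtraction
  expect_equal(unclass(res$counts)["E1", "l2"], 0)
  expect_equal(unname(res$negative_background), c(10, 10))
  expect_equal(unname(res$igg_background), c(5, 5))
  # control rows pass through unmodified
  expect_equal(unclass(res$counts)["I1", ], m["I1", ])

  # toggle off: only the negative background is removed
  res_no <- background_correct(pm, probes, subtract_igg = FALSE)
  expect_equal(unclass(res_no$counts)["E2", ], c(l1 = 90, l2 = 90))
  expect_equal(unname(res_no$igg_background), c(0, 0))
})

test_that("housekeeping selection minimizes the CV of log2 counts", {
  m <- rbind(HA = c(32, 32, 128, 128), HB = c(64, 64, 64, 256),
             N1 = c(1, 1, 1, 1), P1 = c(1, 1, 1, 1))
  colnames(m) <- paste0("l", 1:4)
  probes <- tibble::tibble(
    probe_id = rownames(m), target = rownames(m),
    probe_class = c("housekeeping", "housekeeping", "negative", "positive"),
    is_phospho = NA)
  res <- select_housekeeping(make_matrix(m, "background_corrected"), probes)
  # log2 counts (5,5,7,7) vs (6,6,6,8): direct CV comparison
  cv <- function(x) sd(x) / mean(x)
  expected <- if (cv(c(5, 5, 7, 7)) < cv(c(6, 6, 6, 8))) "HA" else "HB"
  expect_equal(res$probe_id, expected)
  expect_equal(nrow(res$cv_table), 2)

  # constant candidate wins with CV 0
  m["HA", ] <- 64
  res <- select_housekeeping(make_matrix(m, "background_corrected"), probes)
  expect_equal(res$probe_id, "HA")
  expect_equal(res$cv_table$cv[res$cv_table$probe_id == "HA"], 0)

  # single candidate selected unconditionally
  probes1 <- probes
  probes1$probe_class[2] <- "endogenous"
  res <- select_housekeeping(make_matrix(m, "background_corrected"), probes1)
  expect_equal(res$probe_id, "HA")
  expect_equal(nrow(res$cv_table), 1)
})

test_that("housekeeping normalization makes the reference constant", {
  m <- rbind(E = c(10, 10), H = c(2, 8))
  colnames(m) <- c("l1", "l2")
  hm <- housekeeping_normalize(make_matrix(m, "background_corrected"), "H")
  # hk geomean 4 -> lane ratios (0.5, 2) -> endogenous (20, 5)
  expect_equal(unclass(hm)["E", ], c(l1 = 20, l2 = 5))
  expect_equal(unname(unclass(hm)["H", ]), c(4, 4))

  # constant housekeeping leaves the matrix unchanged
  m2 <- rbind(E = c(10, 20), H = c(5, 5))
  colnames(m2) <- c("l1", "l2")
  hm2 <- housekeeping_normalize(make_matrix(m2, "background_corrected"), "H")
  expect_equal(vals(hm2), m2)

  # single lane unchanged
  hm3 <- housekeeping_normalize(
    make_matrix(m[, 1, drop = FALSE], "background_corrected"), "H")
  expect_equal(vals(hm3), m[, 1, drop = FALSE])

  m4 <- m
  m4["H", 2] <- 0
  expect_error(housekeeping_normalize(
    make_matrix(m4, "background_corrected"), "H"), "zero counts")
})

test_that("half-minimum imputation and log2 follow the per-protein rule", {
  m <- rbind(A = c(0, 4, 8), B = c(0, 0, 6), C = c(1, 1, 1))
  colnames(m) <- paste0("l", 1:3)
  res <- impute_and_log(make_matrix(m, "housekeeping_normalized"))
  expect_equal(unname(unclass(res$expr)["A", ]), c(1, 2, 3))
  expect_equal(unname(unclass(res$expr)["B", ]), log2(c(3, 3, 6)))
  expect_equal(unname(unclass(res$expr)["C", ]), c(0, 0, 0))
  expect_equal(nrow(res$imputation_log), 3)
  expect_true(all(is.finite(unclass(res$expr))))

  m["B", ] <- 0
  expect_error(impute_and_log(make_matrix(m, "housekeeping_normalized")), "B")
})

test_that("undetected probes require being below IgG in every lane", {
  m <- rbind(E1 = c(5, 5), E2 = c(5, 50), I1 = c(16, 16), I2 = c(25, 25))
  colnames(m) <- c("l1", "l2")
  probes <- tibble::tibble(
    probe_id = rownames(m), target = rownames(m),
    probe_class = c("endogenous", "endogenous", "igg", "igg"),
    is_phospho = NA)
  # IgG geomean = 20 per lane
  expect_equal(detect_above_background(make_matrix(m), probes), "E1")
  probes_no_igg <- probes[1:2, ]
  expect_error(detect_above_background(make_matrix(m[1:2, ]), probes_no_igg),
               "IgG")
})

test_that("full chain matches the hand-worked fixture to 1e-9", {
  ds <- npx_dataset(fixture_counts(), fixture_probes(), fixture_samples())
  norm <- run_normalization(ds)
  oracle <- fixture_oracle()
  expect_equal(norm$report$undetected_probes, oracle$undetected)
  expect_equal(sort(rownames(norm$expr)), sort(rownames(oracle$expr)))
  expect_equal(unclass(norm$expr)[rownames(oracle$expr), ], oracle$expr,
               tolerance = 1e-9)
  expect_equal(unname(norm$report$lane_scaling_factors), c(1, 0.5, 2))
  expect_equal(unname(norm$report$negative_background), rep(6, 3))
  expect_equal(unname(norm$report$igg_background), rep(12, 3))
  expect_equal(norm$report$zero_imputation_log$probe_id, "E2")
})

test_that("stage order is enforced and errors are stage-annotated", {
  ds <- npx_dataset(fixture_counts(), fixture_probes(), fixture_samples())
  expect_error(background_correct(ds$counts, ds$probes), "stage")
  bad <- fixture_counts()
  bad["P1", 2] <- 0
  ds_bad <- npx_dataset(bad, fixture_probes(), fixture_samples())
  expect_error(run_normalization(ds_bad), "positive_control_normalize")
})

test_that("identity-control datasets pass through to plain log2", {
  # constant controls, constant housekeeping: chain is identity up to log2
  m <- rbind(E1 = c(12, 24, 48), E2 = c(5, 10, 20),
             P1 = c(50, 50, 50), N1 = c(0, 0, 0),
             I1 = c(0, 0, 0), H1 = c(30, 30, 30))
  colnames(m) <- paste0("l", 1:3)
  probes <- tibble::tibble(
    probe_id = rownames(m), target = rownames(m),
    probe_class = c("endogenous", "endogenous", "positive", "negative",
                    "igg", "housekeeping"),
    is_phospho = c(TRUE, FALSE, NA, NA, NA, NA))
  samples <- tibble::tibble(
    lane_id = paste0("l", 1:3), patient_id = paste0("p", 1:3),
    specimen = "core", surgery = "unknown", tumour_size_mm = NA_real_,
    dilution_tag = NA_character_)
  norm <- run_normalization(npx_dataset(m, probes, samples))
  # zero-count negative/IgG probes contribute a 0.5 background offset
  expect_equal(unclass(norm$expr)["E1", ], log2(m["E1", ] - 1),
               tolerance = 1e-12)
})

test_that("lane-wise count scaling is absorbed up to a global constant", {
  # scaling one lane by c > 0 shifts the cohort reference by c^(1/n_lanes);
  # the log2 matrix moves by that single global constant, so every
  # difference, correlation and comparison downstream is unchanged
  ds <- npx_dataset(fixture_counts(), fixture_probes(), fixture_samples())
  norm <- run_normalization(ds)
  m2 <- fixture_counts()
  m2[, 2] <- m2[, 2] * 3.7
  norm2 <- run_normalization(npx_dataset(m2, fixture_probes(),
                                         fixture_samples()))
  shift <- vals(norm2$expr) - vals(norm$expr)
  expect_equal(unname(shift), matrix(log2(3.7) / 3, nrow(shift), ncol(shift)),
               tolerance = 1e-9)
  d1 <- difference_matrix(norm$expr, fixture_samples())
  d2 <- difference_matrix(norm2$expr, fixture_samples())
  expect_equal(d2$difference, d1$difference, tolerance = 1e-9)
})

test_that("lane permutation permutes outputs identically", {
  ds <- npx_dataset(fixture_counts(), fixture_probes(), fixture_samples())
  norm <- run_normalization(ds)
  perm <- c(3, 1, 2)
  m <- fixture_counts()[, perm]
  sm <- fixture_samples()[perm, ]
  norm_p <- run_normalization(npx_dataset(m, fixture_probes(), sm))
  expect_equal(vals(norm_p$expr)[, colnames(norm$expr)],
               vals(norm$expr), tolerance = 1e-12)
})

test_that("IgG toggle changes results only via the IgG stage", {
  ds <- npx_dataset(fixture_counts(), fixture_probes(), fixture_samples())
  with_igg <- run_normalization(ds, subtract_igg = TRUE)
  without <- run_normalization(ds, subtract_igg = FALSE)
  expect_equal(unname(without$report$igg_background), rep(0, 3))
  expect_equal(without$report$lane_scaling_factors,
               with_igg$report$lane_scaling_factors)
  expect_equal(without$report$negative_background,
               with_igg$report$negative_background)
  expect_false(isTRUE(all.equal(unclass(without$expr)[rownames(with_igg$expr), ],
                                unclass(with_igg$expr))))
})
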