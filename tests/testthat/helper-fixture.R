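# A 12-probe x 3-lane fixture with hand-workable numbers, plus its
# spreadsheet-style oracle: every normalization stage recomputed with plain
# arithmetic, independent of the package implementation.

fixture_counts <- function() {
  m <- rbind(
    E1 = c(118, 116, 19),
    E2 = c(20, 34, 59),
    E3 = c(26, 52, 13),
    E4 = c(5, 8, 1.5),
    P1 = c(10, 20, 5),
    P2 = c(40, 80, 20),
    P3 = c(160, 320, 80),
    N1 = c(4, 8, 2),
    N2 = c(9, 18, 4.5),
    I1 = c(14, 28, 7),
    I2 = c(24, 48, 12),
    H1 = c(38, 116, 14)
  )
  colnames(m) <- c("L1", "L2", "L3")
  m
}

fixture_probes <- function() {
  tibble::tibble(
    probe_id = c("E1", "E2", "E3", "E4", "P1", "P2", "P3", "N1", "N2",
                 "I1", "I2", "H1"),
    target = probe_id,
    probe_class = c(rep("endogenous", 4), rep("positive", 3),
                    rep("negative", 2), rep("igg", 2), "housekeeping"),
    is_phospho = c(TRUE, TRUE, FALSE, FALSE, rep(NA, 8))
  )
}

fixture_samples <- function() {
  tibble::tibble(
    lane_id = c("L1", "L2", "L3"),
    patient_id = c("Q1", "Q1", "Q2"),
    specimen = c("core", "excision", "core"),
    surgery = c("lumpectomy", "lumpectomy", "mastectomy"),
    tumour_size_mm = c(20, 20, 40),
    dilution_tag = NA_character_
  )
}

# manual computation of all five stages, spelled out stage by stage
fixture_oracle <- function() {
  raw <- fixture_counts()
  gm <- function(x) exp(mean(log(x)))

  # stage 1: positive-control scaling
  g <- c(gm(raw[c("P1", "P2", "P3"), 1]), gm(raw[c("P1", "P2", "P3"), 2]),
         gm(raw[c("P1", "P2", "P3"), 3]))
  G <- gm(g)
  f <- G / g
  pn <- sweep(raw, 2, f, `*`)

  # stage 2a: negative background
  b_neg <- c(gm(pn[c("N1", "N2"), 1]), gm(pn[c("N1", "N2"), 2]),
             gm(pn[c("N1", "N2"), 3]))
  endo_hk <- c("E1", "E2", "E3", "E4", "H1")
  bc <- pn
  bc[endo_hk, ] <- pmax(sweep(pn[endo_hk, ], 2, b_neg, `-`), 0)

  # stage 2b: IgG background (on negative-subtracted IgG counts)
  igg_corr <- pmax(sweep(pn[c("I1", "I2"), ], 2, b_neg, `-`), 0)
  b_igg <- c(gm(igg_corr[, 1]), gm(igg_corr[, 2]), gm(igg_corr[, 3]))
  bc[endo_hk, ] <- pmax(sweep(bc[endo_hk, ], 2, b_igg, `-`), 0)

  # stage 3: housekeeping normalization
  hk <- bc["H1", ]
  ratio <- hk / gm(hk)
  hn <- sweep(bc, 2, ratio, `/`)

  # stage 4: undetected = below the IgG geometric mean in every lane
  igg_gm <- c(gm(pn[c("I1", "I2"), 1]), gm(pn[c("I1", "I2"), 2]),
              gm(pn[c("I1", "I2"), 3]))
  endo <- c("E1", "E2", "E3", "E4")
  undetected <- endo[rowSums(sweep(pn[endo, ], 2, igg_gm, `<`)) == 3]

  # stage 5: half-minimum imputation, log2
  kept <- setdiff(endo, undetected)
  out <- hn[kept, , drop = FALSE]
  for (p in rownames(out)) {
    z <- out[p, ] == 0
    if (any(z)) out[p, z] <- min(out[p, out[p, ] > 0]) / 2
  }
  list(expr = log2(out), factors = f, b_neg = b_neg, b_igg = b_igg,
       undetected = undetected)
}
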