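---
title: "Methods: paired-specimen protein panel analysis under delayed fixation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-specimen protein panel analysis under delayed fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphodrift)
```

# Scope

`phosphodrift` analyses multiplex barcode-antibody protein counts from paired
FFPE specimens: a core-cut biopsy fixed essentially at collection and a
surgical excision whose interior fixes only as formalin penetrates (about
1 mm/h at room temperature). The package covers the normalization chain from
raw probe counts to log2 expression, paired nonparametric differential
statistics, concordance with IHC scores, two-way correlation clustering and
dilution-replicate QC, and a generative model of the fixation artifact used
for calibration, power assessment and parameter-recovery testing. Wet-lab
steps, vendor file formats, and IHC scoring itself are out of scope; IHC
scores enter as data.

# Normalization model

Raw counts are modelled as (signal + non-specific background) distorted by
two per-lane nuisance factors: hybridization efficiency, which scales every
count in a lane, and sample input amount, which scales the tissue-derived
counts only. The chain removes these in order:

1. **Positive-control scaling.** Lane `l` is multiplied by `f_l = G / g_l`,
   where `g_l` is the geometric mean of the six ERCC positive spike probes in
   that lane and `G` the geometric mean of the `g_l`. Because the spikes are
   added at fixed amounts, `g_l` is a pure measure of lane efficiency. Any
   fixed reference would differ from `G` only by a cohort-level constant that
   cancels from every downstream difference and correlation; using `G` makes
   the factors multiply to 1, which the report asserts to 1e-9. A zero
   spike count is treated as an assay failure and is an error naming the
   lane.
2. **Background correction.** Per lane, the geometric mean of the six ERCC
   negative probes is subtracted from every endogenous and housekeeping
   count, flooring at zero; then (unless disabled) the geometric mean of the
   two IgG non-specific controls — themselves negative-subtracted first — is
   subtracted likewise. Negative abundance is meaningless, hence the floor;
   whether to allow negative intermediate values was an open choice and
   flooring after each subtraction is the documented decision. Zeros among
   negative/IgG control counts are replaced by 0.5 before the log so the
   background stays estimable in clean lanes. Control probe rows pass
   through unchanged for reporting.
3. **Housekeeping normalization.** Counts are divided by
   `hk(l) / geomean(hk)`, making the housekeeping probe (Histone H3 in the
   default panel) constant across lanes and cancelling input-amount
   differences. When several housekeeping candidates exist, the one with the
   lowest coefficient of variation of log2 counts across lanes is selected
   and the full CV table reported; the variation metric is not prescribed
   anywhere authoritative, so CV of log2 counts is the package's documented
   operationalization, computed on background-corrected counts.
4. **Detection filtering.** An endogenous probe whose count sits below the
   lane's IgG geometric mean in *every* lane has no evidence of target and
   is excluded. This comparison is made on positive-normalized counts,
   before background correction, because background correction subtracts the
   IgG level from the endogenous probes and would make the comparison
   circular.
5. **Imputation and transform.** Remaining zeros are replaced per protein by
   half that protein's smallest positive value across all lanes (jointly,
   not per specimen type), then values are log2 transformed. Every
   imputation is logged; a probe with no positive value anywhere is an
   error, since it should have been caught by detection filtering.

For direct comparison with IHC the chain is re-run with
`subtract_igg = FALSE`; the pipeline always produces both branches when the
concordance analysis is enabled so the two analyses cannot silently share
the wrong matrix.

# Statistics

All tests are two-sided and exact in the regimes this design needs:

* **Wilcoxon signed-rank** for paired core/excision comparisons. Zero
  differences are dropped (Wilcoxon's original treatment — consequential at
  n = 16, hence documented), absolute differences are mid-ranked, and for up
  to 25 effective pairs the p-value is computed from the full distribution
  over all `2^n` sign patterns via convolution over doubled ranks, which
  stays exact under ties. Beyond that, a normal approximation with tie
  correction is used.
* **Mann–Whitney U** for surgery-type comparisons: exact by enumeration of
  all group labelings up to a combined n of 12, then normal approximation
  with tie correction.
* **Spearman correlation** for size associations and IHC concordance: rho is
  the Pearson correlation of mid-ranks; p is exact by full permutation
  enumeration up to n = 9 and a t approximation with n − 2 degrees of
  freedom beyond. Ordinal IHC scales (HER2 0–3+) enter as mid-ranks; no
  dichotomization is attempted. A constant margin yields a flagged
  `undefined` result rather than an error so per-protein batch analyses can
  proceed.

The exact/approximate thresholds (25, 12, 9) were chosen so the 16-pair
design always uses the exact Wilcoxon distribution. Two-sided p-values are
twice the smaller tail, capped at 1. No multiple-testing correction is
applied by default — the analyses are exploratory by design — but
`paired_protein_tests(adjust_p = TRUE)` adds Benjamini–Hochberg adjusted
values for reporting.

Percent changes are summarised on the linear scale per pair
(`100 * (excision/core − 1)`, then averaged); the alternative ratio-of-means
convention is available as a reporting option but is not the default, since
the per-pair convention matches the per-pair threshold counts (>50%
reduction means ratio < 0.5, strictly; >75% means < 0.25; >100% increase
means > 2).

# Clustering and QC

Two-way unsupervised clustering uses Spearman-correlation distance
`d = 1 − rho` and average linkage on both axes, after centring each protein
at its mean log2 value (the heatmap scaling). Average linkage is the common
default for correlation-distance expression heatmaps; it is configurable, as
is clustering the uncentred matrix. The two-group cut is structural (remove
the final merge) rather than a height threshold. Items are ordered
lexicographically before clustering so ties break deterministically across
platforms. Trees export to Newick with merge heights as branch lengths.

Dilution-replicate QC clusters all replicate lanes and passes a sample only
if its replicates form a complete subtree — every replicate merges with the
others before any other sample's lane joins. Spearman distance is invariant
to the per-lane scaling a dilution induces, so the QC isolates count noise
and real profile differences.

# The synthetic-cohort generator

The generator encodes the study conditions the analysis assumes, so that
passing tests say something definite:

* **Cohort structure.** 16 patients, each with one core and one excision
  lane; tumour sizes log-normal with median 33.5 mm and log-sd 0.6
  (IQR close to 20–45 mm), truncated to 15–100 mm, the plausible clinical
  range for excised primaries; mastectomy above 30 mm, giving roughly half
  the cohort, with larger tumours in the mastectomy group by construction.
* **Fixation delay.** Cores fix at `core_delay_h = 0.05` h. The default
  excision delay is `size/2 ÷ 1 mm/h` plus a 3 h handling offset
  (devascularization to fixative equilibration) — delay increases with
  specimen size, which is what produces greater loss in larger tumours and
  hence in mastectomies. An alternative `"surgery"` model (mastectomy
  half-thickness capped at 5 mm by slicing, lumpectomies unsliced overnight)
  is implemented for exploring the opposite regime, and a `"constant"` model
  serves as the no-size-coupling control in the size-association tests.
* **Protein effects.** Excision abundance is
  `core × exp(−λ d) × (1 + γ (1 − exp(−d/τ)))`: exponential epitope decay at
  rate λ (per hour) plus a saturating stress-response induction with gain γ
  and time constant τ = 6 h (bounded fold change, so large observed
  increases remain reachable without unbounded counts). True per-protein
  rates are unknowable from net effects, so defaults are *calibrated*: λ and
  γ are solved numerically so the expected mean linear reduction/increase
  over the delay distribution (deterministic quantile quadrature over the
  size distribution) equals each protein's target — e.g. 59.5% reduction for
  pAKT, 54.2% for p4EBP1, 40% for pRPS6, 87% increase for 4EBP1, 120% for
  pan-KRT; proteins reported as stable get a nominal 10% reduction. The
  panel's `pEGFR` emulates a probe with no target: near-zero abundance and
  below-IgG non-specific binding, so it exercises the detection filter.
* **Measurement layers.** Endogenous counts are negative binomial around
  `count_scale × abundance × lane_effect × input_amount` plus additive
  non-specific background (the negative-probe level plus an IgG-level term
  scaling with input). Positive spikes scale with the lane effect only;
  negative probes measure the lane background; IgG probes scale with input.
  This composition makes the normalization chain exact in the noise-free
  limit: a test asserts that with all noise terms zero the pipeline recovers
  `log2(abundance)` per protein up to a global constant, to 1e-6. Default
  dispersion 0.01 corresponds to about a 10% technical CV, typical of
  barcode counting; lane-effect and input log-sds default to 0.15 and 0.3.
* **Patient heterogeneity.** Between-patient abundance log-sd defaults
  to 0.2. The emulated cohort is biologically homogeneous (all ER-positive
  primaries), and its observed near-perfect specimen-type clustering implies
  the fixation artifact dominates patient-level profile variation; the
  default encodes that regime.
* **IHC read-outs.** For the five mapped proteins (Ki67 percent positive,
  HER2 ordinal 0–3, PgR/pAKT/pERK1/2 H-score), the score is a saturating
  Hill transform of the same specimen-level latent abundance (half
  saturation at the protein's baseline), plus Gaussian noise of 8% of the
  scale maximum, clipped to bounds, rounded for the ordinal scale. Both
  read-outs thus share latent truth, which is what makes pooled concordance
  exceed within-stratum concordance when a specimen effect spreads the
  pooled abundances.
* **Dilution series.** The QC generator emulates the assay-optimization
  experiment: 6 samples alternating core/excision, three dilutions each,
  counts expressed relative to the canonical 10× dilution, all lanes of one
  sample sharing that sample's input amount (dilutions of a single
  cleaved-tag lysate). QC samples span routine FFPE material, so their
  between-sample abundance spread (log-sd 0.4) is wider than the matched
  cohort's.
* **Determinism.** One seeded stream per cohort with a fixed draw order
  (sizes, abundances, lane effects, input amounts, counts, IHC noise); the
  same seed reproduces byte-identical output within this implementation.
  Cross-implementation equality is not promised, only distributional
  equivalence.

What the generator does *not* emulate: spatial diffusion within tissue,
epitope-retrieval chemistry, cartridge batch effects, lane-level QC failures,
tumour-content variation between the paired specimens, and any dependence
between proteins beyond the shared delay. Passing tests therefore
demonstrate that the pipeline recovers the effects this mechanism produces at
these noise levels — not that real cohorts will show them.

# Numerical choices and degenerate inputs

* Geometric means require strictly positive input; background control probes
  are the one place zeros are legal, and there they are offset to 0.5.
* Stage provenance is enforced: each operation checks the incoming matrix's
  stage, so the chain cannot run out of order.
* Matrices round-trip through TSV via shortest-round-trip double formatting;
  the round-trip test asserts 1e-12 relative agreement.
* All-zero paired differences, constant correlation margins, and
  insufficient group sizes yield flagged results (`degenerate`,
  `undefined`, `insufficient_n`) rather than exceptions, because per-protein
  batch analyses must not abort on one degenerate protein; hard errors are
  reserved for structural problems (missing controls, zero spike counts,
  unmatched probes).
* Patients missing a specimen, a tumour size, or a known surgery type are
  excluded listwise from exactly the analyses that need the missing field.
* When dilution replicates exist, the lane tagged `10x` is canonical for
  analysis; other dilutions feed only the QC.

# Problem sizes in the test suite

The acceptance-style tests simulate at the study's own scale: 16-pair
cohorts; 2,000 protein-level null tests (80 cohorts × 25 proteins) for
calibration; 200 cohorts for effect recovery at a 50% true mean reduction;
100 cohorts each for size-coupling, clustering separation and concordance
structure; 50 seeds for dilution QC. Exact-test oracles enumerate up to
n = 10 (sign patterns and labelings) and n = 7 (permutations). These sizes
give binomial standard errors comfortably inside the asserted bands while
keeping the whole suite under a few minutes.

# Known limitations

* The delay model is deliberately minimal (one number per specimen); it
  cannot represent gradients within a section or differences between the
  tumour centre and margin.
* Calibration targets are net effects; λ and γ are identifiable only
  jointly with the assumed delay distribution.
* The surgery-type comparison inherits whatever confounding the delay model
  encodes: under the default size-proportional model, surgery effects are
  purely size effects.
* Exact Mann–Whitney enumeration is limited to a combined n of 12; the
  16-patient surgery comparison (8 + 8) therefore uses the tie-corrected
  normal approximation, whose null behaviour is verified in the test suite.
* IHC concordance treats each (patient, specimen) as one observation;
  replicate IHC scores per specimen are not modelled.
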