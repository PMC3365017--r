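---
title: "Gradient Encoding: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient Encoding: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradecode)
```

## The measurement model

Polysome profiling separates mRNAs in a sucrose gradient by the number of
ribosomes they carry. Gradient Encoding compresses the usual
one-array-per-fraction design into a single two-color array per gradient:
fraction `f` contributes a proportion `a[f]` of its mRNA to a Cy5-labeled
pool and `1 - a[f]` to a Cy3-labeled pool, with `a[f]` strictly increasing
from the top of the gradient to the bottom. A transcript distributed over
fractions with masses `m_f` then reports

$$\log_2\frac{\mathrm{Cy5}}{\mathrm{Cy3}}
  = \log_2\frac{\sum_f m_f\,a_f}{\sum_f m_f\,(1-a_f)},$$

a single number that encodes its average position in the gradient. Note this
is the ratio of pooled sums — the physically correct form for pooled
material — and not the abundance-weighted mean of per-fraction ratios; the
two differ whenever the transcript spans several fractions. Both the decoder
and the qRT-PCR oracle use the pooled-sums form.

Interpreting position as translation rests on three assumptions, which the
synthetic generator realizes literally: sedimentation is determined by the
number of bound ribosomes; initiation is rate-limiting with uniform
elongation, so ribosome load is proportional to translational efficiency;
and ORF length is constant across conditions (ORF-length effects on
ribosome capacity are not modeled at all).

## From ratio to ribosome number

Decoding proceeds in four calibrated steps:

1. **Dye calibration.** Doping controls — synthetic spike-in mRNAs added to
   each fraction at a fixed mass (default 4 per fraction, 100 pg) — have a
   known expected log2 ratio $\log_2(a_f/(1-a_f))$. A least-squares fit of
   measured on expected control ratios absorbs per-array dye distortions;
   its inverse affine map puts gene ratios on the expected scale.
2. **Ratio to position.** The map from integer fraction to expected log2
   ratio is inverted. Two inversions are provided: piecewise-linear
   interpolation between the integer-fraction knots (the decoder's default)
   and the regression of expected ratio on fraction number (used by the
   explicit qRT-PCR calculation). On the default ramp (below) the two agree
   exactly. Ratios outside the scheme's range are clamped to fraction 1 or
   `n` and flagged; the unclamped value is kept alongside, so monotone
   ranking is never destroyed by clamping.
3. **Position to time.** Fraction midpoint elution times are interpolated
   linearly in position; positions beyond the first or last midpoint
   extrapolate with the adjacent segment's slope. The field maps fraction
   midpoints to time but is silent on sub-fraction interpolation; linear is
   the minimal choice.
4. **Time to ribosomes.** Successive A260 peaks are assigned ribosome counts
   1, 2, 3, ... and fit as $k = \alpha + \beta\,\ln t$ ($\beta > 0$). The
   sentence defining this calibration is ambiguous about which variable is
   logged; we fix count-linear-in-log-time because polysome peaks compress
   geometrically with depth, making this the only reading that yields a
   usable continuous map. The alternative ($\ln k$ linear in $t$) is not
   implemented. Decoded average ribosome numbers are continuous, may fall
   below 1 near the top of the gradient, and are never clipped.

Each gradient carries its own peak calibration: gradients are not perfectly
superimposable, so the generator jitters peak times per run and both the
decoder and the oracle use the run's own calibration.

## The encoding ramp

The true pooling proportions used in the original experiments are not
available; only their monotonicity is. Two ramps are implemented:

* `ramp = "log2"` (default): expected log2 ratio linear in fraction index
  (logistic `a[f]`). With this ramp the regression and piecewise inversions
  of step 2 coincide exactly, which is what makes the explicit qRT-PCR
  oracle and the array decoder agree to machine precision on noiseless data.
* `ramp = "proportion"`: `a[f]` linear in `f`. Monotone and symmetric like
  the default, but its expected-ratio curve is logit-shaped, so the two
  inversions disagree by up to ~0.85 fractions at the ends of a
  (0.1, 0.9) ramp.

Both ramps share endpoints (`a_min = 0.1`, `a_max = 0.9` by default — both
channels always detectable) and are symmetric about the middle fraction.
Whether the original pooling was linear in proportion or in log-ratio is
unknowable from the available material; the log2-linear ramp is the only
internally consistent default for a pipeline that must use both inversion
forms.

## The differential test

Treated/untreated changes are tested with a moderated two-class statistic
$d = (\bar{x}_T - \bar{x}_U)/(s + s_0)$, where $s$ is the unpaired pooled
standard error and $s_0$ a fudge factor that keeps near-zero-variance rows
from dominating. Choices:

* Sample columns are **mean-centered** before testing. This removes
  per-array offsets but silently assumes the cohort-average change is zero:
  if the true changes are asymmetric, centering transfers the average onto
  every unchanged gene. The generator's default cohort therefore has
  sign-balanced translation effects; users simulating strongly asymmetric
  cohorts should expect anti-conservative calls, which is a property of the
  centering normalization, not of the permutation machinery.
* $s_0$ defaults to the median of $s$ over rows (the classic
  coefficient-of-variation grid search is deliberately not reproduced;
  numeric parity with any particular implementation is a non-goal). The
  degenerate 0/0 case (no change, no variance) is defined as $d = 0$.
* With 3 vs 3 replicates the permutation null enumerates all 20 label
  assignments deterministically — no sampling, no seed. For other designs a
  seeded random set of relabelings is available.
* FDR at threshold $c$ is $\hat\pi_0 \times \mathrm{median}_b
  |\{i: |d_i^{(b)}| \ge c\}| / |\{i: |d_i| \ge c\}|$, with $\hat\pi_0$ the
  proportion of observed $d$ inside the interquartile range of the permuted
  $d$, capped at 1. A row's q-value is the minimum FDR over thresholds that
  call it, so q is nonincreasing in $|d|$ and clipped to [0, 100]%.
* Only tail-area q-values are reported. Per-gene local FDR is not
  implemented: the kernel machinery behind local FDR estimates is not part
  of this package's scope and a mislabeled approximation would be worse than
  none.
* Genes with several array oligos are tested per oligo and collapsed
  afterwards: the gene change is the mean of oligo changes; a gene is
  significant when any oligo passes. A `max_change` collapsing mode (take
  the oligo with the largest absolute change, optionally judged on a
  separate selector quantity) is provided for display orderings.

Classification then crosses translational significance with the mRNA
abundance change: a significant gene whose abundance change lies within one
standard deviation of the cohort mean (mean and SD over *all* detectable
genes) is called `translation_only`.

## pSILAC aggregation

Peptide medium/heavy ratios are filtered at identification probability
≥ 0.95 and a curation flag, median-centered in log2 within each experiment
direction (removing loading bias), aggregated per protein as the geometric
mean of ratios over at least two unique peptide sequences, and combined
across the forward and label-swapped reverse experiments after flipping the
reverse ratios to treated:untreated. Proteins seen in a single direction are
retained and flagged rather than dropped — whether the original comparison
set kept them is unstated, and discarding data silently seemed worse.
Spectral search, quantitation and curation themselves are out of scope;
their effects enter only through the probability and quality fields of the
input table.

## What the synthetic generator emulates

`sim_config()` / `simulate_experiment()` generate complete seeded
experiments: 15-fraction gradients with subunit and ribosome A260 peaks,
per-replicate peak-time jitter (1%), discretized-Gaussian transcript
profiles in position space, linear pooling with doping controls, per-array
affine dye distortion, Gaussian array noise with simulated quality-metric
fields, per-fraction qPCR tables with their own doping control, and
peptide-level pSILAC tables in both directions whose protein truth is
`c_t * Δtranslation + c_a * Δabundance + noise` (defaults `c_t = c_a = 1`,
noise SD 0.3).

Key default conditions, chosen once:

* **Cohort**: 2000 genes, 3 replicates per condition, 7.5% regulated
  (2% translation-up, 2% translation-down, 0.75% each abundance class,
  2% coupled). The regulated fraction matches the scale observed in the
  motivating system (~7% of ~10,500 genes translationally regulated);
  translation effects are sign-balanced (see mean-centering above) and
  abundance effects are scaled by 0.7 so translation-effect variance
  dominates — the regime in which translation is expected to be the better
  single predictor of protein production.
* **Effects**: |log2 effect| uniform on (0.7, 2). Treated loads are clamped
  to the calibrated range of the gradient (~0.55–5.8 ribosomes for the
  default 6-peak calibration, since material cannot sediment past the
  bottom) and the realized post-clamp change is recorded as the truth.
* **Loads and spread**: untreated mean loads log-uniform on (1, 4.2)
  ribosomes; per-gene gradient dispersion 0.6–0.9 fractions (SD of the
  position-space Gaussian). A transcript's spread is modeled as Gaussian in
  position space, matching the "average position" semantics, rather than as
  a multinomial over discrete ribosome counts.
* **Noise**: array log2 ratio SD 0.06, fraction-mass lognormal SD 0.04,
  qPCR CV 5%, 5% of features drawn to fail the quality filter (pixel
  correlation < 0.6 *and* intensity/background < 2.5), per-array dye slope
  SD 0.05 and offset SD 0.1. No magnitudes for these are published; they
  were set once so that replicate correlations of log average ribosome
  number land just above 0.95, the level reported for the real replicates,
  and they are ordinary tunables of the configuration.
* **Validation panel**: 9 qPCR genes spanning the extremes and middle of the
  translation-change range, the way validation genes are picked in practice.

**Ground truth for the round trip.** Pooling is nonlinear, so a dispersed
profile's encoded position is deterministically offset from its center: the
assay measures the logit-pooled position, not the arithmetic mean position.
The generator therefore records two truths per gene and run — the generative
mean load and the *encoded* load implied by the noiseless profile — and the
machine-precision round-trip guarantee applies to the encoded load (the
quantity the assay defines), while agreement with the generative load is a
rank-correlation property.

What the generator does **not** emulate: microarray image artifacts and
spatial effects (quality metrics are drawn, not computed from pixels),
amplification efficiency differences between pools, dye bleaching and ozone
effects, drop-based fraction volume variation, Ct-level qPCR standard
curves, and any mass-spectrometry upstream of the peptide ratio table.
Passing tests on synthetic data therefore demonstrate the correctness and
calibration of the *computations*, not the wet-lab robustness of the assay.

## Numerical choices and degenerate inputs

* Peak finding uses the prominence rule "height above the higher of the two
  flanking minima ≥ a fraction of the trace range" (default 0.05), with the
  search window expected to start at the 80S region so 40S/60S subunit peaks
  are excluded. A flat trace yields no peaks (not an error); non-monotone or
  non-uniform trace times are errors. Peak times are reported on the
  sampling grid; with the default 1.5 s step this quantization is the main
  error source when calibrations are re-derived from traces, which is why
  the simulation pipeline defaults to the run's exact calibration and treats
  trace-derived calibration as a separately validated option.
* Calibration requires ≥ 2 peaks and positive times; the decoder requires
  doping controls from ≥ 2 distinct fractions; abundance normalization
  requires spike-ins at ≥ 2 known levels. All are hard errors naming the
  problem.
* qPCR error propagation combines relative errors in quadrature through the
  control division only; the subsequent sum-to-1 rescale uses measured
  totals and is treated as exact. Zero control means are errors naming the
  fraction; zero input errors propagate to exactly zero.
* The quality filter partitions its input exactly (every row is kept or
  rejected-with-reason, never both); features missing from any replicate
  after filtering are dropped pipeline-wide. Decoded loads that are
  non-positive on the log scale (possible for noisy transcripts near the
  gradient top) drop the feature everywhere, keeping the test matrix
  complete.
* All randomness flows from one master seed through fixed arithmetic
  sub-streams (`sub_seed()`): stream 1 truth, 100+ gradient runs, 300+
  abundance arrays, 500 pSILAC. No global state leaks between components,
  and any component can be regenerated in isolation.

## Known limitations

* The decode assigns one position per feature; bimodal gradient profiles
  (e.g. a transcript split between a repressed and a polysomal pool)
  collapse to a single intermediate load, exactly as in the real assay.
* The FDR estimator's granularity at 3 vs 3 is limited by the 20 possible
  relabelings; q-values move in coarse steps and small call sets are
  expected to over- or under-shoot nominal FDR within that granularity.
* Mean centering assumes a globally balanced response (discussed above).
* The ±1 SD abundance band classifies relative to the realized cohort; it is
  a descriptive rule, not an error-controlled test of "no abundance change".
* Clamped decodes (beyond the first/last fraction's expected ratio) preserve
  rank but compress magnitude at the gradient edges.
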