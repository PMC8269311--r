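---
title: "gravmet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gravmet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravmet)
```

# The measurement model

The pipeline consumes relative metabolite abundances (RMA): GC-MS peak
signals normalised to spiked internal standards, dimensionless and
non-negative, from cell-culture *supernatants*. A supernatant
measurement mixes two sources: the medium background (what the cell-free
medium contains, the *blank*) and the cells' net exchange with the
medium. Subtracting the per-metabolite blank converts abundances into
signed net fluxes — positive for net secretion, negative for net uptake.
All downstream statistics (fold changes, tests, correlations) operate on
these signed net fluxes, which is why fold changes can be negative: a
negative FC means the metabolite switched between net production and net
consumption between conditions, and "effect size" always refers to the
magnitude |x| of a net flux, not to its sign.

Two experimental designs are supported. The short-term design
(`TEXUS54`) has one flight sample per condition (hypergravity, then
~5 min of microgravity) and two ground controls, each measured in three
technical GC-MS injections, plus three blank injections. The long-term
design (`CELLBOX`) has five flight samples and three ground controls,
each split over two hardware compartments whose recovered fluids are
combined *in silico* by the volume-weighted mean
$\bar{x} = \sum_i v_i x_i / \sum_i v_i$; ground compartments carry two
technical replicates, flight compartments one, and the blank six.

# The preprocessing ladder

Order: unannotated removal → technical-pair imputation → replicate
averaging → compartment combination → missingness filter → residual
within-group mean imputation → blank preparation/subtraction → mean
scaling to the reference platform → problematic-metabolite removal.

Key parameters (all in `grav_constants()`, all overridable):

* **LOD = 50 RMA units.** Signals below it are treated as censorable:
  a failed injection whose partner replicate sits below 50 is read as
  censoring and imputed as `impute_fraction` (= 1/5) of the lowest
  signal observed anywhere in the dataset (blanks included); a failed
  injection whose partner is at or above 50 is read as a technical
  dropout and the partner's value is carried over. The boundary is
  closed upward (exactly 50 counts as detected) — the rule text says
  "below".
* **Missingness filter.** Rule A removes a metabolite when its missing
  count reaches `ceiling(2/5 · n_flight)` flight or
  `ceiling(1/3 · n_ground)` ground samples *and* every observed value in
  the triggering group exceeds the LOD (strictly): observed near-LOD
  values make the missingness plausibly censoring, which the filter must
  not punish. Rule B removes independently when strictly more than half
  the values are missing in *both* groups. The ceilings generalise the
  stated 2-of-5 / 1-of-3 counts to other replicate numbers.
* **Residual imputation** uses the *within-group* mean. The alternative
  (grand mean) would leak the flight/ground contrast into imputed cells
  and bias the tests toward the null or away from it depending on the
  missingness side; group means are contrast-neutral.
* **Blank position.** The blank is subtracted *after* the missingness
  filter so that the filter's ">50" clauses act on raw signals, the
  scale on which an LOD of 50 is defined. (On net fluxes the LOD has no
  meaning — a net flux of 10 can come from 1000 − 990.)
* **Inter-platform scaling** divides the long-term table by
  k = mean(target)/mean(reference) so both share a grand mean; the
  post-condition |mean(scaled) − mean(reference)| ≤ 1e−9·|mean| is
  asserted. k ≤ 0 (opposite-sign grand means) is refused as degenerate —
  a world in which "scaling by division" is meaningless. Every
  downstream quantity that matters (FC, correlation, quadrants) is
  scale-free, which the test suite asserts numerically.

# Statistics

* **Tests.** Long-term: Welch two-sample t (unequal variances),
  two-sided. Short-term: each flight condition has a *single* biological
  sample, so its three blank-subtracted technical replicates are tested
  one-sample, two-sided, against the pooled ground mean as µ₀. This is
  the only reading of a "single-sample t-test with unequal variance"
  that is well-defined at n = 1 biological sample; the "unequal
  variance" qualifier is vacuous for one sample and ignored. Note the
  caveat: technical replicates measure injection noise, not biological
  variability, so short-term p-values are anti-conservative by
  construction and the two-tier banding below is deliberately loose.
  Degenerate inputs use the conventions p = 1 for identical constant
  groups and p = 0 for distinct constant groups.
* **FDR and bands.** Benjamini–Hochberg step-up adjustment (the method
  behind the study's "estimated FDR" is not named; BH is the field
  default and monotone, which a two-band scheme needs). Bands: `++` for
  FDR < 0.35, `+` for 0.35 ≤ FDR ≤ 0.50, `ns` above. Both boundaries
  resolve downward into `+` ("between 0.35 and 0.50", and the plot
  captions' "FDR ≤ 0.5"). The deliberately liberal 0.35/0.50 tiers admit
  weakly powered members of metabolite networks; they are *screening*
  thresholds, not confirmatory ones.
* **Effect regions.** On the signed FC axis, significant records are
  classified as strong increase (FC > 2), weak or inverted decrease
  (−0.5 < FC < 0.5), strong inversion (FC < −1). All boundaries are
  open: FC = 2, ±0.5, −1 stay unclassified, reading "double or more" as
  strictly beyond the doubling point. A zero ground mean makes FC
  undefined: the record gets `NA` and `unclassified`, never an error
  that aborts a panel.
* **Correlation clusters.** Pearson r between metabolite profiles over
  all samples, conditions ignored. Candidates are all subtrees of the
  first dataset's average-linkage dendrogram (equivalent to cutting at
  every height); acceptance needs mean pairwise |r| ≥ 0.8 in both
  datasets and ≥ 2 members; only maximal accepted groups are returned.
  |r| rather than r because anticorrelation is equally strong evidence
  of a coupled network. The 0.8 threshold operationalises a judgement
  the original analysis made visually; it is a default, not a measured
  quantity. Zero-variance metabolites correlate 0 by convention so the
  clustering stays total.
* **Quadrants.** Each axis is read as effect strength s = |FC| with a
  separate inversion flag (fc < 0), because inverted metabolites are an
  exception to a naive quadrant reading — their direction of change is
  flipped, and discarding them would lose exactly the most interesting
  records. The center band [0.5, 2] (closed) reuses the halving/doubling
  thresholds; the source analysis never defines the center numerically.
* **Outlier handling.** A leaking culture chamber concentrates the
  supernatant: nearly every metabolite peaks in that sample. The score
  is the fraction of metabolites whose maximum lies in the sample (ties
  split equally), flagged at ≥ 0.8. Flagging never removes: removal
  requires explicit confirmation in the pipeline config (`"auto"` opts
  in globally). This replaces a visual-plus-physical-evidence judgement
  with an auditable rule.

# The synthetic world

`generate_pair()` draws both platforms from one seeded RNG stream.
The raw signal of metabolite m in sample s is

$$x_{ms} = \big(B_m + N_m\,e(m, c(s))\big)\; L_{b(m),s}\; \varepsilon_{ms},$$

with blank level $B_m$, ground-truth net flux $N_m$, multiplicative
condition effect $e$ (1 for ground; negative values flip
production/consumption), a shared per-sample lognormal block factor
$L$ inducing intra-block correlation, and lognormal measurement noise
$\varepsilon$ with unit mean and CV = `noise_cv`. Outlier samples are
multiplied by an inflation factor (default 3), values are clipped at
zero, and realised signals below the LOD are set missing with
probability `missing_below_lod_prob` (MNAR censoring).

Choices a reader should know:

* **Noise is multiplicative lognormal** (CV 0.1 by default): GC-MS
  intensities are positive and heteroscedastic; the source gives no
  noise magnitudes, so 10 % is a calibration choice.
* **Block correlation is exact by construction.** For a block with
  target ρ the factor's log-variance is
  $\sigma_b^2 = \log\!\big((1-\rho)/(1-\rho e^{\sigma_n^2})\big)$, which
  makes the population Pearson correlation of two block members exactly
  ρ at the technical-replicate level; averaging replicates pushes the
  empirical value slightly above ρ. The factor is tied to the noise
  level, so at `noise_cv = 0` the world is exactly deterministic —
  whence the pipeline's exact fold-change recovery test. A ρ too close
  to 1 for the noise level is refused.
* **Effects mirror the study's phenomenology**: sign inversions of
  magnitude 60/41/12/4/2 on ill-conditioned small-net metabolites, a
  five-member amino-acid-like block (ρ = 0.95) with over-re-adaptation
  (up ~1.3–1.9× short-term, ~0.5× long-term), a second block at
  ρ = 0.85, a >95 % long-term decrease, a concordant riser, and a
  near-LOD trace group on the long-term platform that exercises the
  censoring and filtering rules. Cluster-block members are all
  net-secreted: a mixed consumed/secreted block would be anti-correlated
  by the flight contrast and could not model a coherently reacting
  network. Panels are 63 and 61 annotated metabolites with a
  32-metabolite overlap, plus four unannotated compounds per platform.
* **Scales.** Medium components ("consumed") draw blanks of 500–1500
  and net uptake of 30–55 % of blank; cellular products ("secreted")
  draw blanks of 120–260 and net secretion of 2.5–5.5× blank. This
  makes both platforms' grand means robustly positive (required for
  mean-ratio scaling) and keeps noiseless signals above the LOD — net
  fluxes are shrunk deterministically where a planted effect would push
  a signal below LOD + 5, except for the trace group, which is *meant*
  to straddle the limit.
* **Not emulated:** chromatographic artifacts, retention-time drift,
  annotation errors, batch effects, biological replicate variance
  beyond the lognormal noise, and any real metabolite biochemistry —
  the metabolite names are labels for planted roles. A green test
  therefore establishes that the *rules* of the pipeline do what they
  claim on data with known structure, not that the original biological
  conclusions reproduce.

# Numerical conventions

* PCA: `prcomp` on centered, unscaled data; component signs fixed so
  each component's largest-|loading| is positive; zero-total-variance
  input returns all-zero scores and variance fractions rather than NaN.
* Heatmap: z-scores per metabolite, then one *global* division by the
  maximum |z| — a per-row maximum would force every row to touch ±1 and
  destroy between-metabolite contrast; zero-variance rows become 0 with
  a warning.
* Results TSVs print numerics with `%.12g`, so files round-trip at 12
  significant digits and a fixed seed reproduces every output file
  byte-identically.
* Missingness is `NA` in memory and the `NA`/empty sentinel on disk;
  zero is always a real measurement.

# Known limitations

* With four samples in the short-term design the null distribution of a
  Pearson correlation is uniform on [−1, 1], so chance metabolite pairs
  exceed |r| = 0.8 frequently, and some survive the second dataset's
  gate (n = 8) as false conserved pairs. At desk-scale sample sizes *no*
  method honouring the dual-threshold acceptance rule can guarantee
  zero false clusters; the validation suite quantifies this (the
  planted ρ = 0.95 block is returned in ≥ 90 % of worlds, while the
  zero-false-cluster assertion fails by a measured margin and is
  documented as such). Treat size-2 conserved clusters as screening
  candidates only.
* Short-term p-values rest on technical replicates (see above); the
  package reports them because the design permits nothing stronger, but
  they quantify injection noise around one biological observation.
* The preprocessing order and several rule readings (grand vs group
  mean, blank position, band boundaries, the [−1,1] rescale, the center
  band) are documented judgements where the source text is ambiguous;
  each sits behind one function with one default, so alternative
  readings are one argument away.
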