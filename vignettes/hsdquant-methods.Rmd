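---
title: "Models and quantification methods in hsdquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and quantification methods in hsdquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsdquant)
```

This vignette is the package's own account of its models, defaults and
design choices: what each statistic assumes, why the tunable parameters
default to what they do, what the synthetic-data generators emulate —
and what they deliberately do not, hence what a passing test does and
does not show about real data.

## The pupariation model

A vial assay seeds `larvae_per_vial` larvae on a diet and scores
cumulative pupae on a fixed observation grid. The generator models each
larva's pupariation time as a draw from a normal distribution truncated
at zero, with median `p50_base` (default 110 h after egg laying) and
between-larva SD `sd_pup` (default 6 h). No specific distributional
family is implied by cumulative pupariation curves beyond their sigmoid
shape; the truncated normal is the simplest model producing such
curves, and the truncation point at zero is never active in practice
(the median sits ~18 SDs above it). Permanent developmental arrest is a
per-larva Bernoulli event with probability `arrest_prob`; arrested
larvae simply never appear in the cumulative count, which is how a vial
records them.

Diet enters as a location shift: on the high-sugar diet the median
moves by `control_diet_effect` (default 40 h — the delay high sugar
causes even in controls) plus the genotype's `excess_delay`. A
genotype-intrinsic `genotype_delay` shifts both diets equally and is
used to plant partially-sugar-dependent phenotypes. Observation
cadence defaults to 8 h (`obs_interval`), matching follow-up assays
scored every 4–8 h; the screen generator defaults to daily scoring
(24 h), the realistic cadence for thousands of vials.

### The P50 statistic

`p50_time()` linearly interpolates between the last observation below
0.5 and the first at or above it. Numerical conventions:

* an observation exactly at 0.5 is returned as-is; if a plateau sits
  exactly at 0.5 across several observations, the earliest time is
  taken (the transition has happened by then; later plateau points are
  scoring redundancy);
* a curve whose maximum stays below 0.5 returns `reached = FALSE` with
  `p50 = NA` — arrest is a distinct outcome, not a missing value to
  impute;
* vials with fewer than three pupae are flagged `qualifies = FALSE`
  and excluded from replicate averaging (three pupae is the minimum for
  a halfway-meaningful within-vial curve), but zero-pupae vials still
  count toward arrest-fraction evidence;
* times are continuous hours from the midpoint of the egg-laying
  window, 0-based.

The statistic is exactly invariant to inserting redundant observations
on the same piecewise-linear curve and equivariant under time shifts;
both are tested, along with agreement (±0.01 h) with a dense-resampling
oracle on 1,000 random curves.

### Hit calling

`classify_hit()` walks a deterministic decision tree over per-diet
severity. Severity on a diet is, in order: **full arrest** (pooled
final pupariation fraction over all vials is 0), **partial arrest**
(pooled fraction in (0, 0.5) — consistent with P50 being undefined
below 0.5), **delay**, or none. A delay call requires both a magnitude
and a significance criterion:

* magnitude: at least `delay_h = 12` hours. No published numeric
  cut-off exists for screen-scale delay calling; half a day is the
  smallest delay distinguishable from scoring granularity at the daily
  screen cadence, so it is the default and is configurable.
* significance: two-sided α = 0.05 on a replicate-level test — a
  Welch t-test against the control for the normal-diet delay, and the
  genotype × diet interaction ANOVA for the high-sugar excess delay
  (the interaction term is precisely the hypothesis that the excess
  delay is non-zero).

A degenerate case needs an explicit convention: with daily scoring and
little biological noise, every vial's interpolated P50 can be exactly
equal, so replicate variance is zero and a t-test is undefined. A
non-zero mean difference with literally no replicate scatter is treated
as certain (p = 0), a flat difference as absent (p = 1).

The class map: no normal-diet phenotype with high-sugar full arrest,
partial arrest or delay gives the three sugar-dependent classes;
normal-diet delay followed by high-sugar full or partial arrest, and
normal-diet partial arrest followed by full arrest, give the three
partially-sugar-dependent classes (phenotype on both diets, strictly
stronger on sugar). Any other severity pattern — including
delay-on-both-diets with no worsening — is `none`. No multiple-testing
correction is applied across a screen by default (per-gene calls are
reported as such); `enrichment()` exposes an optional
Benjamini–Hochberg flag where correction is meaningful.

`screen_summary()` reports the hit rate as a percentage rounded to one
decimal and annotation fractions as integer percentages, the precision
at which such screen summaries are conventionally quoted.

## Image quantification

All image operators act on 2-D matrices with 0-based `(row, col)`
coordinates; z-stacks are first collapsed by `sum_project()` (per-pixel
sum, the projection mode that preserves integrated intensity).

* `roi_quant()` follows the moved-ROI convention: the background region
  must have the same pixel count as the signal ROI, so summed
  backgrounds cancel exactly and a constant offset added to the whole
  image leaves the corrected value unchanged. Negative corrected values
  are reported with a warning, not clipped — they are evidence about
  the background placement. Background ROIs are always supplied
  explicitly; the package does not attempt automatic placement.
* `extract_line_profile()` samples at ≤ 1-pixel spacing along the
  segment and averages `width_px = 15` perpendicular offsets per
  position using bilinear interpolation (interpolation scheme is a
  package choice; the 15-pixel width is the field's convention for
  noise reduction). Offsets falling outside the image are dropped from
  the average.
* `tgph_membrane_ratio()` applies the center window 0.45 ≤ x ≤ 0.55
  (closed) and surround windows [0.35, 0.45) and (0.55, 0.65]
  (half-open, exactly as the score is defined); samples outside
  [0.35, 0.65] are ignored. Being a ratio, it is exactly scale
  invariant.
* `droplet_area_fraction()` thresholds the droplet channel within the
  cell mask by Otsu's method on the in-mask intensities (via EBImage).
  How droplet segmentation should be thresholded is genuinely open;
  Otsu is a reasonable default for the strongly bimodal droplet
  channel, and a numeric threshold can be passed instead. A mask with
  no intensity contrast yields 0 rather than a degenerate split.
* `gcamp_ratio_series()` computes mean-signal/mean-reference per soma
  per frame, then the unweighted mean across somata. Rescaling both
  channels by a shared per-frame factor (illumination drift) cancels
  exactly.

### What the image generator emulates

`sim_fatbody_image()` lays cells out as equal square tiles: nuclei at
tile centers, tile boundaries as membranes. This guarantees the
geometry the line-profile score assumes — the midpoint of any
adjacent-nucleus line falls exactly on a membrane. The membrane band
half-width is 5% of the tile side so the band covers exactly the
central 10% of such a line and the surround windows sample pure
cytoplasm; the tile side is forced odd so nucleus centers sit on
integer pixels and line samples hit the lattice exactly, avoiding
bilinear blur of the band edge. Before noise, membrane reporter
intensity is exactly `membrane_enrichment` times the cytoplasm mean.
Droplets are non-overlapping disks on an interior grid, matching the
planted area fraction to within one droplet's area. Images are 2-D
single-plane fixtures; the sum-projection operator is exercised
separately on stacked copies, since every quantification operator acts
on 2-D data.

None of this emulates real tissue: no cell-size heterogeneity, no
oblique membranes, no out-of-focus light, no autofluorescence. Passing
recovery tests therefore demonstrate that the operators are correct on
their stated geometry, not that segmentation-free quantification would
succeed on real micrographs — on real data, ROIs and line endpoints
remain curated inputs.

## Phosphoproteomic response analysis

The design emulated is an 18-channel isobaric-labeling experiment:
3 genotypes (control, two knockdowns) × 2 treatments (mock, insulin) ×
3 parallel replicates. `normalize_channels()` rescales each channel to
the grand-mean total, the standard correction for labeling/loading
differences; it is idempotent and preserves within-channel ratios
exactly.

`insulin_response()` computes the per-site insulin/mock ratio of
replicate means on normalized abundances. A site is called `up` when
the ratio is at least 1 + θ (θ = 0.30) and `down`, by default, when it
is at most 1/(1 + θ) ≈ 0.769 — the reciprocal rule, symmetric on the
log scale, which is the natural reading of "a 30% change in either
direction" for fold changes. The raw rule (≤ 0.70) is implemented as
`down_rule = "raw"` since the choice between the two is genuinely
ambiguous. The direction call is fold-change-only; the attached
per-site Welch t-test p-value serves volcano-style outputs where the
p < 0.05 line is drawn, and `site_anova()` provides the per-site
one-way ANOVA across all six conditions (p = 1 by convention for a
perfectly flat site). Counting is at the phosphosite level — the
headline totals are phosphorylation changes, not proteins — with
`dedupe_proteins()` providing the protein-level collapse where needed
(Venn overlaps, pathway enrichment).

`dependent_set()` takes the control-regulated sites whose direction is
`none` in *every* supplied knockdown (`mode = "all"`, the stricter
reading of dependence across two independent siRNAs) and reports the
dependence fraction as an integer percentage of the control response;
`mode = "any"` is available because the published analyses do not
settle which convention was used. `enrichment()` is a plain two-sided
Fisher's exact test per pathway against the background universe, raw
p < 0.05 by default.

The generator plants a fraction of responsive sites with ±1 log2-unit
effects in control and the same effects multiplied by `blunting` in
knockdowns, Gaussian noise on the log2 scale, and a round-robin
many-to-one site→protein mapping. It does not emulate missing values,
peptide-level interference, compositional effects or phosphosite
localization ambiguity — the operators assume a clean site-level table,
as after upstream search-engine processing.

## Standard curves

Metabolite assays default to the linear Beer–Lambert model; sandwich
ELISAs to the four-parameter logistic
`A = d + (a − d)/(1 + (x/c)^b)`, fitted by Levenberg–Marquardt with
endpoints of the standard series as asymptote starting values and the
median positive dose as the midpoint start. Both models invert in
closed form; 4PL inversion is defined strictly between the asymptotes
and errors outside them. Mean blank absorbance is subtracted before
fitting when blanks are supplied. Absorbances outside the calibrated
range are extrapolated with a warning and flagged — low-end samples in
particular should be treated as below quantification rather than
trusted. An r² below 0.98 triggers a warning; units are carried as
labels and never converted implicitly, with `molar_to_mass()` doing the
one explicit conversion needed (e.g. 5 mM glucose = 900 µg/mL at molar
mass 180). `normalize_sample()` reports metabolite:protein ratios after
undoing dilution (hemolymph conventionally 10-fold).

## Randomness and reproducibility

Every generator takes an explicit integer seed and evaluates under
`withr::with_seed`, so the caller's RNG stream is untouched and
identical seeds give bit-identical output. Compound simulations
(`sim_screen()`, `run_demo()`) derive per-component sub-seeds
deterministically from the top-level seed. The demo pipeline writes a
run log (seed, thresholds, input digests) sufficient to reproduce any
artifact, and its byte-reproducibility is itself under test.

## Problem sizes used in the test suite

The suite exercises: 1,000 random curves against the dense P50 oracle;
20 replicate screens for 24-h excess-delay recovery; 100 null genes for
classification specificity; 1,000 null ANOVA simulations for type-I
calibration; 12 adjacent-cell pairs on 200 × 200-pixel simulated tissue
for membrane-enrichment recovery; 5,000-site phosphoproteomes for
count recovery; and exhaustive 2 × 2 tables at several totals up to 30
for the Fisher oracle. These sizes give stable statistical checks at
interactive runtimes; all recovery tolerances were fixed from the
planted-truth design of the generators, not tuned to outcomes.

## Known limitations

* The pupariation model has no larval-growth, critical-weight or
  hormone dynamics; arrest is all-or-nothing censoring rather than a
  competing-risks process.
* Hit-calling thresholds (12 h, α = 0.05, the 0.5 partial-arrest
  cut-off) are documented defaults, not reconstructions of any
  published rule; borderline genes will move between classes as they
  are varied.
* Image operators assume flat, perpendicular, 2-D geometry and curated
  ROIs; there is no segmentation, registration or deconvolution.
* The phospho analysis starts from a clean abundance table; nothing
  upstream of it (spectra, identification, localization) is modeled.
* Cross-kit harmonization of differently sensitive assay kits is out
  of scope for the standard-curve module.
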