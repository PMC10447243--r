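---
title: "From mitochondrial proteomes to axonal energy state: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mitochondrial proteomes to axonal energy state: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromito)
```

# Overview

`neuromito` links three layers of evidence about neuronal mitochondria in
neuroinflammatory disease models (such as experimental autoimmune
encephalomyelitis, EAE): label-free quantitative (LFQ) proteomics of
immunocaptured neuronal mitochondria, in vivo ratiometric biosensor imaging
of axonal energy and redox state, and a kinetic model of mitochondrial ATP
production whose maximal rates are scaled by the measured proteome. A
synthetic-data module generates every input with known ground truth, so the
whole chain is testable without any external download.

This vignette explains the models and procedures, the parameters that
matter, and the design choices made where conventions were genuinely open.

# Synthetic data: what it emulates and what it does not

`simulateLfq()` draws protein-specific log2-intensity locations from a
Gaussian baseline (default mean 25, s.d. 2, typical of MaxQuant LFQ
intensities on the log2 scale), adds planted case-vs-control log2 fold
changes, biological noise per animal (default s.d. 0.3) and technical noise
per replicate run (default s.d. 0.1). The default cohort — six control and
five case biological samples with technical-replicate pairs — mirrors a
typical acute-disease proteomics design. Missingness is left-censored by
construction: each run's values fall missing with a probability given by a
logistic ramp centred on that run's `censor_quantile` intensity threshold
(scale 0.3 log2 units), so low-abundance proteins go undetected
preferentially; the expected overall missing fraction equals the quantile.
Because the technical-replicate variance is not a published quantity, it is
a configurable default rather than a claim.

The generator does **not** emulate peptide-level evidence, ratio-count
filters, match-between-runs artefacts, or correlated missingness across
samples. Tests passing on these simulations therefore validate the
*arithmetic and statistical contracts* of the pipeline, not its behaviour
on every pathology of real LFQ data.

`simulateBiosensorStack()` paints straight axon tubes (one z-plane each,
configurable width) into a label mask and builds two channels: the
denominator carries the signal plus background, the numerator carries
`true_ratio × signal + crosstalk_alpha × donor + background`, with Gaussian
read noise everywhere. Morphological realism is deliberately absent — tube
geometry suffices to exercise background subtraction, region partitioning
and ratio arithmetic, which is all the downstream code consumes.

# LFQ processing

Technical replicates are averaged per biological sample (mean of observed
values; all-missing stays missing). Missing values are then imputed in two
tiers:

* **Tier 1 (left-censored proteins).** A protein detected in fewer than
  50% of the samples of at least one experimental group has *all* of that
  group's values replaced by draws from
  $\mathcal{N}(\mu_{all} - 2\sigma_{all},\; (0.3\,\sigma_{all})^2)$,
  where $\mu_{all}, \sigma_{all}$ are the mean and s.d. of every observed
  log2 intensity in the dataset. This is the Perseus-style
  missing-not-at-random imputation: such proteins are presumed below the
  detection limit in that group, so they are assigned to the lower tail,
  with a narrow width to control zero inflation. Overwriting the observed
  values of such a group is the literal rule; `overwrite_observed = FALSE`
  restricts tier 1 to the missing cells for users who prefer the milder
  variant.
* **Tier 2 (sporadic missingness).** The remaining missing cells are
  imputed by chained equations: each sample column with holes is regressed
  on all other columns over its observed rows, predictions are drawn with
  residual noise, and the sweep repeats for 10 iterations. The chained
  model is per-sample (columns as regression targets) — the canonical
  continuous-data form when proteins vastly outnumber samples; the
  iteration count and the per-sample orientation are package choices, as
  the method's settings are not published for this pipeline.

Differential abundance uses the two-sided equal-variance Student's t-test
per protein with Bonferroni correction ($p_{bonf} = \min(1, m\,p)$), and
log2 fold change defined as case minus control. PCA quality control runs
over samples with centred proteins as features; outliers are flagged when
their PC1–PC2 distance from the centroid exceeds the median distance plus
3 MADs — a conservative, scale-free rule chosen because published analyses
of this kind remove outliers without stating a criterion. Removal is left
to the caller. Protein-complex-level comparisons use one-way ANOVA on
per-sample mean log2 intensities of member proteins (`stats::aov`
internals via `lm`), which reduces to $F = t^2$ for two groups.

# Enrichment

`enrichmentScore()` implements the weighted Kolmogorov–Smirnov running-sum
statistic: walking down the list ranked by descending score, the sum gains
$|s_i|^p$ (normalised over in-set hits) at members and loses $1/(N-n)$ at
non-members; the enrichment score (ES) is the signed maximum deviation.
Defaults follow classic GSEA conventions (weight $p = 1$), since the
original analysis tool's internals are unpublished. Two documented edge
rules: a set equal to the whole list returns ES 0 (hits and misses
degenerate), and ties in $|{\rm running}|$ — possible with discretised
scores — resolve to the earliest position within a $10^{-12}$ tolerance.

`permutationNes()` builds the null by gene-label permutation (random
same-size sets), normalises by the mean $|ES|$ of matching-sign nulls
(NES), and reports $p = (1 + \#\{\text{same-sign nulls at least as
extreme}\}) / (1 + \#\text{same-sign nulls})$, which can never be zero.
`scaledMeanExpression()` computes each pathway's mean log2 intensity over
*control* samples and min–max scales across the reported collection — the
abundance-in-the-healthy-state companion statistic; control samples are
used because the statistic describes the unperturbed proteome.

# Biosensor quantification

Per channel, the background is the **median** intensity of non-ROI voxels
(robust to stray foreground; the underlying protocols say only that
background is "measured") and is subtracted with clipping at zero. Each
axon is split into three equal-length regions along the principal axis of
its voxel cloud (the protocols do not define region placement; equal
thirds make it deterministic), the pixel-wise numerator/denominator ratio
is averaged within regions, and the axon ratio is the mean over regions.
The per-region convention is ambiguous in the field between
mean-of-pixel-ratios and ratio-of-means; both are implemented
(`method = "pixel"` / `"pooled"`), pixel-mean being the default. Note that
the pixel-mean convention carries a small convexity bias
($\mathbb{E}[A/B] \approx r(1 + \sigma_B^2/\mu_B^2)$), about +1% at
signal-to-noise 10 — below the 2% recovery contract but visible in
benchmarks.

cFRET correction is `acceptor − α × donor` with the measured crosstalk
fraction α, reported as the cFRET:donor ratio; negative cFRET or
non-positive donor invalidates the record. Ratios are normalised to the
control-group mean (batch-difference elimination). Stage-wise outlier
fractions use the control mean + 3 sample s.d. threshold ($n-1$
denominator, appropriate for small control groups). Focal axonal
degeneration (FAD) stages are input annotations — staging was
morphological and manual in the source experiments, so the package never
computes them. Marker puncta inside a reference structure use a 120%
intensity cutoff relative to the mean reference intensity and a 4-pixel
minimum component size; occupancy × mean punctum intensity gives the
integrated density. COX occupancy is the percentage of axonal area covered
by oxidase-active elements, with a 25 µm minimum axon length when lengths
are known.

# Kinetic model

The model is a deliberately reduced network that preserves three
contracts: proteome-proportional maximal rates, a hyperbolic ATP load law,
and group-wise in-silico rectification. Substrate flows through three
sequential TCA-cycle segments (mapped to Idh3, Ogdh/Sdh and Mdh2), each
reducing NAD⁺ to NADH by Michaelis–Menten kinetics; a lumped electron
transport chain oxidises NADH and pumps protons against a logistic
membrane-potential back-pressure; ATP synthase phosphorylates ADP driven
by Δψ; a saturating Δψ-dependent conductance models the proton leak (a
reduced form of a Goldman–Hodgkin–Katz flux, which the property suite only
requires to be qualitatively Δψ-dependent); and ATP consumption follows
$v_{ATP} = k_{load}\,\mathrm{ATP}/(\mathrm{ATP} + K_m)$. NAD⁺ and ADP are
derived from conserved totals, so pool conservation is exact by
construction. Units are mM and seconds for concentrations and mV for Δψ.

Reference parameters are the package's own calibration of a healthy
resting state — Δψ ≈ 175 mV, ATP/ADP ≈ 31, and spare capacity for a load
titration (maximal ATP production ≈ 1.9× the resting rate). One structural
choice matters and is intentional: the TCA segments run near capacity at
rest while the ETC retains headroom. In a serial supply→TCA→ETC topology,
TCA depletion can only limit flux if the segments lack large spare
capacity; this is what lets a proteome with deeper TCA than ETC depletion
show greater benefit from TCA rectification, the qualitative prediction
the model exists to reproduce.

`scaleVmax()` multiplies each reaction's $v_{max}$ by the aggregate
relative abundance of its mapped proteins,
$v_{max}({\rm case}) = v_{max}({\rm ref}) \times E({\rm case})/E({\rm
mean\ control})$. Multi-subunit aggregates default to the arithmetic mean
of subunit factors (geometric mean available); the aggregation rule for
complexes is not defined by the scaling law itself and is a documented
interpretation. Steady states are found by stiff integration (`deSolve`
lsoda) in growing time chunks, with a damped Newton polish once the
relative residual drops below $10^{-3}$; convergence is declared at
$10^{-8}$ and non-convergence is flagged, not thrown. Load titrations
raise $k_{load}$ in geometric ×1.25 steps from the resting value until the
ATP production rate stops increasing (relative step change < $10^{-3}$).
`rectifyGroups()` resets one protein group at a time to control abundance
(factor 1), rebuilds from the reference, and compares resting steady
states (optionally full titrations) against the un-rectified case and the
full control; rectifying all groups reproduces the control model exactly.

Coverage diagnostics: the QC score is the percentage of model-mapped
proteins found in a profile; the QSM score is the mean over scalable
reactions of (mapped proteins found / isoform slots) × 100. Redundant
isoforms share a slot, so complete profiles can exceed 100% — which is why
a well-covered proteome can report a QSM above 100 while 75% remains the
suitability cutoff. Both formulas are package definitions, since only the
scores' names, cutoffs and reported ranges are public.

# Orchestration and reproducibility

`runPipeline()` executes simulate → average → impute → PCA →
differential → ranking → enrichment → proteome-scaled model → titration →
rectification from a single config (list, YAML or JSON), writes every
table as TSV, and emits a JSON manifest with the effective config, the
seed and an md5 checksum per artifact; reruns with the same config and
seed reproduce identical checksums. All stochastic steps take explicit
seeds; generation is bit-reproducible.

Problem sizes used by the test-suite benchmarks are the package's own
choices: 2,000-protein, 6 vs 6 null datasets (200 replicates) for
family-wise error calibration; a 1,000-protein dataset with a 20-protein
depleted pathway for effect-recovery and enrichment power; 30-axon volumes
at signal-to-noise 10 for imaging recovery; $10^5$ draws for tail
calibration.

# Known limitations

* Tier-2 imputation is stochastic regression, not full posterior draws
  with predictive-mean matching; with very few samples its uncertainty is
  understated.
* The reduced kinetic network makes directional, not quantitative,
  predictions; absolute fluxes and concentrations are not comparable to a
  genome-scale bioenergetic model, and calcium/ROS dynamics and glycolysis
  beyond a lumped supply term are out of scope.
* The imaging module consumes label masks; it does not segment or trace
  axons.
* The enrichment module adopts classic GSEA conventions where the original
  analysis tool's internals are unpublished; NES values are comparable
  within this package, not across tools.
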