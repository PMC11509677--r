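---
title: "Models and methods behind caviprox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caviprox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caviprox)
```

This vignette explains the statistical models, numerical choices and design
decisions in `caviprox`, and what the synthetic-data tests do and do not
demonstrate about real data.

## The experimental design and the spatial-ruler model

The design is four groups in triplicate: a Cav1–APEX2 bait profiled under
iso-osmotic control (NT), a 5-minute hypo-osmotic shock (HYPO) and a
30-minute recovery (REC), plus a cytoplasmic NES–APEX2 reference profiled
under NT. APEX2 biotinylates everything within ~20 nm, so the raw bait
proteome is dominated by abundant cytoplasmic proteins. Rather than
subtracting a blank, each Cav1 condition is *tested against the NES
reference*: a protein is interesting only if it is captured by the bait in
excess of its capture by a free cytoplasmic probe. All enrichment statistics
in the package are therefore two-group contrasts on log2 LFQ intensities,
with the NES group as the denominator.

## Pre-statistics processing

**Raw zeros are missing.** MaxQuant writes 0 for "not identified". We map
zeros to `NA` at read time, because the downstream replicate-presence rule
is a *presence* rule: treating 0 as an intensity would both corrupt
variances and make the presence rule vacuous.

**Presence filtering.** A protein is retained iff some (bait, condition)
group has at least *k* non-missing replicates, with *k* defaulting to the
full group size (all three replicates of at least one group). "Group" here
is a bait-condition combination; with one replicate per run this is the only
reading consistent with a triplicate design. The filter is idempotent and
is property-tested against a brute-force evaluation of the rule.

**Imputation is off by default.** Down-shifted normal imputation
(per sample column: Normal(mean − 1.8·sd, (0.3·sd)²), the widely used
Perseus defaults) is provided because contrasts in which one group is
entirely missing are otherwise untestable — a real phenomenon here, since
HYPO-recruited proteins can be absent from all NES runs. We keep it off by
default and flag untestable proteins instead, because silent imputation
manufactures degrees of freedom; both modes are reported when used.

## The moderated t-test

For a contrast between groups of sizes $n_1, n_2$ (non-missing values per
protein), with pooled residual variance $s_g^2$ on $d_g = n_1+n_2-2$ df,
the empirical-Bayes model places a scaled inverse-chi-squared prior
$(d_0, s_0^2)$ on the true variances, giving the posterior variance

$$ s_{post}^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t = \frac{\overline{x}_1 - \overline{x}_2}
            {\sqrt{s_{post}^2 (1/n_1 + 1/n_2)}} $$

referred to a t distribution on $d_0 + d_g$ df, two-sided. The prior is
estimated by moment matching on log variances: the marginal of $s_g^2$ is a
scaled F, so the mean and spread of $\log s_g^2$, bias-corrected with
digamma/trigamma terms for the $\chi^2_{d_g}$ sampling noise, identify
$(d_0, s_0^2)$; the trigamma equation is inverted by Newton iteration. When
the observed spread of log variances does not exceed the sampling
contribution, $d_0$ is infinite; we represent infinity by the documented cap
$10^6$ and return the (geometric-mean) common variance as $s_0^2$. The
estimator is cross-checked in the tests against limma's independent
implementation, and `d0 = 0` provably reduces the statistic to the ordinary
pooled t.

The prior is fitted on within-group residual variances pooled over **all
four groups** (more degrees of freedom per protein), then applied to each
two-group contrast. We deliberately use per-contrast two-group pooled
variances rather than one four-group linear model: with group-specific
missingness, a single model either drops proteins missing in any group or
imputes; the pairwise approach keeps every contrast that has two observed
values per side. This can shift borderline calls relative to a
single-linear-model analysis, which we note as the main source of
count-level differences between otherwise-equivalent implementations.

Proteins with fewer than two present values in either contrasted group are
marked `testable = FALSE`, never dropped and never given p = 0.

## Calls, classification and z-profiles

A protein is *enriched* in a condition iff it is testable, p < 0.05 and
logFC > 0, both inequalities strict — a volcano-plot rule combining a
two-sided p with a one-directional sign criterion. Raw p-values are used by
default; a Benjamini–Hochberg mode (`use_q = TRUE`) is available as a
stricter option. The three boolean calls put each protein into one of the
2³ membership categories; all eight raw categories are preserved so that any
coarser reading (e.g. whether "HYPO-exclusive" includes the triple
intersection) can be reconstructed. The *co-recovered* set is defined as
NT∩REC plus NT∩HYPO∩REC — proteins enriched at rest and after recovery,
with or without enrichment under shock, since the defining property is
re-association after the tension pulse.

Z-score profiles standardise each protein row to mean 0, sd 1 (sample sd,
n−1 denominator) over non-missing entries, either per sample or per
condition mean; rows with fewer than two distinct values are flagged
undefined rather than zero-filled, and missing entries stay flagged — in
the heatmap they mean "not identified", which is information, not noise.

## Network assembly and over-representation

Edge tables are consumed as files (BioGRID-style export, STRING link export,
two-column literature list); there are no live database queries. Evidence
filters mirror standard practice for physical interactomes: BioGRID rows
whose experimental system is Affinity Capture-RNA, Protein-RNA or Proximity
Label-MS are disregarded, and STRING edges require confidence strictly
greater than 0.4 (scores on the 0–1000 scale are normalised to [0, 1]).
Accessions are matched case-insensitively and exactly; identifier-mapping
services are out of scope, so mixed-namespace inputs are the user's
responsibility. Edges found in several sources merge into one edge with a
provenance union; the exported `line_type` attribute (solid = database,
dotted = literature-only) matches the usual network-figure legend.

Over-representation uses the hypergeometric upper tail
$p = P(X \ge k)$ with BH adjustment across sets. The default universe is
**all proteins surviving the presence filter**, not the whole proteome:
proximity proteomics only sees detectable proteins, and an
all-proteome background would inflate every term populated by abundant
proteins.

## Image statistics

Coordinates are row-major with origin top-left and pixel centres at integer
coordinates; areas are in pixels, with `pixel_size_um` carried alongside for
micrometre reporting.

The polarity axis is the principal axis of the mask's second moments. The
rear pole is chosen as the brighter half's pole (caveolae mark the rear), or
by an explicit `rear_hint`; masks with axis ratio below 1.05 are refused as
ambiguous rather than silently oriented. Equal-sized rear/front regions are
built by ordering cell pixels along the axis and taking the rear-most and
front-most ⌊n/2⌋ — this guarantees the "equal size area" property to ±1
pixel for arbitrary mask shapes. The rear-localisation index is the ratio of
background-subtracted region means; it is scale-invariant and exactly 1 on
symmetric images.

Line-scan profiles take cell pixels within half the line width (default 50
pixels, the conventional wide-line setting) of the axis line, project them
onto the axis, and average per integer position; quadrant means average the
same pixels within four equal-length segments ordered rear → front.

PLA dots are connected components (8-connectivity; the labeller explicitly
bridges diagonal contacts) of the Gaussian-smoothed image above
mean + k·sd of the in-mask smoothed intensities, filtered by area and
assigned to the cell containing their centroid. The default k = 5 is chosen
from the detection model itself: smoothing leaves correlated background
noise whose suprathreshold excursions at k ≈ 3 form spurious
minimum-area components, while planted dots of realistic contrast exceed
5 sd comfortably; a pure-background image should and does yield zero
components at the default. Two dots closer than the smoothing scale merge
into one component — documented, tested, and tunable via `sigma`. The exact
ImageJ thresholding recipe behind published PLA counts is not specified
anywhere, so these defaults are calibrated on the synthetic fixtures only.

Pearson colocalisation is the plain correlation over in-mask pixels, with
zero-variance channels refused; it is invariant under positive affine
intensity transforms, which the tests verify.

## Track statistics and the persistent random walk

Speed defaults to path length / duration over the frame-to-frame polyline,
the common convention in track-analysis packages; mean instantaneous step
speed is exposed as an alternative because tools differ and the two diverge
on irregular tracks. Straightness is displacement / path length, flagged
undefined for stationary tracks. The MSD estimator pools all overlapping
ordered pairs across tracks at each lag (ensemble-time average) and reports
pair counts; tracks shorter than 3 samples are excluded with a logged count,
and non-uniform sampling is an error rather than a silent approximation.

The synthetic generator simulates each velocity component as an
Ornstein–Uhlenbeck process with persistence time P and stationary speed
scale S (⟨|v|²⟩ = S²). Per frame we draw the *exact joint* Gaussian
transition of (position increment, velocity) — not an Euler approximation —
so the sampled points are the continuous process observed at the frame
times and the ensemble MSD matches the Fürth form
MSD(τ) = 2S²P(τ − P(1 − e^(−τ/P))) in expectation at every lag. Defaults
(S = 0.4 µm/min, P = 10 min, 5-min frames, 73 frames ≈ 6 h) reflect typical
epithelial translocation rates and imaging schedules. `fit_furth` estimates
(S, P) by Levenberg–Marquardt least squares; a persistence estimate at the
documented bound of 10⁴ min flags a ballistic-regime curve in which P is not
identifiable. Finite sampling biases the *path* speed of an OU walk downward
(the polyline under-samples curvature); the tests characterise this bias and
its disappearance as the frame interval shrinks (E|v| = S√π/2 for the 2-D
Gaussian speed distribution), rather than hiding it.

## The synthetic-data generators as study conditions

The LFQ generator plants five interactor classes with fixed log2
enrichments over NES — core caveolar (NT = 3, HYPO = 0, REC = 3), weaker
co-recovered (2, 0, 2), shock-recruited (0, 2.5, 0), shock-and-recovery
(0, 2.5, 2.5) and background (0, 0, 0) at fractions 5/5/5/3/82% — on
per-protein baselines N(25, 2²) log2 units with replicate noise sd 0.5 and
left-censoring below 22. These values are the package's chosen study
conditions: baseline location and spread match typical LFQ log2-intensity
distributions, replicate sd 0.5 is a mid-range label-free reproducibility
figure, effect sizes ≥ 2 log2 units reflect the strong enrichments proximity
labelling produces for true interactors, and the detection limit is placed
to censor a realistic high-single-digit percentage of values from the lower
tail — enough that missingness is a live concern without crippling the
design. Censoring at a fixed log2 limit makes the missingness
mechanism missing-not-at-random, matching how detection limits act in LFQ
data; a `mcar_rate` switch adds completely-at-random dropout for robustness
testing.

What the generators do **not** emulate: peptide-level roll-up and its
correlated errors, between-sample normalisation artefacts, batch and
run-order effects, interactor intensities correlated with abundance, a real
microscope PSF or uneven illumination, cell segmentation errors (masks are
inputs), and heterogeneous per-cell behaviour in tracks. Passing the
planted-truth tests therefore demonstrates the *correctness of the
computations* under a clean generative model, not the field performance of
the thresholds on any particular instrument's data.

Problem sizes in the tests and acceptance checks — 2,000-protein
experiments, 5,000 simulated variances, 50 image seeds, 200 tracks — are
chosen so that Monte-Carlo error is small against the stated tolerances
while the whole suite runs in well under a minute per module.

## Repository shape

The package is organised as an analysis workflow: `analysis/01…05` are thin
narrative drivers that generate data, run each stage and write tables under
`results/`, while every computation lives in the package's exported
functions, where the tests and `scripts/acceptance.R` exercise it. The
end-to-end orchestration is likewise exposed as functions
(`run_proteomics_pipeline`, `run_demo`) rather than a shell CLI, which is
the natural interface for an R analysis of this kind.

## Known limitations

- No identifier mapping: accession mismatches across edge tables, gene sets
  and the proteome silently reduce overlaps.
- The per-contrast pooled-variance model can disagree at the margins with a
  single four-group linear model (see above); both are defensible readings
  of a moderated-t analysis, and borderline category counts shift
  accordingly.
- PLA counting merges dots closer than the smoothing scale and has no
  intensity-based splitting.
- The GO-style over-representation test is generic: supplied gene sets are
  used as-is, with no ontology-aware propagation.
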