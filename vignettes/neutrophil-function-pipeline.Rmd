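---
title: "Automated analysis of a neutrophil phagocytosis and phagosomal acidification assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated analysis of a neutrophil phagocytosis and phagosomal acidification assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoflow)
```

## The assay and what this package computes

Severely injured patients frequently develop infectious complications in
the first weeks after trauma, and no routine biomarker identifies who is at
risk while there is still time to act. Neutrophils are the first line of
defence: they ingest microbes (phagocytosis) and destroy them inside the
phagolysosome, a process that depends on rapid acidification of that
compartment. Both steps can be read out in whole blood on an automated
flow cytometer using *S. aureus* bioparticles that carry two fluorochromes:

* **PF520**, pH-insensitive — its signal reports how many particles a cell
  has ingested;
* **pHrodo Green**, pH-sensitive — its fluorescence *rises* as the
  phagolysosomal pH falls.

`phagoflow` implements the full analysis chain for this assay:

1. **FCS I/O** — a minimal FCS 3.0/3.1 listmode reader/writer with a
   user-supplied map from instrument parameter names to the six semantic
   channels (FSC, SSC, CD16, CD62L, PHRODO, PF520).
2. **Gating** — granulocytes from a bivariate Gaussian mixture on
   untransformed FSC/SSC; neutrophils as CD16-positive granulocytes
   (excluding CD16-negative eosinophils) via a density-valley cut on
   asinh-transformed CD16; the three CD16/CD62L subsets
   (CD16^dim^/CD62L^bright^ banded cells, CD16^bright^/CD62L^bright^
   mature cells, CD16^bright^/CD62L^dim^ activated cells) by scalar
   dim/bright cuts.
3. **Function metrics** — phagocytosis as the percentage of
   PF520-positive neutrophils, and acidification as the per-cell ratio
   $r_i = \mathrm{pHrodo}_i / \mathrm{PF520}_i$ averaged over
   PF520-positive neutrophils. Dividing by the pH-insensitive channel
   cancels particle number, leaving a pure acidification readout.
4. **Cohort statistics** — GEE over the study days, per-day rank tests,
   healthy-control reference bands, subset ANOVA with Tukey follow-up,
   and baseline exact tests.
5. **Synthetic data** — a generator that emulates the assay end to end
   and supplies per-event ground truth.

## Gating model and its numerical choices

The original assay was gated by visual estimation by two researchers; a
standardized strategy was explicitly left as future work. This package is
that standardization, with a manual mode for replaying fixed thresholds.

**Scatter.** A 3-component bivariate Gaussian mixture (unconstrained
covariances) is fitted to (FSC, SSC), and components are assigned by
ascending side-scatter centre to lymphocytes, other mononuclear cells and
granulocytes. Events below a configurable low FSC quantile (default
0.001) of the fitted lymphocyte component are labeled debris. Mixture
initialisation uses a quantile-spaced subset of events (default 1500), so
gating is fully deterministic for a given table and configuration — no
random seed enters the algorithm. The 3-component model presumes a
roughly physiological population balance; grossly aberrant samples (for
instance a nearly pure granulocyte preparation) can split the dominant
population across components, which is why the manual polygon mode
exists and why per-sample thresholds are logged for review.

**Fluorescence transform.** Marker and bioparticle channels are
transformed with `asinh(x / 150)` before any threshold is placed; ratios
and MFIs are always computed on untransformed intensities, because the
particle-number correction argument assumes linear signals. The cofactor
(150) is conventional for this class of cytometer and configurable per
channel.

**Threshold placement.** All scalar cuts (CD16-positive, CD16 and CD62L
dim/bright, PF520-positive without a reference sample) use the same rule:
a Gaussian-kernel density (bandwidth `nrd0`, 512 grid points) is scanned
for local maxima; peaks shorter than 1% of the tallest are ignored as
noise, and adjacent peaks whose intervening minimum does not drop below
half the smaller peak are treated as ripples on a single mode; the cut
is the deepest minimum between the lowest-intensity mode
(the negative or dim population) and the next mode above it. For a
bimodal distribution this is simply the valley between the two modes; it
is stated this way because the positive population itself is often
multimodal — discrete particle counts produce brightness sub-modes — and
the discriminating boundary must stay at the negative/positive edge
rather than wander between sub-modes. If no second mode is detectable
the cut falls back to a configurable quantile (default 0.05). Events
exactly on a cut go to the bright/positive side — a fixed, testable
convention.

**PF520 positivity.** When a negative reference acquisition is available
(on ice, or the earliest time point), the cut is its 99.5th percentile of
transformed PF520; otherwise the valley rule above. MFIs are summarised
over PF520-positive neutrophils by default (configurable to all
neutrophils); the arithmetic mean is the primary summary with a median
option, mirroring an ambiguity between the main-text and supplementary
definitions of "MFI" in the assay's original description — the mean is
primary here, and the choice is surfaced rather than hidden.

## Cohort statistics

Metrics at the 60-minute incubation point feed the cohort layer, one row
per patient × day:

* **GEE** (`fit_gee`): identity link, Gaussian working variance,
  exchangeable working correlation clustered on patient, robust sandwich
  standard errors. The mean structure is group + categorical day — the
  simplest structure consistent with a single reported group coefficient
  β — with an optional group × day interaction. The moment estimators
  for dispersion and the exchangeable correlation follow the classical
  Liang–Zeger construction; with a single time point the fit degenerates,
  deliberately and flaggedly, to the group-mean difference. The fitter is
  implemented in the package and is verified in the test suite against an
  independent marginal-model implementation on a frozen fixture, and by
  parameter-recovery simulation.
* **Per-day tests** (`per_timepoint_test`): Mann-Whitney U, exact (no
  ties, combined n ≤ 12) or normal approximation with tie and continuity
  corrections. Rank tests are primary; a t-based per-day option exists
  because the original figure legends and methods text disagree on this
  point.
* **Reference band** (`reference_band`): the healthy-control "95%
  confidence interval" is not defined in the original description; this
  package states its choice: mean ± t₀.₉₇₅,ₙ₋₁ · SD/√n of the control
  values.
* **Baseline tests** (`baseline_tests`): Fisher's exact test (2×2 by
  hypergeometric tail summation; 2×k via the Freeman–Halton extension)
  for categorical covariates, Mann-Whitney for continuous ones.
* **Subset comparison** (`subset_anova`): one-way ANOVA with Tukey HSD on
  per-subset mean ratios; zero within-group variance is reported as a
  flagged p-value floor rather than a numerical artefact.

## What the generator emulates — and what it does not

`synth_config()` encodes the study conditions:

* **Populations** in scatter space (fractions 2% debris, 30% lymphocyte,
  8% monocyte, 60% granulocyte) with cluster separations of ≥ 6
  within-cluster SDs, matching the visually separable populations the
  assay relies on. Eosinophils are 5% of granulocytes and CD16-negative.
* **Subsets** at 5% / 85% / 10% (banded / mature / activated), the
  physiological resting distribution, with log-normal CD16/CD62L whose
  modes are well separated after transformation.
* **Uptake**: each neutrophil ingests k ~ Poisson(λ(t, T)) particles with
  λ(t, T) = λ₆₀ · (1 − e^{−t/τ}) / (1 − e^{−60/τ}) · Q₁₀^{(T−30)/10},
  λ₆₀ = 1.5 at the 30 °C assay temperature, τ = 25 min, Q₁₀ = 2 —
  saturating in time and strictly increasing in temperature, which
  reproduces the assay's reported temperature sensitivity of
  phagocytosis.
* **Fluorescence**: each particle contributes one log-normal brightness
  to PF520; the same particle's pHrodo contribution is that brightness
  times a logistic pH response f(pH) = 1/(1 + e^{(pH−6.5)/0.35})
  (midpoint 6.5, strictly decreasing — only the monotone direction is
  physically constrained, so the curve parameters are surfaced in the
  configuration). The per-cell ratio is therefore f(pH) up to noise,
  independent of particle count — precisely the property the assay's
  ratio metric is designed to exploit. Cells with k = 0 carry only
  log-normal autofluorescence, placed low enough that the positivity cut
  is recoverable.
* **Trajectories**: phagosomal pH approaches a group- and day-specific
  steady state, pH(t) = 7.3 − (7.3 − pH_end)·(1 − e^{−t/15}). The
  steady-state table encodes the study's qualitative finding: the
  infection group acidifies strongly on days 0–3 (pH_end ≈ 5.6–5.7) and
  relaxes to low-normal from day 6; the no-infection group is normal
  early (6.25–6.3) and acidifies during days 6–15 (≈ 5.9). Healthy
  controls sit at 6.3. Patient-level (SD 0.08) and day-level (SD 0.04)
  pH offsets create realistic between-subject variation and
  within-patient correlation; banded neutrophils acidify best (subset
  pH offsets −0.25 / 0 / +0.05), mirroring the reported subset ordering.
* **Cohort design**: 6 infection / 9 no-infection patients — the study's
  split — sampled at days 0, 3, 6, 10, 15 and incubation times 10, 20,
  40, 60 min; 10 healthy controls (their number was not reported; 10 is
  this package's default) drawn once.

The generator does **not** simulate instrument electronics, fluidics,
doublets, spectral spillover, or the overlap between PF520-positive and
-negative populations seen on the real instrument. Passing the recovery
tests therefore demonstrates that the algorithms are correct under the
stated statistical structure, not that they would gate arbitrarily messy
clinical samples; the manual/replay mode is the escape hatch for such
samples.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run reduced designs chosen
as the smallest sizes at which each property is sharply testable:
single-sample recovery at 10,000 events; subset recovery at ~20,000
neutrophils; GEE calibration over 200 simulated cohorts of 8 patients per
group over 5 days; the full-cohort qualitative pattern at 4,000 events
per sample with the 60-minute incubation only. Exact-test agreement is
enumerated exhaustively for all 4-vs-5 rank splits and all 2×2 tables
with cells 1..3.

## A worked example

```{r example, eval = FALSE}
library(phagoflow)

# simulate the default cohort (in memory; dir = "..." writes FCS files)
coh <- simulate_cohort(synth_config(seed = 1, n_events = 4000),
                       times = 60, dir = NULL)

# run the pipeline: gate, metrics, cohort statistics
res <- run_pipeline(coh$sheet, samples = coh$samples,
                    config = run_config(seed = 1))

res$stats$gee$mean_acid_ratio      # group effect on acidification
res$stats$bands$mean_acid_ratio    # healthy-control reference band
res$stats$trajectories$mean_acid_ratio
```

## Known limitations

* The scatter gate assumes three resolvable mononuclear/granulocyte
  components plus low-lying debris; monocytes are not specifically
  identified (a monocyte marker would be required, as the assay's
  original description also notes).
* Auto thresholds are re-fitted per sample; whether fixed per-study cuts
  would be preferable is a design question surfaced in the configuration
  (`gate_config` + threshold replay), not answered by the package.
* No absolute pH calibration is attempted — the ratio is a relative
  acidification index.
* The GEE assumes an exchangeable working structure; with 5 time points
  and ≤ 9 patients per group, richer structures are not estimable
  anyway, and the sandwich errors remain valid under misspecification.
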