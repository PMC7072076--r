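# phagoflow

Analysis pipeline for a whole-blood flow-cytometry assay of neutrophil
function, built for monitoring severely injured (trauma) patients in the
ICU. The assay incubates whole blood with *S. aureus* bioparticles that
carry a pH-insensitive fluorochrome (PF520, reporting particle load) and a
pH-sensitive one (pHrodo Green, brighter as the phagolysosome acidifies),
plus CD16/CD62L antibodies for neutrophil subset phenotyping. From the
resulting FCS listmode files the package computes, per sample:

* **phagocytosis** — the percentage of PF520-positive neutrophils;
* **phagosomal acidification** — the mean over PF520-positive neutrophils
  of the per-cell ratio *r* = pHrodo / PF520, which cancels particle
  number and isolates acidification;
* **subset percentages** — CD16<sup>dim</sup>/CD62L<sup>bright</sup>
  (banded), CD16<sup>bright</sup>/CD62L<sup>bright</sup> (mature),
  CD16<sup>bright</sup>/CD62L<sup>dim</sup> (activated) neutrophils;
* **channel MFIs** over the same cells.

A longitudinal cohort layer then compares patients who develop infectious
complications with patients who do not: generalized estimating equations
(identity link, exchangeable working correlation, robust SEs clustered on
patient) for the group effect β over study days {0, 3, 6, 10, 15},
Mann-Whitney tests per day, healthy-control reference bands
(mean ± t·SD/√n), one-way ANOVA with Tukey HSD across subsets, and
Fisher-exact / rank tests for the baseline table. A synthetic-cytometry
generator emulates the whole assay — scatter populations, subset
structure, Poisson particle uptake, pH-dependent fluorescence, and the two
groups' opposite acidification trajectories — and provides per-event
ground truth for every stage.

## Worked example

```r
library(phagoflow)

coh <- simulate_cohort(synth_config(seed = 1, n_events = 4000),
                       times = 60, dir = NULL)   # 6 + 9 patients, 10 controls
res <- run_pipeline(coh$sheet, samples = coh$samples,
                    config = run_config(seed = 1))

res$stats$gee$mean_acid_ratio
#> GEE (exchangeable working correlation, robust SE): beta = -0.109, SE = 0.02049, p = 1.04e-07
#>   rho = 0.000, phi = 0.02966, 15 patients, 75 observations

res$stats$bands$mean_acid_ratio[c("lower", "upper")]
#> $lower
#> [1] 0.5810773
#> $upper
#> [1] 0.6452821

subset(res$stats$trajectories$mean_acid_ratio, group == "infection")
#>       group day     value position
#> 1 infection   0 0.9352424    above
#> 3 infection   3 0.9054848    above
#> 5 infection   6 0.4626009    below
#> 7 infection  10 0.4781354    below
#> 9 infection  15 0.4968319    below
```

Read: the infection group's mean acidification ratio starts far above the
healthy band (stronger-than-normal acidification immediately after
trauma), then falls below it from day 6 — while the no-infection group
does the opposite — and the GEE group effect on acidification is negative
and significant. The negative β matches the direction reported for the
clinical cohort this assay was developed on.

Single-sample use, without the cohort layer:

```r
sim <- simulate_sample(synth_config(seed = 7, n_events = 10000))
g   <- gate_sample(sim$table)             # scatter -> CD16+ -> subsets
thr <- pf520_positive_threshold(sim$table, g$neutrophil)
acidification_metrics(sim$table, g$neutrophil, thr$cut)
#> FunctionMetrics: 5753 neutrophils, 4463 PF520+ (77.6%), mean ratio 0.639
```

Real FCS files are read with `read_fcs(path, channel_map(...), meta)`;
the channel map ties instrument `$PnN` names to the six semantic channels
(FSC, SSC, CD16, CD62L, PHRODO, PF520) and can be a `key=value` file.

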