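# icprofiler

Immune-checkpoint profiling and survival stratification for multiplex
immunofluorescence tissue microarrays (TMAs).

## What this is for

Baseline tumor biopsies — here modeled on immune-enriched non-small-cell
lung cancer TMAs — are stained with multiplex immunofluorescence panels
(DAPI plus CD45, CD3 and immune checkpoints such as PD-1, TIM-3, BTLA,
CD26) and scanned core by core. `icprofiler` implements the full analysis
chain that turns those core images into prognostic biomarker claims, for
computational pathologists and biostatisticians who want every step
testable:

- **Image quantification** — tissue ROI with hole removal, per-channel
  intensity thresholds with size gates (µm²), DAPI-centered cell labels,
  2–4-marker colocalization labels, MFI, and densities per mm² of tissue,
  log10(x+1)-transformed.
- **Patient-level assembly** — replicate-core averaging (or the per-core
  alternative), dichotomization of each marker at the cohort
  **mean ± SEM** (hi / lo / excluded mid-band), ROC validation of the
  cutoffs (trapezoidal AUC = pairwise concordance, Youden optimum).
- **Survival statistics** — Kaplan–Meier, Mantel–Cox log-rank with the
  log-rank hazard ratio HR = (O₁/E₁)/(O₂/E₂) and
  CI95 = exp(log HR ± 1.96·√(1/E₁+1/E₂)); univariate Cox (Efron ties) as
  cross-check; Pearson correlation; cumulative-correlation coexpression
  ranking; Monte-Carlo and Schoenfeld log-rank power.
- **Combination discovery** — exhaustive duplex/triplex scans over
  checkpoint panels (colocalization or additive scoring, optional CD3
  anchor), global checkpoint scores, correlograms, PCA coexpression
  groups with PC-score survival stratification.
- **Interactor refinement** — the four-criterion filter for
  checkpoint-interacting proteins (experimental evidence, redundancy
  across ≥2 checkpoints, OS association, tissue support) with an
  expression-by-outcome quadrant summary, over database-agnostic TSVs.
- **Synthetic TMA generator** — 0.6 mm cores with 742 ± 163 cells,
  40 ± 25% CD45⁺ leukocytes, configurable marker prevalence and
  co-expression, rendered multichannel images with ground-truth cell
  tables, and cohorts with *planted* marker-combination hazard ratios —
  so every downstream stage has an exact oracle.

## Worked example

Simulate a cohort of 81 patients (3–5 cores each) with a planted
TIM-3/CD26 colocalization effect at hazard ratio 0.5, quantify, average
replicate cores, stratify at mean ± SEM, and test:

```r
library(icprofiler)

spec   <- image_spec(um_per_px = 1.29)
cohort <- generate_cohort(
  cohort_spec(n_patients = 81,
              planted_effects = list(planted_effect(c("TIM-3", "CD26"),
                                                    hr = 0.5))),
  spec, seed = 42)

quant <- simulate_quant_matrix(cohort, seed = 43)
mm    <- aggregate_cores(quant, cohort$core_map, method = "average")
strat <- dichotomize(combination_value(mm, c("TIM-3", "CD26"),
                                       mode = "colocalization"))
sv <- unit_survival(mm, cohort$clinical)
hi <- strat$class == "hi"; lo <- strat$class == "lo"
logrank_test(sv$months[hi], sv$event[hi], sv$months[lo], sv$event[lo])
```

This prints (seed 42):

```
n_hi=37 n_lo=44 excluded=0
chi2=7.07 p=0.007823 HR=0.518 [0.313-0.858]
```

i.e. the hi group's hazard is about half the lo group's — the planted
HR of 0.5 recovered through quantification, averaging and mean ± SEM
stratification. `rank_combinations()` runs the same machinery over every
duplex/triplex in a panel and returns a report sorted by p with BH
q-values; `generate_core_image()` + `quantify_core()` run the pixel-level
path (the noiseless renderer is an exact counting oracle — see the
methods vignette in `vignettes/`).

The numbered scripts under `analysis/` walk the whole study end to end
(simulate → quantify → stratify → survival → combination scan →
interactors) and write their tables under `results/`.

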