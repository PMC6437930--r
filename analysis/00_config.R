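# Shared configuration for the analysis scripts. Source from the
# repository root; outputs land under results/.
#
# The study conditions mirror an immune-enriched NSCLC biopsy TMA:
# 0.6 mm cores, 742 +/- 163 cells each, 40 +/- 25% CD45+ leukocytes,
# 81 patients contributing 3-5 cores. One prognostic triple combination
# (TIM-3/CD26/CD39, HR 0.5) is planted so every downstream stage has a
# known truth to recover. Images are rendered at 1.29 um/px (4x optical
# downsampling) to keep the scripts at desk scale.

library(icprofiler)

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

PANEL_PREVALENCE <- c(
  CD45 = 1, CD3 = 0.55,
  `PD-1` = 0.18, `PD-L1` = 0.15, `TIM-3` = 0.15, `LAG-3` = 0.12,
  BTLA = 0.15, TIGIT = 0.14, CD26 = 0.20, CD39 = 0.16, CD73 = 0.12,
  VISTA = 0.10, CD27 = 0.25, ICOS = 0.12)

ICPS <- setdiff(names(PANEL_PREVALENCE), c("CD45", "CD3"))
PLANTED <- c("TIM-3", "CD26", "CD39")

ISPEC <- image_spec(um_per_px = 1.29, marker_prevalence = PANEL_PREVALENCE)
CSPEC <- cohort_spec(
  n_patients = 81,
  planted_effects = list(planted_effect(PLANTED, hr = 0.5)))

SCAN_COMBOS <- c(combn(ICPS, 2, simplify = FALSE),
                 combn(ICPS, 3, simplify = FALSE))

SEED <- 20260101
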