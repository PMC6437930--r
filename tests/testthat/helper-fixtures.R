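# Shared fixtures, all generated in code.

# coarse-scale spec: full study-condition cell numbers, 1.29 um/px canvas
# (four-fold downsampled optics) to keep image tests fast
test_spec <- function(...) {
  image_spec(um_per_px = 1.29, ...)
}

# noiseless rendering: constant foreground, zero background, constant
# autofluorescence so the ROI is still detectable, no bleed-through
noiseless_spec <- function(...) {
  test_spec(intensity_fg = c(mean = 200, sd = 0),
            intensity_bg = c(mean = 0, sd = 0),
            intensity_af = c(mean = 30, sd = 0),
            bleedthrough = 0, ...)
}

# extended 14-channel panel used for combination scans (12 checkpoints)
scan_prevalence <- function() {
  c(CD45 = 1, CD3 = 0.55,
    `PD-1` = 0.18, `PD-L1` = 0.15, `TIM-3` = 0.15, `LAG-3` = 0.12,
    BTLA = 0.15, TIGIT = 0.14, CD26 = 0.20, CD39 = 0.16, CD73 = 0.12,
    VISTA = 0.10, CD27 = 0.25, ICOS = 0.12)
}

scan_icps <- function() setdiff(names(scan_prevalence()), c("CD45", "CD3"))

# all duplex + triplex subsets of the scan checkpoints
scan_combinations <- function(icps = scan_icps()) {
  c(combn(icps, 2, simplify = FALSE), combn(icps, 3, simplify = FALSE))
}

# matrix columns forming the planted coexpression block: the full
# combination, its pair subsets, and the member singles
planted_block <- function(markers) {
  c(combo_key(markers),
    vapply(combn(sort(markers), 2, simplify = FALSE), combo_key,
           character(1)),
    markers)
}

# hand-built 10-protein interaction/annotation fixture with known outcome:
# exactly ALK2, GRB2 and LCK pass all four criteria
fixture_interactions <- function() {
  data.frame(
    protein_a = c("PD-1",  "PD-1", "TIM-3", "TIM-3", "BTLA", "BTLA",
                  "GRB2",  "LCK",  "FYN",   "SHP2",  "CD26", "ALK2",
                  "ALK2"),
    protein_b = c("SHP2",  "GRB2", "GRB2",  "LCK",   "LCK",  "FYN",
                  "TIM-3", "PD-1", "CSK",   "CSK",   "ADA",  "PD-1",
                  "BTLA"),
    evidence  = c("experimental", "experimental", "predicted",
                  "experimental", "experimental", "predicted",
                  "experimental", "experimental", "experimental",
                  "experimental", "experimental", "experimental",
                  "experimental"),
    tissues   = c("lung;liver", "lung", "lung", "lung", "brain", "lung",
                  "lung", "lung", "lung", "liver", "lung", "lung",
                  "lung"),
    sources   = sprintf("PMID%02d", 1:13),
    stringsAsFactors = FALSE)
}

fixture_annotations <- function() {
  data.frame(
    protein = c("SHP2", "GRB2", "LCK", "FYN", "ADA", "ALK2",
                "PD-1", "TIM-3", "BTLA", "CD26"),
    os_association = c("none", "positive", "positive", "positive",
                       "negative", "positive", "positive", "positive",
                       "none", "positive"),
    tumor_expression = c("increased", "increased", "decreased",
                         "increased", "unchanged", "increased",
                         "increased", "increased", "decreased",
                         "increased"),
    stringsAsFactors = FALSE)
}

# exponential survival with administrative censoring, for survival-only
# simulations that bypass the image model
sim_surv <- function(n, hazard, horizon = 72) {
  t <- rexp(n, hazard)
  list(months = pmin(t, horizon), event = as.integer(t <= horizon))
}
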