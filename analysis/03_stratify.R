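#!/usr/bin/env Rscript
# Assemble patient-level matrices (replicate-core averaging and the
# per-core alternative), dichotomize every marker at mean +/- SEM, and
# validate the cutoffs by ROC against the death outcome.

source("analysis/00_config.R")

quant <- read.csv(file.path(RESULTS, "quant.csv"), check.names = FALSE)
clinical <- read.csv(file.path(RESULTS, "clinical.csv"))
core_map <- read.csv(file.path(RESULTS, "core_map.csv"))

for (method in c("average", "per_core")) {
  mm <- aggregate_cores(quant, core_map, method = method)
  message(sprintf("method=%s: %d analysis units x %d marker keys", method,
                  nrow(mm$values), ncol(mm$values)))
  write.csv(data.frame(unit_id = mm$unit_id, patient_id = mm$patient_id,
                       mm$values, check.names = FALSE),
            file.path(RESULTS, sprintf("matrix_%s.csv", method)),
            row.names = FALSE)
}

mm <- aggregate_cores(quant, core_map, method = "average")
sv <- unit_survival(mm, clinical)

strat <- do.call(rbind, lapply(colnames(mm$values), function(key) {
  st <- dichotomize(mm$values[, key], mm$unit_id)
  data.frame(marker = key, n_hi = attr(st, "n_hi"),
             n_lo = attr(st, "n_lo"), n_excluded = attr(st, "n_excluded"),
             cutoff_lo = attr(st, "cutoff_lo"),
             cutoff_hi = attr(st, "cutoff_hi"))
}))
write.csv(strat, file.path(RESULTS, "stratification.csv"),
          row.names = FALSE)
message(sprintf(
  "mean +/- SEM stratification: median group sizes hi=%d lo=%d excluded=%d of %d",
  median(strat$n_hi), median(strat$n_lo), median(strat$n_excluded),
  nrow(mm$values)))

roc <- do.call(rbind, lapply(c("CD3", PLANTED, combo_key(PLANTED)),
                             function(key) {
  st <- dichotomize(mm$values[, key], mm$unit_id)
  r <- roc_validate(mm$values[, key], sv$event,
                    cutoffs = c(hi = attr(st, "cutoff_hi"),
                                lo = attr(st, "cutoff_lo")))
  data.frame(marker = key, auc = r$auc,
             youden_cutoff = r$youden$cutoff,
             sens_at_hi = r$at_cutoffs$sens[1],
             spec_at_hi = r$at_cutoffs$spec[1])
}))
write.csv(roc, file.path(RESULTS, "roc_validation.csv"), row.names = FALSE)
message(sprintf("ROC: planted combination %s AUC = %.3f",
                combo_key(PLANTED),
                roc$auc[roc$marker == combo_key(PLANTED)]))
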