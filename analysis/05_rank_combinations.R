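#!/usr/bin/env Rscript
# Discovery stage: exhaustive duplex/triplex combination scan in both
# scoring modes, global checkpoint scores, the coexpression correlogram,
# and PCA coexpression groups with PC-score survival stratification.

source("analysis/00_config.R")

quant <- read.csv(file.path(RESULTS, "quant.csv"), check.names = FALSE)
clinical <- read.csv(file.path(RESULTS, "clinical.csv"))
core_map <- read.csv(file.path(RESULTS, "core_map.csv"))
mm <- aggregate_cores(quant, core_map, method = "average")

for (mode in c("colocalization", "additive")) {
  rep <- rank_combinations(mm, clinical, ICPS, sizes = c(2, 3),
                           mode = mode)
  write.csv(rep, file.path(RESULTS, sprintf("combinations_%s.csv", mode)),
            row.names = FALSE)
  rk <- which(rep$combination == combo_key(PLANTED))
  message(sprintf(
    "%s scan: %d combinations; planted %s ranks #%d (p = %.2e, HR = %.2f)",
    mode, nrow(rep), combo_key(PLANTED), rk, rep$p[rk], rep$hr[rk]))
}

gs <- global_score(mm, ICPS)
write.csv(gs, file.path(RESULTS, "global_score.csv"), row.names = FALSE)
st <- dichotomize(gs$sum_score, gs$unit_id)
sv <- unit_survival(mm, clinical)
hi <- st$class == "hi"; lo <- st$class == "lo"
lr <- logrank_test(sv$months[hi], sv$event[hi],
                   sv$months[lo], sv$event[lo])
message(sprintf(
  "global checkpoint sum score: %dhi vs %dlo, log-rank p = %.4f, HR = %.2f",
  lr$n_hi, lr$n_lo, lr$p, lr$hr))

cg <- correlogram(mm, ICPS)
write.csv(data.frame(marker = rownames(cg$r), cg$r, check.names = FALSE),
          file.path(RESULTS, "correlogram.csv"), row.names = FALSE)
message(sprintf("strongest coexpressed pair: %s / %s (r = %.3f)",
                cg$top_pair[1], cg$top_pair[2],
                cg$r[cg$top_pair[1], cg$top_pair[2]]))

pg <- pca_groups(mm, markers = ICPS, n_components = 2)
grp <- do.call(rbind, lapply(pg$groups, function(g)
  data.frame(component = g$component,
             members = paste(g$members, collapse = ";"),
             variance = pg$variance_proportion[g$component])))
write.csv(grp, file.path(RESULTS, "pca_groups.csv"), row.names = FALSE)
pc <- pc_survival(pg$scores[, 1], mm, clinical)
message(sprintf(
  "PC1 group {%s}: %.0f%% variance; PC1-hi log-rank p = %.4f, HR = %.2f",
  grp$members[1], 100 * grp$variance[1], pc$p, pc$hr))
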