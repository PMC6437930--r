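#!/usr/bin/env Rscript
# Simulate the study cohort: clinical table, core-to-patient map, latent
# combination truth, and a few rendered example core images.

source("analysis/00_config.R")

coh <- generate_cohort(CSPEC, ISPEC, seed = SEED)

write.csv(coh$clinical, file.path(RESULTS, "clinical.csv"),
          row.names = FALSE)
write.csv(coh$core_map, file.path(RESULTS, "core_map.csv"),
          row.names = FALSE)
write.csv(coh$truth, file.path(RESULTS, "truth.csv"), row.names = FALSE)

message(sprintf("cohort: %d patients, %d cores, %.0f%% events",
                nrow(coh$clinical), nrow(coh$core_map),
                100 * mean(coh$clinical$event)))
message(sprintf("latent %s prevalence: %.2f", combo_key(PLANTED),
                mean(coh$truth[[combo_key(PLANTED)]])))

# render two example cores (one latent-positive, one negative patient)
# as multichannel TIFFs with ground-truth cell tables
dir.create(file.path(RESULTS, "cores"), showWarnings = FALSE)
status <- coh$truth[[combo_key(PLANTED)]]
examples <- c(coh$clinical$patient_id[which(status == 1)[1]],
              coh$clinical$patient_id[which(status == 0)[1]])
for (pid in examples) {
  cid <- coh$core_map$core_id[coh$core_map$patient_id == pid][1]
  ci <- generate_core_image(ISPEC, coh$profiles[[pid]],
                            seed = SEED + match(pid, examples),
                            core_id = cid)
  write_core_tiff(ci, file.path(RESULTS, "cores", paste0(cid, ".tif")))
  write.csv(ci$cells, file.path(RESULTS, "cores", paste0(cid, "_cells.csv")),
            row.names = FALSE)
  message(sprintf("rendered %s: %d cells, %.3f mm2 tissue", cid,
                  nrow(ci$cells), ci$area_mm2))
}

panel <- default_panel(ISPEC, combinations = SCAN_COMBOS)
write_panel_config(panel, file.path(RESULTS, "panel.yaml"))
message("wrote clinical/core map/truth tables, example cores and panel config")
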