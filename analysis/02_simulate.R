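#!/usr/bin/env Rscript
# Step 2 — synthetic study materials.
#
# Generates the seeded synthetic inputs the downstream analyses consume:
# a 200-rule catalog carrying the published presentation-type mix
# (39/39/22) and general-category mix as planted ground truth, an EMR
# capability profile over the synthetic field pool, and a small patient
# panel. Writes:
#   results/synthetic_catalog.yaml
#   results/synthetic_profile.yaml
#   results/synthetic_patients.json

suppressMessages(library(pgxcds))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L

catal <- gen_rule_catalog(seed = seed, n = 200)
save_catalog(catal, "results/synthetic_catalog.yaml")
gt <- table(catal$metadata$ground_truth$presentation)
cat("Generated", length(catal), "rules; planted labels:\n")
print(gt)

prof <- gen_capability_profile(seed = seed + 1)
save_profile(prof, "results/synthetic_profile.yaml")
statuses <- vapply(prof$entries, function(e) e$status, character(1))
cat("\nProfile field statuses:\n")
print(table(statuses))

patients <- lapply(1:20, function(i) gen_patient(seed = seed + 100 + i))
json <- jsonlite::toJSON(lapply(patients, function(p) {
  list(patient_id = p$patient_id, age = p$age, sex = p$sex,
       medications_active = p$medications_active,
       disease_statuses = p$disease_statuses,
       germline_genotypes = p$germline_genotypes)
}), auto_unbox = TRUE, pretty = TRUE, null = "null")
writeLines(json, "results/synthetic_patients.json")
cat("\nWrote", length(patients), "synthetic patients.\n")
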