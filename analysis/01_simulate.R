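#!/usr/bin/env Rscript
# Step 1: generate the synthetic claims database the analysis runs on.
#
# The generator emulates the structure of a Japanese employee health
# insurance claims database: month-stamped diagnoses carrying (ICD-10,
# standard disease name) pairs, day-stamped ATC-coded prescriptions, ~62%
# women, mean age ~44, and ~14%/year enrolment attrition. 300 Population 1
# and 150 Population 2 members are planted with exactly qualifying claim
# patterns so step 2 can assess recovery.

suppressPackageStartupMessages(library(coughcohort))

out_dir <- "results/claims"
cfg <- sim_config(n_beneficiaries = 20000L, seed = 20L,
                  planted = c(p1 = 300L, p2 = 150L))
sim <- simulate_claims(cfg)

write_claims(sim$bundle, out_dir)
tr <- sim$ground_truth
tr$index <- ifelse(is.na(tr$index), "", ym_format(tr$index))
tr$dropout <- ym_format(tr$dropout)
data.table::fwrite(tr, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                   quote = FALSE)

cat(sprintf(
  "simulated %d beneficiaries: %d diagnosis claims, %d prescription claims\n",
  nrow(sim$bundle$beneficiaries), nrow(sim$bundle$diagnoses),
  nrow(sim$bundle$prescriptions)))
ben <- sim$bundle$beneficiaries
p <- study_periods()
cat(sprintf("  %.1f%% women; mean age %.1f y at selection start\n",
            100 * mean(ben$gender == "female"),
            mean((p$selection_start - ben$birth) / 12)))
cat(sprintf("  %.1f%% leave within their first year (configured 14%%)\n",
            100 * mean(sim$ground_truth$dropout <= p$study_start + 11L)))
cat("claims written under", out_dir, "\n")
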