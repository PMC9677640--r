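#!/usr/bin/env Rscript
# Step 3: longitudinal extraction.
#
# For each analysis population: cough-code persistence at Months 10-12
# (priority partition: retained original code / other cough code / disease
# code only / left the cohort), and medication-class utilisation in the
# index month and the four-week windows at Months 1, 2, 3, 6, 9, 12, split
# by central-antitussive co-prescription.

suppressPackageStartupMessages(library(coughcohort))

bundle <- read_claims("results/claims")
cb <- load_codebooks()
periods <- study_periods()
cohort <- build_cohort(bundle, cb, periods)

# persistence partitions of the cohort-defining codes
parts <- list(
  P1 = persistence_partition(population_subset(cohort, "P1"), bundle, cb,
                             "CHRONIC"),
  CVA = persistence_partition(population_subset(cohort, "CVA"), bundle, cb,
                              "CVA"),
  OTHER = persistence_partition(population_subset(cohort, "OTHER"), bundle, cb,
                                "OTHER")
)
jsonlite::write_json(parts, "results/persistence.json", auto_unbox = TRUE,
                     pretty = TRUE)
for (nm in names(parts)) {
  pp <- parts[[nm]]
  cat(sprintf(
    "%-6s enrolled %4d | evaluable %4d | retained %d (%.1f%%) | other cough %d | disease only %d | left %d\n",
    nm, pp$enrolled, pp$evaluable, pp$retained_original,
    ifelse(pp$evaluable > 0, 100 * pp$retained_original / pp$evaluable, NA),
    pp$other_cough, pp$disease_only, pp$left_cohort))
}

# medication windows for the whole cohort
med <- lapply(c(list("index"), as.list(c(1L, 2L, 3L, 6L, 9L, 12L))),
              function(k) {
                s <- medication_summary(population_subset(cohort, "All"),
                                        bundle, cb, k)
                s$classes <- as.data.frame(s$classes)
                s
              })
names(med) <- c("index", paste0("M", c(1, 2, 3, 6, 9, 12)))
jsonlite::write_json(med, "results/medication_windows.json",
                     auto_unbox = TRUE, pretty = TRUE)
idx <- med$index
cat(sprintf("index month: %d of %d members on any medication of interest; %d on central antitussives alone\n",
            idx$n, idx$n_enrolled, idx$antitussive_alone))
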