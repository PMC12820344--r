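#!/usr/bin/env Rscript
# Code the raw survey answers into the analysis-ready panel.
#
# Applies every coding and cleaning rule: the three activity-limitation
# questions define health, "working now" defines work, arthritis is an
# irreversible ever-diagnosis, obesity is BMI >= 30 from baseline height and
# per-wave weight, states map to census regions, dates are imputed at month
# resolution, time-varying gaps are filled from the nearest wave, and the
# exclusion rules are logged.

suppressPackageStartupMessages(library(hwle))

raw <- read.csv("results/raw_answers.csv", stringsAsFactors = FALSE)
panel <- prepare_panel(raw)
excl <- attr(panel, "exclusions")

write_panel(panel, "results/panel_coded.csv")
write.csv(excl, "results/exclusion_log.csv", row.names = FALSE)

cat(sprintf("Coded %d person-waves for %d persons; excluded %d persons.\n",
            nrow(panel), length(unique(panel$id)), nrow(excl)))
if (nrow(excl)) print(table(excl$reason))
desc <- descriptive_table(panel)
write.csv(desc, "results/table1_descriptives.csv", row.names = FALSE)
cat("Wrote results/panel_coded.csv, results/exclusion_log.csv, results/table1_descriptives.csv\n")
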