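#!/usr/bin/env Rscript
# Calendar-period sensitivity of the anchor prevalence.
#
# The expectancies anchor on the observed state prevalence, so this checks
# whether the prevalence of the four living states at ages 55, 60 and 65 is
# stable across survey years; a range beyond 10 percentage points in any
# state/age cell is flagged as a calendar trend.

suppressPackageStartupMessages(library(hwle))

panel <- read_panel("results/panel_coded.csv")
sens <- sensitivity_prevalence_by_wave(panel, ages = c(55, 60, 65))

write.csv(sens$prevalence, "results/sensitivity_prevalence.csv",
          row.names = FALSE)
write.csv(sens$ranges, "results/sensitivity_ranges.csv", row.names = FALSE)
cat("Overall flag:", sens$flag, "\n")
print(sens$ranges)
cat("\nInterpretation: the synthetic cohort enters in 1994-95 with the same",
    "\ninitial state mix at every entry age, so the observed mix at a fixed",
    "\nage drifts while the entry cohort equilibrates (most visible at age",
    "\n60); the transition process itself has no calendar-period effects.",
    "\nA 'trend' flag here reflects that entry artefact, which is why the",
    "\nexpectancies anchor on prevalence at age 50, where respondents are",
    "\nfresh entrants.\n")
cat("Wrote results/sensitivity_prevalence.csv, results/sensitivity_ranges.csv\n")
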