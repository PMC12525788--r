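#!/usr/bin/env Rscript
# Selection predictability: how much of the reference-defined top 5/10/15%
# of the 2023 samples the NIRS ranking captures, for each validation
# strategy (on each strategy's held-out samples only).

source("analysis/common.R")

sets <- load_study()
sc <- default_study_config()
base <- run_calibration(sets, c("2021", "2022"), sc)
strategies <- lapply(sc$expand_fractions, function(fr)
  run_validation_strategy(sets, c("2021", "2022"), "2023", fr, sc,
                          base = base))

grid <- run_selection_analysis(strategies, sc$cutoffs)
wide <- reshape(grid[, c("strategy", "cutoff_pct", "match_pct")],
                idvar = "cutoff_pct", timevar = "strategy",
                direction = "wide")
names(wide) <- c("selection_intensity_pct", "match_no_expansion",
                 "match_expand_25", "match_expand_50")
wide[-1] <- round(wide[-1])
print(wide, row.names = FALSE)
write.table(wide, file.path(RESULTS_DIR, "04_selection_matches.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message("Wrote results/04_selection_matches.tsv")
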