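#!/usr/bin/env Rscript
# Validate the pooled 2021+2022 equation on the 2023 season with three
# strategies: (a) all 2023 samples held out; (b) 25% moved into the
# calibration (refit) and 75% validated; (c) a 50/50 split. SEP is
# reported after bias correction.

source("analysis/common.R")

sets <- load_study()
sc <- default_study_config()
base <- run_calibration(sets, c("2021", "2022"), sc)

rows <- list()
for (fr in sc$expand_fractions) {
  v <- run_validation_strategy(sets, c("2021", "2022"), "2023", fr, sc,
                               base = base)
  message(sprintf(
    "expand %3.0f%%: n_val %3d, SEP %.2f, R2 %.2f, bias %+.2f",
    100 * fr, v$validation$n, v$validation$se, v$validation$r2,
    v$validation$bias))
  if (!is.null(v$cross_validation))
    rows[[paste0("cv", fr)]] <- cbind(pct_2023 = 100 * fr,
                                      report_table(v$cross_validation))
  rows[[paste0("val", fr)]] <- cbind(pct_2023 = 100 * (1 - fr),
                                     report_table(v$validation))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(RESULTS_DIR, "03_validation_strategies.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message("Wrote results/03_validation_strategies.tsv")
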