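#!/usr/bin/env Rscript
# Develop the MPLS calibrations: single-season (2021) with
# cross-validation, its external validation on 2022, and the pooled
# two-season (2021 + 2022) calibration. Spectra are preprocessed with
# SNV + detrend + second derivative (2,5,5,1) on the 1100-2498 nm window.

source("analysis/common.R")

sets <- load_study()
sc <- default_study_config()

cal21 <- run_calibration(sets, "2021", sc)
message(sprintf("2021 calibration: %d factors, SEC %.2f, SECV %.2f, 1-VR %.2f",
                cal21$model$n_factors_selected, cal21$calibration$se,
                cal21$cross_validation$se, cal21$cross_validation$r2))

# external validation of the 2021 equation on the 2022 season
proc22 <- apply_math_treatment(sets[["2022"]], sc$math_treatment)
pred22 <- predict(cal21$model, proc22$absorbance)
val22 <- summarize_evaluation(proc22$reference, pred22, "validation",
                              year = "2022")
message(sprintf("2021 equation on 2022: SEP %.2f, R2 %.2f, bias %+.2f",
                val22$se, val22$r2, val22$bias))

cal_pool <- run_calibration(sets, c("2021", "2022"), sc)
message(sprintf("pooled 2021+2022: %d factors, SEC %.2f, SECV %.2f, 1-VR %.2f",
                cal_pool$model$n_factors_selected, cal_pool$calibration$se,
                cal_pool$cross_validation$se, cal_pool$cross_validation$r2))

tab <- report_table(list(cal21$calibration, cal21$cross_validation, val22,
                         cal_pool$calibration, cal_pool$cross_validation))
write.table(tab, file.path(RESULTS_DIR, "02_calibration_statistics.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
dir.create("scratch", showWarnings = FALSE)
write_mpls_model(cal_pool$model, "scratch/pooled_model.json")
message("Wrote results/02_calibration_statistics.tsv; ",
        "pooled model serialized to scratch/pooled_model.json")
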