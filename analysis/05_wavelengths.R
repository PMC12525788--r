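#!/usr/bin/env Rscript
# Significant wavelength regions: average the second-derivative spectra of
# the 50 lowest- and 50 highest-TMQ samples of the pooled study, compute
# the per-wavelength SD between the two averages, and locate its peaks.

source("analysis/common.R")

sets <- load_study()
sc <- default_study_config()

pool <- combine_samples(sets)
wa <- run_wavelength_analysis(pool, sc, n_each = 50, top_k = 5,
                              min_separation = 20)

low_ref <- pool$reference[match(wa$low_ids, pool$sample_id)]
high_ref <- pool$reference[match(wa$high_ids, pool$sample_id)]
message(sprintf("low group: %.2f-%.2f mg/g; high group: %.2f-%.2f mg/g",
                min(low_ref), max(low_ref), min(high_ref), max(high_ref)))
message("top SD-profile peaks (nm): ",
        paste(wa$peaks$wavelength, collapse = ", "))

write.csv(data.frame(wavelength_nm = wa$profile$wavelengths,
                     sd = signif(wa$profile$sd, 6)),
          file.path(RESULTS_DIR, "05_sd_profile.csv"), row.names = FALSE)
write.csv(wa$peaks, file.path(RESULTS_DIR, "05_peaks.csv"),
          row.names = FALSE)
message("Wrote results/05_sd_profile.csv and results/05_peaks.csv")
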