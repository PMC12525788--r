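# Shared setup for the numbered analysis scripts: one root seed fixes the
# simulated study and every downstream split, so the scripts can be run
# independently and still analyse the same data.

library(nirseed)

ROOT_SEED <- 1
DATA_DIR <- "scratch/data"
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

default_config <- function() synthetic_config()
default_study_config <- function() study_config(seed = ROOT_SEED)

# Load the simulated seasons from scratch/data if 01_simulate.R has run,
# otherwise regenerate them (bit-identical, same seed).
load_study <- function() {
  files <- file.path(DATA_DIR, paste0("spectra_", c(2021, 2022, 2023), ".csv"))
  if (all(file.exists(files))) {
    sets <- lapply(files, read_spectra)
    names(sets) <- c("2021", "2022", "2023")
    sets
  } else {
    generate_study(default_config(), seed = ROOT_SEED)
  }
}
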