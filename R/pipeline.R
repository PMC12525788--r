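#' Study-level configuration
#'
#' Bundles the preprocessing recipe, cross-validation settings, factor cap,
#' expansion strategies and selection cutoffs used across the calibration,
#' validation, selection and wavelength analyses, with one root seed that
#' drives named randomness substreams (simulation / cross-validation /
#' validation splits) so strategies are compared on the same data.
#'
#' @param math_treatment a [math_treatment()]; default SNV + detrend +
#'   second derivative (2,5,5,1) on the 1100-2498 nm window.
#' @param cv_groups cross-validation group count.
#' @param max_factors latent-factor cap.
#' @param modified use the MPLS residual scaling.
#' @param expand_fractions calibration-expansion fractions of the target
#'   season used by the validation strategies.
#' @param cutoffs selection cutoffs in percent.
#' @param seed root seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(math_treatment = nirseed::math_treatment(),
                         cv_groups = 5, max_factors = 16, modified = TRUE,
                         expand_fractions = c(0, 0.25, 0.5),
                         cutoffs = c(5, 10, 15), seed = 1) {
  stopifnot(all(expand_fractions >= 0), all(expand_fractions < 1),
            all(cutoffs > 0), all(cutoffs < 100))
  structure(list(math_treatment = math_treatment,
                 cv_groups = as.integer(cv_groups),
                 max_factors = as.integer(max_factors),
                 modified = isTRUE(modified),
                 expand_fractions = expand_fractions, cutoffs = cutoffs,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognised keys mirror the [study_config()] arguments; the
#' `math_treatment` block accepts `snv`, `detrend`, `detrend_order`,
#' `window` and a `derivative: {d, gap, smooth1, smooth2}` sub-block.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  mt_args <- y$math_treatment %||% list()
  if (!is.null(mt_args$derivative) && is.list(mt_args$derivative)) {
    d <- mt_args$derivative
    mt_args$derivative <- d$d
    mt_args$gap <- d$gap %||% 5
    mt_args$smooth1 <- d$smooth1 %||% 5
    mt_args$smooth2 <- d$smooth2 %||% 1
  }
  if (!is.null(mt_args$window)) mt_args$window <- as.numeric(mt_args$window)
  args <- y[setdiff(names(y), "math_treatment")]
  args$math_treatment <- do.call(math_treatment, mt_args)
  do.call(study_config, args)
}

#' Calibrate on a pool of seasons
#'
#' Pools the requested seasons, applies the math treatment, fits the MPLS
#' calibration and cross-validates it, returning Table-shaped calibration
#' and cross-validation reports.
#'
#' @param sets named list of `spectra_set` (one per season) with
#'   reference values.
#' @param years character vector naming the seasons to pool.
#' @param config a [study_config()].
#' @return list with `model` (n_factors_selected set from
#'   cross-validation), `processed` (the processed pooled set),
#'   `calibration` and `cross_validation` reports, and the `cv` result.
#' @export
run_calibration <- function(sets, years, config = study_config()) {
  years <- as.character(years)
  if (!all(years %in% names(sets)))
    stop("unknown season(s): ",
         paste(setdiff(years, names(sets)), collapse = ", "), call. = FALSE)
  pool <- combine_samples(sets[sort(years)])
  if (is.null(pool$reference))
    stop("calibration pool has no reference values", call. = FALSE)
  processed <- apply_math_treatment(pool, config$math_treatment)
  X <- processed$absorbance
  y <- processed$reference
  cv <- cross_validate(X, y, max_factors = config$max_factors,
                       modified = config$modified,
                       n_groups = config$cv_groups,
                       seed = derive_seed(config$seed, "cv"))
  model <- fit_mpls(X, y, config$max_factors, modified = config$modified)
  model$n_factors_selected <- min(cv$n_factors, model$n_factors)
  label <- paste(years, collapse = " + ")
  list(model = model, processed = processed,
       calibration = summarize_evaluation(
         y, predict(model, X, n_factors = model$n_factors_selected),
         "calibration", n_factors = model$n_factors_selected, year = label),
       cross_validation = summarize_evaluation(
         y, cv$cv_predictions, "cross-validation",
         n_factors = cv$n_factors, year = label),
       cv = cv)
}

#' Validate a calibration on a target season, optionally expanding it
#'
#' Splits the target season at random (seeded): the expansion subset is
#' appended to the calibration pool and the model refitted (with a new
#' cross-validation report); the remainder is validated with
#' bias-corrected SEP. `expand_fraction = 0` is a pure external
#' validation with the base model untouched.
#'
#' @param sets named list of season `spectra_set`s.
#' @param model_years seasons in the base calibration pool.
#' @param target_year season to validate on.
#' @param expand_fraction fraction of the target season moved into the
#'   calibration pool (in `[0, 1)`).
#' @param config a [study_config()]; the split seed is derived from
#'   `config$seed` and the fraction.
#' @param base optional precomputed [run_calibration()] result for
#'   `model_years` (avoids refitting when looping over strategies).
#' @return list with `validation` (report), `cross_validation` (report for
#'   the expanded model, `NULL` when not expanding), `model`,
#'   `predictions`, `reference` and `sample_id` of the evaluation subset,
#'   and `expand_fraction`.
#' @export
run_validation_strategy <- function(sets, model_years, target_year,
                                    expand_fraction = 0,
                                    config = study_config(), base = NULL) {
  stopifnot(expand_fraction >= 0, expand_fraction < 1)
  target_year <- as.character(target_year)
  target <- sets[[target_year]]
  if (is.null(target)) stop("unknown target season", call. = FALSE)
  n <- n_samples(target)
  n_exp <- as.integer(floor(expand_fraction * n + 0.5))
  if (n - n_exp < 2)
    stop("expansion leaves fewer than 2 validation samples", call. = FALSE)
  exp_idx <- if (n_exp > 0)
    with_seed(derive_seed(config$seed, sprintf("split-%g", expand_fraction)),
              sample(n, n_exp))
  else integer(0)
  eval_idx <- setdiff(seq_len(n), exp_idx)

  if (n_exp > 0) {
    sets2 <- sets[as.character(model_years)]
    sets2[[target_year]] <- subset_samples(target, exp_idx)
    calib <- run_calibration(sets2, names(sets2), config)
    cv_report <- calib$cross_validation
  } else {
    calib <- base %||% run_calibration(sets, model_years, config)
    cv_report <- NULL
  }
  eval_set <- apply_math_treatment(subset_samples(target, eval_idx),
                                   config$math_treatment)
  pred <- predict(calib$model, eval_set$absorbance,
                  n_factors = calib$model$n_factors_selected)
  list(validation = summarize_evaluation(eval_set$reference, pred,
                                         "validation", year = target_year),
       cross_validation = cv_report, model = calib$model,
       predictions = pred, reference = eval_set$reference,
       sample_id = eval_set$sample_id, expand_fraction = expand_fraction)
}

#' Selection-predictability grid across strategies and cutoffs
#'
#' For each validation strategy, the percentage of the reference-defined
#' top q% of the strategy's evaluation subset captured by the NIRS
#' predictions, at each cutoff.
#'
#' @param strategies list of [run_validation_strategy()] results.
#' @param cutoffs cutoff percentages.
#' @return data.frame with columns `strategy` (expansion fraction),
#'   `cutoff_pct`, `k`, `match_pct`.
#' @export
run_selection_analysis <- function(strategies, cutoffs = c(5, 10, 15)) {
  do.call(rbind, lapply(strategies, function(s) {
    sc <- selection_curve(s$predictions, s$reference, cutoffs, s$sample_id)
    cbind(strategy = s$expand_fraction, sc[, c("cutoff_pct", "k", "match_pct")])
  }))
}

#' Wavelength-significance analysis from low/high group averages
#'
#' Preprocesses the set, averages the `n_each` lowest- and highest-
#' reference samples, computes the per-wavelength SD between the two
#' average spectra and locates its peaks.
#'
#' @param set a `spectra_set` with reference values (pool the seasons
#'   first for a study-wide profile).
#' @param config a [study_config()] (supplies the math treatment).
#' @param n_each group size (default 50).
#' @param top_k,min_separation passed to [find_peaks()].
#' @return list with `profile` (an `sd_profile`), `peaks` (data.frame),
#'   `low_ids`, `high_ids`.
#' @export
run_wavelength_analysis <- function(set, config = study_config(),
                                    n_each = 50, top_k = 5,
                                    min_separation = 20) {
  groups <- extreme_groups(set, n_each)
  processed <- apply_math_treatment(set, config$math_treatment)
  prof <- sd_profile(group_average(processed, groups$low),
                     group_average(processed, groups$high))
  list(profile = prof,
       peaks = find_peaks(prof, top_k = top_k,
                          min_separation = min_separation),
       low_ids = groups$low, high_ids = groups$high)
}

#' Run the complete multi-season study
#'
#' Orchestrates the full analysis on a set of season spectra: pooled
#' calibration on the first two seasons, the three validation/expansion
#' strategies on the third, the selection-predictability grid, and the
#' wavelength-significance profile on the pooled data.
#'
#' @param sets named list of three season `spectra_set`s (calibration
#'   seasons first, target season last).
#' @param config a [study_config()].
#' @return list with `calibration` (the pooled [run_calibration()]
#'   result), `strategies` (one [run_validation_strategy()] result per
#'   expansion fraction), `selection` (the grid), `wavelengths` (the
#'   profile analysis).
#' @export
run_study <- function(sets, config = study_config()) {
  stopifnot(length(sets) >= 3)
  model_years <- names(sets)[1:2]
  target_year <- names(sets)[length(sets)]
  base <- run_calibration(sets, model_years, config)
  strategies <- lapply(config$expand_fractions, function(fr)
    run_validation_strategy(sets, model_years, target_year, fr, config,
                            base = base))
  names(strategies) <- paste0("expand_", config$expand_fractions)
  list(calibration = base,
       strategies = strategies,
       selection = run_selection_analysis(strategies, config$cutoffs),
       wavelengths = run_wavelength_analysis(combine_samples(sets), config))
}
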