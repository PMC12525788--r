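#' Per-season parameters for the synthetic study
#'
#' @param year integer year label.
#' @param n number of individual plants (seed samples) for the season.
#' @param mean,min,max target thymoquinone distribution (mg g-1 seed).
#' @param offset season-specific spectral offset amplitude, in units of
#'   the configuration's `year_offset_unit` (0 = no season effect).
#' @param offset_centers wavelengths (nm) of the two spectral features
#'   carrying the season effect; seasons perturb the spectra along
#'   season-specific directions, so each season gets its own centers.
#' @return list of class `year_params`.
#' @export
year_params <- function(year, n, mean, min, max, offset = 0,
                        offset_centers = c(2120, 1500)) {
  stopifnot(n >= 1, min <= mean, mean <= max, length(offset_centers) == 2)
  structure(list(year = as.integer(year), n = as.integer(n), mean = mean,
                 min = min, max = max, offset = offset,
                 offset_centers = offset_centers),
            class = "year_params")
}

#' Default three-season parameters
#'
#' Sample sizes and thymoquinone distributions of the three growing
#' seasons a multi-year black cumin breeding study spans (288, 313 and 179
#' individual plants; means 7.75, 12.00 and 8.75 mg g-1). The third season
#' carries the largest spectral offset so that naive across-season
#' prediction shows a bias that calibration expansion removes.
#'
#' @return named list of [year_params()].
#' @export
default_year_params <- function() {
  list("2021" = year_params(2021, 288, 7.75, 0.68, 14.46, offset = 0),
       "2022" = year_params(2022, 313, 12.00, 1.74, 17.30, offset = 0.5,
                            offset_centers = c(2066, 1560)),
       "2023" = year_params(2023, 179, 8.75, 1.08, 13.49, offset = 1,
                            offset_centers = c(2120, 1500)))
}

#' Gaussian absorption band table
#'
#' @param center band centers in nm.
#' @param width Gaussian sigma in nm.
#' @param amplitude peak absorbance per unit driver (per mg g-1 for
#'   analyte bands, per unit constituent loading otherwise).
#' @param constituent optional grouping label for matrix bands.
#' @return data.frame with one row per band.
#' @export
band_table <- function(center, width, amplitude, constituent = NULL) {
  stopifnot(all(width > 0))
  df <- data.frame(center = center, width = width, amplitude = amplitude)
  if (!is.null(constituent)) df$constituent <- constituent
  df
}

# Thymoquinone absorption bands: one CH band near 1650 nm, a doublet in
# the 2038-2114 nm combination region (CH bend + C=O stretch) and a
# quadruplet in the 2226-2418 nm methylene combination region.
default_tmq_bands <- function() {
  band_table(center = c(1650, 2090, 2106, 2228, 2256, 2272, 2294),
             width = c(9, 7, 7, 7, 8, 7, 8),
             amplitude = c(5, 6, 8, 5, 7, 5, 4) * 1e-4)
}

# Interfering seed-matrix constituents with literature-typical band
# positions: oil (CH2 overtone/combination), protein (amide combination),
# water (OH overtone/combination). Loadings vary log-normally per sample.
default_matrix_bands <- function() {
  band_table(center = c(1726, 2308, 2180, 1450, 1940),
             width = c(18, 22, 28, 30, 35),
             amplitude = c(0.060, 0.050, 0.040, 0.050, 0.070),
             constituent = c("oil", "oil", "protein", "water", "water"))
}

#' Configuration of the synthetic seed-spectra generator
#'
#' Absorbance spectra are built as baseline + analyte bands scaled by the
#' true thymoquinone content + matrix-constituent bands with random
#' per-sample loadings + per-sample scatter (multiplicative, additive and
#' linear-tilt terms) + a season-specific additive offset + iid noise.
#' The reference values handed to calibration emulate the reference
#' chromatography assay: truth plus Gaussian error.
#'
#' @param years named list of [year_params()].
#' @param grid wavelength grid in nm (default 400-2498 at 2 nm).
#' @param tmq_bands analyte [band_table()] (absorbance per mg g-1).
#' @param matrix_bands constituent [band_table()] with a `constituent`
#'   column; one log-normal loading per constituent per sample.
#' @param loading_sdlog sdlog of the constituent loadings.
#' @param scatter list with `mult_sd`, `add_sd`, `tilt_sd` (per-sample
#'   scatter coefficient SDs; the tilt is per 1000 nm).
#' @param noise_sd iid spectral noise SD in absorbance units.
#' @param hplc_error_sd reference-method error SD in mg g-1.
#' @param tmq_shape gamma shape of the (reflected) analyte distribution;
#'   smaller values give stronger left skew.
#' @param year_offset_unit absorbance amplitude of one unit of season
#'   offset (scaled per season by `year_params$offset`).
#' @param offset_cv coefficient of variation of the per-sample season
#'   offset loading (`1 + Normal(0, offset_cv)` times the season mean):
#'   seasonal matrix variation is not uniform across plants, which is
#'   what degrades across-season precision until the calibration is
#'   expanded with samples from the new season.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(years = default_year_params(),
                             grid = seq(400, 2498, by = 2),
                             tmq_bands = default_tmq_bands(),
                             matrix_bands = default_matrix_bands(),
                             loading_sdlog = 0.2,
                             scatter = list(mult_sd = 0.05, add_sd = 0.02,
                                            tilt_sd = 0.01),
                             noise_sd = 1.6e-3,
                             hplc_error_sd = 0.12,
                             tmq_shape = 5,
                             year_offset_unit = 5e-3,
                             offset_cv = 1.0) {
  stopifnot(noise_sd >= 0, hplc_error_sd >= 0, loading_sdlog >= 0,
            tmq_shape > 0)
  for (b in list(tmq_bands, matrix_bands))
    if (any(b$center < min(grid) | b$center > max(grid)))
      stop("band center outside the wavelength grid", call. = FALSE)
  structure(list(years = years, grid = grid, tmq_bands = tmq_bands,
                 matrix_bands = matrix_bands, loading_sdlog = loading_sdlog,
                 scatter = scatter, noise_sd = noise_sd,
                 hplc_error_sd = hplc_error_sd, tmq_shape = tmq_shape,
                 year_offset_unit = year_offset_unit,
                 offset_cv = offset_cv),
            class = "synthetic_config")
}

# Sum of Gaussian bands evaluated on the grid, weighted by amplitude.
band_signature <- function(bands, grid) {
  sig <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    sig <- sig + bands$amplitude[i] *
      exp(-((grid - bands$center[i])^2) / (2 * bands$width[i]^2))
  sig
}

# Smooth absorbance baseline typical of intact-seed reflectance spectra.
baseline_curve <- function(grid) {
  0.3 + 4e-4 * (grid - 400) + 0.25 * exp(-((grid - 1900) / 600)^2)
}

# Season offset shape: two moderately narrow features that survive
# derivative preprocessing, emulating a season-specific matrix/instrument
# drift that biases across-season prediction.
year_offset_shape <- function(grid, centers = c(2120, 1500)) {
  exp(-((grid - centers[1]) / 15)^2) +
    0.7 * exp(-((grid - centers[2]) / 18)^2)
}

#' Draw thymoquinone contents for one season
#'
#' Left-skewed distribution (higher frequencies at high content, as in a
#' breeding program selecting for the trait): `max - G` with `G` a gamma
#' variate truncated to `[0, max - min]`. The gamma scale is solved so the
#' truncated mean matches the season's target mean exactly.
#'
#' @param params a [year_params()].
#' @param n number of draws.
#' @param shape gamma shape parameter.
#' @return numeric vector in `[min, max]` with expectation `params$mean`.
#'   Uses the current RNG stream; seed externally for reproducibility.
#' @export
sample_tmq <- function(params, n, shape = 4) {
  stopifnot(n >= 1)
  if (params$min == params$max) return(rep(params$min, n))
  cmax <- params$max - params$min
  target <- params$max - params$mean    # truncated-gamma mean to achieve
  if (target <= 0) return(rep(params$max, n))
  if (target >= cmax * shape / (shape + 1))
    stop("infeasible season mean for the configured skew", call. = FALSE)
  trunc_mean <- function(theta)
    shape * theta * stats::pgamma(cmax, shape + 1, scale = theta) /
      stats::pgamma(cmax, shape, scale = theta)
  theta <- stats::uniroot(function(th) trunc_mean(th) - target,
                          lower = 1e-9, upper = 1e4 * cmax,
                          tol = 1e-12)$root
  out <- numeric(0)
  while (length(out) < n) {
    g <- stats::rgamma(2 * (n - length(out)) + 10, shape, scale = theta)
    out <- c(out, g[g <= cmax])
  }
  params$max - out[seq_len(n)]
}

#' Generate seed spectra for given thymoquinone contents
#'
#' @param tmq vector of true analyte contents (mg g-1).
#' @param config a [synthetic_config()].
#' @param params the season's [year_params()] (supplies the year label and
#'   spectral offset); defaults to a neutral season.
#' @param sample_id ids (default `"<year>_<i>"`).
#' @return a `spectra_set` (without reference values) whose `true_tmq`
#'   element stores the generating truth. Uses the current RNG stream.
#' @export
generate_spectra <- function(tmq, config, params = year_params(0, 1, 0, 0, 1),
                             sample_id = NULL) {
  n <- length(tmq)
  grid <- config$grid
  p <- length(grid)
  analyte <- band_signature(config$tmq_bands, grid)
  base <- baseline_curve(grid)
  X <- matrix(rep(base, each = n), n, p) + tmq %o% analyte
  if (params$offset != 0) {
    off_load <- params$offset * config$year_offset_unit *
      (1 + stats::rnorm(n, 0, config$offset_cv))
    X <- X + off_load %o% year_offset_shape(grid, params$offset_centers)
  }
  constituents <- unique(config$matrix_bands$constituent)
  for (cst in constituents) {
    sig <- band_signature(
      config$matrix_bands[config$matrix_bands$constituent == cst, ], grid)
    load <- stats::rlnorm(n, meanlog = 0, sdlog = config$loading_sdlog)
    X <- X + load %o% sig
  }
  alpha <- 1 + stats::rnorm(n, 0, config$scatter$mult_sd)
  beta <- stats::rnorm(n, 0, config$scatter$add_sd)
  gamma <- stats::rnorm(n, 0, config$scatter$tilt_sd)
  tilt <- (grid - mean(grid)) / 1000
  X <- X * alpha + outer(beta, rep(1, p)) + gamma %o% tilt
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  if (is.null(sample_id))
    sample_id <- sprintf("%d_%03d", params$year, seq_len(n))
  set <- spectra_set(X, grid, sample_id, params$year, step = NULL)
  set$true_tmq <- as.numeric(tmq)
  set
}

#' Generate the full multi-season synthetic study
#'
#' One `spectra_set` per configured season, each with noisy reference
#' values (`reference`, emulating the chromatography assay) and the
#' generating truth (`true_tmq`). Bit-identical for a given seed.
#'
#' @param config a [synthetic_config()].
#' @param seed root RNG seed; per-season substreams are derived from it.
#' @return named list of `spectra_set`, one per season.
#' @export
generate_study <- function(config = synthetic_config(), seed = 1) {
  out <- list()
  for (nm in names(config$years)) {
    params <- config$years[[nm]]
    out[[nm]] <- with_seed(derive_seed(seed, paste0("year-", nm)), {
      tmq <- sample_tmq(params, params$n, config$tmq_shape)
      set <- generate_spectra(tmq, config, params)
      set$reference <- pmax(0, tmq + stats::rnorm(params$n, 0,
                                                  config$hplc_error_sd))
      set
    })
  }
  out
}
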