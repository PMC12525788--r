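#' Average spectrum of a sample subset
#'
#' @param set a (typically preprocessed) `spectra_set`.
#' @param ids character vector of sample ids, or integer indices.
#' @return list with `wavelengths` and `values` (pointwise mean spectrum).
#' @export
group_average <- function(set, ids) {
  if (length(ids) == 0) stop("empty sample subset", call. = FALSE)
  sub <- subset_samples(set, ids)
  list(wavelengths = sub$wavelengths, values = colMeans(sub$absorbance))
}

#' Per-wavelength standard deviation between two average spectra
#'
#' At each wavelength the sample standard deviation of the two group
#' averages, i.e. `|a - b| / sqrt(2)`. Large values mark wavelength
#' regions that discriminate the two groups.
#'
#' @param avg_low,avg_high average spectra as returned by
#'   [group_average()] (lists with `wavelengths` and `values`), or plain
#'   numeric vectors with `wavelengths` supplied.
#' @param wavelengths grid, required when the averages are bare vectors.
#' @return object of class `sd_profile`: list with `wavelengths` and `sd`.
#' @export
sd_profile <- function(avg_low, avg_high, wavelengths = NULL) {
  if (is.list(avg_low)) {
    wavelengths <- avg_low$wavelengths
    a <- avg_low$values
  } else a <- avg_low
  b <- if (is.list(avg_high)) {
    if (!isTRUE(all.equal(avg_high$wavelengths, wavelengths)))
      stop("average spectra are on different grids", call. = FALSE)
    avg_high$values
  } else avg_high
  if (length(a) != length(b) || is.null(wavelengths) ||
      length(wavelengths) != length(a))
    stop("average spectra are on different grids", call. = FALSE)
  structure(list(wavelengths = wavelengths, sd = abs(a - b) / sqrt(2)),
            class = "sd_profile")
}

#' Locate and rank peaks of an SD profile
#'
#' Local maxima of the profile ranked by height, greedily enforcing a
#' minimum wavelength separation between reported peaks (so shoulders of
#' one band are not double-counted).
#'
#' @param profile an `sd_profile`.
#' @param top_k maximum number of peaks to report.
#' @param min_separation minimum distance between reported peaks in nm.
#' @return data.frame with columns `wavelength`, `sd`, `rank`; zero rows
#'   for a flat profile.
#' @export
find_peaks <- function(profile, top_k = 5, min_separation = 20) {
  stopifnot(inherits(profile, "sd_profile"), top_k >= 1)
  s <- profile$sd
  p <- length(s)
  empty <- data.frame(wavelength = numeric(0), sd = numeric(0),
                      rank = integer(0))
  if (p < 3 || max(s) == min(s)) return(empty)
  is_max <- c(FALSE, s[2:(p - 1)] > s[1:(p - 2)] &
                s[2:(p - 1)] >= s[3:p], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(empty)
  cand <- cand[order(-s[cand], profile$wavelengths[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == top_k) break
    if (all(abs(profile$wavelengths[i] - profile$wavelengths[kept])
            >= min_separation))
      kept <- c(kept, i)
  }
  data.frame(wavelength = profile$wavelengths[kept], sd = s[kept],
             rank = seq_along(kept))
}

#' Sample ids of the lowest- and highest-reference groups
#'
#' @param set a `spectra_set` with reference values.
#' @param n_each group size (default 50, the conventional group size for
#'   average-spectra comparisons).
#' @return list with character vectors `low` and `high`.
#' @export
extreme_groups <- function(set, n_each = 50) {
  if (is.null(set$reference))
    stop("spectra set has no reference values", call. = FALSE)
  n <- n_samples(set)
  if (2 * n_each > n)
    stop("need at least ", 2 * n_each, " samples for two groups of ",
         n_each, call. = FALSE)
  ord <- order(set$reference, set$sample_id)
  list(low = set$sample_id[ord[seq_len(n_each)]],
       high = set$sample_id[ord[seq(n - n_each + 1, n)]])
}
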