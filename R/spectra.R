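#' Construct a set of NIRS spectra on a shared wavelength grid
#'
#' A `spectra_set` holds absorbance spectra (log(1/R)) recorded on one
#' uniform, strictly increasing wavelength grid, together with per-sample
#' metadata (identifier, harvest year) and an optional reference value of
#' the analyte (thymoquinone, mg per g seed) for each sample.
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavelength; all values must be finite.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing with a constant step.
#' @param sample_id character vector of unique sample identifiers.
#' @param year integer vector of year labels (recycled if length 1).
#' @param reference optional numeric vector of reference analyte
#'   concentrations (mg g-1), aligned with `sample_id`; values must be >= 0.
#' @param step expected grid step in nm (default 2).
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths`, `absorbance`, `sample_id`, `year`, `reference`.
#' @export
spectra_set <- function(absorbance, wavelengths, sample_id,
                        year = 0L, reference = NULL, step = 2) {
  absorbance <- as.matrix(absorbance)
  wavelengths <- as.numeric(wavelengths)
  check_grid(wavelengths, step = step)
  n <- nrow(absorbance)
  if (ncol(absorbance) != length(wavelengths))
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(wavelengths), " wavelengths", call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance values must all be finite", call. = FALSE)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n)
    stop("sample_id length does not match the number of spectra", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  year <- as.integer(rep_len(year, n))
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != n)
      stop("reference length does not match the number of spectra",
           call. = FALSE)
    if (any(!is.finite(reference)) || any(reference < 0))
      stop("reference values must be finite and >= 0", call. = FALSE)
  }
  rownames(absorbance) <- sample_id
  colnames(absorbance) <- format(wavelengths, trim = TRUE, scientific = FALSE)
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 sample_id = sample_id, year = year, reference = reference),
            class = "spectra_set")
}

# Grid contract: strictly increasing, constant step (within 1e-6 nm).
# step = NULL accepts any uniform spacing.
check_grid <- function(wavelengths, step = 2) {
  if (length(wavelengths) < 2)
    stop("grid must contain at least 2 wavelengths", call. = FALSE)
  d <- diff(wavelengths)
  if (any(d <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-6)
    stop("non-uniform wavelength grid (steps range ",
         format(min(d)), " to ", format(max(d)), " nm)", call. = FALSE)
  if (!is.null(step) && abs(d[1] - step) > 1e-6)
    stop("grid step is ", format(d[1]), " nm; expected ", step, " nm",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set: ", length(x$sample_id), " spectra, ",
      length(x$wavelengths), " points (",
      x$wavelengths[1], "-", x$wavelengths[length(x$wavelengths)], " nm, ",
      diff(x$wavelengths[1:2]), " nm step)\n", sep = "")
  cat("years: ", paste(sort(unique(x$year)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$reference))
    cat(sprintf("reference: mean %.2f, range %.2f-%.2f mg/g\n",
                mean(x$reference), min(x$reference), max(x$reference)))
  invisible(x)
}

#' Number of samples in a spectra set
#' @param set a `spectra_set`.
#' @return integer count.
#' @export
n_samples <- function(set) length(set$sample_id)

#' Subset a spectra set by sample
#'
#' @param set a `spectra_set`.
#' @param idx integer/logical index or character vector of sample ids.
#' @return a `spectra_set` containing the selected samples, in the
#'   requested order.
#' @export
subset_samples <- function(set, idx) {
  if (is.character(idx)) {
    pos <- match(idx, set$sample_id)
    if (anyNA(pos))
      stop("unknown sample_id: ", paste(idx[is.na(pos)], collapse = ", "),
           call. = FALSE)
    idx <- pos
  }
  spectra_set(set$absorbance[idx, , drop = FALSE], set$wavelengths,
              set$sample_id[idx], set$year[idx],
              if (!is.null(set$reference)) set$reference[idx],
              step = NULL)
}

#' Combine spectra sets sharing one grid
#'
#' @param ... `spectra_set` objects (or a single list of them).
#' @return one pooled `spectra_set`. All inputs must share the grid; the
#'   reference is kept only if present in every input.
#' @export
combine_samples <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "spectra_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  grid <- sets[[1]]$wavelengths
  for (s in sets)
    if (!isTRUE(all.equal(s$wavelengths, grid)))
      stop("spectra sets do not share a wavelength grid", call. = FALSE)
  has_ref <- all(vapply(sets, function(s) !is.null(s$reference), logical(1)))
  spectra_set(do.call(rbind, lapply(sets, `[[`, "absorbance")), grid,
              unlist(lapply(sets, `[[`, "sample_id")),
              unlist(lapply(sets, `[[`, "year")),
              if (has_ref) unlist(lapply(sets, `[[`, "reference")),
              step = NULL)
}

#' Read spectra from a delimited text file
#'
#' The dialect is a plain CSV: first column `sample_id`, second column
#' `year`, optional column `tmq_mg_per_g` with the reference analyte
#' concentration, and the remaining columns named by wavelength in nm
#' (e.g. `1100`, `1102`, ...). One sample per row.
#'
#' Rows containing non-numeric absorbance values are rejected with a
#' warning that reports their row indices.
#'
#' @param path path to the CSV file.
#' @param step required grid step in nm (default 2); `NULL` accepts any
#'   uniform grid.
#' @return a `spectra_set`.
#' @export
read_spectra <- function(path, step = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3 || names(df)[1] != "sample_id" || names(df)[2] != "year")
    stop("expected columns sample_id, year, [tmq_mg_per_g], <wavelengths...>",
         call. = FALSE)
  has_ref <- names(df)[3] == "tmq_mg_per_g"
  wl_cols <- seq(if (has_ref) 4L else 3L, ncol(df))
  wavelengths <- suppressWarnings(as.numeric(names(df)[wl_cols]))
  if (anyNA(wavelengths))
    stop("non-numeric wavelength column names", call. = FALSE)
  check_grid(wavelengths, step = step)
  absorb <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, wl_cols, drop = FALSE])),
           nrow = nrow(df)))
  bad <- which(apply(absorb, 1, anyNA))
  if (length(bad)) {
    warning("rejecting ", length(bad), " row(s) with non-numeric absorbance: ",
            paste(bad, collapse = ", "), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    absorb <- absorb[-bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid spectra in file", call. = FALSE)
  reference <- if (has_ref) as.numeric(df[[3]])
  spectra_set(absorb, wavelengths, df$sample_id,
              as.integer(df$year), reference, step = step)
}

#' Write spectra to a delimited text file
#'
#' Writes the CSV dialect read by [read_spectra()]; round-trips absorbance
#' and reference values to within 1e-9.
#'
#' @param set a non-empty `spectra_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  if (!inherits(set, "spectra_set")) stop("not a spectra_set", call. = FALSE)
  if (n_samples(set) == 0) stop("cannot write an empty spectra_set",
                                call. = FALSE)
  df <- data.frame(sample_id = set$sample_id, year = set$year,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(set$reference)) df$tmq_mg_per_g <- set$reference
  ab <- as.data.frame(set$absorbance, check.names = FALSE)
  rownames(ab) <- NULL
  df <- cbind(df, ab)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Attach reference analyte values to a spectra set by sample id
#'
#' Alignment is by `sample_id`, never by row order, so a shuffled
#' reference table gives the same result as a sorted one.
#'
#' @param set a `spectra_set`.
#' @param table data.frame with columns `sample_id` and `tmq_mg_per_g`.
#' @param policy `"strict"` (error on a sample without a reference value)
#'   or `"drop"` (drop such samples from the returned set).
#' @return a `spectra_set` with `reference` filled in.
#' @export
attach_reference <- function(set, table, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  if (!all(c("sample_id", "tmq_mg_per_g") %in% names(table)))
    stop("reference table needs columns sample_id and tmq_mg_per_g",
         call. = FALSE)
  if (anyDuplicated(table$sample_id))
    stop("duplicate sample_id in reference table", call. = FALSE)
  pos <- match(set$sample_id, as.character(table$sample_id))
  if (anyNA(pos)) {
    missing_ids <- set$sample_id[is.na(pos)]
    if (policy == "strict")
      stop("no reference value for sample(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    set <- subset_samples(set, which(!is.na(pos)))
    pos <- pos[!is.na(pos)]
  }
  set$reference <- as.numeric(table$tmq_mg_per_g)[pos]
  if (any(!is.finite(set$reference)) || any(set$reference < 0))
    stop("reference values must be finite and >= 0", call. = FALSE)
  set
}
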