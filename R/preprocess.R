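#' Define a spectral math treatment
#'
#' A math treatment is the ordered preprocessing recipe applied to every
#' spectrum before regression: restriction to a wavelength window, standard
#' normal variate (SNV) scatter correction, detrend (subtraction of a
#' low-order polynomial baseline), and a gap-segment derivative written in
#' the conventional `(d, gap, smooth1, smooth2)` notation in data points —
#' the default `(2, 5, 5, 1)` is a second derivative at a gap of 5 points
#' (10 nm on a 2 nm grid) with one 5-point smoothing pass.
#'
#' @param snv apply SNV (per-spectrum centering/scaling)?
#' @param detrend subtract a least-squares polynomial in wavelength?
#' @param detrend_order polynomial degree for detrend (default 2).
#' @param derivative derivative order d, one of 0, 1, 2.
#' @param gap gap g in data points (>= 1).
#' @param smooth1,smooth2 running-mean segment lengths in data points;
#'   must be odd (or 1 = no smoothing).
#' @param window numeric `c(min, max)` wavelength window in nm, or `NULL`
#'   for the full grid.
#' @return an object of class `math_treatment`.
#' @export
math_treatment <- function(snv = TRUE, detrend = TRUE, detrend_order = 2,
                           derivative = 2, gap = 5, smooth1 = 5, smooth2 = 1,
                           window = c(1100, 2498)) {
  stopifnot(derivative %in% 0:2, gap >= 1, smooth1 >= 1, smooth2 >= 1)
  if (smooth1 %% 2 == 0 || smooth2 %% 2 == 0)
    stop("smoothing segment lengths must be odd (or 1)", call. = FALSE)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
  }
  structure(list(snv = isTRUE(snv), detrend = isTRUE(detrend),
                 detrend_order = as.integer(detrend_order),
                 derivative = as.integer(derivative), gap = as.integer(gap),
                 smooth1 = as.integer(smooth1), smooth2 = as.integer(smooth2),
                 window = window),
            class = "math_treatment")
}

#' @export
print.math_treatment <- function(x, ...) {
  parts <- c(if (x$snv) "SNV",
             if (x$detrend) paste0("detrend(", x$detrend_order, ")"),
             paste0("(", x$derivative, ",", x$gap, ",", x$smooth1, ",",
                    x$smooth2, ")"))
  cat("math_treatment:", paste(parts, collapse = " + "))
  if (!is.null(x$window))
    cat(", window ", x$window[1], "-", x$window[2], " nm", sep = "")
  cat("\n")
  invisible(x)
}

#' Standard normal variate transformation
#'
#' Centers each spectrum to mean 0 and scales it to unit sample standard
#' deviation, removing additive offsets and multiplicative scatter.
#'
#' @param x numeric vector (one spectrum) or matrix (samples in rows).
#' @return transformed vector/matrix with per-spectrum mean 0, SD 1.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
    if (any(s <= 0))
      stop("constant spectrum (zero standard deviation) in row(s): ",
           paste(which(s <= 0), collapse = ", "), call. = FALSE)
    (x - m) / s
  } else {
    if (length(x) < 2) stop("SNV needs at least 2 points", call. = FALSE)
    s <- stats::sd(x)
    if (s <= 0) stop("constant spectrum (zero standard deviation)",
                     call. = FALSE)
    (x - mean(x)) / s
  }
}

#' Detrend: subtract a least-squares polynomial baseline in wavelength
#'
#' @param x numeric vector (one spectrum) or matrix (samples in rows).
#' @param grid wavelengths in nm, one per point.
#' @param order polynomial degree (default 2); residuals are orthogonal to
#'   the polynomial basis.
#' @return residual vector/matrix (spectrum minus its polynomial fit).
#' @export
detrend <- function(x, grid, order = 2) {
  p <- if (is.matrix(x)) ncol(x) else length(x)
  if (length(grid) != p) stop("grid length mismatch", call. = FALSE)
  if (order >= p - 1)
    stop("polynomial order ", order, " too high for ", p, " points",
         call. = FALSE)
  # orthogonal polynomial basis incl. intercept; projection by QR
  basis <- if (order > 0) cbind(1, stats::poly(grid, degree = order))
           else matrix(1, p, 1)
  q <- qr.Q(qr(basis))
  if (is.matrix(x)) x - (x %*% q) %*% t(q) else
    as.numeric(x - q %*% crossprod(q, x))
}

# Centered running mean over s points; trims (s-1)/2 points at each edge.
# x: matrix with spectra in rows. Returns list(values, keep_index).
running_mean <- function(x, s) {
  if (s == 1) return(list(values = x, trim = 0L))
  h <- (s - 1L) %/% 2L
  p <- ncol(x)
  if (s > p) stop("smoothing segment longer than spectrum", call. = FALSE)
  idx <- (h + 1L):(p - h)
  out <- matrix(0, nrow(x), length(idx))
  for (k in -h:h) out <- out + x[, idx + k, drop = FALSE]
  list(values = out / s, trim = h)
}

# One gap-difference pass: symmetric stencil at +/- ceiling(g/2) points,
# scaled by the wavelength distance between the stencil points.
gap_difference <- function(x, grid, g) {
  h <- as.integer(ceiling(g / 2))
  p <- ncol(x)
  if (2L * h + 1L > p)
    stop("gap stencil larger than spectrum", call. = FALSE)
  idx <- (h + 1L):(p - h)
  dl <- grid[idx + h] - grid[idx - h]
  vals <- sweep(x[, idx + h, drop = FALSE] - x[, idx - h, drop = FALSE],
                2, dl, "/")
  list(values = vals, grid = grid[idx])
}

#' Gap-segment derivative
#'
#' Smooths each spectrum by a centered running mean over `s1` points (then
#' a second pass over `s2` points; 1 = identity), then applies the gap
#' difference operator `d` times: the first derivative at a point is the
#' difference between the values `ceiling(g/2)` points to the right and to
#' the left, divided by the wavelength distance between those stencil
#' points. Edges where the stencil is incomplete are trimmed; the
#' surviving wavelengths are returned alongside the values.
#'
#' @param x numeric vector (one spectrum) or matrix (samples in rows).
#' @param grid wavelengths in nm.
#' @param d derivative order (0, 1 or 2).
#' @param g gap in data points.
#' @param s1,s2 smoothing segment lengths in data points (odd or 1).
#' @return list with `values` (same shape class as `x`, trimmed) and
#'   `wavelengths` (the surviving grid).
#' @export
gap_segment_derivative <- function(x, grid, d = 2, g = 5, s1 = 5, s2 = 1) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1)
  if (ncol(x) != length(grid)) stop("grid length mismatch", call. = FALSE)
  stopifnot(d %in% 0:2, g >= 1, s1 >= 1, s2 >= 1)
  sm <- running_mean(x, s1)
  grid2 <- if (sm$trim > 0) grid[(sm$trim + 1):(length(grid) - sm$trim)] else grid
  sm2 <- running_mean(sm$values, s2)
  if (sm2$trim > 0)
    grid2 <- grid2[(sm2$trim + 1):(length(grid2) - sm2$trim)]
  vals <- sm2$values
  if (d > 0) for (i in seq_len(d)) {
    gd <- gap_difference(vals, grid2, g)
    vals <- gd$values
    grid2 <- gd$grid
  }
  list(values = if (vec) as.numeric(vals) else vals, wavelengths = grid2)
}

#' Apply a math treatment to a spectra set
#'
#' Operations are applied in a fixed order: wavelength-window restriction,
#' SNV, detrend, derivative. All spectra are processed identically and the
#' result shares one (possibly trimmed) grid.
#'
#' @param set a `spectra_set`.
#' @param mt a [math_treatment()].
#' @return a processed `spectra_set` (same samples, transformed absorbance,
#'   possibly shorter grid).
#' @export
apply_math_treatment <- function(set, mt) {
  stopifnot(inherits(set, "spectra_set"), inherits(mt, "math_treatment"))
  grid <- set$wavelengths
  x <- set$absorbance
  if (!is.null(mt$window)) {
    keep <- grid >= mt$window[1] - 1e-9 & grid <= mt$window[2] + 1e-9
    if (!any(keep))
      stop("window ", mt$window[1], "-", mt$window[2],
           " nm does not overlap the grid", call. = FALSE)
    grid <- grid[keep]
    x <- x[, keep, drop = FALSE]
  }
  if (mt$snv) {
    x <- tryCatch(snv(x), error = function(e)
      stop("SNV failed: ", conditionMessage(e), " [sample_id: ",
           paste(utils::head(set$sample_id, 3), collapse = ","), " ...]",
           call. = FALSE))
  }
  if (mt$detrend) x <- detrend(x, grid, mt$detrend_order)
  der <- gap_segment_derivative(x, grid, mt$derivative, mt$gap,
                                mt$smooth1, mt$smooth2)
  spectra_set(der$values, der$wavelengths, set$sample_id, set$year,
              set$reference, step = NULL)
}
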