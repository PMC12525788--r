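test_that("snv centers and scales each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  # mean 0.25, sample SD sqrt(0.03)
  expect_equal(snv(c(0.4, 0.1, 0.4, 0.1)),
               c(0.8660254, -0.8660254, 0.8660254, -0.8660254),
               tolerance = 1e-6)
  expect_error(snv(c(5, 5, 5)), "constant")

  set.seed(7)
  X <- snv(matrix(rnorm(1000 * 60, 2, 0.3), 1000, 60))
  expect_lt(max(abs(rowMeans(X))), 1e-10)
  expect_lt(max(abs(apply(X, 1, sd) - 1)), 1e-10)
})

test_that("detrend removes exactly the polynomial part", {
  grid <- seq(1100, 2498, 2)
  quad <- 2 + 0.003 * grid - 1e-6 * grid^2
  expect_lt(max(abs(detrend(quad, grid, 2))), 1e-8)

  set.seed(1)
  x <- rnorm(700)
  expect_lt(abs(mean(detrend(x, grid, 0))), 1e-12)

  # quadratic + sine: residual recovers the (near-orthogonal) sine part
  sine <- sin(grid / 5)
  r <- detrend(quad + sine, grid, 2)
  expect_lt(max(abs(r - (sine - mean(sine)))), 0.05)
  expect_gt(cor(r, sine), 0.999)
  # residual is orthogonal to the polynomial basis
  expect_lt(max(abs(crossprod(cbind(1, poly(grid, 2)), r))) /
              sqrt(sum(r^2)), 1e-8)
  expect_error(detrend(c(1, 2, 3), c(1, 2, 3), 2), "order")
})

test_that("gap-segment derivative annihilates affine and fixes quadratics", {
  grid <- seq(1100, 2498, 2)
  affine <- 0.2 + 0.0004 * grid
  for (prm in list(c(5, 5, 1), c(4, 3, 3), c(2, 1, 1))) {
    d2 <- gap_segment_derivative(affine, grid, 2, prm[1], prm[2], prm[3])
    expect_lt(max(abs(d2$values)), 1e-15)
  }
  a <- 3e-7
  quad <- a * grid^2
  for (prm in list(c(5, 5, 1), c(5, 5, 5), c(3, 7, 1))) {
    d2 <- gap_segment_derivative(quad, grid, 2, prm[1], prm[2], prm[3])
    expect_equal(d2$values, rep(2 * a, length(d2$wavelengths)),
                 tolerance = 1e-8)
  }
  ident <- gap_segment_derivative(affine, grid, 0, 5, 1, 1)
  expect_identical(ident$values, affine)
  expect_identical(ident$wavelengths, grid)
})

test_that("derivative matches the brute-force oracle and is linear", {
  grid <- seq(1100, 1298, 2)
  set.seed(11)
  for (prm in list(c(1, 5, 5, 1), c(1, 4, 3, 1), c(2, 5, 5, 5),
                   c(2, 6, 7, 3))) {
    x <- rnorm(length(grid))
    y <- rnorm(length(grid))
    got <- gap_segment_derivative(x, grid, prm[1], prm[2], prm[3], prm[4])
    want <- brute_gap_deriv(x, grid, prm[1], prm[2], prm[3], prm[4])
    expect_equal(got$wavelengths, want$wavelengths)
    expect_lt(max(abs(got$values - want$values)), 1e-10)

    gx <- gap_segment_derivative(x, grid, prm[1], prm[2], prm[3], prm[4])$values
    gy <- gap_segment_derivative(y, grid, prm[1], prm[2], prm[3], prm[4])$values
    gxy <- gap_segment_derivative(2 * x - 3 * y, grid,
                                  prm[1], prm[2], prm[3], prm[4])$values
    expect_equal(gxy, 2 * gx - 3 * gy, tolerance = 1e-10)
  }
  expect_error(gap_segment_derivative(rnorm(5), seq(2, 10, 2), 2, 5, 1, 1),
               "stencil")
})

test_that("apply_math_treatment composes window, SNV, detrend, derivative", {
  grid <- seq(400, 2498, 2)
  set.seed(3)
  set <- spectra_set(matrix(rnorm(5 * 1050, 0.5, 0.1), 5), grid,
                     paste0("s", 1:5), step = NULL)

  # window restriction alone: 700 points survive before derivative trimming
  mt_id <- math_treatment(snv = FALSE, detrend = FALSE, derivative = 0,
                          smooth1 = 1, smooth2 = 1, window = c(1100, 2498))
  out <- apply_math_treatment(set, mt_id)
  expect_length(out$wavelengths, 700)
  expect_equal(out$absorbance, set$absorbance[, grid >= 1100],
               ignore_attr = TRUE)

  # SNV-only treatment is snv() applied per spectrum
  mt_snv <- math_treatment(snv = TRUE, detrend = FALSE, derivative = 0,
                           smooth1 = 1, smooth2 = 1, window = NULL)
  expect_equal(apply_math_treatment(set, mt_snv)$absorbance,
               snv(set$absorbance), ignore_attr = TRUE)

  # identity treatment on the full grid leaves the input unchanged
  mt_full_id <- math_treatment(snv = FALSE, detrend = FALSE, derivative = 0,
                               smooth1 = 1, smooth2 = 1, window = NULL)
  expect_equal(apply_math_treatment(set, mt_full_id)$absorbance,
               set$absorbance)

  # default (2,5,5,1) trims the smoothing and two gap-stencil margins
  proc <- apply_math_treatment(set, math_treatment())
  expect_length(proc$wavelengths, 700 - 2 * 2 - 2 * 3 - 2 * 3)

  # permutation equivariance over samples
  perm <- c(3, 5, 1, 2, 4)
  proc_perm <- apply_math_treatment(subset_samples(set, perm),
                                    math_treatment())
  expect_equal(proc_perm$absorbance, proc$absorbance[perm, ],
               ignore_attr = TRUE)
})
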