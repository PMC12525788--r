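# One latent concentration driving a fixed band shape exactly: the
# single-factor model is then exact, so 1 PLS factor must fit perfectly.
noiseless_instance <- function(n = 25, p = 40, seed = 2) {
  set.seed(seed)
  t <- rnorm(n)
  v <- exp(-((seq_len(p) - 12)^2) / 18)
  list(X = t %o% v, y = 3 * t + 7)
}

test_that("noiseless single-band data is fitted exactly with one factor", {
  d <- noiseless_instance()
  for (mod in c(FALSE, TRUE)) {
    m <- fit_mpls(d$X, d$y, 5, modified = mod)
    fit <- predict(m, d$X, n_factors = 1)
    expect_gt(cor(fit, d$y)^2, 1 - 1e-9)
    expect_lt(m$sec[1], 1e-8 * sd(d$y))
  }
})

test_that("modified=off equals the independent Krylov PLS1 oracle", {
  set.seed(42)
  for (i in 1:8) {
    X <- matrix(rnorm(20 * 50), 20, 50)
    y <- rnorm(20)
    k <- sample(1:4, 1)
    m <- fit_mpls(X, y, k, modified = FALSE)
    o <- krylov_pls1(X, y, k)
    expect_lt(max(abs(m$coefficients[, k] - o$coef)), 1e-8)
    expect_lt(max(abs(predict(m, X, n_factors = k) -
                        (as.numeric(X %*% o$coef) + o$intercept))), 1e-8)
  }
})

test_that("factor-path and collapsed-coefficient predictions agree", {
  set.seed(5)
  X <- matrix(rnorm(30 * 25), 30, 25)
  y <- rnorm(30, 10, 2)
  Xnew <- matrix(rnorm(6 * 25), 6, 25)
  for (mod in c(FALSE, TRUE)) {
    m <- fit_mpls(X, y, 6, modified = mod)
    for (f in c(1, 3, 6))
      expect_lt(max(abs(predict(m, Xnew, n_factors = f, path = "factors") -
                          predict(m, Xnew, n_factors = f,
                                  path = "coefficients"))), 1e-8)
  }
})

test_that("prediction contracts: mean spectrum, training consistency, permutation", {
  set.seed(6)
  X <- matrix(rnorm(30 * 25), 30, 25)
  y <- rnorm(30, 10, 2)
  m <- fit_mpls(X, y, 4)
  expect_equal(predict(m, matrix(m$x_center, 1)), m$y_center,
               tolerance = 1e-10)
  perm <- sample(30)
  expect_equal(predict(m, X[perm, ]), predict(m, X)[perm])
  expect_error(predict(m, X[, 1:10]), "grid")
})

test_that("training SEC is non-increasing in the factor count", {
  set.seed(8)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 30), 40, 30)
    y <- as.numeric(X %*% rnorm(30)) + rnorm(40)
    m <- fit_mpls(X, y, 8, modified = (i %% 2 == 0))
    rms <- m$sec * sqrt((40 - seq_along(m$sec) - 1) / 40)  # undo dof factor
    expect_true(all(diff(rms) < 1e-10))
  }
})

test_that("predictions are equivariant under shifting and scaling y", {
  set.seed(9)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30, 5)
  Xnew <- matrix(rnorm(4 * 20), 4, 20)
  base <- predict(fit_mpls(X, y, 3), Xnew, n_factors = 3)
  shifted <- predict(fit_mpls(X, y + 11, 3), Xnew, n_factors = 3)
  scaled <- predict(fit_mpls(X, -2 * y, 3), Xnew, n_factors = 3)
  expect_equal(shifted, base + 11, tolerance = 1e-9)
  expect_equal(scaled, -2 * base, tolerance = 1e-9)
})

test_that("rank bound is enforced with a warning", {
  set.seed(10)
  X <- matrix(rnorm(8 * 30), 8, 30)
  y <- rnorm(8)
  expect_warning(m <- fit_mpls(X, y, 16), "rank")
  expect_lte(m$n_factors, 6)
  expect_error(fit_mpls(X, rep(1, 8), 2), "constant")
})

test_that("cross-validation is deterministic and selects 1 factor on noiseless data", {
  d <- noiseless_instance(n = 40)
  cv1 <- cross_validate(d$X, d$y, max_factors = 6, seed = 3)
  cv2 <- cross_validate(d$X, d$y, max_factors = 6, seed = 3)
  expect_identical(cv1$plan$assignment, cv2$plan$assignment)
  expect_identical(cv1$secv, cv2$secv)
  expect_equal(cv1$n_factors, 1)
  expect_lt(cv1$secv[1], 1e-6)
  expect_gt(cv1$one_minus_vr, 1 - 1e-6)

  sizes <- tabulate(cv1$plan$assignment)
  expect_lte(diff(range(sizes)), 1)
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(12)
  X <- matrix(rnorm(25 * 15), 25, 15)
  y <- rnorm(25, 8)
  m <- fit_mpls(X, y, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_mpls_model(m, path)
  m2 <- read_mpls_model(path)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$n_factors_selected, m$n_factors_selected)
})
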