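# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# PLS1 via the Krylov-subspace closed form (Helland): the k-factor PLS1
# coefficient vector is the least-squares solution restricted to
# span{X'y, (X'X)X'y, ..., (X'X)^(k-1) X'y} of the centered problem.
krylov_pls1 <- function(X, y, k) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) { K[, j] <- v; v <- crossprod(Xc, Xc %*% v) }
  Q <- qr.Q(qr(K))
  b <- Q %*% solve(crossprod(Xc %*% Q), crossprod(Q, s))
  list(coef = as.numeric(b), intercept = ym - sum(xm * b))
}

# Brute-force gap-segment derivative on one spectrum: explicit loops,
# average first, then difference over the symmetric gap stencil.
brute_gap_deriv <- function(x, grid, d, g, s1, s2) {
  avg <- function(x, grid, s) {
    if (s == 1) return(list(x = x, grid = grid))
    h <- (s - 1) %/% 2
    idx <- (h + 1):(length(x) - h)
    list(x = vapply(idx, function(i) mean(x[(i - h):(i + h)]), 0),
         grid = grid[idx])
  }
  a <- avg(x, grid, s1)
  a <- avg(a$x, a$grid, s2)
  x <- a$x; grid <- a$grid
  for (pass in seq_len(d)) {
    h <- ceiling(g / 2)
    idx <- (h + 1):(length(x) - h)
    x <- vapply(idx, function(i)
      (x[i + h] - x[i - h]) / (grid[i + h] - grid[i - h]), 0)
    grid <- grid[idx]
  }
  list(values = x, wavelengths = grid)
}

# Random spectra-like matrix for property tests.
random_spectra_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p) + outer(rep(1, n), sin(seq_len(p) / 7))
}

# Tiny synthetic configuration for fast end-to-end tests: two small
# seasons plus a small target season, sharing the default spectral model.
tiny_config <- function(n1 = 40, n2 = 40, n3 = 30, ...) {
  synthetic_config(
    years = list(
      "2021" = year_params(2021, n1, 7.75, 0.68, 14.46, offset = 0),
      "2022" = year_params(2022, n2, 12.00, 1.74, 17.30, offset = 0.5,
                           offset_centers = c(2066, 1560)),
      "2023" = year_params(2023, n3, 8.75, 1.08, 13.49, offset = 1,
                           offset_centers = c(2120, 1500))),
    ...)
}

# Population variance written out directly.
var_pop_oracle <- function(x) sum((x - sum(x) / length(x))^2) / length(x)
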