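#' Fit a (modified) partial least squares calibration
#'
#' PLS1 by iterative latent-factor extraction (NIPALS): X and y are mean
#' centered; for each factor the weight vector is the covariance direction
#' between the X residual and the y residual, scores are the projection on
#' it, and both residuals are deflated. With `modified = TRUE` the
#' Shenk–Westerhaus modification is applied: after each factor every
#' wavelength's residual column and the y residual are divided by their
#' standard deviations before the next factor is extracted; the scale
#' vectors are stored and replayed at prediction time. `modified = FALSE`
#' is standard PLS1.
#'
#' @param X numeric matrix of processed spectra (samples in rows).
#' @param y numeric vector of reference analyte values (mg g-1).
#' @param max_factors maximum number of latent factors (clipped with a
#'   warning to the rank bound `min(n - 2, p)`).
#' @param modified apply the per-factor residual standardization?
#' @return an object of class `mpls_model` with elements `x_center`,
#'   `y_center`, per-factor `weights`, `loadings`, `y_loadings`,
#'   `x_scales`, `y_scales`, cumulative `coefficients` (p x k, column f is
#'   the collapsed linear predictor using f factors), `intercepts`,
#'   `n_factors` (fitted), `n_factors_selected` (set by [cross_validate()];
#'   defaults to `n_factors`), `sec` (per-factor training SEC).
#' @export
fit_mpls <- function(X, y, max_factors = 16, modified = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (stats::sd(y) == 0) stop("reference values are constant", call. = FALSE)
  kmax <- min(max_factors, n - 2L, p)
  if (kmax < max_factors)
    warning("max_factors clipped to rank bound ", kmax, call. = FALSE)

  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  scale0 <- mean(sqrt(colSums(E^2) / (n - 1)))   # typical spectral scale
  sd_floor <- max(1e-10 * scale0, 1e-300)

  W <- P <- Sx <- matrix(0, p, kmax)
  q <- sy <- numeric(kmax)
  k <- 0L
  for (a in seq_len(kmax)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(scale0, 1) * max(stats::sd(y), 1)) break
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-28) break
    pv <- as.numeric(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qa * t
    k <- a
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
    if (modified) {
      sx <- sqrt(colSums(sweep(E, 2, colMeans(E))^2) / (n - 1))
      sx[sx < sd_floor] <- 1
      E <- sweep(E, 2, sx, "/")
      s <- stats::sd(f)
      if (s < max(1e-10 * stats::sd(y), 1e-300)) s <- 1
      f <- f / s
      Sx[, a] <- sx; sy[a] <- s
    } else {
      Sx[, a] <- 1; sy[a] <- 1
    }
  }
  if (k == 0L) stop("no latent factor could be extracted", call. = FALSE)
  W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
  Sx <- Sx[, seq_len(k), drop = FALSE]
  q <- q[seq_len(k)]; sy <- sy[seq_len(k)]

  # Collapse the factor recursion to an equivalent linear predictor.
  # With e_1 = x - xm, t_a = w_a' e_a, e_{a+1} = (e_a - t_a p_a) / sx_a,
  # yhat = ym + sum_a c_a t_a with c_a = q_a * prod_{j<a} sy_j, each t_a is
  # linear in x: t_a = v_a' (x - xm), with v_a obtained by propagating w_a
  # backwards through the deflation/scaling chain.
  V <- matrix(0, p, k)
  for (a in seq_len(k)) {
    r <- W[, a]
    if (a > 1) for (j in (a - 1L):1L) {
      r <- r / Sx[, j]
      r <- r - sum(r * P[, j]) * W[, j]
    }
    V[, a] <- r
  }
  cy <- q * c(1, cumprod(sy))[seq_len(k)]
  coef <- V %*% diag(cy, k)                      # per-factor contributions
  coef <- t(apply(t(coef), 2, cumsum))           # cumulative over factors
  if (k == 1) coef <- matrix(coef, p, 1)
  intercepts <- ym - as.numeric(xm %*% coef)

  fitted_all <- sweep(sweep(X, 2, xm) %*% coef, 2, ym, "+")
  resid_all <- fitted_all - y
  sec_curve <- vapply(seq_len(k), function(f0) {
    dof <- n - f0 - 1L
    if (dof > 0) sqrt(sum(resid_all[, f0]^2) / dof) else NA_real_
  }, numeric(1))

  structure(list(x_center = xm, y_center = ym, weights = W, loadings = P,
                 y_loadings = q, x_scales = Sx, y_scales = sy,
                 factor_coefs = cy, coefficients = coef,
                 intercepts = intercepts, n_factors = k,
                 n_factors_selected = k, modified = modified,
                 sec = sec_curve, n = n, p = p),
            class = "mpls_model")
}

#' @export
print.mpls_model <- function(x, ...) {
  cat("mpls_model: ", x$n_factors, " factors fitted (",
      x$n_factors_selected, " selected), ", x$p, " wavelengths, n = ",
      x$n, if (x$modified) ", Shenk-Westerhaus residual scaling", "\n",
      sep = "")
  invisible(x)
}

#' Predict analyte values from an MPLS model
#'
#' @param object an `mpls_model`.
#' @param X matrix of processed spectra on the training grid (or a
#'   `spectra_set` already carrying the processed values).
#' @param n_factors number of factors to use (default: the selected count).
#' @param path `"coefficients"` (collapsed linear predictor, default) or
#'   `"factors"` (replay the factor recursion); the two agree to ~1e-12.
#' @param ... unused.
#' @return numeric vector of predictions (mg g-1).
#' @export
predict.mpls_model <- function(object, X, n_factors = NULL,
                               path = c("coefficients", "factors"), ...) {
  path <- match.arg(path)
  if (inherits(X, "spectra_set")) X <- X$absorbance
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != object$p)
    stop("grid mismatch: model has ", object$p, " wavelengths, input has ",
         ncol(X), call. = FALSE)
  f <- n_factors %||% object$n_factors_selected
  stopifnot(f >= 1, f <= object$n_factors)
  if (path == "coefficients")
    return(as.numeric(X %*% object$coefficients[, f]) + object$intercepts[f])
  E <- sweep(X, 2, object$x_center)
  yhat <- rep(object$y_center, nrow(X))
  for (a in seq_len(f)) {
    t <- as.numeric(E %*% object$weights[, a])
    yhat <- yhat + object$factor_coefs[a] * t
    E <- E - tcrossprod(t, object$loadings[, a])
    E <- sweep(E, 2, object$x_scales[, a], "/")
  }
  yhat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a grouped cross-validation plan
#'
#' Seeded random partition of `n` samples into `n_groups` groups whose
#' sizes differ by at most one.
#'
#' @param n number of samples.
#' @param n_groups number of groups (>= 2).
#' @param seed RNG seed for the partition.
#' @return object of class `cv_plan` with the group `assignment`.
#' @export
cv_plan <- function(n, n_groups = 5, seed = 1) {
  stopifnot(n_groups >= 2, n >= n_groups)
  assignment <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(rep_len(seq_len(n_groups), n))
  })
  structure(list(n = n, n_groups = as.integer(n_groups), seed = seed,
                 assignment = assignment), class = "cv_plan")
}

#' Grouped cross-validation with parsimonious factor selection
#'
#' For each left-out group an MPLS model is fitted on the remaining
#' samples and the group is predicted at every factor count. SECV(f) is
#' the root mean square of the pooled out-of-group residuals at f factors.
#' The selected factor count is the smallest f whose SECV is within 2% of
#' the curve minimum (an absolute floor of 1e-8 * sd(y) keeps numerically
#' zero curves from selecting spurious extra factors).
#'
#' @param X processed spectra matrix.
#' @param y reference values.
#' @param plan a [cv_plan()] (or `NULL` to build one from `n_groups`/`seed`).
#' @param max_factors maximum factors per fold fit.
#' @param modified passed to [fit_mpls()].
#' @param n_groups,seed used when `plan` is `NULL`.
#' @param selection_tol relative tolerance of the parsimony rule (0.02).
#' @return list with `secv` (per-factor curve), `n_factors` (chosen),
#'   `cv_predictions` (pooled out-of-group predictions at the chosen f),
#'   `one_minus_vr`, and the `plan`.
#' @export
cross_validate <- function(X, y, plan = NULL, max_factors = 16,
                           modified = TRUE, n_groups = 5, seed = 1,
                           selection_tol = 0.02) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(plan)) plan <- cv_plan(n, n_groups, seed)
  stopifnot(inherits(plan, "cv_plan"), plan$n == n)
  sizes <- tabulate(plan$assignment, plan$n_groups)
  if (any(sizes < 1)) stop("cross-validation group with no samples",
                           call. = FALSE)
  kmax <- min(max_factors, n - max(sizes) - 2L, ncol(X))
  pred <- matrix(NA_real_, n, kmax)
  for (g in seq_len(plan$n_groups)) {
    out <- plan$assignment == g
    fit <- fit_mpls(X[!out, , drop = FALSE], y[!out], kmax,
                    modified = modified)
    for (f in seq_len(kmax))
      pred[out, f] <- if (f <= fit$n_factors)
        predict(fit, X[out, , drop = FALSE], n_factors = f)
      else pred[out, f - 1]
  }
  secv <- sqrt(colMeans((pred - y)^2))
  thr <- (1 + selection_tol) * min(secv) + 1e-8 * stats::sd(y)
  chosen <- which(secv <= thr)[1]
  list(secv = secv, n_factors = chosen, cv_predictions = pred[, chosen],
       one_minus_vr = one_minus_variance_ratio(pred[, chosen], y),
       plan = plan)
}

#' Serialize an MPLS model to a versioned JSON document
#'
#' @param model an `mpls_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mpls_model <- function(model, path) {
  stopifnot(inherits(model, "mpls_model"))
  doc <- c(list(format = "nirseed-mpls", version = 1L),
           unclass(model))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' Read an MPLS model written by [write_mpls_model()]
#'
#' @param path path to the JSON document.
#' @return an `mpls_model`.
#' @export
read_mpls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "nirseed-mpls"))
    stop("not a nirseed MPLS model document", call. = FALSE)
  doc$format <- NULL; doc$version <- NULL
  for (nm in c("weights", "loadings", "x_scales", "coefficients"))
    doc[[nm]] <- if (is.matrix(doc[[nm]])) t(doc[[nm]])   # cols arrive as rows
      else matrix(unlist(doc[[nm]]), nrow = doc$p)
  structure(doc, class = "mpls_model")
}
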