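# Partial least-squares regression, single response (PLS1).
#
# Implemented from the algorithmic definition: mean-centered predictors and
# response, latent variables extracted by deflating the cross-product vector
# s = X'y against an orthonormal basis of the X-loadings (the SIMPLS
# sequence, which for a single response is algebraically identical to NIPALS
# PLS1 but never rewrites the X matrix — each extra component costs two
# matrix-vector products). Coefficients are nested: fitting A components
# yields the coefficient vector of every model with 1..A components, which
# the cross-validation layer exploits.

#' Fit a PLS1 regression model
#'
#' Predictors are mean-centered (no unit-variance scaling: reflectance bands
#' share units); the response is centered. If the centered predictor matrix
#' runs out of rank before `n_lv` components, extraction stops early and the
#' remaining coefficient columns repeat the last extractable model (the fit
#' cannot improve past the rank).
#'
#' @param X numeric matrix, samples x predictors; no missing values.
#' @param y numeric response vector; no missing values, non-zero variance.
#' @param n_lv number of latent variables, `1 <= n_lv <=
#'   min(nrow(X) - 1, ncol(X))`.
#' @param weights optional non-negative case weights; replicating a row `r`
#'   times and weighting it by `r` give identical coefficients.
#' @return An object of class `plsr_model` with the centering constants, the
#'   weight/loading vectors and the nested coefficient matrix `B`
#'   (`ncol(X) x n_lv`, column `a` = coefficients of the `a`-component
#'   model).
#' @export
fit_plsr <- function(X, y, n_lv, weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) fail("fit_plsr: %d rows of X vs %d responses", n, length(y))
  if (anyNA(X) || anyNA(y)) fail("fit_plsr: missing values are not allowed")
  max_lv <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > max_lv) {
    fail("fit_plsr: n_lv must be in [1, %d] for %d samples x %d predictors", max_lv, n, p)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    fail("fit_plsr: weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  x_mean <- as.numeric(crossprod(w, X))
  y_mean <- sum(w * y)
  if (max(abs(y - y_mean)) < 1e-12 * max(1, abs(y_mean))) {
    fail("fit_plsr: response has zero variance; latent construction is undefined")
  }
  sw <- sqrt(w)
  Xc <- sw * sweep(X, 2L, x_mean)   # rows scaled so crossprods are weighted
  yc <- sw * (y - y_mean)

  R <- matrix(0, p, n_lv)  # projection weights (X-space)
  V <- matrix(0, p, n_lv)  # orthonormal loading basis used for deflation
  P <- matrix(0, p, n_lv)  # loadings
  Q <- numeric(n_lv)       # y-loadings
  B <- matrix(0, p, n_lv)  # nested coefficients
  s <- as.numeric(crossprod(Xc, yc))
  eff <- 0L
  tol <- 1e-12 * max(abs(s), 1)
  for (a in seq_len(n_lv)) {
    if (sqrt(sum(s^2)) <= tol) break
    r <- s
    t <- as.numeric(Xc %*% r)
    nt <- sqrt(sum(t^2))
    if (nt <= 1e-12) break
    t <- t / nt; r <- r / nt
    pv <- as.numeric(crossprod(Xc, t))
    Q[a] <- sum(yc * t)
    v <- pv
    if (a > 1L) {
      v <- v - V[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1L), drop = FALSE], pv)
    }
    nv <- sqrt(sum(v^2))
    if (nv <= 1e-12) break
    v <- as.numeric(v) / nv
    s <- s - v * sum(v * s)
    R[, a] <- r; P[, a] <- pv; V[, a] <- v
    B[, a] <- if (a == 1L) r * Q[a] else B[, a - 1L] + r * Q[a]
    eff <- a
  }
  if (eff == 0L) fail("fit_plsr: predictors carry no covariance with the response")
  if (eff < n_lv) for (a in (eff + 1L):n_lv) B[, a] <- B[, eff]
  structure(list(n_lv = as.integer(n_lv), effective_lv = eff,
                 x_mean = x_mean, y_mean = y_mean,
                 weights_used = !all(weights == weights[1L]),
                 R = R[, seq_len(eff), drop = FALSE],
                 P = P[, seq_len(eff), drop = FALSE],
                 Q = Q[seq_len(eff)], B = B),
            class = "plsr_model")
}

#' Predict from a PLS1 model
#'
#' Affine map: `y_hat = y_mean + (X - x_mean) B[, n_lv]`.
#'
#' @param object a `plsr_model`.
#' @param newdata matrix on the model's training grid (same column count).
#' @param n_lv number of components to use (default: the fitted `n_lv`);
#'   any value `1..n_lv` is available from the nested coefficient matrix.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    fail("predict.plsr_model: %d predictors but model was trained on %d (grid mismatch?)",
         ncol(X), length(object$x_mean))
  }
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  as.numeric(object$y_mean + sweep(X, 2L, object$x_mean) %*% object$B[, n_lv])
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s)%s, %d predictors%s\n",
              x$n_lv,
              if (x$effective_lv < x$n_lv) sprintf(" (rank-limited to %d)", x$effective_lv) else "",
              length(x$x_mean),
              if (x$weights_used) ", case-weighted" else ""))
  invisible(x)
}
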