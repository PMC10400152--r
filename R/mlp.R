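# Single-hidden-layer relu network regressor with L2 penalty — the "deep
# neural network" stand-in of the modeling comparison. Inputs and response
# are standardized before training; the penalized least-squares objective is
# minimized with L-BFGS-B from a seeded random initialization, stopping on
# vanishing loss change (factr 1e7, ~2e-9 on the scaled loss) or 2000
# iterations.

mlp_unpack <- function(theta, p, h) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  w2 <- theta[i + seq_len(h)]; i <- i + h
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(Xs, pars) {
  A <- sweep(Xs %*% pars$W1, 2L, pars$b1, `+`)
  H <- pmax(A, 0)
  list(A = A, H = H, yhat = as.numeric(H %*% pars$w2 + pars$b2))
}

#' Fit a relu MLP regressor
#'
#' One hidden layer of `hidden_size` relu units; loss is
#' `mean((yhat - y)^2) / 2 + l2 / (2 n) * (||W1||^2 + ||w2||^2)` (biases
#' unpenalized) on standardized inputs and response, minimized by L-BFGS-B.
#' Training is reproducible at a fixed seed.
#'
#' @param X numeric matrix, samples x predictors, no missing values.
#' @param y numeric response, no missing values.
#' @param hidden_size hidden-unit count.
#' @param l2 L2 penalty weight (`alpha`).
#' @param seed integer seed for the weight initialization.
#' @param maxit iteration cap (default 2000).
#' @return An object of class `mlp_model` holding the weights and the
#'   input/response standardization constants; predictions are returned in
#'   original response units.
#' @export
fit_mlp <- function(X, y, hidden_size, l2, seed = 1, maxit = 2000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) fail("fit_mlp: %d rows of X vs %d responses", n, length(y))
  if (anyNA(X) || anyNA(y)) fail("fit_mlp: missing values are not allowed")
  stopifnot(hidden_size >= 1, l2 >= 0)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, `/`)
  ys <- (y - y_mean) / y_sd
  h <- as.integer(hidden_size)

  iter <- 0L
  objective <- function(theta) {
    iter <<- iter + 1L
    pars <- mlp_unpack(theta, p, h)
    fw <- mlp_forward(Xs, pars)
    resid <- fw$yhat - ys
    loss <- mean(resid^2) / 2 + l2 / (2 * n) * (sum(pars$W1^2) + sum(pars$w2^2))
    if (!is.finite(loss)) fail("fit_mlp: non-finite loss at iteration %d", iter)
    loss
  }
  gradient <- function(theta) {
    pars <- mlp_unpack(theta, p, h)
    fw <- mlp_forward(Xs, pars)
    resid <- (fw$yhat - ys) / n
    mask <- (fw$A > 0) * 1
    dH <- (resid %o% pars$w2) * mask          # n x h
    gW1 <- crossprod(Xs, dH) + (l2 / n) * pars$W1
    gb1 <- colSums(dH)
    gw2 <- as.numeric(crossprod(fw$H, resid)) + (l2 / n) * pars$w2
    gb2 <- sum(resid)
    c(as.numeric(gW1), gb1, gw2, gb2)
  }
  theta0 <- with_seed(seed, c(
    stats::rnorm(p * h, 0, sqrt(2 / (p + h))),
    rep(0.01, h),
    stats::rnorm(h, 0, sqrt(2 / (h + 1))),
    0
  ))
  fit <- stats::optim(theta0, objective, gradient, method = "L-BFGS-B",
                      control = list(maxit = as.integer(maxit),
                                     factr = 1e7,
                                     pgtol = 0))
  pars <- mlp_unpack(fit$par, p, h)
  structure(list(hidden_size = h, l2 = l2, activation = "relu",
                 W1 = pars$W1, b1 = pars$b1, w2 = pars$w2, b2 = pars$b2,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                 seed = as.integer(seed), loss = fit$value,
                 converged = fit$convergence == 0L),
            class = "mlp_model")
}

#' Predict from an MLP model
#'
#' @param object an `mlp_model`.
#' @param newdata matrix on the model's training grid.
#' @param ... unused.
#' @return Numeric predictions in original response units.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    fail("predict.mlp_model: %d predictors but model was trained on %d (grid mismatch?)",
         ncol(X), length(object$x_mean))
  }
  Xs <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_sd, `/`)
  fw <- mlp_forward(Xs, object[c("W1", "b1", "w2", "b2")])
  object$y_mean + object$y_sd * fw$yhat
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d relu hidden units, L2 %g, %d inputs (loss %.4g%s)\n",
              x$hidden_size, x$l2, length(x$x_mean), x$loss,
              if (x$converged) "" else ", iteration cap reached"))
  invisible(x)
}
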