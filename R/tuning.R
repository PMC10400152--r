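# 10-fold cross-validation, hyperparameter selection by lowest RMSE_CV and
# final refit on the full calibration set.

#' Random k-fold assignment
#'
#' Plain random permutation split into folds whose sizes differ by at most
#' one; deterministic at a fixed seed.
#'
#' @param n sample count.
#' @param k fold count, `2 <= k <= n`.
#' @param seed integer seed.
#' @return An object of class `fold_assignment`: `k`, `n`, `seed` and
#'   `fold` (per-sample fold index in `1..k`).
#' @export
assign_folds <- function(n, k = 10L, seed = 1L) {
  if (k < 2L) fail("assign_folds: k must be at least 2")
  if (n < k) fail("assign_folds: cannot split %d samples into %d folds", n, k)
  fold <- integer(n)
  fold[with_seed(seed, sample.int(n))] <- rep(seq_len(k), length.out = n)
  structure(list(k = as.integer(k), n = as.integer(n),
                 seed = as.integer(seed), fold = fold),
            class = "fold_assignment")
}

#' Hyperparameter grids
#'
#' The reference grids: PLSR models with up to `max_lv` latent variables;
#' MLP hidden sizes {5, 10, 15, 20} crossed with L2 penalties
#' {0.005, 0.01, 0.03}.
#'
#' @param max_lv largest latent-variable count (default 30).
#' @return A data.frame, one row per grid point (`n_lv` for PLSR;
#'   `hidden_size` and `l2` for MLP).
#' @export
plsr_grid <- function(max_lv = 30L) data.frame(n_lv = seq_len(max_lv))

#' @rdname plsr_grid
#' @param hidden_sizes,l2 MLP grid axes.
#' @export
mlp_grid <- function(hidden_sizes = c(5L, 10L, 15L, 20L),
                     l2 = c(0.005, 0.01, 0.03)) {
  expand.grid(hidden_size = hidden_sizes, l2 = l2, KEEP.OUT.ATTRS = FALSE)
}

normalize_grid <- function(method, grid) {
  if (is.null(grid)) grid <- if (method == "plsr") plsr_grid() else mlp_grid()
  if (method == "plsr" && !is.data.frame(grid)) grid <- data.frame(n_lv = as.integer(grid))
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) fail("empty hyperparameter grid")
  need <- if (method == "plsr") "n_lv" else c("hidden_size", "l2")
  miss <- setdiff(need, names(grid))
  if (length(miss)) fail("grid for method '%s' lacks column(s) %s", method, paste(miss, collapse = ", "))
  if (anyDuplicated(grid[need])) fail("hyperparameter grid points must be unique")
  grid[need]
}

# parsimony order: fewest LVs / smallest hidden size then smallest l2
grid_order <- function(method, grid) {
  if (method == "plsr") order(grid$n_lv) else order(grid$hidden_size, grid$l2)
}

# ties within one part in 1e8 of the minimum RMSE_CV go to the smallest
# model; grid points that were infeasible in some fold (NA) are never chosen
choose_grid_point <- function(method, grid, rmse_cv) {
  if (all(is.na(rmse_cv))) fail("no feasible hyperparameter grid point")
  best <- min(rmse_cv, na.rm = TRUE)
  tie <- !is.na(rmse_cv) & rmse_cv <= best * (1 + 1e-8)
  ord <- grid_order(method, grid)
  ord[tie[ord]][1L]
}

#' Cross-validate a hyperparameter grid
#'
#' For every grid point, out-of-fold predictions are pooled across all k
#' folds and RMSE_CV / R2_CV are computed once on the pooled vector; every
#' grid point shares the same fold assignment. Samples with the trait
#' missing must be excluded before building `folds` (see [calibrate()]).
#' PLSR grids are evaluated from a single nested fit per fold. Grid points
#' infeasible for some fold (more latent variables than training samples
#' minus one) get `NA` and are never selected.
#'
#' @param lib a [spectral_library] with no missing values for `trait`.
#' @param trait trait name.
#' @param method `"plsr"` or `"mlp"`.
#' @param grid hyperparameter grid (see [plsr_grid()], [mlp_grid()]);
#'   default the method's reference grid.
#' @param folds a [assign_folds()] result for `n_samples(lib)`.
#' @return An object of class `cv_result`: `method`, `trait`, `grid` (with
#'   `rmse_cv`, `r2_cv`, `chosen` columns), `chosen` (row index), `folds`.
#' @export
cross_validate <- function(lib, trait, method = c("plsr", "mlp"), grid = NULL,
                           folds) {
  method <- match.arg(method)
  stopifnot(inherits(lib, "spectral_library"), inherits(folds, "fold_assignment"))
  grid <- normalize_grid(method, grid)
  y <- trait_values(lib, trait)
  if (anyNA(y)) fail("cross_validate: trait '%s' has missing values; exclude them before folding", trait)
  if (folds$n != length(y)) {
    fail("cross_validate: fold assignment is for %d samples, library has %d", folds$n, length(y))
  }
  X <- lib$spectra
  n <- length(y)
  pred <- matrix(NA_real_, n, nrow(grid))
  for (f in seq_len(folds$k)) {
    te <- folds$fold == f
    tr <- !te
    y_tr <- y[tr]
    if (stats::sd(y_tr) < 1e-12) {
      fail("cross_validate: training part of fold %d has zero variance in trait '%s'", f, trait)
    }
    if (method == "plsr") {
      cap <- min(sum(tr) - 1L, ncol(X))
      feas <- grid$n_lv <= cap
      if (any(feas)) {
        fit <- fit_plsr(X[tr, , drop = FALSE], y_tr, n_lv = max(grid$n_lv[feas]))
        for (g in which(feas)) {
          pred[te, g] <- predict(fit, X[te, , drop = FALSE], n_lv = grid$n_lv[g])
        }
      }
    } else {
      for (g in seq_len(nrow(grid))) {
        fit <- fit_mlp(X[tr, , drop = FALSE], y_tr,
                       hidden_size = grid$hidden_size[g], l2 = grid$l2[g],
                       seed = derive_seed(folds$seed, sprintf("mlp/%d/%g/%d",
                                                              grid$hidden_size[g], grid$l2[g], f)))
        pred[te, g] <- predict(fit, X[te, , drop = FALSE])
      }
    }
  }
  ok <- colSums(is.na(pred)) == 0L
  grid$rmse_cv <- ifelse(ok, sqrt(colMeans((pred - y)^2)), NA_real_)
  sst <- sum((y - mean(y))^2)
  grid$r2_cv <- ifelse(ok, 1 - colSums((pred - y)^2) / sst, NA_real_)
  chosen <- choose_grid_point(method, grid, grid$rmse_cv)
  grid$chosen <- seq_len(nrow(grid)) == chosen
  structure(list(method = method, trait = trait, grid = grid,
                 chosen = chosen, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- x$grid[x$chosen, ]
  pars <- if (x$method == "plsr") sprintf("n_lv = %d", g$n_lv) else
    sprintf("hidden_size = %d, l2 = %g", g$hidden_size, g$l2)
  cat(sprintf("<cv_result> %s for %s over %d grid points; chosen %s (RMSE_CV %.4g, R2_CV %.3f)\n",
              toupper(x$method), x$trait, nrow(x$grid), pars, g$rmse_cv, g$r2_cv))
  invisible(x)
}

#' Calibrate a trait model on a library
#'
#' The full calibration recipe: drop samples with the trait missing, assign
#' k folds, select the hyperparameter with the lowest pooled RMSE_CV, refit
#' at the chosen point on the whole calibration set, and bundle the refit
#' with its CV table and preprocessing provenance.
#'
#' @inheritParams cross_validate
#' @param seed integer seed controlling folding (and MLP initialization).
#' @param k fold count (default 10).
#' @return An object of class `calibration_model`: `method`, `trait`,
#'   `model` (the refit), `cv` (the [cross_validate()] result), `n`,
#'   `window_nm` (from the library, if window-averaged), `seed`.
#' @export
calibrate <- function(lib, trait, method = c("plsr", "mlp"), grid = NULL,
                      seed = 1L, k = 10L) {
  method <- match.arg(method)
  y <- trait_values(lib, trait)
  keep <- !is.na(y)
  if (!any(keep)) fail("calibrate: trait '%s' is entirely missing", trait)
  sub <- if (all(keep)) lib else subset_library(lib, keep)
  # fold seed does not involve the trait: traits with the same retained
  # samples share fold assignments at a given seed
  folds <- assign_folds(n_samples(sub), k = k, seed = derive_seed(seed, "folds"))
  cv <- cross_validate(sub, trait, method, grid, folds)
  g <- cv$grid[cv$chosen, ]
  y_sub <- trait_values(sub, trait)
  model <- if (method == "plsr") {
    fit_plsr(sub$spectra, y_sub, n_lv = g$n_lv)
  } else {
    fit_mlp(sub$spectra, y_sub, hidden_size = g$hidden_size, l2 = g$l2,
            seed = derive_seed(seed, paste0("final/", trait)))
  }
  structure(list(method = method, trait = trait, model = model, cv = cv,
                 n = n_samples(sub),
                 window_nm = attr(lib, "window_nm"),
                 wavelengths = lib$wavelengths,
                 seed = as.integer(seed)),
            class = "calibration_model")
}

#' Predict a trait from a calibration model
#'
#' @param object a [calibrate()] result.
#' @param newdata a [spectral_library] or spectra matrix on the model's
#'   (window-averaged) grid.
#' @param ... unused.
#' @return Numeric predictions in trait units.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_library")) {
    if (!isTRUE(all.equal(newdata$wavelengths, object$wavelengths))) {
      fail("predict: library grid differs from the model's training grid")
    }
    newdata$spectra
  } else {
    as.matrix(newdata)
  }
  predict(object$model, X)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s for %s (n = %d%s)\n", toupper(x$method),
              x$trait, x$n,
              if (!is.null(x$window_nm)) sprintf(", %g nm windows", x$window_nm) else ""))
  print(x$cv)
  invisible(x)
}
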