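# Prediction-quality statistics and the PCA spectral diagnostic.

check_obs_pred <- function(obs, pred, min_n = 1L) {
  if (length(obs) != length(pred)) {
    fail("observed (%d) and predicted (%d) lengths differ", length(obs), length(pred))
  }
  if (anyNA(obs) || anyNA(pred)) fail("observed/predicted values must not be missing")
  if (length(obs) < min_n) fail("need at least %d observations", min_n)
  invisible(NULL)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE / SST` with SST about the observed mean. This is the
#' coefficient of determination, not squared Pearson correlation: on
#' external test sets it can be negative (model worse than the test-set
#' mean) and is reported unclipped.
#'
#' @param obs observed values (length >= 2, non-zero variance).
#' @param pred predicted values.
#' @return A single numeric, at most 1.
#' @export
r_squared <- function(obs, pred) {
  check_obs_pred(obs, pred, 2L)
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) fail("r_squared: observed values have zero variance")
  1 - sum((pred - obs)^2) / sst
}

#' Root mean-squared error
#' @inheritParams r_squared
#' @return `sqrt(mean((pred - obs)^2))`, in trait units.
#' @export
rmse <- function(obs, pred) {
  check_obs_pred(obs, pred)
  sqrt(mean((pred - obs)^2))
}

#' Prediction bias
#'
#' Sign convention: `mean(predicted - observed)` — positive bias means
#' over-prediction.
#'
#' @inheritParams r_squared
#' @return Mean signed error, in trait units.
#' @export
bias <- function(obs, pred) {
  check_obs_pred(obs, pred)
  mean(pred - obs)
}

#' Ratio of performance to deviation
#'
#' Standard chemometric definition: the sample SD of the observed values
#' (n-1 denominator) divided by the prediction RMSE. Larger is better; RPD
#' around 2 or above usually marks a usable calibration.
#'
#' @inheritParams r_squared
#' @return A positive numeric.
#' @export
rpd <- function(obs, pred) {
  check_obs_pred(obs, pred, 2L)
  e <- rmse(obs, pred)
  if (e <= 0) fail("rpd: RMSE is zero (perfect prediction); RPD is undefined")
  stats::sd(obs) / e
}

#' Full evaluation report for one trait
#'
#' @inheritParams r_squared
#' @param trait trait label recorded in the report.
#' @return One-row data.frame: `trait`, `n`, `r2`, `rmse`, `bias`, `rpd`.
#' @export
evaluate_predictions <- function(obs, pred, trait = NA_character_) {
  check_obs_pred(obs, pred, 2L)
  data.frame(trait = trait, n = length(obs),
             r2 = r_squared(obs, pred), rmse = rmse(obs, pred),
             bias = bias(obs, pred), rpd = rpd(obs, pred),
             stringsAsFactors = FALSE)
}

#' PCA projection of spectra
#'
#' Mean-centered principal-component projection of a set of spectra,
#' returned with group labels — the diagnostic used to visualize domain
#' shift between the library and external sets (95% ellipses per group).
#'
#' @param x a [spectral_library], a numeric spectra matrix, or a list of
#'   [spectrum] objects on one grid.
#' @param labels group label per spectrum (defaults to the library's
#'   `dataset` column when `x` is a library).
#' @param n_scores number of score columns to keep (default 2).
#' @return An object of class `pca_diagnostic` with `scores`
#'   (samples x `n_scores`), `loadings`, `explained` (variance fractions,
#'   all components, non-increasing) and `labels`.
#' @export
pca_project <- function(x, labels = NULL, n_scores = 2L) {
  if (inherits(x, "spectral_library")) {
    if (is.null(labels)) labels <- x$meta$dataset
    S <- x$spectra
  } else if (is.list(x) && !is.data.frame(x)) {
    if (!all(vapply(x, inherits, logical(1), "leaf_spectrum"))) {
      fail("pca_project: list input must contain leaf_spectrum objects")
    }
    wl <- x[[1L]]$wavelengths
    for (s in x[-1L]) {
      if (!identical(s$wavelengths, wl)) fail("pca_project: heterogeneous wavelength grids")
    }
    S <- do.call(rbind, lapply(x, `[[`, "values"))
  } else {
    S <- as.matrix(x)
  }
  if (nrow(S) < 3L) fail("pca_project: need at least 3 spectra")
  if (is.null(labels)) labels <- rep("all", nrow(S))
  stopifnot(length(labels) == nrow(S))
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_scores, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl, labels = labels),
            class = "pca_diagnostic")
}

#' @export
print.pca_diagnostic <- function(x, ...) {
  cat(sprintf("<pca_diagnostic> %d spectra, %d groups; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), length(unique(x$labels)),
              100 * x$explained[1L],
              if (length(x$explained) > 1L) 100 * x$explained[2L] else 0))
  invisible(x)
}

#' Plot a PCA diagnostic with group ellipses
#'
#' Scatter of PC1/PC2 scores colored by group with 95% normal-theory
#' ellipses, in the style used to compare library and external spectra.
#' Requires ggplot2.
#'
#' @param diag a [pca_project()] result.
#' @return A ggplot object.
#' @export
plot_pca_diagnostic <- function(diag) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fail("plot_pca_diagnostic: ggplot2 is not installed")
  }
  df <- data.frame(PC1 = diag$scores[, 1L], PC2 = diag$scores[, 2L],
                   group = diag$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2, colour = group)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * diag$explained[1L]),
                  y = sprintf("PC2 (%.1f%%)", 100 * diag$explained[2L]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed-vs-predicted scatter plot
#'
#' Prediction scatter with the 1:1 line and the evaluation statistics in the
#' subtitle. Requires ggplot2.
#'
#' @inheritParams r_squared
#' @param trait trait label for the axes.
#' @return A ggplot object.
#' @export
plot_predictions <- function(obs, pred, trait = "") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fail("plot_predictions: ggplot2 is not installed")
  }
  rep <- evaluate_predictions(obs, pred, trait)
  ggplot2::ggplot(data.frame(obs = obs, pred = pred),
                  ggplot2::aes(x = obs, y = pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste("Observed", trait), y = paste("Predicted", trait),
                  subtitle = sprintf("R2 = %.3f, RMSE = %.3g, bias = %.3g, RPD = %.2f (n = %d)",
                                     rep$r2, rep$rmse, rep$bias, rep$rpd, rep$n)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("PC1", "PC2", "group"))
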