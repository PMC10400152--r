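# Calibration transfer by extra-weighted spiking: spike-set selection, the
# three calibration/testing schemes, and the spike-size sweep.

#' Draw a spike partition from an external set
#'
#' Uniform random selection without replacement of `n_spike` samples to be
#' the spiking set; the remaining samples become the test set and are never
#' used in any calibration.
#'
#' @param external a [spectral_library] (one external dataset).
#' @param n_spike spike-set size, `1 <= n_spike < n_samples(external)`
#'   (default 20, the reference protocol).
#' @param seed integer seed.
#' @return An object of class `spike_partition`: `name`, `spike_ids`,
#'   `test_ids`, `seed`.
#' @export
draw_spike <- function(external, n_spike = 20L, seed = 1L) {
  stopifnot(inherits(external, "spectral_library"))
  n <- n_samples(external)
  if (n_spike < 1L) fail("draw_spike: n_spike must be at least 1")
  if (n_spike >= n) {
    fail("draw_spike: n_spike (%d) must be smaller than the external set (%d)", n_spike, n)
  }
  idx <- with_seed(seed, sample.int(n, n_spike))
  structure(list(name = external$meta$dataset[1L],
                 spike_ids = external$meta$id[sort(idx)],
                 test_ids = external$meta$id[-sort(idx)],
                 seed = as.integer(seed)),
            class = "spike_partition")
}

#' @export
print.spike_partition <- function(x, ...) {
  cat(sprintf("<spike_partition> '%s': %d spike, %d test samples (seed %d)\n",
              x$name, length(x$spike_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Extra-weight a library with a spike set
#'
#' Appends `r = round(n_library / n_spike)` copies of every spike sample to
#' the library so the two groups carry (nearly) equal statistical weight —
#' with the reference sizes (2460-sample library, 20 spikes) `r = 123` and
#' the augmented set has exactly twice the library's samples. Replicated
#' rows are physical copies with ids suffixed `.rep<k>`; see
#' `spike_weights()` for the equivalent case-weight formulation.
#'
#' @param lib the library [spectral_library].
#' @param spike a [spectral_library] of spike samples (non-empty, same
#'   wavelength grid).
#' @return List: `library` (the augmented [spectral_library]),
#'   `replication` (`r`), `spike_ids` (original ids).
#' @export
extra_weight <- function(lib, spike) {
  stopifnot(inherits(lib, "spectral_library"), inherits(spike, "spectral_library"))
  if (n_samples(spike) == 0L) fail("extra_weight: spike set is empty")
  if (!isTRUE(all.equal(lib$wavelengths, spike$wavelengths))) {
    fail("extra_weight: spike and library wavelength grids differ")
  }
  r <- max(1L, as.integer(round(n_samples(lib) / n_samples(spike))))
  reps <- lapply(seq_len(r), function(k) {
    copy <- spike
    copy$meta$id <- paste0(spike$meta$id, ".rep", k)
    rownames(copy$spectra) <- copy$meta$id
    copy
  })
  aug <- do.call(combine_libraries,
                 c(list(lib), reps,
                   provenance = sprintf("%s + spike '%s' x%d", lib$provenance,
                                        spike$meta$dataset[1L], r)))
  attr(aug, "window_nm") <- attr(lib, "window_nm")
  list(library = aug, replication = r, spike_ids = spike$meta$id)
}

#' Equivalent case weights for extra-weighted spiking
#'
#' The replicated-copies calibration matrix of [extra_weight()] is
#' numerically equivalent to concatenating the library with one copy of the
#' spike set and weighting spike rows by `r`; this helper returns that
#' weight vector (an optimization for weight-aware fitters such as
#' [fit_plsr()]).
#'
#' @inheritParams extra_weight
#' @return List: `library` (library + one spike copy), `weights` (per-row),
#'   `replication`.
#' @export
spike_weights <- function(lib, spike) {
  stopifnot(inherits(lib, "spectral_library"), inherits(spike, "spectral_library"))
  if (n_samples(spike) == 0L) fail("spike_weights: spike set is empty")
  r <- max(1L, as.integer(round(n_samples(lib) / n_samples(spike))))
  combined <- combine_libraries(lib, spike, provenance = lib$provenance)
  list(library = combined,
       weights = c(rep(1, n_samples(lib)), rep(r, n_samples(spike))),
       replication = r)
}

# strip the .rep<k> suffix added by extra_weight
base_ids <- function(ids) sub("\\.rep[0-9]+$", "", ids)

#' Run one calibration/testing scheme on an external set
#'
#' The three transfer schemes compared in the workflow:
#' * `library_only` — tune and fit on the library, predict the test set;
#' * `spike_only` — tune and fit on the spike samples alone;
#' * `spiked_library` — tune and fit on the extra-weighted augmented set.
#' Each scheme re-tunes its hyperparameters on its own calibration set via
#' [calibrate()] (pass `grid` of one row to reuse a fixed point instead)
#' and is evaluated only on the partition's test samples. Test ids are
#' asserted absent from every calibration set.
#'
#' @param lib the library [spectral_library] (window-averaged).
#' @param external the external [spectral_library] the partition was drawn
#'   from (same grid).
#' @param partition a [draw_spike()] result.
#' @param trait trait name.
#' @param method,grid,seed,k as in [calibrate()].
#' @param scheme one of `"library_only"`, `"spike_only"`,
#'   `"spiked_library"`.
#' @return An object of class `scheme_result`: `scheme`, `trait`,
#'   `available`, `report` (see [evaluate_predictions()]; `NA` metrics when
#'   the trait is unmeasured in the external set), `replication` (spiked
#'   scheme only), `calibration_ids`, `test_ids`, `model`.
#' @export
run_scheme <- function(lib, external, partition, trait,
                       method = c("plsr", "mlp"), grid = NULL,
                       scheme = c("library_only", "spike_only", "spiked_library"),
                       seed = 1L, k = 10L) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  stopifnot(inherits(partition, "spike_partition"))
  spike <- subset_library(external, partition$spike_ids)
  test <- subset_library(external, partition$test_ids)
  replication <- NA_integer_
  calib <- switch(scheme,
    library_only = lib,
    spike_only = spike,
    spiked_library = {
      ew <- extra_weight(lib, spike)
      replication <- ew$replication
      ew$library
    })
  calib_ids <- unique(base_ids(calib$meta$id))
  leaked <- intersect(calib_ids, partition$test_ids)
  if (length(leaked)) {
    fail("run_scheme: test sample '%s' leaked into the calibration set", leaked[1L])
  }
  y_test <- trait_values(test, trait)
  available <- any(!is.na(trait_values(calib, trait))) && sum(!is.na(y_test)) >= 2L
  if (!available) {
    report <- data.frame(trait = trait, n = NA_integer_, r2 = NA_real_,
                         rmse = NA_real_, bias = NA_real_, rpd = NA_real_,
                         stringsAsFactors = FALSE)
    model <- NULL
  } else {
    model <- calibrate(calib, trait, method, grid,
                       seed = derive_seed(seed, paste0(scheme, "/", trait)), k = k)
    keep <- !is.na(y_test)
    pred <- predict(model, test$spectra[keep, , drop = FALSE])
    report <- evaluate_predictions(y_test[keep], pred, trait)
  }
  structure(list(scheme = scheme, trait = trait, available = available,
                 report = report, replication = replication,
                 calibration_ids = calib_ids, test_ids = partition$test_ids,
                 model = model),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("<scheme_result> %s / %s: trait unavailable in the external set\n",
                x$scheme, x$trait))
  } else {
    cat(sprintf("<scheme_result> %s / %s: R2 %.3f, RMSE %.4g, bias %.3g, RPD %.2f (n = %d)\n",
                x$scheme, x$trait, x$report$r2, x$report$rmse, x$report$bias,
                x$report$rpd, x$report$n))
  }
  invisible(x)
}

#' Run all three schemes over the available traits
#'
#' Convenience wrapper returning a tidy table, one row per scheme x trait.
#'
#' @inheritParams run_scheme
#' @param traits trait names to model (default all nine).
#' @return data.frame with columns `external`, `scheme`, `trait`,
#'   `available`, `n`, `r2`, `rmse`, `bias`, `rpd`.
#' @export
run_all_schemes <- function(lib, external, partition, traits = TRAIT_NAMES,
                            method = "plsr", grid = NULL, seed = 1L, k = 10L) {
  rows <- list()
  for (scheme in c("library_only", "spike_only", "spiked_library")) {
    for (trait in traits) {
      res <- run_scheme(lib, external, partition, trait, method, grid, scheme,
                        seed = seed, k = k)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(external = partition$name, scheme = scheme,
                   available = res$available, stringsAsFactors = FALSE),
        res$report)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("external", "scheme", "trait", "available", "n", "r2", "rmse", "bias", "rpd")]
}

#' Spike-size sweep
#'
#' Quantifies how spike-set size drives transfer: a pool of `pool_size`
#' samples is drawn once and held aside from the external set; for each
#' requested size a random subset of the pool spikes the library
#' (extra-weighted), the model is recalibrated, and performance is measured
#' on the external samples outside the pool. Reference protocol: sizes
#' 10/20/30/40/50 from a 50-sample pool.
#'
#' @inheritParams run_scheme
#' @param sizes spike sizes to evaluate; all `<= pool_size`.
#' @param pool_size held-aside pool size, `< n_samples(external)`.
#' @param traits trait names to model.
#' @return data.frame, one row per size x trait: `external`, `size`,
#'   `trait`, `n`, `r2`, `rmse`, `bias`, `rpd`, `replication`.
#' @export
spike_size_sweep <- function(lib, external, sizes = c(10L, 20L, 30L, 40L, 50L),
                             pool_size = 50L, traits = TRAIT_NAMES,
                             method = "plsr", grid = NULL, seed = 1L, k = 10L) {
  stopifnot(inherits(lib, "spectral_library"), inherits(external, "spectral_library"))
  n <- n_samples(external)
  if (pool_size >= n) fail("spike_size_sweep: pool_size (%d) must be smaller than the external set (%d)", pool_size, n)
  if (any(sizes > pool_size)) fail("spike_size_sweep: sizes must not exceed pool_size (%d)", pool_size)
  if (any(sizes < 1L)) fail("spike_size_sweep: sizes must be positive")
  pool_idx <- with_seed(derive_seed(seed, "pool"), sample.int(n, pool_size))
  pool <- subset_library(external, sort(pool_idx))
  eval_set <- subset_library(external, setdiff(seq_len(n), sort(pool_idx)))
  rows <- list()
  for (size in sizes) {
    spike <- if (size == pool_size) pool else {
      subset_library(pool, sort(with_seed(derive_seed(seed, paste0("size/", size)),
                                          sample.int(pool_size, size))))
    }
    ew <- extra_weight(lib, spike)
    leaked <- intersect(unique(base_ids(ew$library$meta$id)), eval_set$meta$id)
    if (length(leaked)) fail("spike_size_sweep: evaluation sample '%s' leaked into calibration", leaked[1L])
    for (trait in traits) {
      y <- trait_values(eval_set, trait)
      keep <- !is.na(y)
      if (sum(keep) < 2L || all(is.na(trait_values(ew$library, trait)))) {
        rows[[length(rows) + 1L]] <- data.frame(
          external = external$meta$dataset[1L], size = size, trait = trait,
          n = NA_integer_, r2 = NA_real_, rmse = NA_real_, bias = NA_real_,
          rpd = NA_real_, replication = ew$replication, stringsAsFactors = FALSE)
        next
      }
      model <- calibrate(ew$library, trait, method, grid,
                         seed = derive_seed(seed, sprintf("sweep/%d/%s", size, trait)),
                         k = k)
      pred <- predict(model, eval_set$spectra[keep, , drop = FALSE])
      rep_ <- evaluate_predictions(y[keep], pred, trait)
      rows[[length(rows) + 1L]] <- data.frame(
        external = external$meta$dataset[1L], size = size, trait = trait,
        n = rep_$n, r2 = rep_$r2, rmse = rep_$rmse, bias = rep_$bias,
        rpd = rep_$rpd, replication = ew$replication, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pool_ids") <- pool$meta$id
  attr(out, "eval_ids") <- eval_set$meta$id
  out
}
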