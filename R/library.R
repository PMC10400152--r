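#' Spectral library container
#'
#' The calibration currency of every stage: an ordered collection of leaf
#' samples, each with metadata, a (possibly incomplete) trait vector and a
#' reflectance spectrum on a grid shared across the whole collection.
#'
#' @param meta data.frame with columns `id`, `species`, `dataset`, `year`,
#'   `environment`; ids must be unique.
#' @param traits data.frame with the nine columns of [TRAIT_NAMES]; `NA`
#'   marks a missing measurement.
#' @param spectra numeric matrix, one row per sample, one column per
#'   wavelength, reflectance fractions in `[0, 1]`.
#' @param wavelengths numeric vector of wavelengths (nm), strictly
#'   increasing, one per spectra column.
#' @param provenance free-text note on where the collection came from.
#' @param coarse logical; `TRUE` after window averaging (wavelengths are
#'   window centers).
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(meta, traits, spectra, wavelengths,
                             provenance = "", coarse = FALSE) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  traits <- as.data.frame(traits)
  need <- c("id", "species", "dataset", "year", "environment")
  miss <- setdiff(need, names(meta))
  if (length(miss)) fail("spectral_library: meta lacks column(s) %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$id)) {
    dup <- meta$id[duplicated(meta$id)][1L]
    fail("spectral_library: duplicate sample id '%s'", dup)
  }
  miss <- setdiff(TRAIT_NAMES, names(traits))
  if (length(miss)) fail("spectral_library: traits lack column(s) %s", paste(miss, collapse = ", "))
  traits <- traits[, TRAIT_NAMES, drop = FALSE]
  spectra <- as.matrix(spectra)
  if (nrow(meta) != nrow(traits) || nrow(meta) != nrow(spectra)) {
    fail("spectral_library: meta (%d), traits (%d) and spectra (%d) row counts differ",
         nrow(meta), nrow(traits), nrow(spectra))
  }
  if (ncol(spectra) != length(wavelengths)) {
    fail("spectral_library: %d spectra columns vs %d wavelengths",
         ncol(spectra), length(wavelengths))
  }
  if (any(diff(wavelengths) <= 0)) fail("spectral_library: wavelengths must be strictly increasing")
  if (nrow(spectra) && (min(spectra) < 0 || max(spectra) > 1)) {
    fail("spectral_library: reflectance outside [0,1] (range %.3g..%.3g)",
         min(spectra), max(spectra))
  }
  rownames(spectra) <- meta$id
  rownames(meta) <- NULL
  rownames(traits) <- NULL
  structure(
    list(meta = meta, traits = traits, spectra = spectra,
         wavelengths = as.numeric(wavelengths), provenance = provenance,
         coarse = isTRUE(coarse)),
    class = "spectral_library"
  )
}

#' Number of samples in a library
#' @param lib a [spectral_library].
#' @return Integer sample count.
#' @export
n_samples <- function(lib) nrow(lib$meta)

#' @export
print.spectral_library <- function(x, ...) {
  sp <- table(x$meta$species)
  cat(sprintf("<spectral_library> %d samples, %d wavelengths (%g-%g nm%s)\n",
              n_samples(x), length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), if (x$coarse) ", window-averaged" else ""))
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  present <- colSums(!is.na(x$traits))
  cat("  traits present:", paste(sprintf("%s=%d", names(present), present), collapse = " "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Subset a spectral library
#'
#' @param lib a [spectral_library].
#' @param i integer/logical index or character vector of sample ids.
#' @return A `spectral_library` with the selected samples, in the requested
#'   order.
#' @export
subset_library <- function(lib, i) {
  if (is.character(i)) {
    idx <- match(i, lib$meta$id)
    if (anyNA(idx)) fail("subset_library: unknown sample id '%s'", i[is.na(idx)][1L])
  } else {
    idx <- seq_len(n_samples(lib))[i]
  }
  spectral_library(lib$meta[idx, , drop = FALSE], lib$traits[idx, , drop = FALSE],
                   lib$spectra[idx, , drop = FALSE], lib$wavelengths,
                   provenance = lib$provenance, coarse = lib$coarse)
}

#' Concatenate spectral libraries
#'
#' All libraries must share one wavelength grid; sample ids must stay unique
#' after concatenation (use `allow_duplicate_ids` only for the replicated
#' rows created by [extra_weight], which disambiguates ids itself).
#'
#' @param ... `spectral_library` objects.
#' @param provenance provenance note for the combined object.
#' @return A single `spectral_library`.
#' @export
combine_libraries <- function(..., provenance = "") {
  libs <- list(...)
  stopifnot(length(libs) >= 1L)
  wl <- libs[[1L]]$wavelengths
  for (l in libs[-1L]) {
    if (!isTRUE(all.equal(l$wavelengths, wl))) fail("combine_libraries: wavelength grids differ")
  }
  spectral_library(
    do.call(rbind, lapply(libs, `[[`, "meta")),
    do.call(rbind, lapply(libs, `[[`, "traits")),
    do.call(rbind, lapply(libs, `[[`, "spectra")),
    wl, provenance = provenance, coarse = libs[[1L]]$coarse
  )
}

# trait vector of a library with missing-measurement NAs, checked name
trait_values <- function(lib, trait) {
  if (!trait %in% TRAIT_NAMES) fail("unknown trait '%s'", trait)
  lib$traits[[trait]]
}
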