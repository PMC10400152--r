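#' Wavelength grid
#'
#' Describes a regular wavelength sampling. The canonical raw grid of the
#' contact-probe spectroradiometer workflow runs 350--2500 nm at a 1 nm
#' interval, giving 2151 reflectance values per scan.
#'
#' @param start first wavelength (nm).
#' @param stop last wavelength (nm); must exceed `start`.
#' @param step sampling interval (nm), > 0.
#' @return An object of class `wavelength_grid` with elements `start`,
#'   `stop`, `step`, `wavelengths` and `n`.
#' @examples
#' g <- wavelength_grid()
#' g$n  # 2151
#' @export
wavelength_grid <- function(start = 350, stop = 2500, step = 1) {
  if (stop <= start) fail("wavelength_grid: stop (%s) must exceed start (%s)", stop, start)
  if (step <= 0) fail("wavelength_grid: step must be > 0")
  n <- floor((stop - start) / step) + 1L
  structure(
    list(start = start, stop = stop, step = step,
         wavelengths = start + step * (seq_len(n) - 1), n = as.integer(n)),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d points\n",
              x$start, x$stop, x$step, x$n))
  invisible(x)
}

#' Single reflectance spectrum
#'
#' One leaf scan (or scan average) as reflectance fractions on a wavelength
#' grid. Values must lie in `[0, 1]`.
#'
#' @param values numeric reflectance fractions.
#' @param wavelengths numeric wavelengths (nm), same length, strictly
#'   increasing. A [wavelength_grid] is also accepted.
#' @return An object of class `leaf_spectrum`.
#' @export
spectrum <- function(values, wavelengths) {
  if (inherits(wavelengths, "wavelength_grid")) wavelengths <- wavelengths$wavelengths
  if (length(values) != length(wavelengths)) {
    fail("spectrum: %d values on a %d-point grid", length(values), length(wavelengths))
  }
  if (any(!is.finite(values))) fail("spectrum: non-finite reflectance values")
  if (any(values < 0 | values > 1)) {
    fail("spectrum: reflectance must be a fraction in [0,1] (range %.3g..%.3g)",
         min(values), max(values))
  }
  if (any(diff(wavelengths) <= 0)) fail("spectrum: wavelengths must be strictly increasing")
  structure(list(wavelengths = as.numeric(wavelengths), values = as.numeric(values)),
            class = "leaf_spectrum")
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat(sprintf("<leaf_spectrum> %d points, %g-%g nm, reflectance %.3f-%.3f\n",
              length(x$values), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Average replicate scans of one leaf
#'
#' Replicate scans of the same leaf (nine in the library protocol: three
#' readings at each of the tip, middle and basal sections) are averaged
#' pointwise into a single measurement to suppress within-leaf heterogeneity.
#'
#' @param scans list of [spectrum] objects on identical grids.
#' @return A single `leaf_spectrum`, the pointwise arithmetic mean.
#' @export
average_replicate_scans <- function(scans) {
  if (!is.list(scans) || length(scans) == 0L) {
    fail("average_replicate_scans: need a non-empty list of spectra")
  }
  if (!all(vapply(scans, inherits, logical(1), "leaf_spectrum"))) {
    fail("average_replicate_scans: all elements must be leaf_spectrum objects")
  }
  wl <- scans[[1L]]$wavelengths
  for (s in scans[-1L]) {
    if (!identical(s$wavelengths, wl)) fail("average_replicate_scans: mismatched wavelength grids")
  }
  vals <- rowMeans(vapply(scans, `[[`, numeric(length(wl)), "values"))
  spectrum(vals, wl)
}

# windowed means of the columns of a spectra matrix (samples x wavelengths).
# Windows are contiguous, non-overlapping, anchored at the first wavelength;
# a trailing partial window is averaged over the points it contains.
window_average_matrix <- function(S, wavelengths, window_nm) {
  steps <- diff(wavelengths)
  step <- steps[1L]
  if (any(abs(steps - step) > 1e-9)) {
    fail("window_average: requires a regular wavelength grid")
  }
  if (window_nm < step) fail("window_average: window (%g nm) smaller than grid step (%g nm)", window_nm, step)
  ratio <- window_nm / step
  if (abs(ratio - round(ratio)) > 1e-9) {
    fail("window_average: window must be a positive multiple of the grid step")
  }
  ppw <- as.integer(round(ratio))
  p <- length(wavelengths)
  grp <- (seq_len(p) - 1L) %/% ppw
  sizes <- tabulate(grp + 1L)
  means <- t(rowsum(t(S), grp, reorder = TRUE)) / rep(sizes, each = nrow(S))
  full <- sizes == ppw
  centers <- wavelengths[1L] + unique(grp) * window_nm + window_nm / 2
  # partial trailing window: center is the mean of the wavelengths it covers
  if (any(!full)) {
    centers[!full] <- as.numeric(rowsum(wavelengths, grp)[!full] / sizes[!full])
  }
  colnames(means) <- NULL
  list(values = means, centers = centers)
}

#' Wavelength window averaging
#'
#' Reduces spectral dimensionality by averaging reflectance over contiguous,
#' non-overlapping windows (10 nm in the reference workflow: 2151 raw points
#' become 216 bands — 215 full 10-point windows plus one trailing point).
#' Windows are anchored at the first wavelength; a trailing partial window is
#' kept and averaged over the points it contains.
#'
#' @param x a [spectrum] or a [spectral_library].
#' @param window_nm window width in nm; a positive multiple of the grid step.
#' @return Object of the same class on the coarsened grid; the new
#'   wavelengths are window centers.
#' @export
window_average <- function(x, window_nm = 10) UseMethod("window_average")

#' @export
window_average.leaf_spectrum <- function(x, window_nm = 10) {
  out <- window_average_matrix(matrix(x$values, nrow = 1L), x$wavelengths, window_nm)
  spectrum(as.numeric(out$values), out$centers)
}

#' @export
window_average.spectral_library <- function(x, window_nm = 10) {
  out <- window_average_matrix(x$spectra, x$wavelengths, window_nm)
  lib <- spectral_library(x$meta, x$traits, out$values, out$centers,
                          provenance = x$provenance, coarse = TRUE)
  attr(lib, "window_nm") <- window_nm
  lib
}

#' Leaf water content from gravimetric data
#'
#' `LWC (%) = (FW - DW) / FW * 100`, the water fraction of the fresh leaf.
#'
#' @param fw fresh weight (g), > 0.
#' @param dw dry weight (g), with `0 < dw <= fw`.
#' @return LWC in percent, in `[0, 100)`.
#' @export
derive_lwc <- function(fw, dw) {
  stopifnot(length(fw) == length(dw))
  if (any(dw <= 0)) fail("derive_lwc: dry weight must be positive")
  if (any(dw > fw)) fail("derive_lwc: dry weight exceeds fresh weight (data-entry fault?)")
  (fw - dw) / fw * 100
}

#' Leaf mass per area from gravimetric data
#'
#' `LMA (g m-2) = DW / LA`, with leaf area supplied in cm^2 as produced by a
#' bench leaf-area meter and converted internally to m^2.
#'
#' @param dw dry weight (g), > 0.
#' @param la_cm2 one-sided leaf area (cm^2), > 0.
#' @return LMA in g m-2.
#' @export
derive_lma <- function(dw, la_cm2) {
  stopifnot(length(dw) == length(la_cm2))
  if (any(la_cm2 <= 0)) fail("derive_lma: leaf area must be positive")
  if (any(dw <= 0)) fail("derive_lma: dry weight must be positive")
  dw / (la_cm2 * 1e-4)
}
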