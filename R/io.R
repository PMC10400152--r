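# Wide-CSV reader/writer for spectral libraries.
#
# Dialect: UTF-8, comma-delimited, one row per sample, header
#   id, species, dataset, year, environment, N, P, K, Mg, Ca, S, LWC, CHL,
#   LMA, wl_0350 ... wl_2500
# Raw-grid wavelength headers are "wl_" + zero-padded integer nm; after
# window averaging the headers are "wl_c" + the window-center nm
# ("wl_c0355" for the 350-359 nm window). Missing traits are empty fields
# ("NA" is also accepted on read). An optional leading "# ..." comment line
# (used by the pipeline commands to stamp the config hash) is skipped.

meta_cols <- c("id", "species", "dataset", "year", "environment")

#' Write a spectral library to wide CSV
#'
#' @param lib a [spectral_library].
#' @param path output file path.
#' @param header_comment optional comment (without the leading `#`) written
#'   as the first line, e.g. a config hash stamp.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, header_comment = NULL) {
  stopifnot(inherits(lib, "spectral_library"))
  if (min(lib$spectra) < 0 || max(lib$spectra) > 1) {
    fail("write_library: reflectance outside [0,1]; refusing to write")
  }
  wl <- lib$wavelengths
  wl_names <- if (lib$coarse) {
    sprintf("wl_c%04d", as.integer(round(wl)))
  } else {
    sprintf("wl_%04d", as.integer(round(wl)))
  }
  spec_df <- as.data.frame(lib$spectra)
  names(spec_df) <- wl_names
  out <- cbind(lib$meta[meta_cols], lib$traits, spec_df)
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    data.table::fwrite(out, path, na = "", append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(out, path, na = "")
  }
  invisible(path)
}

#' Read a spectral library from wide CSV
#'
#' Validates the dialect strictly: unknown columns, non-monotone wavelength
#' headers and duplicate sample ids are errors, and files whose reflectance
#' looks like percent (maximum value above 1.5) are rejected with a hint
#' rather than silently rescaled.
#'
#' @param path CSV file path.
#' @param provenance provenance note attached to the result (defaults to the
#'   file path).
#' @return A [spectral_library].
#' @export
read_library <- function(path, provenance = path) {
  if (!file.exists(path)) fail("read_library: no such file '%s'", path)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  dt <- data.table::fread(path, skip = skip, na.strings = c("", "NA"),
                          colClasses = list(character = c("id", "species", "dataset", "environment")))
  nms <- names(dt)
  is_wl <- grepl("^wl_c?[0-9]+(\\.[0-9]+)?$", nms)
  known <- nms %in% c(meta_cols, TRAIT_NAMES) | is_wl
  if (any(!known)) {
    fail("read_library: unknown column(s) %s in '%s'",
         paste(sQuote(nms[!known]), collapse = ", "), path)
  }
  miss <- setdiff(c(meta_cols, TRAIT_NAMES), nms)
  if (length(miss)) fail("read_library: '%s' lacks column(s) %s", path, paste(miss, collapse = ", "))
  if (!any(is_wl)) fail("read_library: '%s' has no wavelength columns", path)
  wl_names <- nms[is_wl]
  coarse <- any(startsWith(wl_names, "wl_c"))
  wl <- as.numeric(sub("^wl_c?", "", wl_names))
  if (any(diff(wl) <= 0)) {
    fail("read_library: non-monotone wavelength headers in '%s' (near %s)",
         path, wl_names[which(diff(wl) <= 0)[1L] + 1L])
  }
  ids <- dt$id
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    fail("read_library: duplicate sample id '%s' (line %d of '%s')",
         d, which(ids == d)[2L] + 1L + skip, path)
  }
  S <- as.matrix(dt[, wl_names, with = FALSE])
  colnames(S) <- NULL
  if (nrow(S) && max(S, na.rm = TRUE) > 1.5) {
    fail(paste0("read_library: reflectance values look like percent (max %.3g > 1.5) in '%s'; ",
                "store reflectance as a fraction in [0,1]"), max(S, na.rm = TRUE), path)
  }
  spectral_library(
    as.data.frame(dt[, meta_cols, with = FALSE]),
    as.data.frame(dt[, TRAIT_NAMES, with = FALSE]),
    S, wl, provenance = provenance, coarse = coarse
  )
}
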