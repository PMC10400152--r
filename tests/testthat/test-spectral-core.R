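# domain types, preprocessing and file round-trips

test_that("canonical wavelength grid has 2151 points and validates its inputs", {
  g <- wavelength_grid()
  expect_equal(g$n, 2151L)
  expect_equal(g$wavelengths[1], 350)
  expect_equal(g$wavelengths[g$n], 2500)
  expect_error(wavelength_grid(500, 400), "must exceed")
  expect_error(wavelength_grid(350, 2500, 0), "step")
})

test_that("spectrum enforces grid consistency and reflectance range", {
  expect_error(spectrum(c(0.1, 0.2), c(500, 510, 520)), "2 values")
  expect_error(spectrum(c(0.1, 1.2), c(500, 510)), "\\[0,1\\]")
  expect_error(spectrum(c(0.1, 0.2), c(510, 500)), "increasing")
})

test_that("replicate-scan averaging is the pointwise mean", {
  wl <- c(500, 510)
  one <- spectrum(c(0.2, 0.4), wl)
  expect_equal(average_replicate_scans(list(one)), one)
  nine <- average_replicate_scans(rep(list(one), 9))
  expect_equal(nine$values, one$values)
  two <- average_replicate_scans(list(one, spectrum(c(0.4, 0.2), wl)))
  expect_equal(two$values, c(0.3, 0.3))
  expect_error(average_replicate_scans(list()), "non-empty")
  expect_error(
    average_replicate_scans(list(one, spectrum(c(0.2, 0.4), c(600, 610)))),
    "mismatched"
  )
})

test_that("window averaging bins the canonical grid into 216 bands and matches brute force", {
  set.seed(4)
  g <- wavelength_grid()
  vals <- runif(g$n, 0.1, 0.9)
  sp <- spectrum(vals, g)
  coarse <- window_average(sp, 10)
  # brute-force oracle: explicit contiguous windows of 10 points
  starts <- seq(1, g$n, by = 10)
  oracle <- vapply(starts, function(s) mean(vals[s:min(s + 9, g$n)]), numeric(1))
  expect_length(coarse$values, 216L)
  expect_equal(coarse$values, oracle)
  # 215 full windows + the single trailing 2500 nm point
  expect_equal(coarse$wavelengths[1], 355)
  expect_equal(coarse$wavelengths[215], 2495)
  expect_equal(coarse$wavelengths[216], 2500)
})

test_that("window averaging obeys its algebraic properties", {
  set.seed(5)
  wl <- seq(400, 499, by = 1)
  vals <- runif(100, 0.2, 0.8)
  sp <- spectrum(vals, wl)
  # window = step is the identity
  expect_equal(window_average(sp, 1)$values, vals)
  # all-full windows preserve the global mean
  expect_equal(mean(window_average(sp, 10)$values), mean(vals))
  # constant spectrum stays constant
  expect_equal(unique(window_average(spectrum(rep(0.5, 100), wl), 10)$values), 0.5)
  # one 10-point window mean matches the hand sum
  ten <- spectrum(seq(0.1, 1, by = 0.1), seq(400, 409))
  expect_equal(window_average(ten, 10)$values, sum(seq(0.1, 1, by = 0.1)) / 10)
  expect_error(window_average(sp, 0.5), "smaller than")
  expect_error(window_average(sp, 3.5), "multiple")
})

test_that("gravimetric trait derivations follow their formulas", {
  expect_equal(derive_lwc(1.0, 0.25), 75)
  expect_equal(derive_lwc(2.0, 0.5), 75)   # scale invariance
  expect_equal(derive_lwc(1.0, 1.0), 0)    # fully dry leaf
  expect_error(derive_lwc(1.0, 1.2), "exceeds")
  expect_error(derive_lwc(1.0, 0), "positive")
  expect_equal(derive_lma(0.5, 100), 50)   # 100 cm2 = 0.01 m2
  expect_equal(derive_lma(1.0, 100), 100)  # linear in DW
  expect_equal(derive_lma(0.94, 100), 94)
  expect_error(derive_lma(0.5, -1), "positive")
})

test_that("library round-trips through wide CSV, with missing traits as empty fields", {
  lib <- dummy_library(3)
  lib$traits$CHL[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, path)
  back <- read_library(path, provenance = lib$provenance)
  expect_equal(back$meta, lib$meta)
  expect_equal(back$traits, lib$traits)
  expect_equal(back$spectra, lib$spectra, tolerance = 1e-6)
  expect_equal(back$wavelengths, lib$wavelengths)
  expect_true(is.na(back$traits$CHL[2]))
  # missing is missing, not zero
  expect_false(isTRUE(back$traits$CHL[2] == 0))
  # coarse headers round-trip too
  st <- small_study(3, n_lib = c(maize = 5), n_ext = 3)
  write_library(st$library, path)
  back2 <- read_library(path)
  expect_true(back2$coarse)
  expect_equal(back2$wavelengths, st$library$wavelengths)
})

test_that("reader rejects malformed files with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("id,species,dataset,year,environment", TRAIT_NAMES,
                 "wl_0500,wl_0510"), collapse = ",")
  row <- paste(c("A,maize,d,2020,field", rep("1", 9), "0.2,0.3"), collapse = ",")
  writeLines(c(hdr, row, row), path)  # duplicate id 'A'
  expect_error(read_library(path), "duplicate sample id 'A'")
  # percent-scaled reflectance is rejected, not rescaled
  row2 <- paste(c("B,maize,d,2020,field", rep("1", 9), "20,30"), collapse = ",")
  writeLines(c(hdr, row, sub("^A", "B", row2)), path)
  expect_error(read_library(path), "percent")
  # unknown column
  writeLines(c(paste0(hdr, ",bogus"), paste0(row, ",1")), path)
  expect_error(read_library(path), "unknown column")
  # non-monotone wavelength headers
  writeLines(c(sub("wl_0500,wl_0510", "wl_0510,wl_0500", hdr), row), path)
  expect_error(read_library(path), "non-monotone")
})

test_that("library container enforces unique ids and consistent dimensions", {
  lib <- dummy_library(4)
  meta2 <- lib$meta; meta2$id[2] <- meta2$id[1]
  expect_error(spectral_library(meta2, lib$traits, lib$spectra, lib$wavelengths),
               "duplicate sample id")
  expect_error(spectral_library(lib$meta, lib$traits, lib$spectra[1:3, ], lib$wavelengths),
               "row counts differ")
  sub <- subset_library(lib, c("S002", "S004"))
  expect_equal(sub$meta$id, c("S002", "S004"))
  expect_equal(n_samples(combine_libraries(subset_library(lib, 1:2),
                                           subset_library(lib, 3:4))), 4L)
})
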