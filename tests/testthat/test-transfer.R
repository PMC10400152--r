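# spike partitions, extra weighting, scheme runs and the size sweep

test_that("spike partitions have the documented sizes and are deterministic", {
  ext96 <- dummy_library(96, prefix = "C")
  part <- draw_spike(ext96, 20, seed = 1)
  expect_length(part$spike_ids, 20L)
  expect_length(part$test_ids, 76L)
  ext126 <- dummy_library(126, prefix = "Y")
  expect_length(draw_spike(ext126, 20, seed = 1)$test_ids, 106L)
  expect_length(intersect(part$spike_ids, part$test_ids), 0L)
  expect_setequal(c(part$spike_ids, part$test_ids), ext96$meta$id)
  expect_identical(draw_spike(ext96, 20, seed = 5)$spike_ids,
                   draw_spike(ext96, 20, seed = 5)$spike_ids)
  expect_error(draw_spike(ext96, 96, seed = 1), "smaller than")
  expect_error(draw_spike(ext96, 0, seed = 1), "at least 1")
})

test_that("extra weighting replicates spikes to balance the library", {
  lib100 <- dummy_library(100, prefix = "L")
  spike30 <- dummy_library(30, prefix = "K", seed = 3)
  ew <- extra_weight(lib100, spike30)
  expect_equal(ew$replication, 3L)
  expect_equal(n_samples(ew$library), 190L)
  # spike copies are identifiable and complete: r * |spike| of them
  n_copies <- sum(grepl("\\.rep[0-9]+$", ew$library$meta$id))
  expect_equal(n_copies, 3L * 30L)
  # balanced case is a simple concatenation
  ew2 <- extra_weight(lib100, dummy_library(100, prefix = "M", seed = 4))
  expect_equal(ew2$replication, 1L)
  expect_equal(n_samples(ew2$library), 200L)
  # mismatched grids are rejected
  other <- dummy_library(10, prefix = "Q", p = 7)
  expect_error(extra_weight(lib100, other), "grids differ")
})

test_that("case-weight formulation matches physical spike replication for PLSR", {
  lib <- dummy_library(40, prefix = "L", p = 8, seed = 5)
  spike <- dummy_library(10, prefix = "K", p = 8, seed = 6)
  ew <- extra_weight(lib, spike)
  sw <- spike_weights(lib, spike)
  expect_equal(sw$replication, ew$replication)
  y_copies <- trait_values(ew$library, "N")
  y_w <- trait_values(sw$library, "N")
  m_copies <- fit_plsr(ew$library$spectra, y_copies, 4)
  m_w <- fit_plsr(sw$library$spectra, y_w, 4, weights = sw$weights)
  expect_equal(m_copies$B, m_w$B, tolerance = 1e-9)
})

test_that("schemes use the right calibration sets and never see test samples", {
  st <- small_study(31, n_ext = 40, missing = NULL)
  part <- draw_spike(st$external, 15, seed = 2)
  for (scheme in c("library_only", "spike_only", "spiked_library")) {
    res <- run_scheme(st$library, st$external, part, "N", "plsr",
                      plsr_grid(6), scheme, seed = 3)
    expect_length(intersect(res$calibration_ids, res$test_ids), 0L)
    expect_true(res$available)
    expect_true(is.finite(res$report$r2))
    if (scheme == "library_only") {
      expect_setequal(res$calibration_ids, st$library$meta$id)
    }
    if (scheme == "spike_only") {
      expect_setequal(res$calibration_ids, part$spike_ids)
    }
    if (scheme == "spiked_library") {
      expect_equal(res$replication, round(n_samples(st$library) / 15))
      expect_setequal(res$calibration_ids, c(st$library$meta$id, part$spike_ids))
    }
  }
})

test_that("library-only results are invariant to the spike seed", {
  st <- small_study(32, n_ext = 40, missing = NULL)
  p1 <- draw_spike(st$external, 15, seed = 1)
  p2 <- draw_spike(st$external, 15, seed = 99)
  # different partitions share most test samples; evaluate on the common core
  r1 <- run_scheme(st$library, st$external, p1, "N", "plsr", plsr_grid(6),
                   "library_only", seed = 3)
  r2 <- run_scheme(st$library, st$external, p2, "N", "plsr", plsr_grid(6),
                   "library_only", seed = 3)
  expect_false(identical(p1$spike_ids, p2$spike_ids))
  # the fitted library model is identical: same predictions for any sample
  common <- intersect(p1$test_ids, p2$test_ids)
  X <- subset_library(st$external, common)$spectra
  expect_equal(predict(r1$model, X), predict(r2$model, X), tolerance = 1e-12)
})

test_that("a trait absent from the external set is reported unavailable", {
  st <- small_study(33, n_ext = 40)   # camelina: CHL and LMA masked
  part <- draw_spike(st$external, 15, seed = 2)
  res <- run_scheme(st$library, st$external, part, "CHL", "plsr",
                    plsr_grid(6), "spiked_library", seed = 1)
  expect_false(res$available)
  expect_true(is.na(res$report$r2))
  tab <- run_all_schemes(st$library, st$external, part,
                         traits = c("N", "CHL"), grid = plsr_grid(6), seed = 1)
  expect_equal(nrow(tab), 6L)
  expect_true(all(is.na(tab$r2[tab$trait == "CHL"])))
  expect_true(all(is.finite(tab$r2[tab$trait == "N"])))
})

test_that("zero-shift external sets make the three schemes agree", {
  # identical archetypes and distributions, no decoupling: transfer is easy
  # and no scheme should enjoy a systematic edge
  g <- wavelength_grid(400, 2400, 10)
  arch <- default_archetype("maize", g, shift_magnitude = 0)
  diffs_lib <- diffs_spk <- numeric(5)
  for (s in 1:5) {
    cfg <- simulation_config(
      library = c(maize = 80),
      external = list(list(name = "ext", species = "maize", n = 40, missing = NULL)),
      archetypes = list(maize = arch, ext = arch),
      distributions = list(maize = default_trait_distribution("maize"),
                           ext = default_trait_distribution("maize")),
      noise_sd = 0.002, spectral_decoupling = 0, shift_magnitude = 0,
      grid = g, seed = 700 + s)
    st <- generate_study(cfg)
    part <- draw_spike(st$external$ext, 20, seed = s)
    tab <- run_all_schemes(st$library, st$external$ext, part, traits = "N",
                           grid = plsr_grid(6), seed = s)
    r2 <- setNames(tab$r2, tab$scheme)
    diffs_lib[s] <- r2[["spiked_library"]] - r2[["library_only"]]
    diffs_spk[s] <- r2[["spiked_library"]] - r2[["spike_only"]]
  }
  expect_lt(max(abs(diffs_lib)), 0.05)
  expect_lt(max(abs(diffs_spk)), 0.10)
})

test_that("the size sweep holds the pool aside and reports every size x trait", {
  st <- small_study(34, ext_species = "soybean", n_ext = 60, missing = NULL)
  sw <- spike_size_sweep(st$library, st$external, sizes = c(5, 10, 20),
                         pool_size = 20, traits = c("N", "P"),
                         grid = plsr_grid(6), seed = 4)
  expect_equal(nrow(sw), 6L)
  expect_setequal(sw$size, c(5, 10, 20))
  expect_true(all(sw$n == 40))
  expect_length(intersect(attr(sw, "pool_ids"), attr(sw, "eval_ids")), 0L)
  # size = pool uses the whole pool, hence a fixed replication factor
  expect_equal(unique(sw$replication[sw$size == 20]),
               round(n_samples(st$library) / 20))
  expect_error(spike_size_sweep(st$library, st$external, sizes = 30,
                                pool_size = 20), "exceed")
  expect_error(spike_size_sweep(st$library, st$external, sizes = 10,
                                pool_size = 60), "smaller")
})
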