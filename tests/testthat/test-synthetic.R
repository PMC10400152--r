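# synthetic study generator: trait sampling, spectrum rendering, study assembly

test_that("degenerate trait distribution returns the mean vector exactly", {
  means <- c(N = 2.5, P = 0.25, K = 1.8, Mg = 0.25, Ca = 0.5, S = 0.18,
             LWC = 75, CHL = 450, LMA = 55)
  dist <- trait_distribution(means, setNames(rep(0, 9), TRAIT_NAMES))
  draws <- sample_traits(dist, 5, seed = 1)
  for (i in 1:5) expect_equal(unname(draws[i, ]), unname(means))
})

test_that("sampled traits converge to the configured moments and correlations", {
  means <- c(N = 2.5, P = 0.25, K = 1.8, Mg = 0.25, Ca = 0.5, S = 0.18,
             LWC = 75, CHL = 450, LMA = 55)
  sds <- c(N = 0.5, P = 0.05, K = 0.3, Mg = 0.05, Ca = 0.1, S = 0.03,
           LWC = 4, CHL = 100, LMA = 8)
  dist <- trait_distribution(means, sds)
  draws <- sample_traits(dist, 10000, seed = 42)
  expect_lt(abs(mean(draws[, "N"]) - 2.5), 0.02)
  expect_lt(abs(sd(draws[, "N"]) - 0.5), 0.02)
  # a configured 0.9 correlation is recovered above 0.8 at n = 1000
  R <- diag(9); dimnames(R) <- list(TRAIT_NAMES, TRAIT_NAMES)
  R["N", "CHL"] <- R["CHL", "N"] <- 0.9
  dist2 <- trait_distribution(means, sds, corr = R)
  draws2 <- sample_traits(dist2, 1000, seed = 7)
  expect_gt(cor(draws2[, "N"], draws2[, "CHL"]), 0.8)
  # truncation bounds are respected
  expect_true(all(draws >= 0))
})

test_that("non-PSD correlation matrices are rejected as configuration errors", {
  R <- diag(9); dimnames(R) <- list(TRAIT_NAMES, TRAIT_NAMES)
  R["N", "P"] <- R["P", "N"] <- 0.9
  R["P", "K"] <- R["K", "P"] <- 0.9
  R["N", "K"] <- R["K", "N"] <- -0.9
  means <- setNames(rep(1, 9), TRAIT_NAMES)
  dist <- trait_distribution(means, setNames(rep(0.1, 9), TRAIT_NAMES), corr = R)
  expect_error(sample_traits(dist, 10, seed = 1), "positive-semidefinite")
})

test_that("rendering is baseline + shift under zero sensitivities and localized in traits", {
  g <- wavelength_grid(400, 1600, 10)
  wl <- g$wavelengths
  base <- 0.1 + 0.3 * exp(-0.5 * ((wl - 900) / 400)^2)
  shift <- rep(0.02, length(wl))
  bands0 <- data.frame(trait = c("N", "LWC"), center = c(500, 1000),
                       width = c(15, 15), sens = c(0, 0))
  arch0 <- species_archetype("z", g, base, bands0, shift)
  traits <- c(N = 2, LWC = 70)
  sp <- render_spectrum(arch0, traits, noise_sd = 0, seed = 1)
  expect_equal(sp$values, base + shift)
  # doubling one trait deepens only its own bands
  bands <- data.frame(trait = c("N", "LWC"), center = c(500, 1000),
                      width = c(15, 15), sens = c(0.02, 0.001))
  arch <- species_archetype("z", g, base, bands, shift)
  s1 <- render_spectrum(arch, c(N = 2, LWC = 70), 0, 1)$values
  s2 <- render_spectrum(arch, c(N = 4, LWC = 70), 0, 1)$values
  delta <- s1 - s2
  far <- abs(wl - 500) > 120
  expect_lt(max(abs(delta[far])), 1e-10)
  expect_equal(delta[wl == 500], 2 * 0.02)
  # determinism at fixed seed, even with noise
  n1 <- render_spectrum(arch, traits, 0.01, 9)
  n2 <- render_spectrum(arch, traits, 0.01, 9)
  expect_identical(n1, n2)
  # missing referenced trait is named
  expect_error(render_spectrum(arch, c(N = 2), 0, 1), "LWC")
})

test_that("archetype invariants are enforced", {
  g <- wavelength_grid(400, 700, 10)
  wl <- g$wavelengths
  expect_error(species_archetype("a", g, rep(0.99, length(wl))), "baseline")
  expect_error(species_archetype("a", g, rep(0.5, length(wl)),
                                 bands = data.frame(trait = "N", center = 300,
                                                    width = 10, sens = 0.1)),
               "centers")
  expect_error(species_archetype("a", g, rep(0.5, length(wl)),
                                 bands = data.frame(trait = "N", center = 500,
                                                    width = 0, sens = 0.1)),
               "width")
})

test_that("generate_study produces the configured composition with unique ids", {
  cfg <- simulation_config(
    library = c(maize = 100, sorghum = 80),
    external = list(list(name = "soybean", species = "soybean", n = 30,
                         missing = NULL)),
    grid = wavelength_grid(400, 900, 10), seed = 5
  )
  st <- generate_study(cfg)
  expect_equal(n_samples(st$library), 180L)
  expect_equal(as.integer(table(st$library$meta$species)[c("maize", "sorghum")]),
               c(100L, 80L))
  expect_length(st$external, 1L)
  expect_equal(n_samples(st$external$soybean), 30L)
  all_ids <- c(st$library$meta$id, st$external$soybean$meta$id)
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("missing-trait masks flag every sample of the external set", {
  cfg <- simulation_config(
    library = c(maize = 20),
    external = list(list(name = "camelina", species = "camelina", n = 10,
                         missing = c("CHL", "LMA"))),
    grid = wavelength_grid(400, 900, 10), seed = 2
  )
  st <- generate_study(cfg)
  expect_true(all(is.na(st$external$camelina$traits$CHL)))
  expect_true(all(is.na(st$external$camelina$traits$LMA)))
  expect_true(all(!is.na(st$external$camelina$traits$N)))
  # library traits untouched
  expect_true(all(!is.na(st$library$traits$CHL)))
})

test_that("an identical simulation config reproduces the study byte for byte", {
  cfg <- simulation_config(
    library = c(maize = 15, sorghum = 10),
    external = list(list(name = "soybean", species = "soybean", n = 8,
                         missing = NULL)),
    grid = wavelength_grid(400, 900, 10), seed = 99
  )
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("zero shift with identical archetypes makes library and external indistinguishable", {
  # two-sample t-test on PC1 scores across 20 seeds: p-values behave like a null
  g <- wavelength_grid(400, 2400, 20)
  arch <- default_archetype("maize", g, shift_magnitude = 0)
  pvals <- numeric(20)
  for (s in 1:20) {
    cfg <- simulation_config(
      library = c(maize = 100),
      external = list(list(name = "ext", species = "maize", n = 100, missing = NULL)),
      archetypes = list(maize = arch, ext = arch),
      distributions = list(maize = default_trait_distribution("maize"),
                           ext = default_trait_distribution("maize")),
      shift_magnitude = 0, grid = g, seed = 3000 + s
    )
    st <- generate_study(cfg)
    pc <- pca_project(rbind(st$library$spectra, st$external$ext$spectra),
                      labels = rep(c("lib", "ext"), each = 100))
    pvals[s] <- t.test(pc$scores[pc$labels == "lib", 1],
                       pc$scores[pc$labels == "ext", 1])$p.value
  }
  # under the null ~5% of tests reject at alpha = 0.05; allow up to 4/20
  expect_lte(sum(pvals < 0.05), 4)
  expect_gt(mean(pvals), 0.2)
})
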