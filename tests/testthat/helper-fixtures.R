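# shared fixtures, all generated in code

# minimal hand-built library on an arbitrary grid, for container/transfer
# plumbing tests
dummy_library <- function(n, prefix = "S", p = 5, seed = 1) {
  wl <- seq(500, by = 10, length.out = p)
  set.seed(seed)
  traits <- as.data.frame(matrix(runif(n * 9, 0.1, 0.9), n, 9,
                                 dimnames = list(NULL, TRAIT_NAMES)))
  traits$LWC <- runif(n, 60, 90)
  traits$CHL <- runif(n, 300, 500)
  traits$LMA <- runif(n, 30, 60)
  spectral_library(
    meta = data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
                      species = "maize", dataset = "dummy", year = 2020L,
                      environment = "field", stringsAsFactors = FALSE),
    traits = traits,
    spectra = matrix(runif(n * p, 0.1, 0.6), n, p),
    wavelengths = wl
  )
}

# small two-species study with one shifted external set, on the raw grid
small_study <- function(seed, n_lib = c(maize = 110, sorghum = 110),
                        ext_species = "camelina", n_ext = 60,
                        missing = c("CHL", "LMA"), window = 10, ...) {
  cfg <- simulation_config(
    library = n_lib,
    external = list(list(name = ext_species, species = ext_species,
                         n = n_ext, missing = missing)),
    seed = seed, ...
  )
  st <- generate_study(cfg)
  list(library = window_average(st$library, window),
       external = window_average(st$external[[ext_species]], window))
}

# fully noiseless study with exactly three spectrally coupled traits
# (N, LWC, LMA), used for rank/recovery checks
noiseless_config <- function(seed, n = 200, grid = wavelength_grid(400, 2400, 10)) {
  sds <- setNames(rep(0, 9), TRAIT_NAMES)
  sds[c("N", "LWC", "LMA")] <- c(0.7, 5, 12)
  means <- c(N = 2.5, P = 0.25, K = 1.8, Mg = 0.25, Ca = 0.5, S = 0.18,
             LWC = 75, CHL = 450, LMA = 55)
  dist <- trait_distribution(means, sds, corr = diag(9))
  bands <- data.frame(
    trait = c("N", "LWC", "LMA"),
    center = c(1650, 1450, 1100),
    width = c(60, 55, 200),
    sens = c(1.2e-2, 1.2e-3, 9e-4))
  wl <- grid$wavelengths
  baseline <- 0.06 + 0.40 * stats::plogis((wl - 715) / 20)
  arch <- species_archetype("flat", grid, baseline = baseline, bands = bands)
  simulation_config(
    library = c(flatspecies = n),
    distributions = list(flatspecies = dist),
    archetypes = list(flatspecies = arch),
    noise_sd = 0, spectral_decoupling = 0, shift_magnitude = 0,
    grid = grid, seed = seed
  )
}
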