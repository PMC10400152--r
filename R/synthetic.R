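# Synthetic leaf-spectrum generator.
#
# Stands in for a physical spectral library: each species gets a smooth
# reflectance archetype (VIS floor, green bump, red edge, NIR plateau, mild
# SWIR decline), traits are drawn from a truncated multivariate normal, and
# each trait removes reflectance through Gaussian absorption bands placed at
# chemically motivated wavelengths (chlorophyll in the blue/red, water at
# 970/1450/1940 nm, protein N in the SWIR, ...). Domain shift between
# "library" and "external" species is an additive smooth baseline offset
# plus a multiplicative perturbation of the band sensitivities.

#' Trait distribution for one species
#'
#' Truncated multivariate normal over the nine traits: marginal means/SDs, a
#' correlation matrix and physical truncation bounds (percent traits in
#' `[0, 100]`, CHL and LMA non-negative).
#'
#' @param mean,sd named numeric vectors over [TRAIT_NAMES] (units as in
#'   [TRAIT_UNITS]); SDs must be non-negative.
#' @param corr 9x9 correlation matrix (unit diagonal, symmetric,
#'   positive-semidefinite); default [default_trait_correlation()].
#' @param lower,upper truncation bounds; defaults are the physical bounds.
#' @return An object of class `trait_distribution`.
#' @export
trait_distribution <- function(mean, sd, corr = default_trait_correlation(),
                               lower = NULL, upper = NULL) {
  stopifnot(all(TRAIT_NAMES %in% names(mean)), all(TRAIT_NAMES %in% names(sd)))
  mean <- mean[TRAIT_NAMES]; sd <- sd[TRAIT_NAMES]
  if (any(sd < 0)) fail("trait_distribution: negative SD")
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)) ||
      !isTRUE(all.equal(unname(diag(corr)), rep(1, ncol(corr))))) {
    fail("trait_distribution: correlation matrix must be symmetric with unit diagonal")
  }
  if (is.null(lower)) lower <- c(N = 0, P = 0, K = 0, Mg = 0, Ca = 0, S = 0,
                                 LWC = 0, CHL = 0, LMA = 0)
  if (is.null(upper)) upper <- c(N = 100, P = 100, K = 100, Mg = 100, Ca = 100,
                                 S = 100, LWC = 100, CHL = Inf, LMA = Inf)
  structure(list(mean = mean, sd = sd, corr = corr,
                 lower = lower[TRAIT_NAMES], upper = upper[TRAIT_NAMES]),
            class = "trait_distribution")
}

#' Default inter-trait correlation structure
#'
#' Encodes the biochemical associations the generator emulates, chiefly the
#' strong N-chlorophyll link (a large share of leaf N sits in chlorophyll
#' and photosynthetic proteins), weaker N-P/N-S protein associations, the
#' Mg-chlorophyll link and a mild negative LWC-LMA relation.
#'
#' @return A 9x9 positive-definite correlation matrix over [TRAIT_NAMES].
#' @export
default_trait_correlation <- function() {
  R <- diag(9)
  dimnames(R) <- list(TRAIT_NAMES, TRAIT_NAMES)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("N", "CHL", 0.75)
  set_r("N", "S", 0.50)
  set_r("N", "P", 0.35)
  set_r("N", "Mg", 0.30)
  set_r("Mg", "CHL", 0.40)
  set_r("Ca", "Mg", 0.35)
  set_r("K", "LWC", 0.30)
  set_r("LWC", "LMA", -0.35)
  R
}

#' Sample trait vectors from a distribution
#'
#' Rejection sampling on multivariate-normal draws: draws outside the
#' truncation bounds are discarded until `n` vectors are collected.
#'
#' @param dist a [trait_distribution].
#' @param n number of vectors, >= 1.
#' @param seed integer seed; fixes the output exactly.
#' @return `n x 9` numeric matrix with columns [TRAIT_NAMES].
#' @export
sample_traits <- function(dist, n, seed) {
  stopifnot(inherits(dist, "trait_distribution"), n >= 1)
  ev <- eigen(dist$corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    fail("sample_traits: correlation matrix is not positive-semidefinite (min eigenvalue %.3g)",
         min(ev))
  }
  D <- diag(dist$sd, 9)
  Sigma <- D %*% dist$corr %*% D
  with_seed(seed, {
    out <- matrix(NA_real_, 0L, 9L)
    tries <- 0L
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 100L)
      draw <- MASS::mvrnorm(m, mu = dist$mean, Sigma = Sigma)
      draw <- matrix(draw, ncol = 9L, dimnames = list(NULL, TRAIT_NAMES))
      ok <- rep(TRUE, nrow(draw))
      for (j in seq_len(9L)) {
        ok <- ok & draw[, j] >= dist$lower[j] & draw[, j] <= dist$upper[j]
      }
      out <- rbind(out, draw[ok, , drop = FALSE])
      tries <- tries + 1L
      if (tries > 1000L) fail("sample_traits: truncation bounds reject nearly all draws")
    }
    out[seq_len(n), , drop = FALSE]
  })
}

#' Default trait-linked absorption bands
#'
#' One row per Gaussian absorption feature: trait, center (nm), width (nm)
#' and sensitivity (reflectance removed per trait unit). Chlorophyll absorbs
#' in the blue and red; water at 970, 1450 and 1940 nm; protein-bound N in
#' the 1550--1750 nm amide region; P, K, Mg, Ca, S through weaker indirect
#' SWIR features; LMA through a broad path-length term centered in the NIR.
#'
#' @return data.frame with columns `trait`, `center`, `width`, `sens`.
#' @export
default_bands <- function() {
  data.frame(
    trait = c("CHL", "CHL",
              "N", "N", "N",
              "P", "P",
              "K", "K",
              "Mg", "Mg",
              "Ca", "Ca",
              "S", "S",
              "LWC", "LWC", "LWC",
              "LMA", "LMA"),
    center = c(430, 660,
               1650, 1740, 2180,
               910, 2150,
               1420, 2260,
               530, 2380,
               1770, 2340,
               1510, 2050,
               970, 1450, 1940,
               1100, 2300),
    width = c(25, 30,
              60, 40, 50,
              40, 60,
              60, 70,
              40, 60,
              50, 60,
              50, 60,
              45, 55, 70,
              300, 80),
    sens = c(2.2e-4, 2.6e-4,
             1.2e-2, 8e-3, 6e-3,
             2e-2, 8e-2,
             1.5e-2, 1.2e-2,
             5e-2, 4e-2,
             3e-2, 2.5e-2,
             4e-2, 6e-2,
             4e-4, 1.2e-3, 1.8e-3,
             9e-4, 5e-4),
    stringsAsFactors = FALSE
  )
}

#' Species spectral archetype
#'
#' Baseline reflectance curve, trait-linked absorption bands and an additive
#' smooth shift curve encoding domain shift relative to the library species.
#'
#' @param name species/dataset label.
#' @param wavelengths working grid (nm) or a [wavelength_grid].
#' @param baseline numeric baseline reflectance per grid point, within
#'   `[0.02, 0.95]`.
#' @param bands data.frame as in [default_bands()]; centers must lie in
#'   `[350, 2500]`, widths > 0.
#' @param shift additive smooth offset curve (same length as `baseline`);
#'   zero for library species.
#' @return An object of class `species_archetype`.
#' @export
species_archetype <- function(name, wavelengths, baseline,
                              bands = default_bands(), shift = 0 * baseline) {
  if (inherits(wavelengths, "wavelength_grid")) wavelengths <- wavelengths$wavelengths
  stopifnot(length(baseline) == length(wavelengths), length(shift) == length(baseline))
  if (any(baseline < 0.02 | baseline > 0.95)) {
    fail("species_archetype: baseline outside [0.02, 0.95]")
  }
  stopifnot(all(c("trait", "center", "width", "sens") %in% names(bands)))
  if (any(bands$center < 350 | bands$center > 2500)) {
    fail("species_archetype: band centers must lie within [350, 2500] nm")
  }
  if (any(bands$width <= 0)) fail("species_archetype: band widths must be positive")
  bad <- setdiff(bands$trait, TRAIT_NAMES)
  if (length(bad)) fail("species_archetype: unknown band trait '%s'", bad[1L])
  structure(list(name = name, wavelengths = as.numeric(wavelengths),
                 baseline = as.numeric(baseline), bands = bands,
                 shift = as.numeric(shift)),
            class = "species_archetype")
}

# smooth leaf-like baseline: VIS floor, green bump, red edge to NIR plateau,
# mild SWIR decline (water dips come from the LWC bands, not the baseline)
leaf_baseline <- function(wl, vis_floor = 0.05, green = 0.08, plateau = 0.47) {
  b <- vis_floor +
    green * gauss_band(wl, 550, 35) +
    (plateau - vis_floor) * sigmoid((wl - 715) / 20) -
    0.10 * sigmoid((wl - 1800) / 250)
  pmin(pmax(b, 0.02), 0.95)
}

# smooth unit shift curve; scaled per species by shift_scale * magnitude
shift_basis <- function(wl) {
  0.02 +
    0.03 * gauss_band(wl, 1200, 300) -
    0.02 * gauss_band(wl, 500, 80) +
    0.015 * gauss_band(wl, 2100, 200)
}

#' Built-in species archetypes
#'
#' @param species one of `"maize"`, `"sorghum"`, `"soybean"`, `"camelina"`,
#'   `"maize_external"`, `"sorghum_external"`.
#' @param wavelengths working grid (nm) or a [wavelength_grid].
#' @param shift_magnitude global multiplier on the domain-shift strength;
#'   `0` removes the shift entirely.
#' @return A [species_archetype]. Library species (maize, sorghum) carry no
#'   shift; external species carry per-species shift scales (camelina
#'   largest, as the most spectrally distinct group).
#' @export
default_archetype <- function(species, wavelengths = wavelength_grid(),
                              shift_magnitude = 1) {
  if (inherits(wavelengths, "wavelength_grid")) wavelengths <- wavelengths$wavelengths
  pars <- switch(species,
    maize            = list(vis = 0.050, green = 0.080, plateau = 0.47, scale = 0.0),
    sorghum          = list(vis = 0.048, green = 0.075, plateau = 0.44, scale = 0.0),
    soybean          = list(vis = 0.055, green = 0.090, plateau = 0.50, scale = 1.0),
    camelina         = list(vis = 0.060, green = 0.100, plateau = 0.52, scale = 1.6),
    maize_external   = list(vis = 0.050, green = 0.080, plateau = 0.47, scale = 0.5),
    sorghum_external = list(vis = 0.048, green = 0.075, plateau = 0.44, scale = 0.5),
    fail("default_archetype: no built-in archetype for species '%s'", species)
  )
  base <- leaf_baseline(wavelengths, pars$vis, pars$green, pars$plateau)
  shift <- pars$scale * shift_magnitude * shift_basis(wavelengths)
  bands <- default_bands()
  # band-sensitivity perturbation: fixed alternating pattern so external
  # species also differ in how strongly each feature expresses its trait
  jitter <- rep_len(c(1, -0.8, 0.6, -0.5, 0.9, -0.7), nrow(bands))
  bands$sens <- bands$sens * (1 + 0.25 * pars$scale * shift_magnitude * jitter)
  species_archetype(species, wavelengths, base, bands, shift)
}

#' Render a reflectance spectrum from traits
#'
#' `reflectance = clip(baseline + shift - sum_bands sens * trait *
#' gauss(center, width) + noise, 0, 1)`.
#'
#' @param archetype a [species_archetype].
#' @param traits named numeric vector containing every trait referenced by
#'   the archetype's bands.
#' @param noise_sd per-point Gaussian noise SD (reflectance units), >= 0.
#' @param seed integer seed; output is deterministic given it.
#' @return A [spectrum] on the archetype's grid.
#' @export
render_spectrum <- function(archetype, traits, noise_sd = 0, seed = 1) {
  stopifnot(inherits(archetype, "species_archetype"))
  need <- unique(archetype$bands$trait)
  miss <- need[!(need %in% names(traits)) | is.na(traits[need])]
  if (length(miss)) {
    fail("render_spectrum: trait '%s' referenced by a band but not supplied", miss[1L])
  }
  tm <- matrix(traits[need], nrow = 1L, dimnames = list(NULL, need))
  vals <- render_spectra(archetype, tm, noise_sd, seed)
  spectrum(as.numeric(vals), archetype$wavelengths)
}

# vectorized renderer: trait_mat is n x (>= referenced traits) with named
# columns; returns an n x p reflectance matrix clipped to [0, 1]
render_spectra <- function(archetype, trait_mat, noise_sd, seed) {
  if (noise_sd < 0) fail("render_spectrum: noise_sd must be non-negative")
  wl <- archetype$wavelengths
  b <- archetype$bands
  G <- vapply(seq_len(nrow(b)),
              function(i) b$sens[i] * gauss_band(wl, b$center[i], b$width[i]),
              numeric(length(wl)))           # p x n_bands
  depth <- trait_mat[, b$trait, drop = FALSE] %*% t(G)  # n x p
  base <- matrix(archetype$baseline + archetype$shift,
                 nrow(trait_mat), length(wl), byrow = TRUE)
  vals <- base - depth
  if (noise_sd > 0) {
    vals <- vals + with_seed(seed, matrix(stats::rnorm(length(vals), 0, noise_sd),
                                          nrow(vals), ncol(vals)))
  }
  pmin(pmax(vals, 0), 1)
}

#' Built-in trait distributions
#'
#' Field-plausible means and SDs per species (assumptions of the generator,
#' not measurements): library-scale nutrient levels for maize and sorghum,
#' higher N/Ca for the legume soybean, higher S and Ca for the brassica
#' camelina, and mildly shifted external maize/sorghum populations
#' (different varieties/treatments than the library).
#'
#' @param species as in [default_archetype()].
#' @return A [trait_distribution].
#' @export
default_trait_distribution <- function(species) {
  tbl <- list(
    maize = list(
      mean = c(N = 2.8, P = 0.26, K = 1.9, Mg = 0.25, Ca = 0.45, S = 0.18, LWC = 78, CHL = 480, LMA = 55),
      sd   = c(N = 0.70, P = 0.08, K = 0.60, Mg = 0.08, Ca = 0.18, S = 0.05, LWC = 5, CHL = 140, LMA = 12)),
    sorghum = list(
      mean = c(N = 2.4, P = 0.22, K = 1.6, Mg = 0.28, Ca = 0.50, S = 0.16, LWC = 75, CHL = 430, LMA = 50),
      sd   = c(N = 0.60, P = 0.07, K = 0.50, Mg = 0.09, Ca = 0.20, S = 0.05, LWC = 5, CHL = 120, LMA = 10)),
    soybean = list(
      mean = c(N = 4.2, P = 0.30, K = 2.0, Mg = 0.35, Ca = 0.90, S = 0.22, LWC = 78, CHL = 420, LMA = 40),
      sd   = c(N = 0.80, P = 0.09, K = 0.60, Mg = 0.10, Ca = 0.30, S = 0.06, LWC = 4, CHL = 110, LMA = 8)),
    camelina = list(
      mean = c(N = 3.5, P = 0.35, K = 2.4, Mg = 0.30, Ca = 1.10, S = 0.50, LWC = 80, CHL = 400, LMA = 35),
      sd   = c(N = 0.90, P = 0.10, K = 0.70, Mg = 0.10, Ca = 0.35, S = 0.15, LWC = 4, CHL = 100, LMA = 7)),
    maize_external = list(
      mean = c(N = 2.2, P = 0.24, K = 2.2, Mg = 0.30, Ca = 0.55, S = 0.17, LWC = 74, CHL = 400, LMA = 60),
      sd   = c(N = 0.60, P = 0.08, K = 0.60, Mg = 0.09, Ca = 0.20, S = 0.05, LWC = 5, CHL = 120, LMA = 12)),
    sorghum_external = list(
      mean = c(N = 2.7, P = 0.27, K = 1.8, Mg = 0.25, Ca = 0.42, S = 0.18, LWC = 77, CHL = 470, LMA = 45),
      sd   = c(N = 0.60, P = 0.07, K = 0.50, Mg = 0.08, Ca = 0.18, S = 0.05, LWC = 5, CHL = 120, LMA = 9))
  )
  if (!species %in% names(tbl)) {
    fail("default_trait_distribution: no built-in distribution for species '%s'", species)
  }
  trait_distribution(tbl[[species]]$mean, tbl[[species]]$sd)
}

#' Default spectral-decoupling fractions
#'
#' Fraction of each trait's SD that is *not* expressed in the spectrum —
#' laboratory assay error plus biology with no optical signature. The
#' reported trait value and the spectrally expressed value differ by a
#' Gaussian deviation of `frac * sd`, capping the attainable calibration
#' R^2 at `1 - frac^2`. Defaults are sized so per-trait internal-CV
#' performance lands at a realistic scale (strongly optical CHL/LMA/N high,
#' free-ion nutrients and LWC much lower): ceilings of about 0.84 (N),
#' 0.58 (P), 0.51 (K), 0.75 (Mg), 0.75 (Ca), 0.56 (S), 0.44 (LWC),
#' 0.92 (CHL), 0.84 (LMA).
#'
#' @return Named numeric vector over [TRAIT_NAMES], values in `[0, 1]`.
#' @export
default_spectral_decoupling <- function() {
  c(N = 0.40, P = 0.65, K = 0.70, Mg = 0.50, Ca = 0.50, S = 0.66,
    LWC = 0.75, CHL = 0.28, LMA = 0.40)
}

#' Simulation configuration
#'
#' Fully specifies a synthetic study: library species and sizes, external
#' sets (name, species, size, missing-trait mask), per-dataset trait
#' distributions and archetypes, per-scan noise, domain-shift magnitude and
#' the seed that fixes every draw.
#'
#' @param library data.frame with columns `species`, `n` (or a named integer
#'   vector), the library composition.
#' @param external list of `list(name=, species=, n=, missing=)` entries;
#'   `missing` is a character vector of traits not measured for that set.
#' @param distributions named list of [trait_distribution]s keyed by library
#'   species name and external set name; unspecified keys fall back to
#'   [default_trait_distribution()] for the entry's species.
#' @param archetypes named list of [species_archetype]s keyed the same way;
#'   unspecified keys fall back to [default_archetype()].
#' @param noise_sd per-scan reflectance noise SD (default 0.005).
#' @param spectral_decoupling named fractions of trait SD not expressed in
#'   the spectrum (see [default_spectral_decoupling()]); set to zero for a
#'   fully noiseless, exactly recoverable study.
#' @param shift_magnitude domain-shift strength multiplier (default 1).
#' @param grid a [wavelength_grid] (default the canonical 350--2500 nm, 1 nm
#'   grid).
#' @param seed integer root seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(library, external = list(),
                              distributions = list(), archetypes = list(),
                              noise_sd = 0.005,
                              spectral_decoupling = default_spectral_decoupling(),
                              shift_magnitude = 1,
                              grid = wavelength_grid(), seed = 1) {
  if (!is.data.frame(library)) {
    library <- data.frame(species = names(library), n = as.integer(library),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("species", "n") %in% names(library)))
  if (any(library$n < 1)) fail("simulation_config: library sample counts must be >= 1")
  for (e in external) {
    stopifnot(is.list(e), !is.null(e$name), !is.null(e$species), !is.null(e$n))
    if (e$n < 1) fail("simulation_config: external sample counts must be >= 1")
    bad <- setdiff(e$missing, TRAIT_NAMES)
    if (length(bad)) fail("simulation_config: unknown trait '%s' in missing mask", bad[1L])
  }
  nm <- vapply(external, `[[`, character(1), "name")
  if (anyDuplicated(nm)) fail("simulation_config: duplicate external set name")
  if (noise_sd < 0) fail("simulation_config: noise_sd must be >= 0")
  if (length(spectral_decoupling) == 1L && is.null(names(spectral_decoupling))) {
    spectral_decoupling <- stats::setNames(rep(spectral_decoupling, 9L), TRAIT_NAMES)
  }
  stopifnot(all(TRAIT_NAMES %in% names(spectral_decoupling)))
  if (any(spectral_decoupling < 0 | spectral_decoupling > 1)) {
    fail("simulation_config: spectral_decoupling fractions must lie in [0, 1]")
  }
  stopifnot(inherits(grid, "wavelength_grid"))
  structure(list(library = library, external = external,
                 distributions = distributions, archetypes = archetypes,
                 noise_sd = noise_sd,
                 spectral_decoupling = spectral_decoupling[TRAIT_NAMES],
                 shift_magnitude = shift_magnitude,
                 grid = grid, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default full-scale study configuration
#'
#' Mirrors the structure of the reference study: a 2460-sample library of
#' maize (1571) and sorghum (889) plus four external sets — soybean (126),
#' camelina (96, CHL and LMA unmeasured), maize (163) and sorghum (60) — for
#' 445 external samples in total.
#'
#' @param seed root seed.
#' @param n_scale optional multiplier on every sample count (counts are
#'   rounded and floored at 20), for scaled-down runs.
#' @param grid working [wavelength_grid].
#' @param shift_magnitude,noise_sd generator controls, see
#'   [simulation_config()].
#' @return A [simulation_config].
#' @export
default_simulation_config <- function(seed = 1, n_scale = 1,
                                      grid = wavelength_grid(),
                                      shift_magnitude = 1, noise_sd = 0.005,
                                      spectral_decoupling = default_spectral_decoupling()) {
  sc <- function(n) max(20L, as.integer(round(n * n_scale)))
  simulation_config(
    library = data.frame(species = c("maize", "sorghum"),
                         n = c(sc(1571), sc(889)), stringsAsFactors = FALSE),
    external = list(
      list(name = "soybean",  species = "soybean",          n = sc(126), missing = NULL),
      list(name = "camelina", species = "camelina",         n = sc(96),
           missing = c("CHL", "LMA")),
      list(name = "maize_ext",   species = "maize_external",   n = sc(163), missing = NULL),
      list(name = "sorghum_ext", species = "sorghum_external", n = sc(60),  missing = NULL)
    ),
    noise_sd = noise_sd, spectral_decoupling = spectral_decoupling,
    shift_magnitude = shift_magnitude, grid = grid, seed = seed
  )
}

# resolve the distribution / archetype for one dataset entry
resolve_dist <- function(config, key, species) {
  if (!is.null(config$distributions[[key]])) return(config$distributions[[key]])
  default_trait_distribution(species)
}
resolve_arch <- function(config, key, species) {
  if (!is.null(config$archetypes[[key]])) return(config$archetypes[[key]])
  default_archetype(species, config$grid, config$shift_magnitude)
}

#' Generate a synthetic study
#'
#' Draws the library and every external set defined by a
#' [simulation_config]: traits from each dataset's truncated multivariate
#' normal, spectra from its archetype, missing-trait masks applied to the
#' reported (not the generated) traits — an unmeasured trait still shapes
#' the spectrum, as in a real leaf.
#'
#' @param config a [simulation_config].
#' @return List with elements `library` (a [spectral_library]) and
#'   `external` (named list of [spectral_library]s).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  make_set <- function(key, species, n, missing, role) {
    dist <- resolve_dist(config, key, species)
    arch <- resolve_arch(config, key, species)
    if (!isTRUE(all.equal(arch$wavelengths, config$grid$wavelengths))) {
      fail("generate_study: archetype '%s' is not on the configured grid", key)
    }
    traits <- sample_traits(dist, n, derive_seed(config$seed, paste0("traits/", key)))
    # the spectrum expresses the trait up to a decoupled share of its SD
    # (assay error + non-optical biology); reported traits stay unperturbed
    dec_sd <- config$spectral_decoupling * dist$sd
    expressed <- traits
    if (any(dec_sd > 0)) {
      expressed <- traits + with_seed(
        derive_seed(config$seed, paste0("decouple/", key)),
        matrix(stats::rnorm(n * 9L, 0, rep(dec_sd, each = n)), n, 9L))
    }
    S <- render_spectra(arch, expressed, config$noise_sd,
                        derive_seed(config$seed, paste0("noise/", key)))
    traits <- as.data.frame(traits)
    if (length(missing)) traits[missing] <- NA_real_
    meta <- data.frame(
      id = sprintf("%s_%s_%05d", toupper(role), key, seq_len(n)),
      species = species, dataset = key,
      year = if (role == "lib") 2019L else 2020L,
      environment = if (role == "lib") "field" else "greenhouse",
      stringsAsFactors = FALSE
    )
    spectral_library(meta, traits, S, config$grid$wavelengths,
                     provenance = sprintf("synthetic %s set '%s' (seed %d)",
                                          role, key, config$seed))
  }
  lib_parts <- lapply(seq_len(nrow(config$library)), function(i) {
    make_set(config$library$species[i], config$library$species[i],
             config$library$n[i], NULL, "lib")
  })
  library <- do.call(combine_libraries,
                     c(lib_parts, provenance = sprintf("synthetic library (seed %d)", config$seed)))
  external <- list()
  for (e in config$external) {
    external[[e$name]] <- make_set(e$name, e$species, e$n, e$missing, "ext")
  }
  list(library = library, external = external)
}
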