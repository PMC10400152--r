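# Config-driven orchestration of the three experiments: internal CV
# comparison, three-scheme transfer, and the spike-size sweep. All defaults
# mirror the reference workflow (10 nm windows, k = 10, LV grid 1..30, MLP
# grid 4x3, n_spike = 20, sweep sizes 10..50 from a 50-sample pool). Every
# output file is stamped with the FNV-1a hash of the run configuration, and
# all randomness flows from one root seed through [derive_seed()].

#' Default run configuration
#'
#' @param out_dir output directory for all pipeline commands.
#' @param seed root seed.
#' @param n_scale sample-count multiplier passed to
#'   [default_simulation_config()] (1 = full study scale).
#' @return A nested list understood by the `cmd_*` commands; serialize with
#'   [yaml::write_yaml()] and load with [load_run_config()].
#' @export
default_run_config <- function(out_dir = "specspike_run", seed = 1L, n_scale = 1) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(n_scale = n_scale, noise_sd = 0.005, shift_magnitude = 1),
    preprocess = list(window_nm = 10),
    traits = TRAIT_NAMES,
    methods = "plsr",
    plsr = list(max_lv = 30L),
    mlp = list(hidden_sizes = c(5L, 10L, 15L, 20L), l2 = c(0.005, 0.01, 0.03)),
    cv = list(k = 10L),
    spike = list(n_spike = 20L),
    sweep = list(external = "soybean", sizes = c(10L, 20L, 30L, 40L, 50L),
                 pool_size = 50L)
  )
}

#' Load a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  merge_cfg <- function(base, user) {
    for (nm in names(user)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
        merge_cfg(base[[nm]], user[[nm]]) } else user[[nm]]
    }
    base
  }
  merge_cfg(base, user)
}

#' Hash of a run configuration
#'
#' @param config a run-configuration list.
#' @return 8-hex-digit FNV-1a hash of the YAML serialization, stamped into
#'   every output file header.
#' @export
config_hash <- function(config) fnv1a32(yaml::as.yaml(config))

cfg_grid <- function(config, method) {
  if (method == "plsr") plsr_grid(config$plsr$max_lv)
  else mlp_grid(config$mlp$hidden_sizes, config$mlp$l2)
}

write_stamped_csv <- function(df, path, hash) {
  writeLines(sprintf("# config_hash: %s", hash), path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a pipeline CSV output
#'
#' Skips the config-hash header comment.
#'
#' @param path CSV path written by a `cmd_*` command.
#' @return data.frame.
#' @export
read_stamped_csv <- function(path) {
  as.data.frame(data.table::fread(path, skip = 1L))
}

check_outputs <- function(paths, force) {
  exist <- paths[file.exists(paths)]
  if (length(exist) && !force) {
    fail("output '%s' already exists (use force = TRUE to overwrite)", exist[1L])
  }
}

#' Simulate and write a synthetic study
#'
#' Writes `library.csv`, one `external_<name>.csv` per external set, and a
#' `manifest.json` with the config hash, seed and per-file sample counts.
#'
#' @param config run configuration (see [default_run_config()]).
#' @param force overwrite existing outputs.
#' @return Invisible list with the manifest contents.
#' @export
cmd_simulate <- function(config = default_run_config(), force = FALSE) {
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- default_simulation_config(
    seed = derive_seed(config$seed, "simulate"),
    n_scale = config$simulate$n_scale,
    shift_magnitude = config$simulate$shift_magnitude,
    noise_sd = config$simulate$noise_sd
  )
  study <- generate_study(sim)
  paths <- c(file.path(config$out_dir, "library.csv"),
             file.path(config$out_dir, sprintf("external_%s.csv", names(study$external))),
             file.path(config$out_dir, "manifest.json"))
  check_outputs(paths, force)
  write_library(study$library, paths[1L], header_comment = paste("config_hash:", hash))
  counts <- list(library = n_samples(study$library))
  for (i in seq_along(study$external)) {
    nm <- names(study$external)[i]
    write_library(study$external[[nm]], file.path(config$out_dir, sprintf("external_%s.csv", nm)),
                  header_comment = paste("config_hash:", hash))
    counts[[paste0("external_", nm)]] <- n_samples(study$external[[nm]])
  }
  manifest <- list(config_hash = hash, seed = config$seed, counts = counts,
                   files = basename(paths[-length(paths)]))
  jsonlite::write_json(manifest, paths[length(paths)], auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("[simulate] wrote %d files to %s (config %s)",
                  length(paths), config$out_dir, hash))
  invisible(manifest)
}

read_study <- function(config) {
  lib <- read_library(file.path(config$out_dir, "library.csv"))
  ext_files <- list.files(config$out_dir, pattern = "^external_.*\\.csv$", full.names = TRUE)
  external <- lapply(ext_files, read_library)
  names(external) <- sub("^external_(.*)\\.csv$", "\\1", basename(ext_files))
  win <- config$preprocess$window_nm
  list(library = window_average(lib, win),
       external = lapply(external, window_average, window_nm = win))
}

#' Calibrate library models with cross-validation
#'
#' For every requested trait x method: 10-fold CV over the method's grid on
#' the (window-averaged) library, final refit at the chosen point, CV table
#' and persisted model written per combination, plus `cv_summary.csv`
#' mirroring the per-trait RMSE_CV / R2_CV comparison layout.
#'
#' @inheritParams cmd_simulate
#' @return Invisible summary data.frame.
#' @export
cmd_calibrate <- function(config = default_run_config(), force = FALSE) {
  hash <- config_hash(config)
  study <- read_study(config)
  rows <- list()
  for (method in config$methods) {
    for (trait in config$traits) {
      if (all(is.na(trait_values(study$library, trait)))) {
        warning(sprintf("cmd_calibrate: trait '%s' missing from the library; skipped", trait))
        next
      }
      cm <- calibrate(study$library, trait, method, cfg_grid(config, method),
                      seed = derive_seed(config$seed, paste0("calibrate/", method)),
                      k = config$cv$k)
      g <- cm$cv$grid[cm$cv$chosen, ]
      pars <- if (method == "plsr") sprintf("n_lv=%d", g$n_lv) else
        sprintf("hidden_size=%d,l2=%g", g$hidden_size, g$l2)
      write_stamped_csv(cm$cv$grid,
                        file.path(config$out_dir, sprintf("cv_%s_%s.csv", trait, method)), hash)
      write_model(cm, file.path(config$out_dir, sprintf("model_%s_%s.json", trait, method)))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, method = method, chosen = pars,
        rmse_cv = g$rmse_cv, r2_cv = g$r2_cv, n = cm$n, stringsAsFactors = FALSE)
      message(sprintf("[calibrate] %s/%s: chose %s (RMSE_CV %.4g, R2_CV %.3f)",
                      trait, method, pars, g$rmse_cv, g$r2_cv))
    }
  }
  summary <- do.call(rbind, rows)
  path <- file.path(config$out_dir, "cv_summary.csv")
  check_outputs(path, force = TRUE)
  write_stamped_csv(summary, path, hash)
  invisible(summary)
}

#' Run the three transfer schemes on every external set
#'
#' @inheritParams cmd_simulate
#' @return Invisible tidy data.frame (also written to `schemes.csv`).
#' @export
cmd_spike <- function(config = default_run_config(), force = FALSE) {
  hash <- config_hash(config)
  study <- read_study(config)
  method <- config$methods[1L]
  rows <- list()
  for (nm in names(study$external)) {
    ext <- study$external[[nm]]
    part <- draw_spike(ext, config$spike$n_spike,
                       seed = derive_seed(config$seed, paste0("spike/", nm)))
    tab <- run_all_schemes(study$library, ext, part, traits = config$traits,
                           method = method, grid = cfg_grid(config, method),
                           seed = derive_seed(config$seed, paste0("schemes/", nm)),
                           k = config$cv$k)
    rows[[length(rows) + 1L]] <- tab
    message(sprintf("[spike] %s: %d scheme x trait results", nm, nrow(tab)))
  }
  out <- do.call(rbind, rows)
  write_stamped_csv(out, file.path(config$out_dir, "schemes.csv"), hash)
  invisible(out)
}

#' Run the spike-size sweep
#'
#' @inheritParams cmd_simulate
#' @return Invisible tidy data.frame (also written to `sweep.csv`).
#' @export
cmd_sweep <- function(config = default_run_config(), force = FALSE) {
  hash <- config_hash(config)
  study <- read_study(config)
  method <- config$methods[1L]
  nm <- config$sweep$external
  if (!nm %in% names(study$external)) {
    fail("cmd_sweep: external set '%s' not found in %s", nm, config$out_dir)
  }
  out <- spike_size_sweep(study$library, study$external[[nm]],
                          sizes = config$sweep$sizes,
                          pool_size = config$sweep$pool_size,
                          traits = config$traits, method = method,
                          grid = cfg_grid(config, method),
                          seed = derive_seed(config$seed, "sweep"),
                          k = config$cv$k)
  write_stamped_csv(out, file.path(config$out_dir, "sweep.csv"), hash)
  message(sprintf("[sweep] %s: %d size x trait results", nm, nrow(out)))
  invisible(out)
}
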