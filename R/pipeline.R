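# End-to-end analysis pipeline with a reproducibility manifest.
#
# A run config is a flat YAML (or list) mirroring the parameter objects:
#   seed: 1
#   out: path/to/output/dir
#   kinetics:  {lambda0: 1.21, tau_PB: 48.3, tau_FB: 6.2, ...}
#   landmarks: {head_disappearance: [24, 3], ...}
#   schedule:  {round_duration_range: [0.5, 10], gap_range: [3, 70]}
#   estimator: {n_realizations: 1000, n_boot: 1000, grid_step: 1}
#   scenarios: [baseline, no_fusion_block, ...]
#   chronogram: optional path to an existing chronogram table; when absent a
#     synthetic cohort is generated and censored from `kinetics`.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fk("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_fk("config must be a list or a YAML file path")
  for (key in c("seed", "out"))
    if (is.null(config[[key]]))
      stop_fk("config is missing required key: %s", key)
  config
}

config_objects <- function(config) {
  kin <- do.call(kinetic_params, config$kinetics %||% list())
  lmk <- do.call(landmark_set, lapply(config$landmarks %||% list(),
                                      unlist))
  sch <- do.call(observation_schedule, lapply(config$schedule %||% list(),
                                              unlist))
  est <- utils::modifyList(list(n_realizations = 1000L, n_boot = 1000L,
                                grid_step = 1), config$estimator %||% list())
  list(kinetics = kin, landmarks = lmk, schedule = sch, estimator = est)
}

# small rolling hash over the deparsed config, for the manifest (exact in
# double arithmetic: intermediate values stay below 2^53)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(v)
      if (is.numeric(v)) formatC(v, format = "g", digits = 15) else
        as.character(v))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, from one config: synthetic-data generation and censoring (or
#' loading of an existing chronogram table), count-curve estimation on the
#' fertilized cohort, penetration-block / fusion-block / delay fits, and the
#' what-if simulator scenarios; writes every table plus a manifest
#' (package version, seed, config hash, file list) to the output directory.
#' Identical config + seed reproduces byte-identical outputs.
#'
#' @param config a list or path to a YAML file; see the config layout in
#'   the package source.  Required keys: `seed`, `out`.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the output directory, the manifest, and
#'   the in-memory results (`chronogram`, `curves`, `fits`, `scenarios`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  obj <- config_objects(config)
  seed <- as.integer(config$seed)
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- derive_seeds(seed, 8L)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    files <<- c(files, name)
    path
  }

  # stage 1: data
  if (!is.null(config$chronogram)) {
    say("pipeline: reading chronogram %s", config$chronogram)
    ch <- read_chronogram(config$chronogram)
    obs <- NULL
  } else {
    say("pipeline: generating synthetic cohort (%d oocytes)",
        obj$kinetics$n_oocytes)
    truth <- generate_truth(obj$kinetics, obj$landmarks, seed = seeds[1L])
    cens <- censor_truth(truth, obj$schedule, seed = seeds[2L])
    ch <- cens$chronogram
    obs <- cens$observations
    emit(truth$sperm, "truth.tsv")
    emit(obs, "observations.tsv")
  }
  chron_path <- file.path(out_dir, "chronogram.csv")
  write_chronogram(ch, chron_path)
  files <- c(files, "chronogram.csv")

  # stage 2: curves on the fertilized cohort
  fert <- subset_oocytes(ch, fate = "fertilized")
  if (nrow(fert$oocytes) < 2L)
    stop_fk("pipeline: fewer than 2 fertilized oocytes; nothing to estimate")
  est <- obj$estimator
  say("pipeline: count curves (%d fertilized oocytes, R=%d, B=%d)",
      nrow(fert$oocytes), est$n_realizations, est$n_boot)
  cp <- count_curve(fert, "first_fusion", "penetration",
                    n_realizations = est$n_realizations,
                    n_boot = est$n_boot, seed = seeds[3L],
                    grid_step = est$grid_step)
  cf <- count_curve(fert, "first_fusion", "fusion",
                    n_realizations = est$n_realizations,
                    n_boot = est$n_boot, seed = seeds[4L],
                    grid_step = est$grid_step)
  cv <- count_curve(fert, "first_fusion", "pvs_occupancy",
                    n_realizations = est$n_realizations,
                    n_boot = est$n_boot, seed = seeds[5L],
                    grid_step = est$grid_step)
  fd <- fusion_delay_curve(fert, n_realizations = est$n_realizations,
                           n_boot = est$n_boot, seed = seeds[6L])
  emit(as.data.frame(cp), "penetration_curve.tsv")
  emit(as.data.frame(cf), "fusion_curve.tsv")
  emit(as.data.frame(cv), "pvs_occupancy_curve.tsv")
  emit(data.frame(dt_min = fd$grid, prob = fd$prob), "fusion_delay_curve.tsv")

  # stage 3: fits
  say("pipeline: block-model fits")
  fp <- fit_penetration_block(cp)
  amp <- (sum(fert$oocytes$n_fused) - nrow(fert$oocytes)) /
    nrow(fert$oocytes)
  ff <- if (amp > 0) fit_fusion_block(cf, amplitude = amp) else NULL
  fits <- list(
    penetration_block = list(A = fp$A, tau_PB = fp$tau_PB,
                             initial_rate = fp$initial_rate,
                             A_ci = fp$A_ci, tau_ci = fp$tau_ci,
                             rate_ci = fp$rate_ci),
    fusion_block = if (!is.null(ff))
      list(amplitude = ff$amplitude, tau_FB = ff$tau_FB,
           tau_ci = ff$tau_ci) else NULL,
    fusion_delay = list(mean = fd$mean_delay, sd = fd$delay_sd,
                        mean_ci = fd$mean_delay_ci))
  fits_path <- file.path(out_dir, "fits.yaml")
  yaml::write_yaml(fits, fits_path)
  files <- c(files, "fits.yaml")

  # stage 4: scenarios
  scenarios <- config$scenarios %||% character(0)
  scen_out <- list()
  for (sc in scenarios) {
    say("pipeline: scenario %s", sc)
    sr <- run_scenario(obj$kinetics, sc, seed = seeds[7L])
    scen_out[[sc]] <- sr
    emit(sr$extra_fusion_curve, sprintf("scenario_%s_extra_fusions.tsv", sc))
    emit(data.frame(
      scenario = sc, n_oocytes = sr$n_oocytes,
      n_fertilized = sr$n_fertilized,
      mean_post_fert_penetrations = sr$mean_post_fert_penetrations,
      mean_extra_fusions = sr$mean_extra_fusions,
      polyspermy_fraction = sr$polyspermy_fraction),
      sprintf("scenario_%s_summary.tsv", sc))
  }

  manifest <- list(
    package = "fertkin",
    version = as.character(utils::packageVersion("fertkin")),
    seed = seed,
    config_hash = config_hash(config[setdiff(names(config), "out")]),
    estimator = est[c("n_realizations", "n_boot", "grid_step")],
    files = sort(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("pipeline: wrote %d files to %s", length(files) + 1L, out_dir)
  invisible(list(out = out_dir, manifest = manifest, chronogram = ch,
                 curves = list(penetration = cp, fusion = cf,
                               pvs_occupancy = cv, delay = fd),
                 fits = fits, scenarios = scen_out))
}
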