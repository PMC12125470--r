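# Configuration-driven driver: builds a synthetic nose and runs the four
# analyses (flow + secondary-flow screening, solubility sweep, GC-architecture
# comparison, particle deposition curve) with logging and provenance.

#' Study configuration for a species preset
#'
#' Presets pin the restful-breathing flow rate (mouse 25 mL/min, rat
#' 200 mL/min — the median of the reported physiological ranges, 10-35 mL/min
#' for mice and 100-450 mL/min for rats) together with the species'
#' [nose_spec()].
#'
#' @param name `"mouse"` or `"rat"`.
#' @param ... Overrides forwarded to [study_config()].
#' @return A `study_config`.
#' @export
#' @examples
#' species_preset("mouse")$Q_ml_min
species_preset <- function(name, ...) {
  presets <- c(mouse = 25, rat = 200)
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown species '%s'; available presets: %s.",
                  name, paste(names(presets), collapse = ", ")),
          class = "olfnet_domain_error")
  }
  study_config(species = name, Q_ml_min = presets[[name]], ...)
}

#' Assemble a study configuration
#'
#' @param species `"mouse"`, `"rat"` or `"custom"`.
#' @param Q_ml_min Breathing flow rate, mL/min.
#' @param nose A [nose_spec()]; defaults to the species preset.
#' @param mucosa A [mucosa_spec()].
#' @param beta_grid Partition-coefficient grid for the solubility sweep.
#' @param odorant_beta Partition coefficient of the (ethanol-like) GC
#'   comparison odorant.
#' @param particle_sizes_um Particle diameters for the deposition curve, um.
#' @param particles_per_size Particles released per size.
#' @param stages Character vector among `"flow"`, `"uptake"`, `"gc"`,
#'   `"particles"`.
#' @param seed Integer master seed.
#' @param full_protocol If `TRUE`, use the full release protocol
#'   (8000 particles per size over 1.5-43 um) instead of the reduced default.
#' @return A `study_config` list.
#' @export
study_config <- function(species = "mouse", Q_ml_min = 25, nose = NULL,
                         mucosa = mucosa_spec(),
                         beta_grid = 10^seq(-10, 0, length.out = 21),
                         odorant_beta = 2.4e-4,
                         particle_sizes_um = c(1.5, 3, 5, 8, 12, 20, 30, 43),
                         particles_per_size = 2000,
                         stages = c("flow", "uptake", "gc", "particles"),
                         seed = 1L, full_protocol = FALSE) {
  check_positive(Q_ml_min = Q_ml_min)
  stages <- match.arg(stages, several.ok = TRUE)
  if (full_protocol) {
    particles_per_size <- 8000
    particle_sizes_um <- c(1.5, 3, 5, 8, 12, 20, 30, 43)
  }
  cfg <- list(
    species = species, Q_ml_min = Q_ml_min,
    nose = nose %||% nose_spec(species, random_seed = seed),
    mucosa = mucosa, beta_grid = beta_grid, odorant_beta = odorant_beta,
    particle_sizes_um = particle_sizes_um,
    particles_per_size = particles_per_size,
    stages = stages, seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  cfg
}

#' Read / write a study configuration (YAML)
#'
#' @param path File path.
#' @return For `read_study_config`, a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  nose_args <- y$nose %||% list()
  mucosa_args <- y$mucosa %||% list()
  study_config(
    species = y$species %||% "mouse",
    Q_ml_min = y$Q_ml_min %||% 25,
    nose = if (length(nose_args))
      do.call(nose_spec, c(list(species = y$species %||% "mouse"), nose_args))
      else NULL,
    mucosa = do.call(mucosa_spec, mucosa_args),
    beta_grid = y$beta_grid %||% 10^seq(-10, 0, length.out = 21),
    odorant_beta = y$odorant_beta %||% 2.4e-4,
    particle_sizes_um = y$particle_sizes_um %||%
      c(1.5, 3, 5, 8, 12, 20, 30, 43),
    particles_per_size = y$particles_per_size %||% 2000,
    stages = y$stages %||% c("flow", "uptake", "gc", "particles"),
    seed = y$seed %||% 1L
  )
}

#' @rdname read_study_config
#' @param config A `study_config`.
#' @export
write_study_config <- function(config, path) {
  y <- list(
    species = config$species, Q_ml_min = config$Q_ml_min,
    nose = config$nose[setdiff(names(config$nose), "species")],
    mucosa = config$mucosa[!vapply(config$mucosa, is.null, logical(1))],
    beta_grid = config$beta_grid, odorant_beta = config$odorant_beta,
    particle_sizes_um = config$particle_sizes_um,
    particles_per_size = config$particles_per_size,
    stages = config$stages, seed = config$seed
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Run a configured study end to end
#'
#' Executes the requested stages in dependency order (nose -> flow ->
#' {solubility sweep, GC comparison, particle curve}), optionally writing
#' summary tables and a provenance block (configuration hash, package
#' version, seeds) to `outdir`.
#'
#' @param config A [study_config()].
#' @param outdir Optional output directory; created if missing.
#' @param quiet Suppress progress messages?
#' @return A named list with elements `network`, `flow`, `screening` and (per
#'   requested stage) `sweep`, `gc`, `particles`, plus `provenance` and
#'   `errors`. A failed stage yields `NULL`, its message in `errors` (and an
#'   `error_manifest.json` in `outdir`); completed stages are preserved.
#' @export
#' @examples
#' \donttest{
#' res <- run_study(species_preset("mouse",
#'   stages = c("flow", "gc"), particles_per_size = 200))
#' res$gc$N_peak_ratio
#' }
run_study <- function(config, outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  t0 <- Sys.time()
  Q <- config$Q_ml_min / 60 * 1e-6

  say("building %s nose (seed %d)", config$species, config$seed)
  network <- build_nose(config$nose)
  flow <- solve_flow(network, Q)
  screening <- dimensionless_numbers(network, flow,
                                     breathing_frequency =
                                       if (config$species == "rat") 2 else 4)
  results <- list(network = network, flow = flow, screening = screening)

  # light, highly mucus-soluble comparison odorant (ethanol-like)
  od <- odorant("ethanol", 46.07, 59.2,
                beta = config$odorant_beta, mucosa = config$mucosa)

  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      warn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
  }
  if ("uptake" %in% config$stages) {
    say("solubility sweep over %d beta values", length(config$beta_grid))
    results$sweep <- run_stage("uptake", solubility_sweep(
      network, flow, config$mucosa, beta_grid = config$beta_grid,
      odorant_template = od
    ))
  }
  if ("gc" %in% config$stages) {
    say("GC architecture comparison (parallel vs elongated tube)")
    results$gc <- run_stage("gc", {
      tube <- elongated_tube_variant(network)
      compare_architectures(network, flow, tube, solve_flow(tube, Q),
                            od, config$mucosa)
    })
  }
  if ("particles" %in% config$stages) {
    say("tracking %d particles x %d sizes", config$particles_per_size,
        length(config$particle_sizes_um))
    results$particles <- run_stage("particles", deposition_curve(
      network, flow, sizes_um = config$particle_sizes_um,
      n_per_size = config$particles_per_size, seed = config$seed
    ))
  }
  results$errors <- errors

  results$provenance <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("olfnet")),
    seed = config$seed, species = config$species,
    Q_ml_min = config$Q_ml_min,
    dm_flow_fraction = config$nose$dm_flow_fraction,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(flow), file.path(outdir, "flow_segments.csv"))
    readr::write_csv(screening, file.path(outdir, "dimensionless.csv"))
    if (!is.null(results$sweep)) {
      readr::write_csv(as_tibble(results$sweep),
                       file.path(outdir, "solubility_sweep.csv"))
    }
    if (!is.null(results$gc)) {
      jsonlite::write_json(
        list(table = results$gc$table,
             N_peak_ratio = results$gc$N_peak_ratio,
             N_operating_ratio = results$gc$N_operating_ratio),
        file.path(outdir, "gc_comparison.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(results$particles)) {
      readr::write_csv(as_tibble(results$particles),
                       file.path(outdir, "deposition_curve.csv"))
    }
    jsonlite::write_json(results$provenance,
                         file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(errors) > 0) {
      jsonlite::write_json(errors, file.path(outdir, "error_manifest.json"),
                           auto_unbox = TRUE)
    }
    say("outputs written to %s", outdir)
  }
  invisible(results)
}
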