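#' Save and load experiment configuration
#'
#' Configurations are plain named lists serialized as YAML (default) or
#' JSON, chosen by file extension. `load_config(save_config(x, f))`
#' returns `x` unchanged for any configuration made of scalars, vectors
#' and nested lists.
#'
#' @param config a named list.
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the list.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(config, path, precision = 15)
  }
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Serialize a behavior spec to a config list (and back)
#'
#' @param behavior a [behavior_spec()].
#' @return `behavior_to_config` returns a plain list (`kind`, `r_max`,
#'   `params`); `behavior_from_config` rebuilds the [behavior_spec()].
#' @export
behavior_to_config <- function(behavior) {
  stopifnot(inherits(behavior, "behavior_spec"))
  list(kind = behavior$kind, r_max = behavior$r_max,
       params = behavior$params)
}

#' @rdname behavior_to_config
#' @param config a list as produced by `behavior_to_config`.
#' @export
behavior_from_config <- function(config) {
  behavior_spec(config$kind, config$params, r_max = config$r_max)
}

#' Write a run manifest
#'
#' Records the resolved configuration, package version, timestamp, seed
#' and an inventory of output files with MD5 checksums — enough to
#' re-execute and verify a deterministic run bit-for-bit.
#'
#' @param dir run output directory.
#' @param config the resolved configuration list.
#' @param files character vector of output files (paths relative to
#'   `dir`).
#' @param seed the master seed of the run (or `NULL`).
#' @return The manifest list, invisibly; written to
#'   `file.path(dir, "manifest.json")`.
#' @export
write_manifest <- function(dir, config, files, seed = NULL) {
  paths <- file.path(dir, files)
  stopifnot(all(file.exists(paths)))
  manifest <- list(
    package = "bactaxis",
    version = as.character(utils::packageVersion("bactaxis")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run directory against its manifest
#'
#' @param dir run output directory containing `manifest.json`.
#' @return `TRUE` if every listed file exists and matches its checksum;
#'   otherwise an error naming the first mismatch.
#' @export
verify_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing output file: ", f, call. = FALSE)
    got <- unname(tools::md5sum(path))
    if (!identical(got, manifest$files[[f]]$md5)) {
      stop("checksum mismatch for ", f, call. = FALSE)
    }
  }
  TRUE
}

#' Run a configured experiment and write its outputs
#'
#' Thin dispatcher over the package's runners. `config$task` selects one
#' of `"bifurcation"`, `"trajectory"`, `"map"`, `"search-lattice"`,
#' `"evolve"`, `"spatial"`; remaining entries parameterize the task (all
#' optional, falling back to package defaults). Tabular results are
#' written as CSV, summaries as JSON, and a manifest (with checksums of
#' every output) as `manifest.json`.
#'
#' @param config a named list; see Details.
#' @param out_dir output directory (created if absent).
#' @details Recognized entries: `metabolism` (list of
#'   [metabolism_params()] arguments), `behavior` (list for
#'   [behavior_from_config()], or a kind string for the published
#'   preset), `integrator` (list of [integrator_config()] arguments),
#'   `grid` (list of [initial_grid()] arguments), `init` (length-2
#'   `c(A, F)` for trajectories), `environment` / `population` (lists of
#'   [environment_1d()] / [population_config()] arguments), `search`
#'   (list: `kind`, `resolution`), `ga` (list of [evolve_behavior()]
#'   arguments), `seed`.
#' @return The manifest list, invisibly.
#' @export
run_experiment <- function(config, out_dir = ".") {
  stopifnot(is.list(config), !is.null(config$task))
  task <- match.arg(config$task, c("bifurcation", "trajectory", "map",
                                   "search-lattice", "evolve", "spatial"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- do.call(metabolism_params, config$metabolism %||% list())
  cfg <- do.call(integrator_config, config$integrator %||% list())
  beh <- NULL
  if (!is.null(config$behavior)) {
    beh <- if (is.character(config$behavior)) {
      behavior_preset(config$behavior)
    } else {
      behavior_from_config(config$behavior)
    }
  }
  seed <- config$seed %||% 1L
  files <- character(0)
  put_csv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    files <<- c(files, name)
  }
  put_json <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }
  if (task == "bifurcation") {
    put_csv(bifurcation_scan(p), "bifurcation.csv")
    put_json(list(F_bif = bifurcation_point(p)), "summary.json")
  } else if (task == "trajectory") {
    init <- config$init %||% c(A = 3, F = 2)
    tr <- simulate_trajectory(init[[1]], init[[2]], beh, p, cfg)
    put_csv(tr$states, "trajectory.csv")
    put_json(list(outcome = tr$outcome, time_of_death = tr$time_of_death,
                  final_A = tr$final_A, final_F = tr$final_F,
                  reached_steady = tr$reached_steady), "summary.json")
  } else if (task == "map") {
    grid <- do.call(initial_grid,
                    config$grid %||% list(A_range = c(0, p$A_death_high)))
    g <- survivability_map(beh, p, grid, cfg)
    put_csv(g$cells, "map.csv")
    put_json(as.list(g$proportions), "summary.json")
  } else if (task == "search-lattice") {
    sc <- config$search %||% list()
    res <- do.call(lattice_search,
                   c(list(kind = sc$kind %||% "B1"),
                     sc[setdiff(names(sc), "kind")], list(p = p)))
    put_csv(res$surface, "surface.csv")
    best <- behavior_spec(res$kind, as.list(res$best))
    put_json(behavior_to_config(best), "best_behavior.json")
    put_json(list(best_fitness = res$best_fitness), "summary.json")
  } else if (task == "evolve") {
    ga <- config$ga %||% list()
    res <- do.call(evolve_behavior,
                   c(list(kind = ga$kind %||% "B4"),
                     ga[setdiff(names(ga), "kind")],
                     list(p = p, seed = seed)))
    put_csv(data.frame(tournament = seq_along(res$trace),
                       best_fitness = res$trace), "trace.csv")
    best <- behavior_spec(res$kind, as.list(res$best))
    put_json(behavior_to_config(best), "best_behavior.json")
    put_json(list(best_fitness = res$best_fitness), "summary.json")
  } else if (task == "spatial") {
    env <- do.call(environment_1d, config$environment %||% list())
    pc <- do.call(population_config,
                  c(config$population %||% list(), list(seed = seed)))
    run <- run_population(beh %||% behavior_preset("B1"), env, p, pc)
    put_csv(run$agents, "agents.csv")
    if (!is.null(run$snapshots)) put_csv(run$snapshots, "snapshots.csv")
    put_json(c(list(survival = run$survival),
               as.list(run$death_fractions)), "summary.json")
  }
  write_manifest(out_dir, config, files, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
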