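#' Assemble and validate a run configuration
#'
#' A run configuration bundles the model parameters, the external signal
#' field, and the ensemble specification into a single validated object
#' that can round-trip through YAML. Every simulation driver
#' ([run_scenario()], [run_sweep()]) takes one of these and writes the
#' resolved configuration beside its outputs.
#'
#' @param scenario Free-form scenario name.
#' @param model A [model_params()] (or a named list of overrides for its
#'   defaults).
#' @param signal A [signal_field()] (or a named list of arguments).
#' @param ensemble Named list with `N`, `n_traj`, `T`, `seed` and
#'   optionally `window` (length 2) and `snapshot_dt`.
#' @param grid Optional named list of vectors for sweeps (`beta_bar`
#'   and/or `chi`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "unnamed",
                       model = model_params(),
                       signal = signal_field("uniform"),
                       ensemble = list(N = 37, n_traj = 10, T = 25,
                                       seed = 1),
                       grid = NULL) {
  if (!inherits(model, "model_params"))
    model <- do.call(model_params, normalize_model_list(model))
  if (!inherits(signal, "signal_field"))
    signal <- do.call(signal_field, signal)
  req <- c("N", "n_traj", "T", "seed")
  if (!all(req %in% names(ensemble)))
    rlang::abort(paste("ensemble spec needs fields:",
                       paste(req, collapse = ", ")))
  stopifnot(ensemble$N >= 1, ensemble$n_traj >= 1, ensemble$T > 0)
  if (!is.null(ensemble$window))
    stopifnot(length(ensemble$window) == 2,
              ensemble$window[1] < ensemble$window[2],
              ensemble$window[2] <= ensemble$T + 1e-9)
  if (is.null(ensemble$snapshot_dt)) ensemble$snapshot_dt <- 0.1
  if (!is.null(grid)) {
    bad <- setdiff(names(grid), c("beta_bar", "chi"))
    if (length(bad))
      rlang::abort(paste("unknown grid fields:", paste(bad, collapse = ", ")))
  }
  structure(list(scenario = scenario, model = model, signal = signal,
                 ensemble = ensemble, grid = grid),
            class = "run_config")
}

# Accept a flat list with a nested `legi` list of rates.
normalize_model_list <- function(ml) {
  if (!is.null(ml$legi) && !inherits(ml$legi, "legi_rates"))
    ml$legi <- do.call(legi_rates, ml$legi)
  ml
}

config_as_list <- function(config) {
  m <- config$model
  list(scenario = config$scenario,
       model = c(m[setdiff(names(m), "legi")],
                 list(legi = unclass(m$legi))),
       signal = {
         s <- unclass(config$signal)
         s$axis <- as.numeric(s$axis)
         s[!vapply(s, function(v) all(is.na(v)), logical(1))]
       },
       ensemble = config$ensemble,
       grid = config$grid)
}

#' @describeIn run_config Write a configuration to a YAML file.
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_as_list(config), path, precision = 15)
  invisible(path)
}

#' @describeIn run_config Read and validate a configuration from YAML.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sig <- raw$signal
  if (!is.null(sig$axis)) sig$axis <- as.numeric(unlist(sig$axis))
  ens <- raw$ensemble
  # guard against YAML 1.1 boolean-like bare keys (N, T) in hand-edited files
  names(ens)[names(ens) %in% c("FALSE", "no")] <- "N"
  names(ens)[names(ens) %in% c("TRUE", "yes")] <- "T"
  if (!is.null(ens$window)) ens$window <- as.numeric(unlist(ens$window))
  grid <- raw$grid
  if (!is.null(grid)) grid <- lapply(grid, function(v) as.numeric(unlist(v)))
  run_config(scenario = raw$scenario %||% "unnamed",
             model = raw$model %||% list(),
             signal = sig %||% list(kind = "uniform"),
             ensemble = ens,
             grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  rlang::hash(config_as_list(config))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> '", x$scenario, "': N=", x$ensemble$N,
      ", n_traj=", x$ensemble$n_traj, ", T=", x$ensemble$T,
      ", seed=", x$ensemble$seed, "\n", sep = "")
  print(x$model); print(x$signal)
  invisible(x)
}

#' Bundled scenario configurations
#'
#' Named parameter sets for the canonical study conditions, stored as YAML
#' under the package's `extdata/scenarios` directory:
#' \describe{
#'   \item{rigid_adaptive}{Strongly adherent rigid clusters
#'     (`v_r = v_a = 500`) with LEGI linear response, `alpha = 0.25`,
#'     exponential gradient.}
#'   \item{rigid_amplified}{Rigid clusters with switchlike amplification
#'     (`lam = 1e-2`, `beta_bar = 0.2`).}
#'   \item{loose_chemotaxis}{Co-attraction-bound clusters,
#'     `beta_bar = 70`, `chi = 15`.}
#'   \item{tight_rotating}{Strong co-attraction, `beta_bar = 37.2`,
#'     `chi = 83.3`: rotating clusters.}
#'   \item{rotation_sweep}{`beta_bar = 35`, uniform signal, `chi` grid for
#'     the pitchfork analysis.}
#'   \item{signal_level_sweep}{Adaptation test: exponential gradient with
#'     `S1 = 0.02` at varying base level.}
#' }
#'
#' @param name Scenario name; omit to list available names.
#' @return A [run_config()] (or a character vector of names).
#' @export
scenario_config <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "coguide")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    rlang::abort(paste0("unknown scenario '", name, "'; available: ",
                        paste(avail, collapse = ", ")))
  read_run_config(file.path(dir, paste0(name, ".yaml")))
}

#' Run a configured ensemble and write its outputs
#'
#' Executes the ensemble described by a [run_config()] and writes, under
#' `out_dir`: `ensemble.csv` (one row per trajectory), `summary.json`
#' (chemotactic index, normalized velocity, mean angular speed, standard
#' errors, package version and configuration hash), the resolved
#' configuration `config.yaml`, and optionally per-trajectory CSVs. If a
#' summary with the same configuration hash already exists the run is
#' skipped unless `force = TRUE`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_trajectories Also write one long-format CSV per
#'   trajectory under `out_dir/trajectories/`.
#' @param force Re-run even when an identical-configuration summary
#'   exists.
#' @param quiet Suppress the per-run log line.
#' @return The ensemble tibble, invisibly.
#' @export
run_scenario <- function(config, out_dir, write_trajectories = FALSE,
                         force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  sum_path <- file.path(out_dir, "summary.json")
  if (!force && file.exists(sum_path)) {
    prev <- jsonlite::read_json(sum_path)
    if (identical(prev$config_hash, hash)) {
      if (!quiet) message("run_scenario: up to date (hash ", hash, "); skipping")
      return(invisible(utils::read.csv(file.path(out_dir, "ensemble.csv"))))
    }
  }
  ens <- config$ensemble
  t_start <- Sys.time()
  res <- run_ensemble(config$model, config$signal, N = ens$N, T = ens$T,
                      n_traj = ens$n_traj, seed = ens$seed,
                      window = ens$window, snapshot_dt = ens$snapshot_dt,
                      keep_trajectories = write_trajectories)
  if (write_trajectories) {
    tdir <- file.path(out_dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    trs <- attr(res, "trajectories")
    for (k in seq_along(trs))
      readr::write_csv(trs[[k]],
                       file.path(tdir, sprintf("traj_%03d.csv", k)))
  }
  readr::write_csv(dplyr::select(res, -dplyr::any_of("chi")),
                   file.path(out_dir, "ensemble.csv"))
  v0 <- v0_scale(config)
  ci <- chemotactic_index(res)
  n <- nrow(res)
  summary <- list(
    scenario = config$scenario,
    ci = ci,
    mean_vx = mean(res$vx), se_vx = stats::sd(res$vx) / sqrt(n),
    mean_vx_over_v0 = if (is.finite(v0) && v0 > 0) mean(res$vx) / v0 else NA,
    mean_abs_omega = mean(res$abs_omega),
    se_abs_omega = stats::sd(res$abs_omega) / sqrt(n),
    n_traj = n,
    any_fragmented = any(res$n_fragments > 1),
    window = attr(res, "window"),
    package_version = as.character(utils::packageVersion("coguide")),
    config_hash = hash)
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  if (!quiet) {
    frag <- sum(res$n_fragments > 1)
    message(sprintf(
      "run_scenario '%s': n=%d CI=%.3f <|Omega|>=%.3f (%.1fs)%s",
      config$scenario, n, ci, summary$mean_abs_omega,
      as.numeric(difftime(Sys.time(), t_start, units = "secs")),
      if (frag > 0) sprintf(" WARN: %d fragmented trajectories", frag) else ""))
  }
  invisible(res)
}

# Velocity scale V0 = beta_bar * tau * S1 for gradient fields.
v0_scale <- function(config) {
  s <- config$signal
  if (s$kind %in% c("linear", "exponential"))
    config$model$beta_bar * config$model$tau * abs(s$S1)
  else NA_real_
}

#' Run a (beta_bar, chi) parameter-grid sweep
#'
#' Runs one ensemble per grid point of `config$grid` and writes a tidy
#' table (one row per grid point and trajectory). The sweep is resumable:
#' each completed point is cached as a CSV under `out_dir/points/` and
#' skipped on re-run, so an interrupted sweep finishes to an identical
#' table.
#'
#' @param config A [run_config()] whose `grid` lists `beta_bar` and/or
#'   `chi` vectors.
#' @param out_dir Output directory.
#' @param quiet Suppress per-point log lines.
#' @return The tidy sweep tibble (also written to `out_dir/sweep.csv`).
#' @export
run_sweep <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$grid) || !length(config$grid))
    rlang::abort("run_sweep: config has no grid")
  dir.create(file.path(out_dir, "points"), recursive = TRUE,
             showWarnings = FALSE)
  grid <- expand.grid(
    beta_bar = config$grid$beta_bar %||% config$model$beta_bar,
    chi = config$grid$chi %||% config$model$chi)
  ens <- config$ensemble
  point_seeds <- derive_seeds(ens$seed, nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(k) {
    tag <- sprintf("beta%g_chi%g", grid$beta_bar[k], grid$chi[k])
    cache <- file.path(out_dir, "points", paste0(tag, ".csv"))
    if (file.exists(cache)) {
      if (!quiet) message("run_sweep: ", tag, " cached; skipping")
      return(readr::read_csv(cache, show_col_types = FALSE))
    }
    p <- config$model
    p$beta_bar <- grid$beta_bar[k]
    p$chi <- grid$chi[k]
    res <- run_ensemble(p, config$signal, N = ens$N, T = ens$T,
                        n_traj = ens$n_traj, seed = point_seeds[k],
                        window = ens$window,
                        snapshot_dt = ens$snapshot_dt)
    res <- dplyr::mutate(res, beta_bar = grid$beta_bar[k],
                         chi = grid$chi[k], N = ens$N, .before = 1)
    readr::write_csv(res, cache)
    if (!quiet)
      message(sprintf("run_sweep: %s done (CI=%.3f, <|Omega|>=%.3f)",
                      tag, chemotactic_index(res), mean(res$abs_omega)))
    res
  })
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, file.path(out_dir, "sweep.csv"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  out
}
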