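config_keys <- c("N", "rho", "L", "D", "tau", "dt", "n_equil_steps",
                 "n_sample_steps", "sample_interval", "seed", "external",
                 "potential")
potential_keys <- c("form", "energy_scale", "spring_k", "cutoff")

#' Load and validate a simulation configuration file
#'
#' Reads a YAML (or JSON) run configuration, applies documented defaults
#' and returns a validated [sim_config()]. Unknown keys are rejected with a
#' message naming the offending key; a `dt` larger than `tau/50` is rejected
#' with stiffness guidance.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    # keep YAML-1.1 boolean-like keys (N, y, ...) as literal strings
    yaml::read_yaml(path, handlers = list("bool#no" = function(x) x,
                                          "bool#yes" = function(x) x))
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  pot <- raw$potential
  if (is.null(pot)) pot <- list(form = "inverse_power_12")
  unknown_p <- setdiff(names(pot), potential_keys)
  if (length(unknown_p))
    stop("unknown potential key(s): ",
         paste(paste0("potential.", unknown_p), collapse = ", "))
  pot_args <- c(list(form = pot$form %||% "inverse_power_12"),
                pot[setdiff(names(pot), "form")])
  spec <- do.call(pair_potential, pot_args)
  args <- raw[setdiff(names(raw), "potential")]
  args$potential <- spec
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))` returns an
#' identical configuration.
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  pot <- config$potential
  pl <- list(form = pot$form)
  if (pot$form == "inverse_power_12")
    pl <- c(pl, list(energy_scale = pot$energy_scale, cutoff = pot$cutoff))
  if (pot$form == "harmonic") pl <- c(pl, list(spring_k = pot$spring_k))
  out <- list(N = config$N, L = config$L, D = config$D, tau = config$tau,
              dt = config$dt, n_equil_steps = config$n_equil_steps,
              n_sample_steps = config$n_sample_steps,
              sample_interval = config$sample_interval, seed = config$seed,
              external = config$external, potential = pl)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Persist a trajectory as CSV with a JSON manifest
#'
#' Writes a long-format CSV (sample, time, particle, position, noise,
#' velocity) plus a `<path>.manifest.json` sidecar recording the config,
#' seed, package version, timestamps and the md5 hash of the data file, so
#' every output is traceable to exactly one seeded run.
#'
#' @param traj a `gcn_trajectory`.
#' @param path output CSV path.
#' @return the manifest list, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  n_s <- nrow(traj$positions); N <- ncol(traj$positions)
  dt <- data.table::data.table(
    sample = rep(seq_len(n_s), times = N),
    time = rep(traj$time, times = N),
    particle = rep(seq_len(N), each = n_s),
    position = as.vector(traj$positions),
    noise = as.vector(traj$noises),
    velocity = as.vector(traj$velocities))
  data.table::fwrite(dt, path)
  cfg <- traj$config
  manifest <- list(
    format = "activegcn-trajectory-csv-v1",
    package_version = as.character(utils::packageVersion("activegcn")),
    seed = cfg$seed,
    config = yaml::as.yaml(dump_config_list(cfg)),
    n_samples = n_s, N = N,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

dump_config_list <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  dump_config(config, f)
  yaml::read_yaml(f)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path; the `<path>.manifest.json` sidecar must exist.
#' @return a `gcn_trajectory`.
#' @export
read_trajectory <- function(path) {
  mf <- paste0(path, ".manifest.json")
  if (!file.exists(mf)) stop("manifest sidecar not found: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  raw <- yaml::yaml.load(manifest$config)
  cfgf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, cfgf)
  config <- load_config(cfgf)
  unlink(cfgf)
  dt <- data.table::fread(path)
  n_s <- manifest$n_samples; N <- manifest$N
  structure(
    list(positions = matrix(dt$position, n_s, N),
         noises = matrix(dt$noise, n_s, N),
         velocities = matrix(dt$velocity, n_s, N),
         time = dt$time[seq_len(n_s)], config = config),
    class = "gcn_trajectory")
}

fixture_registry <- function() {
  list(
    fig1_two_particle = list(
      config = list(N = 2L, L = 8, D = 1, tau = 1, dt = 1e-3, seed = 101L,
                    n_equil_steps = 5000L, n_sample_steps = 5e6L,
                    sample_interval = 250L),
      tolerance = list(conditional_stderr_multiple = 3)),
    fig2_many_body = list(
      config = list(N = 200L, rho = 0.5, D = 1, tau = 1, dt = 1e-3,
                    seed = 102L, n_equil_steps = 20000L,
                    n_sample_steps = 5e5L, sample_interval = 500L),
      tolerance = list(ensemble_vs_sim_rel = 0.10)),
    fig3_high_density = list(
      config = list(N = 200L, rho = 0.9, D = 1, tau = 0.3, dt = 2e-4,
                    seed = 103L, n_equil_steps = 50000L,
                    n_sample_steps = 1e6L, sample_interval = 1000L),
      tolerance = list(harmonic_vs_sim_rel = 0.25)),
    free_gas = list(
      config = list(N = 100L, rho = 0.1, D = 1, tau = 1, dt = 1e-3,
                    seed = 104L, n_equil_steps = 2000L,
                    n_sample_steps = 250000L, sample_interval = 500L,
                    potential = list(form = "none")),
      tolerance = list(variance = 1, rel = 0.05)))
}

#' Generate a registered fixture configuration on disk
#'
#' Writes a small seeded run configuration (YAML) and an expected-output
#' tolerance file (JSON) for one of the registered benchmark scenarios.
#'
#' @param name fixture name; an unknown name raises an error listing the
#'   registry.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
fixture_generator <- function(name, dir = ".") {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  fx <- reg[[name]]
  cfg_path <- file.path(dir, paste0(name, ".yaml"))
  tol_path <- file.path(dir, paste0(name, ".expected.json"))
  yaml::write_yaml(fx$config, cfg_path)
  jsonlite::write_json(fx$tolerance, tol_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(config = cfg_path, tolerance = tol_path))
}

#' Emit a theory curve as a data frame / CSV
#'
#' Evaluates one of the closed-form or quadrature velocity-variance
#' predictions on a density grid.
#'
#' @param method one of `"exact"`, `"hard-sphere"`, `"mean-field"`,
#'   `"small-tau"`, `"harmonic"`.
#' @param rho_grid density grid.
#' @param D,tau model parameters.
#' @param spec a [pair_potential()] (exact quadrature).
#' @param phi2 integrated pair curvature for `"mean-field"`/`"small-tau"`
#'   (force-balance closure when `NULL`; `"small-tau"` requires it).
#' @param out optional CSV path; the file carries the normalization
#'   convention in a comment header.
#' @return data.frame with columns abscissa (`rho`), `value`, `method`,
#'   `D`, `tau`.
#' @export
theory_curve <- function(method = c("exact", "hard-sphere", "mean-field",
                                    "small-tau", "harmonic"),
                         rho_grid, D, tau,
                         spec = pair_potential("inverse_power_12"),
                         phi2 = NULL, out = NULL) {
  method <- match.arg(method)
  value <- switch(method,
    "exact" = two_particle_overall_variance(rho_grid, spec, D, tau),
    "hard-sphere" = hard_sphere_variance(rho_grid, D, tau),
    "mean-field" = mean_field_variance(rho_grid, D, tau, phi2 = phi2),
    "small-tau" = {
      if (is.null(phi2)) stop("small-tau curve needs phi2 from ",
                              "small_tau_phi2()")
      mean_field_variance(rho_grid, D, tau, phi2 = phi2)
    },
    "harmonic" = harmonic_variance(harmonic_spring_constant(rho_grid), tau))
  df <- data.frame(rho = rho_grid, value = value, method = method,
                   D = D, tau = tau)
  if (!is.null(out)) {
    writeLines(c("# velocity variance normalized by the free value D/tau",
                 "# columns: rho,value,method,D,tau"), out)
    suppressWarnings(utils::write.table(
      df, out, sep = ",", row.names = FALSE, col.names = TRUE,
      append = TRUE, quote = FALSE))
  }
  df
}
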