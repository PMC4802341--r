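#' Regenerate the data behind the main figures at reduced scale
#'
#' Runs the seeded simulation + theory pipeline for one figure tag and
#' writes matched-abscissa CSV tables plus a pass/fail agreement summary.
#' Sampling is reduced relative to the original study (sizes are stated in
#' the package vignette); tolerances are set accordingly.
#'
#' * `fig1a` - distance-resolved pair velocity variance/correlation:
#'   theory curves and an N = 2 simulation overlay.
#' * `fig1b` - pair overall variance vs density: exact quadrature for
#'   several D plus the hard-sphere closed form.
#' * `fig2`  - many-body overall variance vs density: simulation,
#'   coordinate-averaged MUCNA, mean-field, small-tau and harmonic curves.
#' * `fig3`  - high-density harmonic model vs simulation.
#' * `fig4`  - long-wavelength density fluctuations: simulated and
#'   predicted amplitude over a coarse (rho, D) grid for two tau values.
#'
#' @param tag one of `"fig1a"`, `"fig1b"`, `"fig2"`, `"fig3"`, `"fig4"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed for all simulations.
#' @param scale multiplier (> 0) on the default sample counts.
#' @return list with the emitted tables and an `agreement` data.frame.
#' @export
reproduce_figure <- function(tag = c("fig1a", "fig1b", "fig2", "fig3",
                                     "fig4"),
                             dir = ".", seed = 1L, scale = 1) {
  tag <- match.arg(tag)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- switch(tag,
                fig1a = reproduce_fig1a(seed, scale),
                fig1b = reproduce_fig1b(),
                fig2 = reproduce_fig2(seed, scale),
                fig3 = reproduce_fig3(seed, scale),
                fig4 = reproduce_fig4(seed, scale))
  for (nm in setdiff(names(res), "agreement"))
    utils::write.csv(res[[nm]], file.path(dir, paste0(tag, "_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(res$agreement,
                   file.path(dir, paste0(tag, "_agreement.csv")),
                   row.names = FALSE)
  invisible(res)
}

reproduce_fig1a <- function(seed, scale) {
  spec <- pair_potential("inverse_power_12")
  D <- 1; tau <- 1; L <- 8
  x <- seq(0.9, 3.5, by = 0.02)
  theory <- data.frame(
    dx = x,
    one_particle_wall = single_particle_variance(x, spec, D, tau),
    pair_variance = two_particle_conditional(x, spec, D, tau)$variance,
    pair_correlation = two_particle_conditional(x, spec, D, tau)$correlation,
    separation_density = two_particle_separation_density(x, spec, D, tau, L))
  cfg <- sim_config(N = 2, L = L, D = D, tau = tau, dt = 1e-3, seed = seed,
                    n_equil_steps = 5000L,
                    n_sample_steps = as.integer(2.5e6 * scale),
                    sample_interval = 250L)
  traj <- run_simulation(cfg)
  bins <- seq(0.9, 3.5, by = 0.05)
  cs <- conditional_velocity_stats(traj, bins)
  sim <- data.frame(dx = bin_centers(cs$variance),
                    dx_mean = cs$variance$x_mean,
                    variance = cs$variance$mean,
                    variance_se = cs$variance$stderr,
                    correlation = cs$correlation$mean,
                    correlation_se = cs$correlation$stderr,
                    count = cs$variance$count)
  ok <- !is.na(sim$variance_se) & sim$count >= 50
  thv <- two_particle_conditional(sim$dx_mean[ok], spec, D, tau)
  agree <- data.frame(
    check = c("pair variance vs theory", "pair correlation vs theory"),
    frac_within_3se = c(
      mean(abs(sim$variance[ok] - thv$variance) <= 3 * sim$variance_se[ok]),
      mean(abs(sim$correlation[ok] - thv$correlation) <=
             3 * sim$correlation_se[ok])))
  agree$pass <- agree$frac_within_3se >= 0.9
  list(theory = theory, simulation = sim, agreement = agree)
}

reproduce_fig1b <- function() {
  spec <- pair_potential("inverse_power_12")
  rho <- seq(0.05, 0.9, by = 0.05)
  tau <- 1
  tabs <- do.call(rbind, lapply(c(0.25, 1, 4), function(D) {
    rbind(theory_curve("exact", rho, D, tau, spec),
          theory_curve("hard-sphere", rho, D, tau))
  }))
  wide <- stats::reshape(tabs, idvar = c("rho", "D"), timevar = "method",
                         v.names = "value", direction = "wide")
  dev <- abs(wide$value.exact - wide$`value.hard-sphere`)
  agree <- data.frame(check = "hard-sphere tracks exact quadrature",
                      max_abs_dev = max(dev), pass = max(dev) <= 0.1)
  list(curves = tabs, agreement = agree)
}

fig2_point <- function(rho, D, tau, seed, scale, N = 100L) {
  cfg <- sim_config(N = N, rho = rho, D = D, tau = tau, dt = 1e-3,
                    seed = seed, n_equil_steps = 20000L,
                    n_sample_steps = as.integer(2e5 * scale),
                    sample_interval = 500L)
  traj <- run_simulation(cfg)
  ovv <- overall_velocity_variance(traj)
  ens <- ensemble_variance_from_positions(traj)
  g <- pair_distribution(traj, seq(0.02, 4, by = 0.02))
  list(sim = ovv, ens = ens, g = g)
}

reproduce_fig2 <- function(seed, scale) {
  spec <- pair_potential("inverse_power_12")
  D <- 1; tau <- 1
  rho_grid <- c(0.3, 0.5, 0.7)
  rows <- list()
  for (i in seq_along(rho_grid)) {
    pt <- fig2_point(rho_grid[i], D, tau, seed + i, scale)
    phi2 <- small_tau_phi2(pt$g, spec)
    rows[[i]] <- data.frame(
      rho = rho_grid[i], D = D, tau = tau,
      simulated = pt$sim$value, simulated_se = pt$sim$stderr,
      mucna_ensemble = pt$ens$value, mucna_ensemble_se = pt$ens$stderr,
      mean_field = mean_field_variance(rho_grid[i], D, tau),
      small_tau = mean_field_variance(rho_grid[i], D, tau, phi2 = phi2),
      harmonic = harmonic_variance(harmonic_spring_constant(rho_grid[i]),
                                   tau))
  }
  tab <- do.call(rbind, rows)
  rel <- abs(tab$mucna_ensemble - tab$simulated) / tab$simulated
  # the MUCNA overestimate grows with density; 15% covers the rho <= 0.7
  # range reported here (10% holds at rho = 0.5)
  agree <- data.frame(check = "coordinate-averaged MUCNA vs simulation",
                      max_rel_dev = max(rel), pass = max(rel) <= 0.15)
  list(curves = tab, agreement = agree)
}

reproduce_fig3 <- function(seed, scale) {
  D <- 1; tau <- 0.3
  rho_grid <- c(0.85, 0.95, 1.05)
  rows <- lapply(seq_along(rho_grid), function(i) {
    cfg <- sim_config(N = 100L, rho = rho_grid[i], D = D, tau = tau,
                      dt = 2e-4, seed = seed + i, n_equil_steps = 50000L,
                      n_sample_steps = as.integer(5e5 * scale),
                      sample_interval = 1000L)
    ovv <- overall_velocity_variance(run_simulation(cfg))
    data.frame(rho = rho_grid[i], D = D, tau = tau,
               simulated = ovv$value, simulated_se = ovv$stderr,
               harmonic = harmonic_variance(
                 harmonic_spring_constant(rho_grid[i]), tau))
  })
  tab <- do.call(rbind, rows)
  rel <- abs(tab$harmonic - tab$simulated) / tab$simulated
  agree <- data.frame(check = "harmonic model vs simulation at high rho",
                      max_rel_dev = max(rel), pass = max(rel) <= 0.25)
  list(curves = tab, agreement = agree)
}

reproduce_fig4 <- function(seed, scale, L = 250,
                           rho_grid = c(0.05, 0.1, 0.2, 0.35),
                           D_grid = c(4, 16), tau_grid = c(0.3, 1)) {
  m <- nearest_mode_index(1 / 20, L)
  q <- 2 * pi * m / L
  rows <- list(); k <- 0L
  for (tau in tau_grid) for (D in D_grid) for (rho in rho_grid) {
    k <- k + 1L
    N <- max(4L, as.integer(round(rho * L)))
    dt <- suggest_dt(D, tau)
    t_mode <- 1 / (D * q^2)  # relaxation time of the sampled q-mode
    cfg <- sim_config(N = N, L = L, D = D, tau = tau, dt = dt,
                      seed = seed + k,
                      n_equil_steps = as.integer(ceiling(3 * t_mode / dt)),
                      n_sample_steps = as.integer(
                        ceiling(40 * scale * t_mode / dt)),
                      sample_interval = as.integer(
                        ceiling(t_mode / 5 / dt)))
    traj <- run_simulation(cfg)
    dm <- density_mode_fluctuations(traj, m)
    rows[[k]] <- data.frame(
      rho = rho, D = D, tau = tau, q = dm$q, m = dm$m,
      simulated = dm$value, simulated_se = dm$stderr,
      predicted = predicted_density_fluctuations(rho, D, tau))
  }
  tab <- do.call(rbind, rows)
  agree <- do.call(rbind, lapply(split(tab, list(tab$tau, tab$D)),
    function(s) {
      data.frame(tau = s$tau[1], D = s$D[1],
                 rho_max_sim = s$rho[which.max(s$simulated)],
                 rho_max_pred = s$rho[which.max(s$predicted)])
    }))
  agree$cells_apart <- abs(match(agree$rho_max_sim, rho_grid) -
                             match(agree$rho_max_pred, rho_grid))
  agree$pass <- agree$cells_apart <= 1
  list(colormap = tab, agreement = agree)
}
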