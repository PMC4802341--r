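spec <- inv12()

test_that("configurational log-density reduces to uniform and Boltzmann limits", {
  box <- box_spec(12)
  x <- c(1, 4.2, 7.7)
  # no interactions: constant over configurations
  none <- pair_potential("none")
  expect_equal(config_log_prob(x, none, box, 1, 1),
               config_log_prob(x + 2, none, box, 1, 1))
  expect_equal(config_log_prob(x, none, box, 1, 1), 0)
  # tau -> 0: -phi/D
  D <- 0.7
  lp <- config_log_prob(x, spec, box, D, 1e-12)
  expect_equal(lp, -total_potential(x, spec, box) / D, tolerance = 1e-8)
  # two particles: depends on the separation only
  l1 <- config_log_prob(c(0.2, 1.4), spec, box, 1, 1)
  l2 <- config_log_prob(c(5.0, 6.2), spec, box, 1, 1)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("velocity covariance is (D/tau) inv(I + tau H) with the known pair values", {
  box <- box_spec(8)
  none <- pair_potential("none")
  expect_equal(velocity_covariance(c(1, 3, 6), none, box, 2, 0.5),
               diag(3) * 4)
  # separation 1: phi'' = 156, det(I + tau H) = 313
  C <- velocity_covariance(c(0, 1), spec, box, 1, 1)
  expect_equal(C[1, 1], 157 / 313, tolerance = 1e-12)
  expect_equal(C[1, 2], 156 / 313, tolerance = 1e-12)
  # generic dense-solver oracle on a 6-particle configuration
  x <- c(0.3, 1.5, 2.6, 4.0, 5.3, 6.6)
  M <- diag(6) + 1 * total_hessian(x, spec, box)
  expect_equal(velocity_covariance(x, spec, box, 1, 1), solve(M),
               tolerance = 1e-10)
})

test_that("single-particle and pair conditionals agree with the N=1/N=2 covariances", {
  # flat potential: free value; diverging curvature: 0 and D/(2 tau)
  expect_equal(single_particle_variance(10, spec, 2, 0.5), 4)
  expect_equal(single_particle_variance(1.5, spec, 1, 1), 1 / (1 + 156 * 1.5^-14))
  expect_equal(single_particle_variance(1.5, spec, 1, 1), 0.651731,
               tolerance = 1e-6)
  expect_lt(single_particle_variance(0.55, spec, 1, 1), 1e-3)
  tp <- two_particle_conditional(c(0.9, 1.2, 5.5), spec, 1, 1)
  expect_identical(tp$variance[3], 1)          # beyond cutoff: free value
  expect_identical(tp$correlation[3], 0)
  expect_lt(abs(tp$variance[1] - 0.5), 5e-4)   # near-contact -> D/(2 tau)
  expect_lt(abs(tp$correlation[1] - 0.5), 5e-4)
  # consistency with the full covariance at N = 2 over a grid of separations
  box <- box_spec(40)
  for (dx in seq(0.95, 2.0, by = 0.35)) {
    C <- velocity_covariance(c(0, dx), spec, box, 1.3, 0.6)
    tpc <- two_particle_conditional(dx, spec, 1.3, 0.6)
    expect_equal(C[1, 1], tpc$variance, tolerance = 1e-10)
    expect_equal(C[1, 2], tpc$correlation, tolerance = 1e-10)
  }
  # near-zero correlations compared absolutely (matrix roundoff floor)
  C <- velocity_covariance(c(0, 4.4), spec, box, 1.3, 0.6)
  expect_lt(abs(C[1, 2] - two_particle_conditional(4.4, spec, 1.3,
                                                   0.6)$correlation),
            1e-13)
  # validity error when 1 + 2 tau phi'' <= 0
  soft <- pair_potential("custom", cutoff = 10,
                         value = function(r) -r^2, deriv = function(r) -2 * r,
                         deriv2 = function(r) rep(-2, length(r)))
  expect_error(two_particle_conditional(1, soft, 1, 1), "validity")
})

test_that("pair separation density normalizes to 1 and matches simulation", {
  D <- 1; tau <- 1; L <- 8
  Z <- integrate(function(dx) two_particle_separation_density(dx, spec, D,
                                                              tau, L),
                 1e-3, L / 2, rel.tol = 1e-8)$value * 2
  expect_equal(Z, 1, tolerance = 1e-6)
  # simulated histogram: far field quantitative, contact peak co-located;
  # the colored-noise approximation carries a known bias at the peak, so the
  # global check is a total-variation bound rather than 5% per bin
  cfg <- sim_config(N = 2, L = L, D = D, tau = tau, dt = 1e-3, seed = 14,
                    n_equil_steps = 20000, n_sample_steps = 2e7,
                    sample_interval = 1000)
  tr <- run_simulation(cfg)
  r <- abs(minimum_image(tr$positions[, 1] - tr$positions[, 2], box_spec(L)))
  br <- seq(0, 4, by = 0.05)
  h <- hist(r, breaks = br, plot = FALSE)
  mids <- (br[-1] + br[-length(br)]) / 2
  thbar <- vapply(seq_along(mids), function(i) {
    xs <- seq(br[i], br[i + 1], length.out = 21)
    mean(2 * two_particle_separation_density(pmax(xs, 1e-3), spec, D, tau, L))
  }, numeric(1))
  tv <- sum(abs(h$density - thbar)) * 0.05 / 2
  expect_lt(tv, 0.10)
  expect_lt(abs(mids[which.max(h$density)] - mids[which.max(thbar)]), 0.11)
  far <- mids > 2.6
  expect_lt(abs(mean(h$density[far]) / mean(thbar[far]) - 1), 0.05)
})

test_that("pair overall variance has the free limit and decreases with rho and D", {
  expect_equal(two_particle_overall_variance(0, spec, 1, 1), 1)
  expect_equal(two_particle_overall_variance(1e-4, spec, 1, 1), 1,
               tolerance = 1e-3)
  rho <- seq(0.1, 0.8, by = 0.1)
  for (D in c(0.25, 1, 4)) {
    v <- two_particle_overall_variance(rho, spec, D, 1)
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 0.5 & v <= 1))
  }
  v1 <- two_particle_overall_variance(0.4, spec, 0.25, 1)
  v2 <- two_particle_overall_variance(0.4, spec, 4, 1)
  expect_lt(v2, v1)
})

test_that("pair overall variance agrees with a long two-particle simulation", {
  cfg <- sim_config(N = 2, rho = 0.25, D = 1, tau = 1, dt = 1e-3, seed = 15,
                    n_equil_steps = 20000, n_sample_steps = 1e7,
                    sample_interval = 1000)
  ov <- overall_velocity_variance(run_simulation(cfg))
  th <- two_particle_overall_variance(0.25, spec, 1, 1)
  # 2 combined standard errors plus the ~2% approximation scale
  expect_lt(abs(ov$value - th), 2 * ov$stderr + 0.02 * th)
})

test_that("hard-sphere closed form is bounded, monotone and tracks the quadrature", {
  rho <- seq(0.05, 0.95, by = 0.05)
  for (D in c(1e-2, 1, 1e2, 1e4)) {
    v <- hard_sphere_variance(rho, D, 1)
    expect_true(all(v > 0.5 & v <= 1))
    expect_true(all(diff(v) < 0))
  }
  expect_equal(hard_sphere_variance(0, 1, 1), 1)
  # joint large-rho, large-D limit -> 1/2
  expect_lt(hard_sphere_variance(0.999, 1e8, 1), 0.501)
  expect_error(hard_sphere_variance(1.2, 1, 1), "overlap")
  # follows the exact x^-12 quadrature within 0.1 absolute at D = tau = 1
  rho <- seq(0.05, 0.8, by = 0.05)
  dev <- hard_sphere_variance(rho, 1, 1) -
    two_particle_overall_variance(rho, spec, 1, 1)
  expect_lt(max(abs(dev)), 0.1)
})

test_that("mean-field variance matches the exact trace of the rank-one matrix", {
  expect_equal(mean_field_variance(0, 1, 1), 1)
  # finite-N trace vs large-N limit within 1/N relative
  for (N in c(100, 1000)) {
    fin <- mean_field_variance(0.5, 1, 1, phi2 = 3, N = N)
    lim <- mean_field_variance(0.5, 1, 1, phi2 = 3)
    expect_lt(abs(fin / lim - 1), 1 / N)
  }
  # dense eigensolver oracle at N = 200
  N <- 200; rho <- 0.4; tau <- 0.7; phi2 <- 2.3
  a <- tau * phi2 * rho
  M <- matrix(-a / N, N, N)
  diag(M) <- 1 + a
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(mean_field_variance(rho, 1, tau, phi2 = phi2, N = N),
               mean(1 / ev), tolerance = 1e-10)
  # force-balance closure depends on rho sqrt(D tau) only
  expect_equal(mean_field_variance(0.3, 4, 1), mean_field_variance(0.3, 1, 4))
  expect_equal(mean_field_variance(0.3, 4, 1),
               1 / (1 + 0.3 * sqrt(4)), tolerance = 1e-12)
})

test_that("integrated pair curvature reproduces the analytic g = 1 tail integral", {
  g0 <- data.frame(x = seq(1, 5, by = 0.001), g = 0)
  expect_equal(small_tau_phi2(g0, spec), 0)
  # g == 1 from sigma: integral of phi'' is -phi'(sigma) = 12 sigma^-13
  for (sigma in c(1, 1.3)) {
    g1 <- data.frame(x = seq(sigma, 5, by = 0.0005), g = 1)
    expect_equal(small_tau_phi2(g1, spec), 12 * sigma^-13, tolerance = 1e-4)
  }
  expect_error(small_tau_phi2(data.frame(x = seq(1, 2, by = 0.01), g = 1),
                              spec), "coverage")
  expect_error(small_tau_phi2(data.frame(x = c(1, 2, 3), g = c(1, -1, 1)),
                              inv12(cutoff = 2.9)), "non-negative")
})

test_that("small-tau route predicts the simulated variance at low persistence time", {
  # tau = 0.1, D = 0.5, rho = 0.3: first-order-in-tau closure; the honest
  # accuracy of this approximation here is ~6%, asserted within 10%
  cfg <- sim_config(N = 100, rho = 0.3, D = 0.5, tau = 0.1, dt = 2e-4,
                    seed = 19, n_equil_steps = 50000,
                    n_sample_steps = 250000, sample_interval = 250)
  tr <- run_simulation(cfg)
  ov <- overall_velocity_variance(tr)
  g <- pair_distribution(tr, seq(0.02, 4, by = 0.02))
  phi2 <- small_tau_phi2(g, spec)
  pred <- mean_field_variance(0.3, 0.5, 0.1, phi2 = phi2)
  expect_lt(abs(pred / ov$value - 1), 0.10)
})

test_that("Watson integral equals the chain-spectrum mean inverse eigenvalue", {
  expect_equal(harmonic_variance(0, 1), 1)
  expect_equal(harmonic_variance(156, 0.3), 1 / sqrt(1 + 4 * 0.3 * 156))
  expect_equal(harmonic_variance(156, 0.3), 0.0728937, tolerance = 1e-6)
  N <- 500; k <- 2.4; tau <- 0.7
  ev <- eigen(diag(N) + tau * harmonic_chain_hessian(N, k),
              symmetric = TRUE, only.values = TRUE)$values
  expect_lt(abs(mean(1 / ev) / harmonic_variance(k, tau) - 1), 1e-3)
  expect_equal(harmonic_spring_constant(1), 156)
  expect_equal(harmonic_spring_constant(0.9), 156 * 0.9^14)
})

test_that("ensemble MUCNA variance is exact for ideal gases and self-consistent at N=2", {
  box <- box_spec(20)
  none <- pair_potential("none")
  set.seed(3)
  pos <- matrix(runif(50 * 10, 0, 20), 50, 10)
  ens <- ensemble_variance_from_positions(pos, none, box, 1, 1)
  expect_equal(ens$value, 1)
  expect_equal(ens$n_invalid, 0)
  # N = 2 positions drawn from the MUCNA separation law reproduce the
  # quadrature average within 2 standard errors
  L <- 8; D <- 1; tau <- 1
  dxg <- seq(0.9, 4, by = 0.002)
  w <- two_particle_separation_density(dxg, spec, D, tau, L)
  set.seed(4)
  dx <- sample(dxg, 4000, replace = TRUE, prob = w)
  pos2 <- cbind(0, dx)
  ens2 <- ensemble_variance_from_positions(pos2, spec, box_spec(L), D, tau)
  th <- two_particle_overall_variance(2 / L, spec, D, tau)
  expect_lt(abs(ens2$value - th), 2 * ens2$stderr + 0.003)
})

test_that("ensemble MUCNA variance tracks a many-body simulation", {
  cfg <- sim_config(N = 100, rho = 0.5, D = 1, tau = 1, dt = 1e-3, seed = 8,
                    n_equil_steps = 30000, n_sample_steps = 250000,
                    sample_interval = 500)
  tr <- run_simulation(cfg)
  ov <- overall_velocity_variance(tr)
  ens <- ensemble_variance_from_positions(tr)
  expect_equal(ens$n_invalid, 0)
  expect_lt(abs(ens$value / ov$value - 1), 0.10)
})

test_that("normalized variances stay in (0, 1] and recover 1 as tau -> 0", {
  rho <- c(0.2, 0.5, 0.8)
  # the contact boundary layer contributes O(sqrt(tau)), so convergence to
  # the free value is checked at decreasing tau
  dev <- function(tau) max(abs(two_particle_overall_variance(rho, spec, 1,
                                                             tau) - 1))
  expect_lt(dev(1e-6), 2e-3)
  expect_lt(dev(1e-6), dev(1e-4))
  expect_equal(hard_sphere_variance(rho, 1, 1e-8), rep(1, 3),
               tolerance = 1e-3)
  expect_equal(mean_field_variance(rho, 1, 1e-8), rep(1, 3),
               tolerance = 1e-3)
  expect_equal(harmonic_variance(harmonic_spring_constant(rho), 1e-10),
               rep(1, 3), tolerance = 1e-3)
})
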