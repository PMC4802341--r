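test_that("OU update is the identity at dt = 0 and has the exact stationary law", {
  eta <- c(-1, 0.5, 2)
  expect_identical(ou_step(eta, 0, 1, 1), eta)
  expect_error(ou_step(eta, 0.1, -1, 1), "positive")
  # stationary variance D/tau from a long single-component run
  set.seed(1)
  D <- 2; tau <- 0.5; dt <- 0.05
  n <- 1e5
  e <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    cur <- ou_step(cur, dt, D, tau)
    e[i] <- cur
  }
  # se of the variance of n correlated samples (integrated autocorr ~ tau/dt)
  se <- (D / tau) * sqrt(2 / (n * dt / (2 * tau)))
  expect_lt(abs(var(e) - D / tau), 3 * se)
  expect_lt(abs(mean(e)), 3 * sqrt(D / tau / (n * dt / (2 * tau))))
})

test_that("OU autocorrelation decays as exp(-lag/tau)", {
  set.seed(2)
  D <- 1; tau <- 1; dt <- 0.1
  n <- 20000; m <- 50  # 50 independent components
  eta <- matrix(rnorm(m, 0, sqrt(D / tau)), 1, m)
  out <- matrix(0, n, m)
  cur <- eta[1, ]
  for (i in seq_len(n)) {
    cur <- ou_step(cur, dt, D, tau)
    out[i, ] <- cur
  }
  lags <- c(5, 10, 20)  # 0.5, 1, 2 tau
  for (lg in lags) {
    emp <- mean(out[seq_len(n - lg), ] * out[seq_len(n - lg) + lg, ]) /
      mean(out^2)
    expect_lt(abs(emp - exp(-lg * dt / tau)) / exp(-lg * dt / tau), 0.05)
  }
})

test_that("langevin_step advances free and deterministic cases exactly", {
  # phi == 0, frozen noise c: linear advection by c*dt
  cfg <- sim_config(N = 3, L = 10, D = 1, tau = 1, dt = 1e-3,
                    potential = pair_potential("none"))
  st <- list(x = c(1, 5, 8), eta = c(0.3, -0.2, 1), t = 0)
  set.seed(1)
  st2 <- langevin_step(st, cfg)
  expect_equal(st2$x, st$x + 1e-3 * st$eta)
  expect_equal(st2$v, st$eta)
  # single particle in phi = x^2 with eta = 0: geometric decay (1 - 2 dt)
  cfgq <- sim_config(N = 1, L = Inf, D = 1, tau = 1, dt = 1e-3,
                     potential = pair_potential("none"),
                     external = "harmonic")
  x <- 0.7
  st <- list(x = x, eta = 0, t = 0)
  for (i in 1:5) {
    set.seed(1)
    st <- langevin_step(st, cfgq)
    st$eta <- 0
    expect_equal(st$x, x * (1 - 2e-3)^i, tolerance = 1e-12)
  }
})

test_that("two close particles repel monotonically under the inverse-power force", {
  cfg <- sim_config(N = 2, L = 50, D = 1, tau = 1, dt = 1e-5)
  st <- list(x = c(10, 10.8), eta = c(0, 0), t = 0)
  sep <- 0.8
  for (i in 1:200) {
    set.seed(1)
    st <- langevin_step(st, cfg)
    st$eta <- c(0, 0)
    new_sep <- st$x[2] - st$x[1]
    expect_gte(new_sep, sep)
    sep <- new_sep
  }
  expect_gt(sep, 0.8)
})

test_that("run_simulation is bit-reproducible for a fixed config and seed", {
  cfg <- sim_config(N = 20, rho = 0.4, D = 1, tau = 1, dt = 1e-3, seed = 33,
                    n_equil_steps = 500, n_sample_steps = 2000,
                    sample_interval = 100)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$noises, t2$noises)
  expect_identical(t1$velocities, t2$velocities)
})

test_that("recorded velocities satisfy v = -grad phi + eta and pair forces cancel", {
  cfg <- sim_config(N = 12, rho = 0.5, D = 1, tau = 1, dt = 1e-3, seed = 5,
                    n_equil_steps = 2000, n_sample_steps = 5000,
                    sample_interval = 500)
  tr <- run_simulation(cfg)
  box <- box_spec(cfg$L)
  for (s in seq_len(nrow(tr$positions))) {
    v_expected <- -total_gradient(tr$positions[s, ], cfg$potential, box) +
      tr$noises[s, ]
    expect_equal(tr$velocities[s, ], v_expected, tolerance = 1e-12)
    # momentum-like identity: pair forces cancel in the sum
    expect_equal(sum(tr$velocities[s, ]), sum(tr$noises[s, ]),
                 tolerance = 1e-9)
  }
})

test_that("free particles recover variance D/tau and diffusive spreading 2Dt", {
  D <- 1.5; tau <- 0.8
  cfg <- sim_config(N = 4000, L = Inf, D = D, tau = tau, dt = 2e-3,
                    seed = 21, potential = pair_potential("none"),
                    n_equil_steps = 0, n_sample_steps = 25000,
                    sample_interval = 1250)
  cfg$x0 <- numeric(4000)  # all start at the origin; no interactions anyway
  tr <- run_simulation(cfg)
  ov <- overall_velocity_variance(tr)
  expect_lt(abs(ov$value - 1), 3 * ov$stderr)
  # mean squared displacement after t >> tau: 2 D (t - tau) within 5%
  t_end <- tr$time[length(tr$time)]
  msd <- mean((tr$positions[nrow(tr$positions), ] - 0)^2)
  expect_gt(t_end, 40 * tau)
  expect_lt(abs(msd / (2 * D * (t_end - tau)) - 1), 0.05)
})

test_that("a dilute pair recovers the free velocity variance", {
  cfg <- sim_config(N = 2, L = 400, D = 1, tau = 1, dt = 1e-3, seed = 9,
                    n_equil_steps = 5000, n_sample_steps = 3e5,
                    sample_interval = 500)
  ov <- overall_velocity_variance(run_simulation(cfg))
  expect_lt(abs(ov$value - 1), max(3 * ov$stderr, 0.02))
})

test_that("stiffness and config validation guard against unusable settings", {
  expect_error(sim_config(N = 10, rho = 0.5, dt = 0.1, tau = 1), "tau/50")
  expect_error(sim_config(N = 10, rho = 1.5), "rho")
  expect_error(sim_config(N = 10), "rho or L")
  # a grossly too-large dt trips the stiffness monitor, not a blow-up
  cfg <- sim_config(N = 50, rho = 0.8, D = 20, tau = 10, dt = 0.05,
                    seed = 2, n_equil_steps = 1000, n_sample_steps = 1000,
                    sample_interval = 100)
  expect_error(run_simulation(cfg), "stiffness|degenerate")
})

test_that("position-velocity factorization holds for one particle in a quartic trap", {
  # joint (x, v) statistics factorize with conditional Gaussian variance
  # (D/tau)/(1 + 12 tau x^2); the adiabatic approximation carries a known
  # residual bias at tau = 0.3, covered by the 20% band.
  D <- 0.5; tau <- 0.3
  cfg <- sim_config(N = 1, L = Inf, D = D, tau = tau, dt = 2e-4, seed = 6,
                    external = "quartic", potential = pair_potential("none"),
                    n_equil_steps = 20000, n_sample_steps = 2e7,
                    sample_interval = 1500)
  tr <- run_simulation(cfg)
  x <- tr$positions[, 1]; v <- tr$velocities[, 1]
  br <- seq(-0.9, 0.9, by = 0.2)
  idx <- findInterval(x, br)
  for (b in seq_len(length(br) - 1L)) {
    s <- which(idx == b)
    if (length(s) < 400) next
    th <- (D / tau) / (1 + 12 * tau * mean(x[s])^2)
    expect_lt(abs(var(v[s]) / th - 1), 0.20)
  }
})
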