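# Shared fixtures: small deterministic configurations and a constructor for
# synthetic trajectories (known-distribution oracles).

inv12 <- function(...) pair_potential("inverse_power_12", ...)

# Wrap bare matrices into the trajectory container so observable estimators
# can be fed known distributions.
synthetic_traj <- function(positions, velocities = NULL, noises = NULL,
                           L, D = 1, tau = 1, N = ncol(positions),
                           potential = pair_potential("none")) {
  cfg <- sim_config(N = N, L = L, D = D, tau = tau, dt = 1e-3, seed = 1L,
                    potential = potential, n_equil_steps = 0L,
                    n_sample_steps = 1L, sample_interval = 1L)
  if (is.null(velocities)) velocities <- positions * 0
  if (is.null(noises)) noises <- velocities
  structure(list(positions = positions, noises = noises,
                 velocities = velocities,
                 time = seq_len(nrow(positions)) - 1, config = cfg),
            class = "gcn_trajectory")
}

# Central finite differences of a scalar function
fd_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h^2
    } else {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
      xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
      H[i, j] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}
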