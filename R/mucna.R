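#' MUCNA matrix I + tau * Hessian
#'
#' The multidimensional unified colored noise approximation (MUCNA) expresses
#' both the stationary configurational density and the conditional velocity
#' covariance through the matrix \eqn{M = I + \tau \nabla\nabla\varphi}.
#' The approximation is valid where M is positive definite.
#'
#' @inheritParams total_potential
#' @param tau persistence time.
#' @return list with the matrix `M`, its eigenvalues, and `valid` flag.
#' @export
mucna_matrix <- function(positions, spec, box, tau) {
  H <- total_hessian(positions, spec, box)
  M <- diag(length(positions)) + tau * H
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  list(M = M, eigenvalues = ev, valid = all(ev > 0))
}

mucna_validity_stop <- function() {
  stop("MUCNA validity: I + tau * Hessian is not positive definite at this ",
       "configuration (colored-noise approximation breaks down)")
}

#' Log of the unnormalized MUCNA stationary configurational density
#'
#' \deqn{\log P(x) = -\frac{1}{D}\left[\varphi + \frac{\tau}{2}
#'   |\nabla\varphi|^2\right] + \log\left\|I + \tau\nabla\nabla\varphi\right\|}
#' For \eqn{\tau \to 0} this reduces to the equilibrium Boltzmann weight
#' \eqn{-\varphi/D}.
#'
#' @inheritParams total_potential
#' @param D diffusivity.
#' @param tau persistence time.
#' @return unnormalized log-density (scalar).
#' @export
config_log_prob <- function(positions, spec, box, D, tau) {
  mm <- mucna_matrix(positions, spec, box, tau)
  if (!mm$valid) mucna_validity_stop()
  phi <- total_potential(positions, spec, box)
  grad <- total_gradient(positions, spec, box)
  -(phi + tau / 2 * sum(grad^2)) / D + sum(log(mm$eigenvalues))
}

#' Position-conditional velocity covariance
#'
#' Within the MUCNA the velocities at fixed positions are jointly Gaussian
#' with zero mean and covariance
#' \eqn{(D/\tau)\,(I + \tau\nabla\nabla\varphi)^{-1}}: regions of high
#' potential curvature suppress the local velocity variance below the free
#' value \eqn{D/\tau} and couple the velocities of interacting particles.
#'
#' @inheritParams config_log_prob
#' @return symmetric positive-definite N x N covariance matrix.
#' @export
velocity_covariance <- function(positions, spec, box, D, tau) {
  mm <- mucna_matrix(positions, spec, box, tau)
  if (!mm$valid) mucna_validity_stop()
  Minv <- chol2inv(chol(mm$M))
  (D / tau) * (Minv + t(Minv)) / 2
}

#' Velocity variance of one particle in an external potential
#'
#' \eqn{(D/\tau) / (1 + \tau\varphi''(x))}: the variance drops to zero where
#' the external curvature is large (e.g. against a repulsive wall) and equals
#' the free value where the potential is flat.
#'
#' @param x positions at which to evaluate (distance from the wall when
#'   `potential` is a pair form like \eqn{x^{-12}}).
#' @param potential a [pair_potential()] used as an external profile, or a
#'   function returning the curvature \eqn{\varphi''(x)}.
#' @param D diffusivity.
#' @param tau persistence time.
#' @return vector of velocity variances (absolute units, not normalized).
#' @export
single_particle_variance <- function(x, potential, D, tau) {
  curv <- if (is.function(potential)) potential(x)
          else pair_value_derivs(potential, x)$deriv2
  denom <- 1 + tau * curv
  if (any(denom <= 0)) mucna_validity_stop()
  (D / tau) / denom
}

#' Conditional velocity variance and correlation of an interacting pair
#'
#' For two particles in 1d at separation `dx` the MUCNA gives
#' \deqn{\overline{v^2} = \frac{D}{2\tau}\left(1 +
#'   \frac{1}{1 + 2\tau\varphi''(\Delta x)}\right), \qquad
#'   \overline{v_1 v_2} = \frac{D}{2\tau}\left(1 -
#'   \frac{1}{1 + 2\tau\varphi''(\Delta x)}\right).}
#' At large separation these tend to \eqn{(D/\tau, 0)}; where the curvature
#' diverges both tend to \eqn{D/(2\tau)}, the mean squared speed of the
#' pair's center of mass, and the particles move coherently.
#'
#' @param dx separations (nonzero; the absolute value is used).
#' @param spec a [pair_potential()].
#' @param D diffusivity.
#' @param tau persistence time.
#' @return data.frame with columns `dx`, `variance`, `correlation`
#'   (absolute units).
#' @export
two_particle_conditional <- function(dx, spec, D, tau) {
  if (any(dx == 0)) stop("separation dx must be nonzero")
  d2 <- pair_value_derivs(spec, abs(dx))$deriv2
  denom <- 1 + 2 * tau * d2
  if (any(denom <= 0)) mucna_validity_stop()
  data.frame(dx = dx,
             variance = (D / (2 * tau)) * (1 + 1 / denom),
             correlation = (D / (2 * tau)) * (1 - 1 / denom))
}

# Unnormalized two-particle MUCNA weight as a function of separation r > 0:
# w(r) = exp(-[phi(r) + tau phi'(r)^2]/D) * (1 + 2 tau phi''(r)).
two_particle_weight <- function(r, spec, D, tau) {
  pv <- pair_value_derivs(spec, r)
  exp(-(pv$value + tau * pv$deriv^2) / D) * (1 + 2 * tau * pv$deriv2)
}

# Quadrature of f(r) * w(r) over r in (0, L/2) for the stiff x^-12 weight;
# the flat region beyond the cutoff is added analytically.
two_particle_quadrature <- function(f, spec, D, tau, L,
                                    rel.tol = 1e-10) {
  half <- L / 2
  rc <- min(spec$cutoff, half)
  # below r_lo the Boltzmann factor is < exp(-400); identically zero region
  r_lo <- if (spec$form == "inverse_power_12")
    min((400 * D / spec$energy_scale)^(-1 / 12), rc) else 1e-8
  # peak of the contact weight: where the force matches the propulsion scale
  r_peak <- if (spec$form == "inverse_power_12")
    (12 * spec$energy_scale * sqrt(tau / D))^(1 / 13) else NA_real_
  pts <- sort(unique(pmin(pmax(
    c(r_lo, r_peak, 1.5, 2.5, rc), r_lo), rc)))
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    if (pts[k + 1L] <= pts[k]) next
    iv <- stats::integrate(function(r) f(r) * two_particle_weight(r, spec, D, tau),
                           pts[k], pts[k + 1L],
                           rel.tol = rel.tol, abs.tol = 1e-12,
                           subdivisions = 500L, stop.on.error = FALSE)
    if (!iv$message %in% "OK")
      stop("quadrature failed on (", pts[k], ", ", pts[k + 1L], "): ",
           iv$message)
    total <- total + iv$value
  }
  if (half > rc) {
    # beyond the cutoff w(r) = 1 exactly
    iv <- stats::integrate(f, rc, half, rel.tol = rel.tol,
                           subdivisions = 200L, stop.on.error = FALSE)
    if (!iv$message %in% "OK") stop("quadrature failed beyond cutoff: ",
                                    iv$message)
    total <- total + iv$value
  }
  total
}

#' Normalized MUCNA separation density for two particles
#'
#' The stationary density of the signed minimum-image separation
#' \eqn{\Delta x \in (-L/2, L/2]} of two particles in a periodic box,
#' normalized to integrate to 1.
#'
#' @param dx signed separations.
#' @param spec a [pair_potential()].
#' @param D,tau model parameters.
#' @param L box length.
#' @return density values at `dx`.
#' @export
two_particle_separation_density <- function(dx, spec, D, tau, L) {
  Z <- 2 * two_particle_quadrature(function(r) rep(1, length(r)),
                                   spec, D, tau, L)
  two_particle_weight(abs(dx), spec, D, tau) / Z
}

#' Position-averaged velocity variance of an interacting pair
#'
#' Averages the conditional per-particle velocity variance over the MUCNA
#' separation density in a periodic box of length \eqn{L = 2/\rho}, and
#' normalizes by the free value \eqn{D/\tau}. Decreases from 1 towards 1/2
#' with increasing density and diffusivity.
#'
#' @param rho pair density 2/L (vectorized).
#' @param spec a [pair_potential()].
#' @param D,tau model parameters.
#' @return normalized variance values in (0, 1].
#' @export
two_particle_overall_variance <- function(rho, spec, D, tau) {
  vapply(rho, function(r1) {
    if (r1 <= 0) return(1)
    L <- 2 / r1
    cfun <- function(r) {
      d2 <- pair_value_derivs(spec, r)$deriv2
      0.5 * (1 + 1 / (1 + 2 * tau * d2))
    }
    I1 <- two_particle_quadrature(cfun, spec, D, tau, L)
    I0 <- two_particle_quadrature(function(r) rep(1, length(r)),
                                  spec, D, tau, L)
    I1 / I0
  }, numeric(1L))
}

#' Hard-sphere closed form for the pair velocity variance
#'
#' In the hard-sphere limit the MUCNA separation density collapses to a
#' Dirac peak of area \eqn{\sqrt{\pi D \tau}} at contact
#' (\eqn{\Delta x = \pm\sigma}) plus a flat background, giving
#' \deqn{\frac{\overline{v^2}}{D/\tau} =
#'   \frac{2(1-\rho\sigma) + \rho\sqrt{\pi D \tau}}
#'        {2(1-\rho\sigma) + 2\rho\sqrt{\pi D \tau}}.}
#' The value lies in (1/2, 1], decreases monotonically in \eqn{\rho} and D,
#' approaches 1/2 in the joint large-\eqn{\rho}, large-D limit, and depends
#' on D only through the persistence length \eqn{\ell = \sqrt{D\tau}} via
#' \eqn{\rho\ell/(1-\rho\sigma)}.
#'
#' @param rho pair density (vectorized).
#' @param D,tau model parameters.
#' @param sigma effective hard-sphere diameter (default 1).
#' @return normalized variance values.
#' @export
hard_sphere_variance <- function(rho, D, tau, sigma = 1) {
  if (any(rho < 0)) stop("rho must be non-negative")
  if (any(rho * sigma >= 1)) stop("overlap: rho * sigma must be < 1")
  s <- rho * sqrt(pi * D * tau)
  (2 * (1 - rho * sigma) + s) / (2 * (1 - rho * sigma) + 2 * s)
}

#' Mean-field velocity variance for a uniform active fluid
#'
#' With uniform density and long-ranged interactions the MUCNA matrix has
#' N - 1 identical eigenvalues \eqn{1 + (N+1)\tau\varphi_2\rho/N} and one
#' eigenvalue \eqn{1 + \tau\varphi_2\rho/N}, where \eqn{\varphi_2} is the
#' pair curvature integrated over the line outside the core (see
#' [small_tau_phi2()]). The finite-N normalized variance is the exact trace
#' \deqn{\frac{1}{N}\left[\frac{N-1}{1 + (N+1)\tau\varphi_2\rho/N} +
#'   \frac{1}{1 + \tau\varphi_2\rho/N}\right]}
#' and the large-N limit is \eqn{1/(1 + \tau\varphi_2\rho)}.
#'
#' When `phi2` is omitted, the force-balance closure is used: the effective
#' diameter \eqn{\sigma} is the distance where the repulsion balances the
#' typical propulsion speed, \eqn{-\varphi'(\sigma) = \sqrt{D/\tau}}, so the
#' curvature integrated outward from \eqn{\sigma} is
#' \eqn{\varphi_2 = -\varphi'(\sigma) = \sqrt{D/\tau}} and the variance
#' depends on density only through \eqn{\rho\sqrt{D\tau}}.
#'
#' @param rho number density (vectorized).
#' @param D,tau model parameters.
#' @param phi2 integrated pair curvature; `NULL` selects the force-balance
#'   closure.
#' @param N particle number; `Inf` (default) gives the large-N limit.
#' @return normalized variance values.
#' @export
mean_field_variance <- function(rho, D, tau, phi2 = NULL, N = Inf) {
  if (any(rho < 0)) stop("rho must be non-negative")
  if (is.null(phi2)) phi2 <- sqrt(D / tau)
  a <- tau * phi2 * rho
  if (is.infinite(N)) {
    denom <- 1 + a
    if (any(denom <= 0)) stop("mean-field denominator 1 + tau*phi2*rho <= 0")
    return(1 / denom)
  }
  d1 <- 1 + (N + 1) * a / N
  d2 <- 1 + a / N
  if (any(d1 <= 0) || any(d2 <= 0))
    stop("mean-field denominator <= 0")
  ((N - 1) / d1 + 1 / d2) / N
}

#' Integrated pair curvature from the pair distribution function
#'
#' Small-persistence-time route to the mean-field variance:
#' \eqn{\varphi_2 = \int g(x)\,\varphi''(x)\,dx}, integrated by the
#' trapezoidal rule over the supplied \eqn{|\Delta x|} grid. Feeding the
#' result to [mean_field_variance()] gives the variance prediction
#' \eqn{1/(1+\tau\varphi_2\rho)}, accurate when \eqn{\tau\varphi''} is
#' small over the support of g.
#'
#' @param g a [binned_stat()] holding g(x), or a data.frame with columns
#'   `x` and `g`.
#' @param spec a [pair_potential()].
#' @return scalar \eqn{\varphi_2} (energy/length, reduced units).
#' @export
small_tau_phi2 <- function(g, spec) {
  if (inherits(g, "binned_stat")) {
    x <- bin_centers(g)
    gx <- g$mean
  } else {
    x <- g$x
    gx <- g$g
  }
  if (any(!is.finite(gx)) || any(gx < 0))
    stop("g must be finite and non-negative")
  if (length(x) < 3L || is.unsorted(x)) stop("g grid must be increasing")
  d2_hi <- pair_value_derivs(spec, max(x))$deriv2
  if (is.finite(spec$cutoff) && max(x) < spec$cutoff && d2_hi > 1e-3)
    stop("coverage: g grid ends at ", max(x), " where the pair curvature is ",
         "still ", signif(d2_hi, 3), "; extend the grid over the potential's ",
         "support")
  integrand <- gx * pair_value_derivs(spec, x)$deriv2
  sum(diff(x) * (utils::head(integrand, -1) +
                   utils::tail(integrand, -1)) / 2)
}

#' Watson-integral velocity variance of the active harmonic chain
#'
#' For the periodic nearest-neighbour harmonic chain the MUCNA matrix is a
#' Toeplitz operator with known eigenvalues
#' \eqn{1 + 2\tau k (1 - \cos\theta)}; the mean inverse eigenvalue is the
#' Watson integral
#' \deqn{\frac{1}{2\pi}\int_0^{2\pi}
#'   \frac{d\theta}{1 + 2\tau k(1-\cos\theta)} = \frac{1}{\sqrt{1+4\tau k}}.}
#' Mapping the inverse-power fluid at high density onto this chain uses the
#' effective spring constant \eqn{k(\rho) = 156\rho^{14}}.
#'
#' @param k spring constant (>= 0, vectorized).
#' @param tau persistence time.
#' @return normalized variance values.
#' @export
harmonic_variance <- function(k, tau) {
  if (any(k < 0)) stop("spring constant k must be non-negative")
  if (tau <= 0) stop("tau must be positive")
  1 / sqrt(1 + 4 * tau * k)
}

#' Effective spring constant of the dense inverse-power fluid
#'
#' Expands \eqn{\varphi = x^{-12}} to second order around the mean spacing
#' \eqn{\rho^{-1}}: \eqn{k(\rho) = 156\rho^{14}}.
#' @param rho number density (vectorized).
#' @return spring constants.
#' @export
harmonic_spring_constant <- function(rho) 156 * rho^14

#' Ensemble MUCNA variance from sampled coordinates
#'
#' Evaluates \eqn{\mathrm{tr}[(I + \tau\nabla\nabla\varphi)^{-1}]/(dN)}
#' on each supplied configuration and averages, giving the MUCNA prediction
#' for the overall normalized velocity variance computed directly from
#' simulated coordinates. Configurations where the MUCNA matrix is not
#' positive definite are excluded and counted, not clamped.
#'
#' @param position_samples matrix of configurations (rows) x particles
#'   (columns), or a `gcn_trajectory`.
#' @param spec a [pair_potential()]; taken from the trajectory config when
#'   omitted and a trajectory is supplied.
#' @param box a [box_spec()]; likewise defaulted from the trajectory.
#' @param D,tau model parameters; likewise defaulted.
#' @return list with `value` (normalized variance), `stderr` (jackknife
#'   standard error over configurations), `per_config` values, `n_valid`,
#'   `n_invalid`.
#' @export
ensemble_variance_from_positions <- function(position_samples, spec = NULL,
                                             box = NULL, D = NULL,
                                             tau = NULL) {
  if (inherits(position_samples, "gcn_trajectory")) {
    cfg <- position_samples$config
    if (is.null(spec)) spec <- cfg$potential
    if (is.null(box)) box <- box_spec(cfg$L)
    if (is.null(D)) D <- cfg$D
    if (is.null(tau)) tau <- cfg$tau
    position_samples <- position_samples$positions
  }
  stopifnot(is.matrix(position_samples))
  n_cfg <- nrow(position_samples)
  vals <- rep(NA_real_, n_cfg)
  for (i in seq_len(n_cfg)) {
    mm <- mucna_matrix(position_samples[i, ], spec, box, tau)
    if (mm$valid) vals[i] <- mean(1 / mm$eigenvalues)
  }
  ok <- !is.na(vals)
  if (!any(ok))
    stop("MUCNA validity: no configuration had a positive-definite matrix")
  v <- vals[ok]
  n <- length(v)
  # leave-one-out jackknife of the mean
  jk <- (sum(v) - v) / (n - 1)
  se <- sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  list(value = mean(v), stderr = se, per_config = vals,
       n_valid = n, n_invalid = sum(!ok))
}
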