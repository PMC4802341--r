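#' Mean-field effective free energy per unit length
#'
#' The MUCNA stationary density maps the active system onto a Boltzmann
#' distribution with effective potential
#' \eqn{\varphi + (\tau/2)|\nabla\varphi|^2 - D\ln\|I+\tau\nabla\nabla\varphi\|}.
#' Assuming a homogeneous density, absorbing the repulsive terms into the 1d
#' hard-rod (Tonks) excess free energy and evaluating the determinant term
#' with the mean-field velocity variance gives, per unit length,
#' \deqn{f(\rho)/D = \rho\ln\rho - \rho - \rho\ln(1-\rho\sigma)
#'   - \rho\ln(1 + \tau\varphi_2\rho).}
#' The last term is (twice) the differential entropy of the velocity
#' distribution: configurations with spread-out velocities are penalized,
#' which acts as a weak effective attraction at high persistence length
#' \eqn{\ell = \sqrt{D\tau}}.
#'
#' @param rho number density, 0 < rho*sigma < 1 (vectorized).
#' @param D,tau model parameters; `tau = 0` gives the passive Tonks gas.
#' @param sigma effective hard-rod diameter (default 1; pass the measured
#'   [effective_diameter()] to tie the theory to a particular state point).
#' @param phi2 integrated pair curvature; `NULL` selects the force-balance
#'   closure \eqn{\tau\varphi_2 = \sqrt{D\tau}} (see
#'   [mean_field_variance()]).
#' @param velocity_term_scale internal multiplier on the velocity-entropy
#'   term (default 1); used to sanity-check the spinodal detector.
#' @return free energy per unit length (energy/length).
#' @export
mean_field_free_energy <- function(rho, D, tau, sigma = 1, phi2 = NULL,
                                   velocity_term_scale = 1) {
  check_mf_domain(rho, sigma)
  a <- mf_activity(D, tau, phi2)
  D * (rho * log(rho) - rho - rho * log1p(-rho * sigma) -
         velocity_term_scale * rho * log1p(a * rho))
}

check_mf_domain <- function(rho, sigma) {
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(rho * sigma >= 1))
    stop("domain error: rho * sigma must be < 1 (hard-rod divergence)")
  invisible(TRUE)
}

# tau*phi2: the coefficient of rho inside the velocity-entropy logarithm;
# the force-balance closure gives tau*phi2 = sqrt(D*tau), the persistence
# length
mf_activity <- function(D, tau, phi2) {
  if (is.null(phi2)) sqrt(D * tau) else tau * phi2
}

#' Curvature of the mean-field free energy
#'
#' Analytic second derivative
#' \deqn{f''(\rho)/D = \frac{1}{\rho(1+\tau\varphi_2\rho)^2} +
#'   \frac{\sigma(2-\rho\sigma)}{(1-\rho\sigma)^2},}
#' manifestly positive for every \eqn{\rho, D, \tau}: the homogeneous phase
#' of this mean-field model never crosses a spinodal.
#'
#' @inheritParams mean_field_free_energy
#' @return f'' values (energy x length).
#' @export
free_energy_curvature <- function(rho, D, tau, sigma = 1, phi2 = NULL,
                                  velocity_term_scale = 1) {
  check_mf_domain(rho, sigma)
  a <- mf_activity(D, tau, phi2)
  ideal <- 1 / rho
  hard_rod <- sigma * (2 - rho * sigma) / (1 - rho * sigma)^2
  vel <- -2 * a / (1 + a * rho) + rho * a^2 / (1 + a * rho)^2
  D * (ideal + hard_rod + velocity_term_scale * vel)
}

#' Spinodal stability scan
#'
#' Tabulates the sign of the free-energy curvature over a parameter grid.
#' A negative curvature would signal spinodal decomposition of the
#' homogeneous phase; this mean-field model yields none anywhere.
#'
#' @param rho_grid,D_grid,tau_grid numeric grids (defaults cover
#'   \eqn{\rho\sigma \in (0.01, 0.99)}, \eqn{D \in [10^{-2}, 10^3]},
#'   \eqn{\tau \in [10^{-2}, 10^2]} log-spaced).
#' @inheritParams mean_field_free_energy
#' @return list with the scan `table` (data.frame rho, D, tau, f, fpp,
#'   stable), `n_unstable`, and `min_fpp` row.
#' @export
spinodal_scan <- function(rho_grid = NULL, D_grid = NULL, tau_grid = NULL,
                          sigma = 1, phi2 = NULL, velocity_term_scale = 1) {
  if (is.null(rho_grid)) rho_grid <- seq(0.01, 0.99, length.out = 25) / sigma
  if (is.null(D_grid)) D_grid <- 10^seq(-2, 3, length.out = 11)
  if (is.null(tau_grid)) tau_grid <- 10^seq(-2, 2, length.out = 9)
  tab <- expand.grid(rho = rho_grid, D = D_grid, tau = tau_grid,
                     KEEP.OUT.ATTRS = FALSE)
  tab$f <- mean_field_free_energy(tab$rho, tab$D, tab$tau, sigma, phi2,
                                  velocity_term_scale)
  tab$fpp <- free_energy_curvature(tab$rho, tab$D, tab$tau, sigma, phi2,
                                   velocity_term_scale)
  tab$stable <- tab$fpp > 0
  list(table = tab, n_unstable = sum(!tab$stable),
       min_fpp = tab[which.min(tab$fpp), ])
}

#' Predicted long-wavelength density fluctuations
#'
#' Compressibility form of the small-q density fluctuation amplitude,
#' \eqn{\langle|\delta\rho_q|^2\rangle \approx D / (\rho f''(\rho))},
#' normalized so that the ideal gas (\eqn{\sigma = 0, \tau = 0}) gives
#' exactly 1, matching the [density_mode_fluctuations()] convention. At high
#' persistence length the amplitude develops an interior maximum in density,
#' growing with \eqn{\tau}: the colored noise enhances low-density
#' fluctuations like a weak effective attraction.
#'
#' @inheritParams mean_field_free_energy
#' @return dimensionless fluctuation amplitudes.
#' @export
predicted_density_fluctuations <- function(rho, D, tau, sigma = 1,
                                           phi2 = NULL) {
  fpp <- free_energy_curvature(rho, D, tau, sigma, phi2)
  if (any(fpp <= 0)) stop("curvature must be positive for the ",
                          "compressibility form")
  D / (rho * fpp)
}
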