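#' Pair interaction potential specification
#'
#' Defines a pair potential with analytic value, first and second derivative.
#' Supported forms are the purely repulsive inverse-power potential
#' \eqn{\varphi(x) = \epsilon\, x^{-12}} (truncated at `cutoff`), a harmonic
#' spring \eqn{\varphi(x) = k x^2 / 2}, the null potential (`"none"`, ideal
#' gas), and a user-supplied `"custom"` triple of functions.
#'
#' @param form one of `"inverse_power_12"`, `"harmonic"`, `"none"`, `"custom"`.
#' @param energy_scale energy scale \eqn{\epsilon} of the inverse-power form
#'   (reduced units, default 1).
#' @param spring_k spring constant (energy/length^2) for the harmonic form.
#' @param cutoff truncation radius for the inverse-power form. The default
#'   5.0 is the radius where the force magnitude drops below 1e-8, negligible
#'   against the propulsion scale \eqn{\sqrt{D/\tau}} in all studied regimes.
#' @param value,deriv,deriv2 functions of distance for `form = "custom"`.
#' @return an object of class `pair_potential`.
#' @examples
#' pp <- pair_potential("inverse_power_12")
#' pair_value_derivs(pp, 1)  # curvature 156 at contact distance 1
#' @export
pair_potential <- function(form = c("inverse_power_12", "harmonic", "none", "custom"),
                           energy_scale = 1, spring_k = NULL, cutoff = 5.0,
                           value = NULL, deriv = NULL, deriv2 = NULL) {
  form <- match.arg(form)
  if (form == "inverse_power_12") {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
      stop("cutoff must be a single positive length")
    if (energy_scale <= 0) stop("energy_scale must be positive")
  }
  if (form == "harmonic") {
    if (is.null(spring_k) || spring_k < 0)
      stop("harmonic form needs a non-negative spring_k")
    cutoff <- Inf
  }
  if (form == "none") cutoff <- 0
  if (form == "custom") {
    if (!is.function(value) || !is.function(deriv) || !is.function(deriv2))
      stop("custom form needs value, deriv and deriv2 functions")
    if (!is.finite(cutoff)) stop("custom form needs a finite cutoff")
  }
  structure(
    list(form = form, energy_scale = energy_scale, spring_k = spring_k,
         cutoff = cutoff, value = value, deriv = deriv, deriv2 = deriv2),
    class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat("<pair_potential>", x$form)
  if (x$form == "inverse_power_12")
    cat(sprintf("  epsilon = %g, cutoff = %g", x$energy_scale, x$cutoff))
  if (x$form == "harmonic") cat(sprintf("  k = %g", x$spring_k))
  cat("\n")
  invisible(x)
}

#' Pair potential value and derivatives
#'
#' Evaluates \eqn{\varphi(r)}, \eqn{\varphi'(r)} and \eqn{\varphi''(r)} at
#' strictly positive separations. Beyond the cutoff all three are exactly
#' zero (unshifted truncation).
#'
#' @param spec a [pair_potential()].
#' @param r vector of separations, all strictly positive.
#' @return a data.frame with columns `r`, `value`, `deriv`, `deriv2`.
#' @export
pair_value_derivs <- function(spec, r) {
  stopifnot(inherits(spec, "pair_potential"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("separations r must be finite and strictly positive")
  out <- switch(spec$form,
    none = list(v = numeric(length(r)), d1 = numeric(length(r)),
                d2 = numeric(length(r))),
    inverse_power_12 = {
      eps <- spec$energy_scale
      v  <- eps * r^-12
      d1 <- -12 * eps * r^-13
      d2 <- 156 * eps * r^-14
      out <- r > spec$cutoff
      v[out] <- 0; d1[out] <- 0; d2[out] <- 0
      list(v = v, d1 = d1, d2 = d2)
    },
    harmonic = {
      k <- spec$spring_k
      list(v = 0.5 * k * r^2, d1 = k * r, d2 = rep(k, length(r)))
    },
    custom = {
      v <- spec$value(r); d1 <- spec$deriv(r); d2 <- spec$deriv2(r)
      out <- r > spec$cutoff
      v[out] <- 0; d1[out] <- 0; d2[out] <- 0
      list(v = v, d1 = d1, d2 = d2)
    })
  data.frame(r = r, value = out$v, deriv = out$d1, deriv2 = out$d2)
}

#' Periodic box specification
#'
#' @param L box length (> 0); `Inf` for an open (non-periodic) line.
#' @param d spatial dimension; 1 is the supported production path.
#' @return an object of class `box_spec`.
#' @export
box_spec <- function(L, d = 1L) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("box length L must be a single positive number")
  if (!d %in% c(1L, 2L)) stop("dimension d must be 1 (or 2 by design)")
  if (d == 2L) stop("d = 2 is reserved by design but not implemented")
  structure(list(L = L, d = as.integer(d), periodic = is.finite(L)),
            class = "box_spec")
}

#' Minimum-image separation
#'
#' Folds signed separations into \eqn{(-L/2, L/2]}.
#' @param dx signed separations.
#' @param box a [box_spec()].
#' @return folded separations.
#' @export
minimum_image <- function(dx, box) {
  if (!box$periodic) return(dx)
  L <- box$L
  dx <- dx - L * round(dx / L)
  # round() maps exactly -L/2 to -L/2; fold to +L/2 for the half-open side
  dx[dx == -L / 2] <- L / 2
  dx
}

# All pairwise minimum-image signed separations x_i - x_j (i < j) with indices.
pair_separations <- function(positions, box) {
  n <- length(positions)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), dx = numeric()))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  dx <- minimum_image(positions[i] - positions[j], box)
  data.frame(i = i, j = j, dx = dx)
}

#' Total potential energy of a configuration
#'
#' Sums the pair potential over all minimum-image pairs.
#' @param positions numeric vector of particle positions (d = 1).
#' @param spec a [pair_potential()].
#' @param box a [box_spec()].
#' @return scalar energy.
#' @export
total_potential <- function(positions, spec, box) {
  ps <- pair_separations(positions, box)
  if (nrow(ps) == 0L || spec$form == "none") return(0)
  r <- abs(ps$dx)
  if (any(r == 0)) stop("degenerate configuration: coincident particles")
  sum(pair_value_derivs(spec, r)$value)
}

#' Gradient of the total potential
#'
#' Component i is \eqn{\sum_{j \ne i} \varphi'(x_i - x_j)} with minimum-image
#' separations; the self-propelled particles are driven by the velocities
#' \eqn{-\nabla\varphi}.
#'
#' @inheritParams total_potential
#' @return numeric vector, same length as `positions`.
#' @export
total_gradient <- function(positions, spec, box) {
  n <- length(positions)
  g <- numeric(n)
  ps <- pair_separations(positions, box)
  if (nrow(ps) == 0L || spec$form == "none") return(g)
  r <- abs(ps$dx)
  if (any(r == 0)) stop("degenerate configuration: coincident particles")
  d1 <- pair_value_derivs(spec, r)$deriv * sign(ps$dx)
  acc <- rowsum(c(d1, -d1), group = c(ps$i, ps$j))
  g[as.integer(rownames(acc))] <- acc[, 1L]
  g
}

#' Hessian of the total potential
#'
#' For pure pair interactions each pair (i, j) contributes \eqn{+\varphi''}
#' to the (i,i) and (j,j) entries and \eqn{-\varphi''} to (i,j) and (j,i), so
#' every row sums to zero (translation invariance).
#'
#' @inheritParams total_potential
#' @return symmetric N x N matrix.
#' @export
total_hessian <- function(positions, spec, box) {
  n <- length(positions)
  H <- matrix(0, n, n)
  ps <- pair_separations(positions, box)
  if (nrow(ps) == 0L || spec$form == "none") return(H)
  r <- abs(ps$dx)
  if (any(r == 0)) stop("degenerate configuration: coincident particles")
  d2 <- pair_value_derivs(spec, r)$deriv2
  keep <- d2 != 0
  if (any(keep)) {
    i <- ps$i[keep]; j <- ps$j[keep]; d2 <- d2[keep]
    # off-diagonal entries are unique per pair; diagonal accumulates
    H[cbind(i, j)] <- -d2
    H[cbind(j, i)] <- -d2
    acc <- rowsum(c(d2, d2), group = c(i, j))
    dg <- numeric(n)
    dg[as.integer(rownames(acc))] <- acc[, 1L]
    diag(H) <- dg
  }
  H
}

#' Hessian of the periodic harmonic chain
#'
#' N particles on a ring, each coupled to its two nearest neighbours by a
#' spring of constant k: a banded symmetric Toeplitz matrix with diagonal 2k,
#' first off-diagonals (and corner wrap elements) -k. Its eigenvalues are
#' \eqn{2k(1 - \cos(2\pi m / N))}, m = 0, ..., N-1; the zero eigenvalue is the
#' uniform translation mode.
#'
#' @param N number of particles on the ring (>= 3).
#' @param k spring constant (>= 0).
#' @return N x N matrix.
#' @export
harmonic_chain_hessian <- function(N, k) {
  if (N < 3L) stop("harmonic chain needs N >= 3")
  if (k < 0) stop("spring constant k must be non-negative")
  H <- matrix(0, N, N)
  diag(H) <- 2 * k
  for (i in seq_len(N)) {
    j <- i %% N + 1L
    H[i, j] <- H[i, j] - k
    H[j, i] <- H[j, i] - k
  }
  H
}
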