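#' Binned statistic container
#'
#' Holds per-bin means, counts and standard errors on a strictly increasing
#' grid of bin edges; used for the pair distribution function and the
#' distance-conditioned velocity statistics.
#'
#' @param bin_edges strictly increasing numeric vector (length nbins + 1).
#' @param mean per-bin mean.
#' @param count per-bin sample count.
#' @param stderr per-bin standard error (`NA` where `count < 2`).
#' @param x_mean optional per-bin mean abscissa of the contributing samples.
#' @return an object of class `binned_stat`.
#' @export
binned_stat <- function(bin_edges, mean, count, stderr = NULL,
                        x_mean = NULL) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  stopifnot(length(mean) == nb, length(count) == nb)
  if (any(count < 0)) stop("counts must be non-negative")
  if (is.null(stderr)) stderr <- rep(NA_real_, nb)
  stderr[count < 2] <- NA_real_
  structure(list(bin_edges = bin_edges, mean = mean,
                 count = as.numeric(count), stderr = stderr,
                 x_mean = x_mean),
            class = "binned_stat")
}

#' Bin centers of a binned statistic
#' @param b a [binned_stat()].
#' @return numeric vector of bin midpoints.
#' @export
bin_centers <- function(b) {
  e <- b$bin_edges
  (utils::head(e, -1) + utils::tail(e, -1)) / 2
}

#' @export
print.binned_stat <- function(x, ...) {
  cat(sprintf("<binned_stat> %d bins on [%g, %g], %g samples\n",
              length(x$mean), min(x$bin_edges), max(x$bin_edges),
              sum(x$count)))
  invisible(x)
}

#' @export
as.data.frame.binned_stat <- function(x, ...) {
  data.frame(bin_center = bin_centers(x), mean = x$mean, count = x$count,
             stderr = x$stderr)
}

traj_params <- function(traj) {
  cfg <- traj$config
  list(D = cfg$D, tau = cfg$tau, L = cfg$L, N = cfg$N,
       box = box_spec(cfg$L))
}

#' Overall velocity variance of a trajectory
#'
#' Mean squared velocity over all particles, components and sampled
#' configurations, normalized by the free value \eqn{D/\tau}. Also reports
#' the relative standard deviation across per-configuration variances, the
#' quantity used to put error bars on the simulated curves.
#'
#' @param traj a `gcn_trajectory`.
#' @return list with `value` (normalized), `stderr`, `rel_spread`
#'   (sd/mean across configurations), and `per_config` (raw, unnormalized
#'   per-configuration mean squared velocities).
#' @export
overall_velocity_variance <- function(traj) {
  p <- traj_params(traj)
  v <- traj$velocities
  if (is.null(v) || nrow(v) < 2L)
    stop("need at least two sampled configurations")
  per_cfg <- rowMeans(v^2)
  norm <- p$D / p$tau
  list(value = mean(per_cfg) / norm,
       stderr = stats::sd(per_cfg) / sqrt(length(per_cfg)) / norm,
       rel_spread = stats::sd(per_cfg) / mean(per_cfg),
       per_config = per_cfg)
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Distance-conditioned velocity statistics of a two-particle trajectory
#'
#' Bins the sampled pair by the minimum-image separation \eqn{|\Delta x|}
#' (parity symmetry doubles the statistics) and returns the per-bin sample
#' variance of the single-particle velocity (both particles pooled) and the
#' sample covariance of the two velocities.
#'
#' @param traj an N = 2 `gcn_trajectory`.
#' @param bins strictly increasing bin edges for \eqn{|\Delta x|}.
#' @return list of two [binned_stat()]s: `variance` and `correlation`
#'   (absolute units; divide by \eqn{D/\tau} to normalize). Empty bins keep
#'   count 0 and `NA` statistics rather than being dropped.
#' @export
conditional_velocity_stats <- function(traj, bins) {
  p <- traj_params(traj)
  if (p$N != 2L) stop("conditional velocity statistics need an N = 2 run")
  dx <- minimum_image(traj$positions[, 1L] - traj$positions[, 2L], p$box)
  r <- abs(dx)
  v1 <- traj$velocities[, 1L]
  v2 <- traj$velocities[, 2L]
  idx <- bin_index(r, bins)
  nb <- length(bins) - 1L
  var_m <- var_se <- cov_m <- cov_se <- xm <- rep(NA_real_, nb)
  cnt <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- which(idx == b)
    n <- length(sel)
    cnt[b] <- n
    if (n < 2L) next
    xm[b] <- mean(r[sel])
    pooled <- c(v1[sel], v2[sel])
    var_m[b] <- stats::var(pooled)
    # conservative: treat the n sampled pairs (not 2n values) as independent
    var_se[b] <- var_m[b] * sqrt(2 / (n - 1))
    prod <- v1[sel] * v2[sel]
    cov_m[b] <- mean(prod) - mean(v1[sel]) * mean(v2[sel])
    cov_se[b] <- stats::sd(prod) / sqrt(n)
  }
  list(variance = binned_stat(bins, var_m, cnt, var_se, x_mean = xm),
       correlation = binned_stat(bins, cov_m, cnt, cov_se, x_mean = xm))
}

# Counts of minimum-image pair separations <= r_max, accumulated over
# samples via a sorted forward-gap scan (each unordered pair once).
pair_separation_counts <- function(positions, L, edges) {
  r_max <- max(edges)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  N <- ncol(positions)
  for (s in seq_len(nrow(positions))) {
    xs <- sort(positions[s, ])
    for (k in seq_len(N - 1L)) {
      gap <- c(xs[-seq_len(k)], xs[seq_len(k)] + L) - xs
      if (min(gap) > r_max) break
      gap <- gap[gap <= r_max]
      if (length(gap)) {
        i <- bin_index(gap, edges)
        i <- i[!is.na(i)]
        if (length(i)) counts <- counts + tabulate(i, nbins = n_bins)
      }
    }
  }
  counts
}

#' Pair distribution function g(x)
#'
#' Histogram of minimum-image pair separations normalized so that an ideal
#' gas gives g = 1 in every bin. For the repulsive inverse-power fluid g is
#' practically zero below the effective particle diameter \eqn{\sigma
#' \approx 1} and very peaked just above it.
#'
#' @param traj a `gcn_trajectory` with N >= 2.
#' @param bins strictly increasing bin edges; must not exceed L/2.
#' @return a [binned_stat()]; `mean` holds g per bin with a Poisson
#'   standard error.
#' @export
pair_distribution <- function(traj, bins) {
  p <- traj_params(traj)
  if (p$N < 2L) stop("pair distribution needs N >= 2")
  if (max(bins) > p$L / 2 + 1e-12)
    stop("bin range exceeds L/2: separations beyond the minimum image are ",
         "not defined")
  counts <- pair_separation_counts(traj$positions, p$L, bins)
  n_s <- nrow(traj$positions)
  npairs <- p$N * (p$N - 1) / 2
  expected <- n_s * npairs * 2 * diff(bins) / p$L  # ideal-gas count per bin
  g <- counts / expected
  binned_stat(bins, g, counts, stderr = sqrt(pmax(counts, 1)) / expected)
}

#' Effective particle diameter from g(x)
#'
#' Smallest bin center, scanning outward from zero, where g first reaches
#' `threshold_fraction` of its maximum. For the inverse-power fluid this
#' sits near 1 over a wide range of D and tau.
#'
#' @param g a [binned_stat()] holding g(x).
#' @param threshold_fraction fraction of the g maximum (default 0.05).
#' @return the diameter estimate (length units).
#' @export
effective_diameter <- function(g, threshold_fraction = 0.05) {
  gx <- g$mean
  gx[is.na(gx)] <- 0
  if (max(gx) <= 0) stop("undefined diameter: g is identically zero")
  thr <- threshold_fraction * max(gx)
  i <- which(gx >= thr)[1L]
  bin_centers(g)[i]
}

#' Fourier-mode density fluctuations
#'
#' For the box mode \eqn{q = 2\pi m / L} computes
#' \eqn{\rho_q = \sum_j e^{-i q x_j}} per configuration and returns
#' \eqn{(\langle|\rho_q|^2\rangle - |\langle\rho_q\rangle|^2)/N}, a
#' convention in which iid uniform positions (ideal gas) give exactly 1.
#'
#' @param traj a `gcn_trajectory`.
#' @param m positive integer mode index.
#' @return list with `q`, `m`, `value`, `stderr`, `n_samples`.
#' @export
density_mode_fluctuations <- function(traj, m) {
  p <- traj_params(traj)
  if (m < 1 || m != round(m)) stop("mode index m must be a positive integer")
  if (nrow(traj$positions) < 2L) stop("need at least two configurations")
  q <- 2 * pi * m / p$L
  re <- rowSums(cos(q * traj$positions))
  im <- rowSums(-sin(q * traj$positions))
  amp2 <- (re^2 + im^2) / p$N
  val <- mean(amp2) - (mean(re)^2 + mean(im)^2) / p$N
  list(q = q, m = as.integer(m), value = val,
       stderr = stats::sd(amp2) / sqrt(length(amp2)),
       n_samples = length(amp2))
}

#' Box mode index closest to a target wavevector
#'
#' @param q_target target wavevector (e.g. `1/(20*sigma)` for the
#'   long-wavelength fluctuation analysis).
#' @param L box length.
#' @return integer m >= 1 with `2*pi*m/L` closest to `q_target`.
#' @export
nearest_mode_index <- function(q_target, L) {
  max(1L, as.integer(round(q_target * L / (2 * pi))))
}
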