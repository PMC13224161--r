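#' Transition time of a reactive path
#'
#' The duration from the path's first point (the last point in A) to its
#' last point (the first point in B): `(number of steps) * dt`.
#'
#' @param path a `mash_trajectory`.
#' @param basins optional basin pair; if supplied, the path is checked to
#'   be reactive and a non-reactive path is an error.
#' @return Time in a.t.u.
#' @export
transition_time <- function(path, basins = NULL) {
  stopifnot(inherits(path, "mash_trajectory"))
  if (!is.null(basins) && !is_reactive(path, basins))
    stop("path is not reactive (H_AB != 1)")
  (nrow(path$points) - 1L) * path$dt
}

#' Per-chain-element transition times of a TPS ensemble
#'
#' One value per Monte Carlo step, with repetition on rejection as the
#' chain dictates -- the correct MC estimator weighting.
#'
#' @param ensemble a `natps_ensemble`.
#' @param include_burn_in keep the equilibration part of the chain.
#' @return Numeric vector of transition times (a.t.u.).
#' @export
transition_times <- function(ensemble, include_burn_in = FALSE) {
  ch <- ensemble_chain(ensemble, include_burn_in)
  vapply(ensemble$summaries[ch], function(s) s$tau, numeric(1))
}

#' Autocorrelation of a transition-time series
#'
#' \deqn{C(n) = \frac{\sum_{t=0}^{N-n-1}
#'   (\tau(t)-\langle\tau\rangle)(\tau(t+n)-\langle\tau\rangle)}
#'   {(N-n)\,\sigma_\tau^2}}
#' with the population (1/N) mean and variance of the full series, so that
#' `C(0) = 1` exactly.
#'
#' @param tau numeric series of per-MC-step transition times.
#' @param n_max largest lag (must be < `length(tau)`).
#' @return Numeric vector `C(0), ..., C(n_max)`.
#' @export
tt_autocorrelation <- function(tau, n_max) {
  N <- length(tau)
  stopifnot(N > n_max, n_max >= 0)
  mu <- mean(tau)
  v <- mean((tau - mu)^2)
  if (v == 0) {
    warning("zero variance: C(0) = 1, C(n > 0) = 0 by convention")
    return(c(1, rep(0, n_max)))
  }
  d <- tau - mu
  vapply(0:n_max, function(n) {
    sum(d[1:(N - n)] * d[(1 + n):N]) / ((N - n) * v)
  }, numeric(1))
}

#' Decorrelation length of a Markov chain observable
#'
#' The smallest lag at which the autocorrelation falls to `threshold`
#' (default 1/e, a documented convention).  If no crossing occurs within
#' the computed lags, the largest lag is returned with attribute
#' `crossed = FALSE`.
#'
#' @param C autocorrelation values `C(0), ..., C(n_max)` with `C(0) = 1`.
#' @param threshold crossing level.
#' @return Integer lag, with attribute `crossed`.
#' @export
decorrelation_length <- function(C, threshold = exp(-1)) {
  stopifnot(abs(C[1L] - 1) < 1e-12)
  idx <- which(C <= threshold)
  if (!length(idx)) {
    n <- length(C) - 1L
    attr(n, "crossed") <- FALSE
    return(n)
  }
  n <- idx[1L] - 1L
  attr(n, "crossed") <- TRUE
  n
}

#' Coherence angle of a spin vector
#'
#' \eqn{\phi = \mathrm{atan2}(S_y, S_x)} in \eqn{(-\pi, \pi]}; at a hop,
#' where \eqn{S_z = 0}, the pair \eqn{(\phi, q)} summarizes the electronic
#' coherence and nuclear geometry compactly.
#'
#' @param S numeric 3-vector `c(Sx, Sy, Sz)`.
#' @return Angle in radians.
#' @export
coherence_angle <- function(S) {
  stopifnot(length(S) == 3L)
  if (S[1L] == 0 && S[2L] == 0)
    stop("coherence angle undefined at Sx = Sy = 0")
  atan2(S[2L], S[1L])
}

#' Hop statistics of a TPS ensemble
#'
#' Aggregates hop events over all post-burn-in chain elements with chain
#' multiplicity.  "Hops" counts surface changes (non-frustrated events);
#' frustrated reflections are reported separately.
#'
#' @param ensemble a `natps_ensemble`.
#' @param include_burn_in keep the equilibration part of the chain.
#' @return A list of class `natps_hop_stats`: `hops_per_path` (per chain
#'   element), `fraction_ge` (fraction with >= 1, 2, 3, 4 hops),
#'   `positions`, `phi` (chain-weighted, non-frustrated), `mean_position`,
#'   `n_frustrated_per_path`.
#' @export
hop_statistics <- function(ensemble, include_burn_in = FALSE) {
  ch <- ensemble_chain(ensemble, include_burn_in)
  ss <- ensemble$summaries
  nh <- vapply(ss[ch], function(s) s$n_hops, numeric(1))
  nf <- vapply(ss[ch], function(s) s$n_frustrated, numeric(1))
  pos <- unlist(lapply(ch, function(i) {
    h <- ss[[i]]$hops
    h$q[!h$frustrated]
  }), use.names = FALSE)
  phi <- unlist(lapply(ch, function(i) {
    h <- ss[[i]]$hops
    h$phi[!h$frustrated]
  }), use.names = FALSE)
  frac <- vapply(1:4, function(k) mean(nh >= k), numeric(1))
  names(frac) <- paste0(">=", 1:4)
  structure(list(hops_per_path = nh, n_frustrated_per_path = nf,
                 fraction_ge = frac,
                 positions = pos, phi = phi,
                 mean_position = if (length(pos)) mean(pos) else NA_real_),
            class = "natps_hop_stats")
}

#' @export
print.natps_hop_stats <- function(x, ...) {
  cat("Hop statistics (chain-weighted, non-frustrated hops)\n")
  cat(sprintf("  mean hops/path: %.3f; frustrated/path: %.3f\n",
              mean(x$hops_per_path), mean(x$n_frustrated_per_path)))
  cat(sprintf("  fraction with >=2 hops: %.1f%%\n",
              100 * x$fraction_ge[[">=2"]]))
  if (length(x$positions))
    cat(sprintf("  mean hop position: %.4f bohr (%d hop events)\n",
                x$mean_position, length(x$positions)))
  invisible(x)
}

#' Sampling efficiency ratio
#'
#' The average number of integration steps spent to obtain one transition
#' path, `ER = total_steps / n_paths`.  With zero paths the ratio is only
#' bounded from below by the step count; the returned `Inf` then carries
#' the bound in attribute `lower_bound`.
#'
#' @param total_steps total integration steps generated (all shots or all
#'   brute-force trajectories, accepted or not).
#' @param n_paths number of transition paths obtained.
#' @return Numeric ratio (steps per path), possibly `Inf` with attribute
#'   `lower_bound`.
#' @export
efficiency_ratio <- function(total_steps, n_paths) {
  stopifnot(total_steps >= 0, n_paths >= 0)
  if (n_paths == 0) {
    er <- Inf
    attr(er, "lower_bound") <- total_steps
    return(er)
  }
  total_steps / n_paths
}

#' State-resolved path density
#'
#' Chain-weighted, per-state normalized histograms of visited positions
#' over all stored path points.  The two state densities are normalized
#' jointly, so the total occupancy integrates to one.
#'
#' @param ensemble a `natps_ensemble` (paths must have been stored).
#' @param q_grid histogram break points (bohr).
#' @param include_burn_in keep the equilibration part of the chain.
#' @return A data.frame with columns `q` (bin midpoints), `lower`, `upper`
#'   (densities per bohr).
#' @export
path_density <- function(ensemble, q_grid = seq(-2.5, 2.5, length.out = 101),
                         include_burn_in = FALSE) {
  ch <- ensemble_chain(ensemble, include_burn_in)
  if (any(vapply(ensemble$paths[unique(ch)], is.null, logical(1))))
    stop("path points were not stored (store_paths = FALSE)")
  lower_counts <- numeric(length(q_grid) - 1L)
  upper_counts <- numeric(length(q_grid) - 1L)
  for (i in ch) {
    pts <- ensemble$paths[[i]]$points
    lo <- pts[, "active"] < 0
    if (any(lo))
      lower_counts <- lower_counts +
        hist(pts[lo, "q"], breaks = q_grid, plot = FALSE)$counts
    if (any(!lo))
      upper_counts <- upper_counts +
        hist(pts[!lo, "q"], breaks = q_grid, plot = FALSE)$counts
  }
  dq <- diff(q_grid)
  tot <- sum(lower_counts) + sum(upper_counts)
  data.frame(q = (q_grid[-1L] + q_grid[-length(q_grid)]) / 2,
             lower = lower_counts / (tot * dq),
             upper = upper_counts / (tot * dq))
}

#' Two-sample comparison of transition-time distributions
#'
#' Standard two-sample Kolmogorov--Smirnov test, used e.g. to compare the
#' TPS transition-time distribution with brute-force harvesting at the
#' same temperature.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @return A list with `statistic` and `p.value`.
#' @export
compare_transition_times <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
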