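#' Thermal specification
#'
#' @param temperature absolute temperature in kelvin, > 0.
#' @return A list of class `thermal_spec` with `temperature` and
#'   `beta = 1/(kB T)` in 1/Hartree.
#' @export
thermal_spec <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  structure(list(temperature = temperature,
                 beta = 1 / (kB_hartree * temperature)),
            class = "thermal_spec")
}

#' Sample the stationary MASH Boltzmann distribution
#'
#' Draws points from the canonical density of the extended phase space,
#' \deqn{\rho(q,p,\vec S) \propto
#'   e^{-\beta\left(p^2/2m + \bar V(q) + V_z(q)\,\mathrm{sign}(S_z)\right)}
#'   \,\delta(|\vec S| - 1),}
#' which is stationary under the MASH dynamics.  Momenta are
#' Maxwell--Boltzmann with variance \eqn{m k_B T}; the pair (q, hemisphere)
#' is drawn by tabulated inverse-CDF on a dense grid; the spin is uniform on
#' the selected hemisphere (uniform in `Sz` over the hemisphere and uniform
#' in azimuth -- the marginal of the stationary density).
#'
#' @param model a [two_state_model()].
#' @param thermal a [thermal_spec()].
#' @param n number of draws.
#' @param n_grid grid points of the inverse-CDF table (>= 2^14 by default).
#' @return A data.frame with columns `q`, `p`, `Sx`, `Sy`, `Sz`, `sign`
#'   (one row per draw).  Use [phase_point()] on a row to propagate it.
#' @export
sample_boltzmann <- function(model, thermal, n, n_grid = 2^14) {
  stopifnot(n >= 1, n_grid >= 1024)
  beta <- thermal$beta
  kT <- 1 / beta
  # q range covering all weight within Vbar +/- 12 kT of the lower minima
  qmax <- model$x0 * (1 + sqrt((12 * kT + 2 * model$Vc) / model$epsilon))
  grid <- seq(-qmax, qmax, length.out = n_grid)
  a <- adiabatize(model, grid)
  e0 <- min(a$lower)
  wl <- exp(-beta * (a$lower - e0))
  wu <- exp(-beta * (a$upper - e0))
  dq <- grid[2L] - grid[1L]
  trap <- function(w) sum((w[-1L] + w[-length(w)]) / 2) * dq
  Zl <- trap(wl); Zu <- trap(wu)
  # normalization check: grid must resolve the density
  half <- seq(1L, n_grid, by = 2L)
  Zl2 <- sum((wl[half][-1L] + wl[half][-length(half)]) / 2) * 2 * dq
  if (abs(Zl2 / Zl - 1) > 1e-8)
    stop("inverse-CDF grid under-resolved: increase n_grid")

  upper <- runif(n) < Zu / (Zl + Zu)
  icdf <- function(w, m) {
    cw <- cumsum((w[-1L] + w[-length(w)]) / 2) * dq
    cw <- c(0, cw) / cw[length(cw)]
    approx(cw, grid, xout = runif(m), ties = "ordered")$y
  }
  q <- numeric(n)
  if (any(upper)) q[upper] <- icdf(wu, sum(upper))
  if (any(!upper)) q[!upper] <- icdf(wl, sum(!upper))

  p <- rnorm(n, 0, sqrt(model$mass * kT))
  sz <- ifelse(upper, runif(n), -runif(n))
  az <- runif(n, -pi, pi)
  sperp <- sqrt(pmax(0, 1 - sz^2))
  data.frame(q = q, p = p, Sx = sperp * cos(az), Sy = sperp * sin(az),
             Sz = sz, sign = ifelse(upper, 1, -1))
}

# phase point from a sample row
sample_point <- function(draws, i) {
  phase_point(q = draws$q[i], p = draws$p[i],
              S = c(draws$Sx[i], draws$Sy[i], draws$Sz[i]))
}

#' Harvest reactive segments from an unbiased trajectory
#'
#' Extracts all maximal segments whose first stored point lies in one basin,
#' whose last lies in the other, and whose interior touches neither basin.
#' By default only A-to-B segments are returned (the reactive-path
#' constraint is defined with an A start and a B end); with
#' `direction = "both"`, B-to-A occurrences are also returned, stored
#' time-reversed so every segment reads A-to-B, and flagged with a
#' `reversed` attribute.
#'
#' @param traj a `mash_trajectory`.
#' @param basins a basin pair as from [default_basins()].
#' @param direction `"AB"` or `"both"`.
#' @return A list of `mash_trajectory` segments.
#' @export
harvest_transitions <- function(traj, basins = default_basins(),
                                direction = c("AB", "both")) {
  direction <- match.arg(direction)
  pts <- traj$points
  lab <- basin_label_rows(pts[, "q"], pts[, "active"], basins)
  idx <- which(!is.na(lab))
  segs <- list()
  if (length(idx) < 2L) return(segs)
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    if (lab[i] == lab[j]) next
    keep <- lab[i] == "A" || direction == "both"
    if (!keep) next
    sub <- pts[i:j, , drop = FALSE]
    hops <- traj$hops[traj$hops$t > sub[1L, "t"] &
                      traj$hops$t < sub[nrow(sub), "t"], , drop = FALSE]
    seg <- new_trajectory(sub, hops, traj$dt, status = "reactive")
    if (lab[i] == "B") {
      seg <- reverse_trajectory(seg)
      attr(seg, "reversed") <- TRUE
    }
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

# time-reverse a stored trajectory so it reads in the opposite direction
reverse_trajectory <- function(traj) {
  pts <- traj$points
  tend <- pts[nrow(pts), "t"]
  pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts[, "t"] <- tend - pts[, "t"]
  pts[, "p"] <- -pts[, "p"]
  pts[, "Sy"] <- -pts[, "Sy"]
  hops <- traj$hops
  if (nrow(hops)) {
    hops$t <- tend - hops$t
    hops$Sy <- -hops$Sy
    hops$phi <- atan2(hops$Sy, hops$Sx)
    flip <- !hops$frustrated
    hops$direction[flip] <- ifelse(hops$direction[flip] == "up",
                                   "down", "up")
    hops <- hops[rev(seq_len(nrow(hops))), , drop = FALSE]
    rownames(hops) <- NULL
  }
  new_trajectory(pts, hops, traj$dt, status = traj$status)
}

#' Brute-force reactive-path harvesting from equilibrium dynamics
#'
#' Repeatedly draws initial conditions from the stationary Boltzmann
#' distribution, propagates energy-conserving MASH trajectories of fixed
#' length, and harvests reactive segments.  Step accounting is exact: every
#' integrator step of every trajectory is counted, whether or not it
#' contributes a transition.
#'
#' @param model a [two_state_model()].
#' @param thermal a [thermal_spec()].
#' @param basins a basin pair.
#' @param total_steps_budget maximum total number of integration steps.
#' @param trajectory_length steps per independent trajectory (default 1e5).
#' @param control a [mash_control()].
#' @param target_transitions stop early once this many segments have been
#'   harvested (default `Inf`: spend the whole budget).
#' @param direction passed to [harvest_transitions()].
#' @return A list with `segments` (list of reactive `mash_trajectory`),
#'   `steps_used`, and `n_trajectories`.  Zero transitions within the
#'   budget yields an empty segment list (the step count then only bounds
#'   the efficiency ratio from below).
#' @export
brute_force_run <- function(model, thermal, basins = default_basins(),
                            total_steps_budget, trajectory_length = 1e5,
                            control = mash_control(),
                            target_transitions = Inf,
                            direction = "AB") {
  stopifnot(total_steps_budget > 0, trajectory_length >= 1)
  segs <- list()
  steps <- 0
  ntraj <- 0L
  while (steps < total_steps_budget && length(segs) < target_transitions) {
    nst <- min(trajectory_length, total_steps_budget - steps)
    draw <- sample_boltzmann(model, thermal, 1L)
    gamma <- sample_point(draw, 1L)
    traj <- mash_trajectory(gamma, nst, model, control)
    steps <- steps + nst
    ntraj <- ntraj + 1L
    segs <- c(segs, harvest_transitions(traj, basins,
                                        direction = direction))
  }
  list(segments = segs, steps_used = steps, n_trajectories = ntraj)
}
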