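#' Integrator control parameters
#'
#' Numerical knobs of the time-reversible MASH integrator.
#'
#' @param dt nuclear time step (a.t.u.).  The default 5 a.t.u. keeps the
#'   in-step hop root search robust for the coupled-harmonic model.
#' @param n_sub electronic Magnus substeps per nuclear step.  The default 32
#'   keeps the per-step amplitude error of the electronic propagator below
#'   1e-10 at thermal velocities of the default model.
#' @param root_tol time tolerance of the bisection bracket on the hop time
#'   (a.t.u.).  The tight default makes forward and backward hop times agree
#'   to well below the 1e-8 round-trip reversibility scale.
#' @param hop_mode `"root"` for the piecewise-continuous in-step hop search
#'   (the method proper); `"endpoint"` for naive end-of-step hop detection,
#'   retained only as a reference variant that demonstrably breaks time
#'   reversibility.
#' @param max_steps cap on one-sided propagation length for
#'   [propagate_until_basin()] (default 4000 steps = 20000 a.t.u. at dt 5).
#' @return A list of class `mash_control`.
#' @export
mash_control <- function(dt = 5, n_sub = 32L, root_tol = 1e-10,
                         hop_mode = c("root", "endpoint"),
                         max_steps = 4000L) {
  hop_mode <- match.arg(hop_mode)
  stopifnot(dt > 0, n_sub >= 1, root_tol > 0, max_steps >= 1)
  structure(list(dt = dt, n_sub = as.integer(n_sub), root_tol = root_tol,
                 hop_mode = hop_mode, max_steps = as.integer(max_steps)),
            class = "mash_control")
}

hop_mode_int <- function(ctrl) if (ctrl$hop_mode == "root") 1L else 0L

state_of_point <- function(gamma) {
  c(gamma$q, gamma$p, Re(gamma$c[1L]), Im(gamma$c[1L]),
    Re(gamma$c[2L]), Im(gamma$c[2L]))
}

point_of_state <- function(state, t = 0) {
  phase_point(q = state[1L], p = state[2L],
              c = complex(real = state[c(3L, 5L)],
                          imaginary = state[c(4L, 6L)]),
              t = t)
}

#' Total MASH energy of a phase point
#'
#' \eqn{E = p^2/2m + \bar V(q) + V_z(q)\,\mathrm{sign}(S_z)}, with the
#' deterministic tie-break \eqn{S_z = 0 \to} lower surface.  The energy
#' difference between the two hemispheres at fixed `(q, p)` is \eqn{2V_z(q)}.
#'
#' @param gamma a [phase_point()].
#' @param model a [two_state_model()].
#' @return Energy in Hartree.
#' @export
total_energy <- function(gamma, model) {
  a <- adiabatize(model, gamma$q)
  gamma$p^2 / (2 * model$mass) + a$Vbar + active_sign(gamma) * a$Vz
}

hops_frame <- function(hm) {
  if (is.null(hm) || nrow(hm) == 0L)
    return(data.frame(t = numeric(), q = numeric(), Sx = numeric(),
                      Sy = numeric(), phi = numeric(),
                      direction = character(), frustrated = logical()))
  data.frame(t = hm[, 1L], q = hm[, 2L], Sx = hm[, 3L], Sy = hm[, 4L],
             phi = atan2(hm[, 4L], hm[, 3L]),
             direction = ifelse(hm[, 5L] > 0, "up", "down"),
             frustrated = hm[, 6L] > 0)
}

new_trajectory <- function(points, hops, dt, status = "done",
                           state = NULL) {
  colnames(points) <- c("t", "q", "p", "Sx", "Sy", "Sz", "active")
  structure(list(points = points, hops = hops, dt = dt, status = status,
                 state = state),
            class = "mash_trajectory")
}

#' @export
print.mash_trajectory <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("MASH trajectory: %d points, dt = %g a.t.u., span %g a.t.u.\n",
              n, x$dt, x$points[n, "t"] - x$points[1L, "t"]))
  nh <- nrow(x$hops)
  cat(sprintf("  hops: %d (%d frustrated); status: %s\n",
              nh, sum(x$hops$frustrated), x$status))
  invisible(x)
}

#' @export
plot.mash_trajectory <- function(x, ...) {
  pts <- x$points
  cols <- ifelse(pts[, "active"] > 0, "darkorange", "steelblue")
  plot(pts[, "t"], pts[, "q"], type = "n", xlab = "t (a.t.u.)",
       ylab = "q (bohr)", ...)
  segs <- seq_len(nrow(pts) - 1L)
  graphics::segments(pts[segs, "t"], pts[segs, "q"],
                     pts[segs + 1L, "t"], pts[segs + 1L, "q"],
                     col = cols[segs])
  if (nrow(x$hops)) abline(v = x$hops$t, col = "grey70", lty = 3)
  invisible(x)
}

#' One step of the time-reversible MASH integrator
#'
#' Advances the coupled nuclear-electronic state by one velocity-Verlet step
#' on the active adiabatic surface with concurrent unitary electronic
#' propagation.  If `sign(Sz)` flips within the step, the crossing time is
#' located by an iterative root search; the system is propagated to the
#' crossing, the hop is attempted there (momentum rescaling along the
#' coupling direction, or reflection if the upward hop is frustrated), and
#' the remainder of the step is completed on the resulting surface.  At most
#' one hop per step is permitted; a second sign change aborts with advice to
#' reduce `dt`.
#'
#' @param gamma a [phase_point()].
#' @param model a [two_state_model()].
#' @param control a [mash_control()]; `dt` overrides its time step if given.
#' @param dt optional time step (a.t.u.).
#' @return A list with elements `point` (the advanced [phase_point()]) and
#'   `hop` (a one-row data.frame as in trajectory `$hops`, or `NULL`).
#' @export
mash_step <- function(gamma, model, control = mash_control(), dt = NULL) {
  stopifnot(inherits(gamma, "phase_point"))
  if (is.null(dt)) dt <- control$dt
  r <- cpp_mash_step(state_of_point(gamma), dt, model_pars(model),
                     control$n_sub, control$root_tol, hop_mode_int(control))
  if (r$status == 1L)
    stop("more than 8 S_z sign changes within one step: reduce the time step dt")
  if (r$status == 2L) stop("hop root search failed to converge")
  hop <- NULL
  if (!is.null(r$hop)) {
    hm <- r$hop
    hm[, 1L] <- hm[, 1L] + gamma$t
    hop <- hops_frame(hm)
  }
  list(point = point_of_state(r$state, t = gamma$t + dt), hop = hop)
}

#' Attempt a surface hop at a spin-equator crossing
#'
#' Applies the energy-conserving momentum update at a point with
#' \eqn{S_z = 0} (within `tol`).  A downward hop (upper to lower) is always
#' allowed and rescales the momentum along the coupling direction (in 1D,
#' the full momentum) so that total energy is conserved:
#' \eqn{p'^2 = p^2 + 4 m V_z(q^*)}.  An upward hop is allowed iff the
#' kinetic energy along the coupling direction is at least \eqn{2V_z(q^*)},
#' giving \eqn{p'^2 = p^2 - 4 m V_z(q^*)} with the sign of `p` preserved;
#' otherwise the hop is frustrated: the momentum is reversed and the active
#' surface is unchanged.
#'
#' @param gamma a [phase_point()] with `|Sz|` below `tol`.
#' @param direction `"up"` or `"down"`.
#' @param model a [two_state_model()].
#' @param tol tolerance on `|Sz|` at the crossing.
#' @return The post-hop [phase_point()], with attribute `frustrated`.
#' @export
attempt_hop <- function(gamma, direction = c("up", "down"), model,
                        tol = 1e-6) {
  direction <- match.arg(direction)
  sz <- coeffs_to_spin(gamma$c)[3L]
  if (abs(sz) > tol)
    stop("attempt_hop called away from the S_z = 0 crossing (|Sz| = ",
         format(abs(sz)), ")")
  Vzq <- adiabatize(model, gamma$q)$Vz
  p <- gamma$p
  frustrated <- FALSE
  if (direction == "down") {
    p <- sign_pref(p) * sqrt(p^2 + 4 * model$mass * Vzq)
  } else if (p^2 / (2 * model$mass) >= 2 * Vzq) {
    p <- sign_pref(p) * sqrt(p^2 - 4 * model$mass * Vzq)
  } else {
    p <- -p
    frustrated <- TRUE
  }
  out <- phase_point(q = gamma$q, p = p, c = gamma$c, t = gamma$t)
  attr(out, "frustrated") <- frustrated
  out
}

sign_pref <- function(p) if (p >= 0) 1 else -1

#' Propagate a MASH trajectory for a fixed number of steps
#'
#' @param gamma initial [phase_point()].
#' @param n_steps number of nuclear steps.
#' @param model a [two_state_model()].
#' @param control a [mash_control()].
#' @return A `mash_trajectory` with `n_steps + 1` grid points and all hop
#'   events.
#' @export
mash_trajectory <- function(gamma, n_steps, model,
                            control = mash_control()) {
  stopifnot(inherits(gamma, "phase_point"), n_steps >= 1)
  ba <- basin_args(default_basins())  # unused in mode 0 but required args
  r <- cpp_propagate(state_of_point(gamma), gamma$t, control$dt,
                     as.integer(n_steps), model_pars(model), control$n_sub,
                     control$root_tol, hop_mode_int(control), 0L,
                     ba$boundA, ba$sideA, ba$boundB, ba$sideB, ba$req_sign)
  new_trajectory(r$points, hops_frame(r$hops), control$dt,
                 status = r$status, state = r$state)
}

#' Propagate until a basin is reached
#'
#' Forward mode propagates with [mash_step()] until the point enters basin A
#' or B, or `max_steps` is exhausted (`status = "uncommitted"`).  Backward
#' mode applies [time_reverse()], propagates forward, then time-reverses
#' every stored point and reverses the order, so the returned segment always
#' reads in physical time order (times are relative to the segment start).
#' A start already inside a basin returns a single-point segment with that
#' basin as status.
#'
#' @param gamma starting [phase_point()].
#' @param basins a basin pair as from [default_basins()].
#' @param direction `"forward"` or `"backward"`.
#' @param model a [two_state_model()].
#' @param control a [mash_control()] (supplies `dt` and `max_steps`).
#' @return A `mash_trajectory` whose `status` is `"A"`, `"B"` or
#'   `"uncommitted"`, with a `steps` attribute counting integration steps.
#' @export
propagate_until_basin <- function(gamma, basins = default_basins(),
                                  direction = c("forward", "backward"),
                                  model, control = mash_control()) {
  direction <- match.arg(direction)
  start <- if (direction == "backward") time_reverse(gamma) else gamma
  ba <- basin_args(basins)
  r <- cpp_propagate(state_of_point(start), 0, control$dt,
                     control$max_steps, model_pars(model), control$n_sub,
                     control$root_tol, hop_mode_int(control), 1L,
                     ba$boundA, ba$sideA, ba$boundB, ba$sideB, ba$req_sign)
  status <- if (r$status == "maxsteps") "uncommitted" else r$status
  pts <- r$points
  hops <- hops_frame(r$hops)
  if (direction == "backward" && nrow(pts) > 1L) {
    tend <- pts[nrow(pts), 1L]
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    pts[, 1L] <- tend - pts[, 1L]      # physical time order
    pts[, 3L] <- -pts[, 3L]            # p is odd
    pts[, 5L] <- -pts[, 5L]            # Sy is odd
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
  }
  traj <- new_trajectory(pts, hops, control$dt, status = status,
                         state = r$state)
  attr(traj, "steps") <- r$steps
  traj
}

# phase point at a stored trajectory row (global phase convention applied;
# the dynamics depends only on the spin, so this is exact for re-shooting)
trajectory_point <- function(traj, i) {
  row <- traj$points[i, ]
  phase_point(q = row[["q"]], p = row[["p"]],
              S = c(row[["Sx"]], row[["Sy"]], row[["Sz"]]), t = row[["t"]])
}

# energies along a stored trajectory
trajectory_energy <- function(traj, model) {
  pts <- traj$points
  a <- adiabatize(model, pts[, "q"])
  pts[, "p"]^2 / (2 * model$mass) + a$Vbar + pts[, "active"] * a$Vz
}
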