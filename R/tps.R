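#' Configuration of a transition path sampling run
#'
#' @param temperature kelvin; sets the Maxwell--Boltzmann distribution used
#'   by the shooting-move velocity perturbation.
#' @param alpha Uhlenbeck--Ornstein mixing parameter in (0, 1); the default
#'   0.9 perturbs the velocity smoothly while still decorrelating the path
#'   ensemble quickly.
#' @param n_paths number of shooting moves (Monte Carlo chain length).
#' @param burn_in_fraction fraction of the chain discarded as equilibration
#'   by the analysis functions (default 0.15).
#' @param dt,n_sub,root_tol,max_steps_per_side integrator knobs, see
#'   [mash_control()].
#' @param reverse_policy what to do with candidates whose backward side
#'   lands in B and forward side in A: `"reverse-accept"` (default) stores
#'   them time-reversed so they read A-to-B, exploiting microscopic
#'   reversibility; `"strict-reject"` discards them.
#' @param store_paths keep full point matrices of accepted paths (default
#'   `TRUE`; summaries and hop events are always kept).
#' @return A list of class `tps_config`.
#' @export
tps_config <- function(temperature, alpha = 0.9, n_paths = 1000L,
                       burn_in_fraction = 0.15, dt = 5, n_sub = 32L,
                       root_tol = 1e-10, max_steps_per_side = 4000L,
                       reverse_policy = c("reverse-accept", "strict-reject"),
                       store_paths = TRUE) {
  reverse_policy <- match.arg(reverse_policy)
  stopifnot(alpha > 0, alpha < 1, n_paths >= 1,
            burn_in_fraction >= 0, burn_in_fraction < 1)
  structure(list(temperature = temperature, alpha = alpha,
                 n_paths = as.integer(n_paths),
                 burn_in_fraction = burn_in_fraction,
                 dt = dt, n_sub = as.integer(n_sub), root_tol = root_tol,
                 max_steps_per_side = as.integer(max_steps_per_side),
                 reverse_policy = reverse_policy,
                 store_paths = isTRUE(store_paths)),
            class = "tps_config")
}

control_of <- function(config) {
  mash_control(dt = config$dt, n_sub = config$n_sub,
               root_tol = config$root_tol,
               max_steps = config$max_steps_per_side)
}

#' Uhlenbeck--Ornstein velocity perturbation
#'
#' \eqn{v' = \alpha v + \sqrt{1-\alpha^2}\,\Delta v} with \eqn{\Delta v} a
#' fresh Maxwell--Boltzmann draw at the given temperature.  The move leaves
#' the Maxwell--Boltzmann distribution invariant and satisfies detailed
#' balance, which is what makes the two-sided shooting move a valid path
#' sampling proposal.
#'
#' @param v current velocity (bohr/a.t.u.), any length.
#' @param thermal a [thermal_spec()].
#' @param alpha mixing parameter in \[0, 1\].
#' @param mass nuclear mass (electron masses).
#' @return Perturbed velocity of the same length.
#' @export
perturb_velocity <- function(v, thermal, alpha, mass) {
  stopifnot(alpha >= 0, alpha <= 1)
  dv <- rnorm(length(v), 0, sqrt(1 / (thermal$beta * mass)))
  alpha * v + sqrt(1 - alpha^2) * dv
}

# is a stored path reactive (A start, B end, clean interior)?
is_reactive <- function(traj, basins) {
  pts <- traj$points
  lab <- basin_label_rows(pts[, "q"], pts[, "active"], basins)
  n <- length(lab)
  !is.na(lab[1L]) && !is.na(lab[n]) && lab[1L] == "A" && lab[n] == "B" &&
    (n <= 2L || all(is.na(lab[2:(n - 1L)])))
}

# join a backward segment (physical order, ends at gamma) with a forward
# segment (starts at gamma); returns a trajectory starting at t = 0
join_segments <- function(back, fwd, dt) {
  bp <- back$points
  fp <- fwd$points
  tb <- bp[nrow(bp), "t"] - bp[1L, "t"]
  bp[, "t"] <- bp[, "t"] - bp[1L, "t"]
  fp[, "t"] <- fp[, "t"] - fp[1L, "t"] + tb
  pts <- rbind(bp, fp[-1L, , drop = FALSE])
  hb <- back$hops; hf <- fwd$hops
  if (nrow(hb)) hb$t <- hb$t - back$points[1L, "t"]
  if (nrow(hf)) hf$t <- hf$t - fwd$points[1L, "t"] + tb
  hops <- rbind(hb, hf)
  rownames(hops) <- NULL
  new_trajectory(pts, hops, dt, status = "reactive")
}

#' Generate an initial reactive path
#'
#' Propagates the start point forward and backward in time until both ends
#' commit to (different) basins and trims to the reactive segment.  The
#' default start -- `q = 1` bohr, velocity `-0.0087` bohr/a.t.u. (a kinetic
#' temperature of ~44,000 K) and the spin at the south pole -- reliably
#' connects the basins for the default model; if a start fails to connect,
#' fresh thermal velocities are drawn and the shot is retried.
#'
#' @param model a [two_state_model()].
#' @param basins a basin pair.
#' @param config a [tps_config()].
#' @param start_point optional [phase_point()] to start from.
#' @param max_retries retries with fresh thermal velocities.
#' @return A reactive `mash_trajectory` (reads A-to-B, time starts at 0).
#' @export
make_initial_path <- function(model, basins = default_basins(), config,
                              start_point = NULL, max_retries = 50L) {
  ctrl <- control_of(config)
  thermal <- thermal_spec(config$temperature)
  if (is.null(start_point))
    start_point <- phase_point(q = 1.0, p = model$mass * (-0.0087),
                               S = c(0, 0, -1))
  gamma <- start_point
  for (try in seq_len(max_retries + 1L)) {
    # a fixed two-sided window through the start point (the start may lie
    # inside a basin, so commitment-stopping propagation is not usable here)
    fwd <- mash_trajectory(gamma, ctrl$max_steps, model, ctrl)
    bwd0 <- mash_trajectory(time_reverse(gamma), ctrl$max_steps, model, ctrl)
    bwd <- reverse_trajectory(bwd0)
    full <- join_segments(bwd, fwd, ctrl$dt)
    segs <- harvest_transitions(full, basins, direction = "both")
    if (length(segs)) {
      path <- segs[[1L]]
      path$status <- "reactive"
      if (!is_reactive(path, basins))
        stop("internal error: assembled initial path is not reactive")
      return(path)
    }
    v <- perturb_velocity(gamma$p / model$mass, thermal, 0, model$mass)
    gamma <- phase_point(q = start_point$q, p = model$mass * v,
                         c = start_point$c)
  }
  stop("no reactive initial path found in ", max_retries, " retries; ",
       "try a start point nearer the crossing or a higher temperature")
}

#' One shooting move
#'
#' Picks a shooting index uniformly along the current path, perturbs the
#' velocity there ([perturb_velocity()]) while retaining position and
#' electronic state, propagates forward and backward until basin
#' commitment, and applies the flexible-path-length Metropolis rule: the
#' candidate is accepted iff its ends connect A to B (in that order, after
#' the optional reversal) and a uniform draw falls below
#' `min(1, L_old/L_new)`.  Steps generated by both sides are counted
#' whether or not the candidate is accepted.
#'
#' @param current_path a reactive `mash_trajectory`.
#' @param basins a basin pair.
#' @param config a [tps_config()].
#' @param model a [two_state_model()].
#' @return A list with `path` (new or retained), `accepted`,
#'   `steps_generated`, and `candidate_status` (one of `"accepted"`,
#'   `"not_reactive"`, `"uncommitted"`, `"length_rejected"`,
#'   `"reversed_rejected"`).
#' @export
shoot <- function(current_path, basins = default_basins(), config, model) {
  ctrl <- control_of(config)
  thermal <- thermal_spec(config$temperature)
  n <- nrow(current_path$points)
  idx <- sample.int(n, 1L)
  gamma <- trajectory_point(current_path, idx)
  vnew <- perturb_velocity(gamma$p / model$mass, thermal, config$alpha,
                           model$mass)
  gamma <- phase_point(q = gamma$q, p = model$mass * vnew, c = gamma$c)

  fwd <- propagate_until_basin(gamma, basins, "forward", model, ctrl)
  bwd <- propagate_until_basin(gamma, basins, "backward", model, ctrl)
  steps <- attr(fwd, "steps") + attr(bwd, "steps")
  reject <- function(status)
    list(path = current_path, accepted = FALSE, steps_generated = steps,
         candidate_status = status)

  if (fwd$status == "uncommitted" || bwd$status == "uncommitted")
    return(reject("uncommitted"))
  if (fwd$status == bwd$status) return(reject("not_reactive"))

  cand <- join_segments(bwd, fwd, ctrl$dt)
  if (bwd$status == "B") {
    if (config$reverse_policy == "strict-reject")
      return(reject("reversed_rejected"))
    cand <- reverse_trajectory(cand)
  }
  L_old <- nrow(current_path$points) - 1L
  L_new <- nrow(cand$points) - 1L
  if (runif(1L) >= min(1, L_old / L_new))
    return(reject("length_rejected"))
  list(path = cand, accepted = TRUE, steps_generated = steps,
       candidate_status = "accepted")
}

# per-path summaries cached in the ensemble
path_summary <- function(path) {
  h <- path$hops
  list(tau = (nrow(path$points) - 1L) * path$dt,
       L = nrow(path$points) - 1L,
       n_hops = sum(!h$frustrated),
       n_frustrated = sum(h$frustrated),
       hops = h)
}

#' Run transition path sampling
#'
#' Runs `config$n_paths` shooting moves from a reactive seed path.  On
#' rejection the previous trajectory is retained in the chain, so chain
#' averages are correct Monte Carlo estimators.  The first
#' `burn_in_fraction` of the chain is marked as equilibration and excluded
#' from analysis by default.
#'
#' @param initial_path a reactive `mash_trajectory`, e.g. from
#'   [make_initial_path()].
#' @param basins a basin pair.
#' @param config a [tps_config()].
#' @param model a [two_state_model()].
#' @param progress print a progress line every `progress` shots (0 = quiet).
#' @return An object of class `natps_ensemble`: accepted paths, the chain
#'   (with repetition on rejection), per-shot records, exact step
#'   accounting and the run configuration.
#' @export
run_tps <- function(initial_path, basins = default_basins(), config, model,
                    progress = 0L) {
  if (!is_reactive(initial_path, basins))
    stop("the seed path is not reactive (H_AB != 1)")
  n <- config$n_paths
  paths <- vector("list", n + 1L)
  summaries <- vector("list", n + 1L)
  paths[[1L]] <- if (config$store_paths) initial_path else NULL
  summaries[[1L]] <- path_summary(initial_path)
  chain <- integer(n)
  rec <- data.frame(shot = seq_len(n), accepted = FALSE,
                    steps = 0, status = character(n),
                    stringsAsFactors = FALSE)
  cur <- initial_path
  cur_idx <- 1L
  n_stored <- 1L
  total_steps <- 0
  for (k in seq_len(n)) {
    s <- shoot(cur, basins, config, model)
    total_steps <- total_steps + s$steps_generated
    rec$accepted[k] <- s$accepted
    rec$steps[k] <- s$steps_generated
    rec$status[k] <- s$candidate_status
    if (s$accepted) {
      cur <- s$path
      n_stored <- n_stored + 1L
      cur_idx <- n_stored
      paths[[cur_idx]] <- if (config$store_paths) cur else NULL
      summaries[[cur_idx]] <- path_summary(cur)
    }
    chain[k] <- cur_idx
    if (progress > 0 && k %% progress == 0L)
      message(sprintf("shot %d/%d: acc %.2f, steps %g", k, n,
                      mean(rec$accepted[1:k]), total_steps))
  }
  structure(list(paths = paths[seq_len(n_stored)],
                 summaries = summaries[seq_len(n_stored)],
                 chain = chain,
                 records = rec,
                 burn_in = as.integer(ceiling(config$burn_in_fraction * n)),
                 total_steps = total_steps,
                 config = config, model = model, basins = basins),
            class = "natps_ensemble")
}

#' Post-burn-in chain view of an ensemble
#'
#' @param ensemble a `natps_ensemble`.
#' @param include_burn_in keep the equilibration part of the chain.
#' @return Integer vector of path indices, one per retained MC step.
#' @export
ensemble_chain <- function(ensemble, include_burn_in = FALSE) {
  ch <- ensemble$chain
  if (!include_burn_in && ensemble$burn_in > 0L)
    ch <- ch[-seq_len(min(ensemble$burn_in, length(ch)))]
  ch
}

#' Path-space temperature annealing
#'
#' Runs a ladder of TPS simulations at strictly descending temperatures;
#' each simulation is seeded with the final accepted path of the previous
#' (warmer) one, re-trimmed if it is no longer reactive.  Per-temperature
#' chain lengths are scaled so that the statistical error of the mean
#' transition time, \eqn{\sigma_\tau/\sqrt{N}}, stays approximately
#' constant, using a short pilot chain to estimate \eqn{\sigma_\tau}.
#'
#' @param temperatures strictly descending temperatures (kelvin).
#' @param config a [tps_config()]; its `n_paths` is the chain length at the
#'   first (hottest) temperature.
#' @param model a [two_state_model()].
#' @param basins a basin pair.
#' @param pilot_n pilot chain length for the sigma_tau estimate.
#' @param n_min,n_max bounds on the per-temperature chain length.
#' @return A named list of `natps_ensemble`, one per temperature.
#' @export
anneal <- function(temperatures, config, model, basins = default_basins(),
                   pilot_n = 200L, n_min = 200L, n_max = NULL) {
  stopifnot(length(temperatures) >= 1,
            all(diff(temperatures) < 0) || length(temperatures) == 1L)
  if (is.null(n_max)) n_max <- 4L * config$n_paths
  out <- vector("list", length(temperatures))
  names(out) <- paste0("T", temperatures)
  seed_path <- NULL
  sigma_ref <- NULL
  for (i in seq_along(temperatures)) {
    Ti <- temperatures[i]
    cfg <- config
    cfg$temperature <- Ti
    if (is.null(seed_path)) {
      seed_path <- make_initial_path(model, basins, cfg)
    } else if (!is_reactive(seed_path, basins)) {
      seed_path <- make_initial_path(model, basins, cfg)
    }
    # pilot estimate of sigma_tau at this temperature
    pcfg <- cfg; pcfg$n_paths <- as.integer(pilot_n)
    pcfg$burn_in_fraction <- 0
    pilot <- run_tps(seed_path, basins, pcfg, model)
    sig <- sd(transition_times(pilot, include_burn_in = TRUE))
    if (is.null(sigma_ref)) sigma_ref <- max(sig, 1e-12)
    n_i <- ceiling(config$n_paths * (sig / sigma_ref)^2)
    cfg$n_paths <- as.integer(min(max(n_i, n_min), n_max))
    seed2 <- pilot$paths[[tail(pilot$chain, 1L)]]
    if (is.null(seed2)) seed2 <- seed_path
    out[[i]] <- run_tps(seed2, basins, cfg, model)
    ens <- out[[i]]
    seed_path <- ens$paths[[tail(ens$chain, 1L)]]
  }
  out
}

#' Coupling-strength sweep of ensemble statistics
#'
#' Runs one TPS ensemble per diabatic coupling value at fixed temperature
#' and reports mean transition time and mean hop count.
#'
#' @param Vc_values diabatic couplings (Hartree).
#' @param temperature kelvin.
#' @param config a [tps_config()] (its `temperature` is overridden).
#' @param model_base a [two_state_model()] supplying the other constants.
#' @param basins a basin pair.
#' @return A data.frame with columns `Vc`, `mean_tau`, `mean_hops`,
#'   `acceptance`.
#' @export
sweep_coupling <- function(Vc_values, temperature, config,
                           model_base = two_state_model(),
                           basins = default_basins()) {
  cfg <- config
  cfg$temperature <- temperature
  res <- lapply(Vc_values, function(vc) {
    m <- two_state_model(epsilon = model_base$epsilon, x0 = model_base$x0,
                         Vc = vc, mass = model_base$mass)
    seed <- make_initial_path(m, basins, cfg)
    ens <- run_tps(seed, basins, cfg, m)
    ch <- ensemble_chain(ens)
    data.frame(Vc = vc,
               mean_tau = mean(transition_times(ens)),
               mean_hops = mean(vapply(ens$summaries[ch],
                                       function(s) s$n_hops, numeric(1))),
               acceptance = mean(ens$records$accepted))
  })
  do.call(rbind, res)
}
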