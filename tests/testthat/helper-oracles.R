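# shared fixtures and independent oracles

default_model <- function() two_state_model()

# central finite difference
fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# independent RK4 integration of the adiabatic-basis Schroedinger equation
# with derivative coupling along the linear drift path q(t) = q0 + v t;
# the reference for the local-diabatization propagator
rk4_tdse <- function(c0, q0, v, tau, model, nfine = 5000) {
  H <- function(q) {
    a <- adiabatize(model, q)
    matrix(c(a$lower, 1i * v * a$nac, -1i * v * a$nac, a$upper), 2, 2)
  }
  f <- function(t, cc) -1i * (H(q0 + v * t) %*% cc)
  h <- tau / nfine
  cc <- c0
  for (k in 0:(nfine - 1)) {
    t <- k * h
    k1 <- f(t, cc); k2 <- f(t + h / 2, cc + h / 2 * k1)
    k3 <- f(t + h / 2, cc + h / 2 * k2); k4 <- f(t + h, cc + h * k3)
    cc <- cc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(cc)
}

random_coeffs <- function() {
  th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
  c(complex(modulus = cos(th / 2), argument = 0),
    complex(modulus = sin(th / 2), argument = ph))
}

# hand-built trajectory from explicit columns (for harvest tests)
synthetic_traj <- function(q, active, dt = 5) {
  n <- length(q)
  pts <- cbind(t = (seq_len(n) - 1) * dt, q = q, p = 0, Sx = 0, Sy = 0,
               Sz = active * 0.5, active = active)
  natps:::new_trajectory(pts, natps:::hops_frame(NULL), dt)
}

# the reference high-energy start that reliably crosses the barrier
hot_start <- function(model = default_model()) {
  phase_point(q = 1.0, p = -0.0087 * model$mass, S = c(0, 0, -1))
}

# memoised heavy runs shared by the acceptance tests
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

tps_run_12000 <- function() cached("tps12000", {
  set.seed(20251201)
  m <- default_model()
  cfg <- tps_config(temperature = 12000, n_paths = 5000L)
  run_tps(make_initial_path(m, config = cfg), config = cfg, model = m)
})

bf_run_12000 <- function() cached("bf12000", {
  set.seed(20251202)
  m <- default_model()
  brute_force_run(m, thermal_spec(12000), total_steps_budget = 2e6,
                  trajectory_length = 3000, target_transitions = 800,
                  direction = "both")
})
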