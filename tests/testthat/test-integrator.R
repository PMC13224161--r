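test_that("total energy follows the spin-dependent energy function", {
  m <- default_model()
  g <- phase_point(q = 1, p = 0, S = c(0, 0, -1))
  expect_equal(total_energy(g, m), 0.1 - sqrt(0.01 + 1e-4), tolerance = 1e-12)
  # hemisphere energy difference at fixed (q, p) is 2 Vz
  for (q in c(-0.7, 0.2, 1.3)) {
    glo <- phase_point(q = q, p = 3, S = c(0.6, 0, -0.8))
    ghi <- phase_point(q = q, p = 3, S = c(0.6, 0, 0.8))
    expect_equal(total_energy(ghi, m) - total_energy(glo, m),
                 2 * adiabatize(m, q)$Vz, tolerance = 1e-12)
  }
})

test_that("hop bookkeeping conserves energy in closed form", {
  m <- default_model()
  ke2p <- function(ke) sqrt(2 * m$mass * ke)
  at_seam <- function(p) phase_point(q = 0, p = p, S = c(1, 0, 0))
  # downward hop: KE 0.005 -> 0.025 (Vz = 0.01 at the seam)
  g <- attempt_hop(at_seam(ke2p(0.005)), "down", m)
  expect_equal(g$p^2 / (2 * m$mass), 0.025, tolerance = 1e-14)
  expect_false(attr(g, "frustrated"))
  # frustrated upward hop: KE 0.015 < 2 Vz = 0.02 -> reflection
  g <- attempt_hop(at_seam(ke2p(0.015)), "up", m)
  expect_equal(g$p, -ke2p(0.015))
  expect_true(attr(g, "frustrated"))
  # allowed upward hop: KE 0.025 -> 0.005, total energy unchanged
  g0 <- at_seam(ke2p(0.025))
  g <- attempt_hop(g0, "up", m)
  expect_equal(g$p^2 / (2 * m$mass), 0.005, tolerance = 1e-14)
  E0 <- g0$p^2 / (2 * m$mass) + adiabatize(m, 0)$lower
  E1 <- g$p^2 / (2 * m$mass) + adiabatize(m, 0)$upper
  expect_equal(E1, E0, tolerance = 1e-14)
  expect_error(attempt_hop(phase_point(q = 0, p = 1, S = c(0, 0, -1)),
                           "up", m), "away from")
})

test_that("a hop-free step is plain velocity Verlet plus electronic propagation", {
  m <- default_model()
  g <- phase_point(q = -1.1, p = 2.5, S = c(0.2, 0.1, -sqrt(1 - 0.05)))
  st <- mash_step(g, m, mash_control())
  expect_null(st$hop)
  # hand velocity Verlet on the lower surface
  dt <- 5
  ph <- g$p + dt / 2 * mash_force(m, g$q, -1)
  qn <- g$q + dt * ph / m$mass
  pn <- ph + dt / 2 * mash_force(m, qn, -1)
  expect_equal(st$point$q, qn, tolerance = 1e-13)
  expect_equal(st$point$p, pn, tolerance = 1e-13)
  cn <- propagate_electronic(g$c, g$q, qn, dt = dt, model = m)
  expect_lt(max(Mod(st$point$c - cn)), 1e-13)
})

test_that("coefficient and spin pictures stay consistent along a trajectory", {
  m <- default_model()
  ctrl <- mash_control()
  g <- hot_start(m)
  tr <- mash_trajectory(g, 60, m, ctrl)
  gg <- g
  for (k in 1:60) gg <- mash_step(gg, m, ctrl)$point
  S <- coeffs_to_spin(gg$c)
  expect_equal(unname(tr$points[61, c("Sx", "Sy", "Sz")]), S,
               tolerance = 1e-10)
  expect_equal(unname(tr$points[61, "q"]), gg$q, tolerance = 1e-12)
})

test_that("the integrator is time reversible across hops; endpoint hopping is not", {
  m <- default_model()
  run_n <- function(g, n, ctrl) {
    for (k in seq_len(n)) g <- mash_step(g, m, ctrl)$point
    g
  }
  g0 <- hot_start(m)
  tr <- mash_trajectory(g0, 1000, m, mash_control())
  expect_gt(nrow(tr$hops), 0)   # the window contains hops
  roundtrip_err <- function(ctrl) {
    g1 <- run_n(g0, 1000, ctrl)
    g3 <- time_reverse(run_n(time_reverse(g1), 1000, ctrl))
    max(abs(g3$q - g0$q), abs(g3$p - g0$p),
        abs(coeffs_to_spin(g3$c) - coeffs_to_spin(g0$c)))
  }
  err_root <- roundtrip_err(mash_control())
  err_naive <- roundtrip_err(mash_control(hop_mode = "endpoint"))
  expect_lt(err_root, 1e-8)
  expect_gt(err_naive / err_root, 1e4)
})

test_that("spin norm is conserved and energy stays within the integrator envelope", {
  m <- default_model()
  tr <- mash_trajectory(hot_start(m), 10000, m, mash_control())
  sn <- sqrt(tr$points[, "Sx"]^2 + tr$points[, "Sy"]^2 + tr$points[, "Sz"]^2)
  expect_lt(max(abs(sn - 1)), 1e-10)
  E <- natps:::trajectory_energy(tr, m)
  # velocity-Verlet shadow-energy oscillation: amplitude ~ (w dt)^2/8 * E,
  # with the stiffest curvature near the avoided crossing; no secular drift
  a <- adiabatize(m, seq(-2, 2, length.out = 401))
  wmax2 <- max(abs(diff(a$lower, differences = 2)) / diff(a$q)[1]^2) / m$mass
  envelope <- (wmax2 * 25) / 8 * max(E) * 2
  expect_lt(max(abs(E - E[1])), envelope)
  drift <- abs(mean(tail(E, 500)) - mean(head(E, 500)))
  expect_lt(drift, max(abs(E - E[1])) / 3)
  # second-order scaling of the energy error with the time step
  tr1 <- mash_trajectory(hot_start(m), 10000, m, mash_control(dt = 1))
  E1 <- natps:::trajectory_energy(tr1, m)
  ratio <- max(abs(E - E[1])) / max(abs(E1 - E1[1]))
  expect_gt(ratio, 8)
  expect_lt(ratio, 90)
})

test_that("the one-step map conserves phase-space volume away from hops", {
  m <- default_model()
  ctrl <- mash_control()
  coords_step <- function(x) {
    sz <- x[3]; phi <- x[4]
    sp <- sqrt(1 - sz^2)
    g <- phase_point(q = x[1], p = x[2],
                     S = c(sp * cos(phi), sp * sin(phi), sz))
    st <- mash_step(g, m, ctrl)
    stopifnot(is.null(st$hop))
    S <- coeffs_to_spin(st$point$c)
    c(st$point$q, st$point$p, S[3], atan2(S[2], S[1]))
  }
  x0 <- c(-0.95, 1.5, -0.5, 0.7)
  h <- c(1e-6, 1e-5, 1e-6, 1e-6)
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h[j]
    J[, j] <- (coords_step(x0 + e) - coords_step(x0 - e)) / (2 * h[j])
  }
  expect_equal(det(J), 1, tolerance = 1e-6)
})

test_that("basin-commitment propagation behaves at both ends and under reversal", {
  m <- default_model()
  ctrl <- mash_control()
  basins <- default_basins()
  inA <- phase_point(q = -0.95, p = 0, S = c(0, 0, -1))
  seg <- propagate_until_basin(inA, basins, "forward", m, ctrl)
  expect_identical(seg$status, "A")
  expect_identical(nrow(seg$points), 1L)
  expect_identical(attr(seg, "steps"), 0L)
  # backward propagation is forward propagation of the reversed point
  set.seed(8)
  g <- phase_point(q = 0.1, p = 6, S = c(0.4, 0.3, -sqrt(1 - 0.25)))
  bwd <- propagate_until_basin(g, basins, "backward", m, ctrl)
  fwd_of_rev <- propagate_until_basin(time_reverse(g), basins, "forward",
                                      m, ctrl)
  expect_identical(bwd$status, fwd_of_rev$status)
  pf <- fwd_of_rev$points
  pb <- bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE]
  expect_equal(unname(pb[, "q"]), unname(pf[, "q"]), tolerance = 1e-12)
  expect_equal(unname(pb[, "p"]), unname(-pf[, "p"]), tolerance = 1e-12)
  expect_equal(unname(pb[, "Sy"]), unname(-pf[, "Sy"]), tolerance = 1e-10)
  # a high-energy start between the wells commits quickly
  hot <- phase_point(q = 0, p = sqrt(2 * m$mass * 0.05), S = c(0, 0, -1))
  seg <- propagate_until_basin(hot, basins, "forward", m, ctrl)
  expect_true(seg$status %in% c("A", "B"))
})
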