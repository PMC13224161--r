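test_that("Boltzmann sampler reproduces Maxwell-Boltzmann momenta and hemisphere weights", {
  set.seed(10)
  m <- default_model()
  th <- thermal_spec(12000)
  n <- 1e5
  d <- sample_boltzmann(m, th, n)
  kT <- 1 / th$beta
  # momentum variance m kB T within 3 standard errors
  se <- sqrt(2 / (n - 1)) * m$mass * kT
  expect_lt(abs(var(d$p) - m$mass * kT), 3 * se)
  expect_lt(abs(mean(d$p)), 3 * sqrt(m$mass * kT / n))
  # hemisphere weight against independent quadrature of the two surfaces
  zl <- integrate(function(q) exp(-th$beta * adiabatize(m, q)$lower),
                  -5, 5, rel.tol = 1e-10)$value
  zu <- integrate(function(q) exp(-th$beta * adiabatize(m, q)$upper),
                  -5, 5, rel.tol = 1e-10)$value
  pu <- zu / (zl + zu)
  phat <- mean(d$sign > 0)
  expect_lt(abs(phat - pu), 3 * sqrt(pu * (1 - pu) / n))
  # conditional hemisphere ratio near the seam ~ exp(-2 beta Vz(q))
  sel <- abs(d$q) < 0.05
  ratio <- mean(d$sign[sel] > 0) / mean(d$sign[sel] < 0)
  expect_equal(ratio, exp(-2 * th$beta * adiabatize(m, 0)$Vz),
               tolerance = 0.15)
})

test_that("the spin marginal is uniform within each hemisphere", {
  set.seed(11)
  m <- default_model()
  d <- sample_boltzmann(m, thermal_spec(12000), 1e5)
  up <- d$Sz[d$sign > 0]
  lo <- -d$Sz[d$sign < 0]
  expect_gt(suppressWarnings(ks.test(up, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(lo, "punif"))$p.value, 0.01)
  az <- atan2(d$Sy, d$Sx)
  expect_gt(suppressWarnings(ks.test((az + pi) / (2 * pi),
                                     "punif"))$p.value, 0.01)
})

test_that("the sampled distribution is stationary under the dynamics", {
  set.seed(12)
  m <- default_model()
  th <- thermal_spec(12000)
  n <- 1500
  d <- sample_boltzmann(m, th, n)
  ctrl <- mash_control()
  qf <- numeric(n); sf <- numeric(n)
  for (i in seq_len(n)) {
    tr <- mash_trajectory(natps:::sample_point(d, i), 20, m, ctrl)
    qf[i] <- tr$points[21, "q"]
    sf[i] <- tr$points[21, "active"]
  }
  expect_gt(suppressWarnings(ks.test(d$q, qf))$p.value, 0.001)
  p0 <- mean(d$sign > 0)
  expect_lt(abs(mean(sf > 0) - p0),
            3 * sqrt(2 * p0 * (1 - p0) / n) + 0.01)
})

test_that("transition harvesting extracts exactly the reactive segments", {
  basins <- default_basins()
  # labels [A, A, -, -, B, B, -, A]: one A->B segment from the last A of
  # the first block to the first B
  tr <- synthetic_traj(q = c(-0.9, -0.85, -0.5, 0.5, 0.85, 0.9, 0.5, -0.9),
                       active = rep(-1, 8))
  segs <- harvest_transitions(tr, basins)
  expect_length(segs, 1)
  expect_equal(unname(segs[[1]]$points[1, "q"]), -0.85)
  expect_equal(unname(segs[[1]]$points[nrow(segs[[1]]$points), "q"]), 0.85)
  # with direction = "both" the trailing B->A transit is also returned,
  # reversed so it reads A->B
  segs2 <- harvest_transitions(tr, basins, direction = "both")
  expect_length(segs2, 2)
  expect_true(isTRUE(attr(segs2[[2]], "reversed")))
  expect_equal(unname(segs2[[2]]$points[1, "q"]), -0.9)
  # recrossing back to the same basin yields nothing
  tr2 <- synthetic_traj(q = c(-0.9, 0.0, -0.9), active = rep(-1, 3))
  expect_length(harvest_transitions(tr2, basins), 0)
  # upper-state points at basin positions do not count as basin visits
  tr3 <- synthetic_traj(q = c(-0.9, 0.9, 0.9), active = c(-1, 1, -1))
  segs3 <- harvest_transitions(tr3, basins)
  expect_length(segs3, 1)
  expect_identical(nrow(segs3[[1]]$points), 3L)
})

test_that("an unbiased high-temperature trajectory contains harvestable transitions", {
  set.seed(13)
  m <- default_model()
  tr <- mash_trajectory(hot_start(m), 4000, m, mash_control())
  segs <- harvest_transitions(tr, default_basins(), direction = "both")
  expect_gt(length(segs), 0)
  for (s in segs) expect_true(natps:::is_reactive(s, default_basins()))
})

test_that("brute-force accounting is exact and a cold start finds nothing", {
  set.seed(14)
  m <- default_model()
  bf <- brute_force_run(m, thermal_spec(300), total_steps_budget = 2000,
                        trajectory_length = 500)
  expect_length(bf$segments, 0)
  expect_identical(bf$steps_used, 2000)
  expect_identical(bf$n_trajectories, 4L)
})
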