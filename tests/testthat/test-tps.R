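test_that("basin membership requires the lower state and the right side", {
  b <- default_basins()
  expect_true(in_basin(phase_point(q = -0.9, p = 0, S = c(0, 0, -1)), b$A))
  expect_false(in_basin(phase_point(q = -0.9, p = 0, S = c(0, 0, 1)), b$A))
  expect_false(in_basin(phase_point(q = -0.9, p = 0, S = c(0, 0, 1)), b$B))
  g0 <- phase_point(q = 0, p = 0, S = c(0, 0, -1))
  expect_false(in_basin(g0, b$A))
  expect_false(in_basin(g0, b$B))
  expect_true(in_basin(phase_point(q = 0.81, p = 0, S = c(0, 0, -1)), b$B))
})

test_that("velocity perturbation has the right limits and leaves Maxwell-Boltzmann invariant", {
  m <- default_model()
  th <- thermal_spec(12000)
  set.seed(20)
  v <- rnorm(5)
  expect_identical(perturb_velocity(v, th, 1, m$mass), v)
  n <- 1e5
  sig2 <- 1 / (th$beta * m$mass)
  v0 <- rnorm(n, 0, sqrt(sig2))
  va <- perturb_velocity(v0, th, 0, m$mass)
  expect_lt(abs(var(va) - sig2), 3 * sqrt(2 / n) * sig2)
  # iterating the alpha = 0.9 move preserves mean and variance
  v <- v0
  for (k in 1:20) v <- perturb_velocity(v, th, 0.9, m$mass)
  expect_lt(abs(mean(v)), 3 * sqrt(sig2 / n))
  expect_lt(abs(var(v) - sig2), 3 * sqrt(2 / n) * sig2)
})

test_that("the reference start point yields a reactive initial path", {
  set.seed(21)
  m <- default_model()
  cfg <- tps_config(temperature = 12000, n_paths = 10L)
  path <- make_initial_path(m, config = cfg)
  expect_true(natps:::is_reactive(path, default_basins()))
  lab <- natps:::basin_label_rows(path$points[, "q"],
                                  path$points[, "active"],
                                  default_basins())
  expect_identical(lab[1], "A")
  expect_identical(lab[length(lab)], "B")
  expect_true(all(is.na(lab[2:(length(lab) - 1)])))
})

test_that("a non-reactive seed path is rejected at entry", {
  m <- default_model()
  cfg <- tps_config(temperature = 12000, n_paths = 5L)
  bad <- synthetic_traj(q = c(-0.9, 0, -0.9), active = rep(-1, 3))
  expect_error(run_tps(bad, config = cfg, model = m), "not reactive")
})

test_that("seeded chains are reproducible and every chain element is reactive", {
  m <- default_model()
  cfg <- tps_config(temperature = 12000, n_paths = 120L)
  set.seed(22)
  seed_path <- make_initial_path(m, config = cfg)
  set.seed(23)
  e1 <- run_tps(seed_path, config = cfg, model = m)
  set.seed(23)
  e2 <- run_tps(seed_path, config = cfg, model = m)
  expect_identical(e1$chain, e2$chain)
  expect_identical(e1$total_steps, e2$total_steps)
  expect_equal(transition_times(e1), transition_times(e2))
  acc <- mean(e1$records$accepted)
  expect_gt(acc, 0); expect_lt(acc, 1)
  for (p in e1$paths[unique(e1$chain)])
    expect_true(natps:::is_reactive(p, default_basins()))
  # rejected shots repeat the previous chain element
  rej <- which(!e1$records$accepted)
  if (length(rej)) {
    prev <- ifelse(rej == 1L, 1L, e1$chain[pmax(rej - 1L, 1L)])
    expect_identical(e1$chain[rej], prev)
  }
  # step accounting sums the per-shot records
  expect_identical(e1$total_steps, sum(e1$records$steps))
})

test_that("reactive paths carry an even number of surface changes", {
  ens <- tps_run_12000()
  nh <- vapply(ens$summaries[unique(ens$chain)],
               function(s) s$n_hops, numeric(1))
  expect_true(all(nh %% 2 == 0))
})

test_that("annealing runs a descending ladder and cools out the hops", {
  set.seed(24)
  m <- default_model()
  cfg <- tps_config(temperature = 12000, n_paths = 150L)
  ladder <- anneal(c(12000, 1000), cfg, m, pilot_n = 40L, n_min = 60L)
  expect_named(ladder, c("T12000", "T1000"))
  cold <- ladder$T1000
  expect_identical(cold$config$temperature, 1000)
  nh <- vapply(cold$summaries[unique(cold$chain)],
               function(s) s$n_hops, numeric(1))
  expect_true(all(nh == 0))   # only adiabatic pathways remain at 1000 K
  # a single-temperature ladder is an ordinary run
  set.seed(25)
  one <- anneal(12000, cfg, m, pilot_n = 40L)
  expect_s3_class(one[[1]], "natps_ensemble")
  expect_length(one, 1)
})
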