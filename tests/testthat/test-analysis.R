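test_that("transition time is steps times dt and guards reactivity", {
  tr <- synthetic_traj(q = c(-0.9, seq(-0.5, 0.5, length.out = 99), 0.9),
                       active = rep(-1, 101))
  expect_equal(transition_time(tr), 500)
  expect_equal(transition_time(tr, default_basins()), 500)
  bad <- synthetic_traj(q = c(-0.9, 0, -0.9), active = rep(-1, 3))
  expect_error(transition_time(bad, default_basins()), "not reactive")
})

test_that("autocorrelation matches a direct-summation oracle and its conventions", {
  tau <- c(1, 2, 3, 4)
  C <- tt_autocorrelation(tau, 2)
  # brute-force evaluation of the defining sum
  mu <- mean(tau); v <- mean((tau - mu)^2)
  oracle <- function(n) {
    N <- length(tau)
    s <- 0
    for (t in 0:(N - n - 1)) s <- s + (tau[t + 1] - mu) * (tau[t + n + 1] - mu)
    s / ((N - n) * v)
  }
  expect_equal(C[1], 1)
  expect_equal(C[2], oracle(1))
  expect_equal(C[3], oracle(2))
  # iid series decorrelates immediately
  set.seed(30)
  x <- rnorm(4000)
  Ci <- tt_autocorrelation(x, 10)
  expect_true(all(abs(Ci[-1]) < 4 / sqrt(length(x))))
  expect_warning(tt_autocorrelation(rep(2, 10), 3), "zero variance")
})

test_that("decorrelation length finds the 1/e crossing", {
  expect_identical(as.integer(decorrelation_length(exp(-(0:50) / 10))), 10L)
  expect_identical(as.integer(decorrelation_length(c(1, rep(0, 20)))), 1L)
  n <- decorrelation_length(c(1, rep(0.9, 5)))
  expect_false(attr(n, "crossed"))
})

test_that("coherence angle is the planar arctangent", {
  expect_equal(coherence_angle(c(1, 0, 0)), 0)
  expect_equal(coherence_angle(c(0, 1, 0)), pi / 2)
  expect_equal(coherence_angle(c(-1, 0, 0)), pi)
  expect_error(coherence_angle(c(0, 0, 1)), "undefined")
})

test_that("efficiency ratio divides steps by paths and bounds the empty case", {
  expect_equal(efficiency_ratio(1000, 5), 200)
  er <- efficiency_ratio(15e6, 0)
  expect_identical(unname(er[1]), Inf)
  expect_equal(attr(er, "lower_bound"), 15e6)
})

test_that("distribution comparison has the right degenerate limits", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_transition_times(x, x)$statistic, 0)
  expect_equal(compare_transition_times(x, x + 100)$statistic, 1)
})

test_that("hop statistics and path density summarize the ensemble consistently", {
  ens <- tps_run_12000()
  hs <- hop_statistics(ens)
  ch <- ensemble_chain(ens)
  expect_length(hs$hops_per_path, length(ch))
  expect_identical(length(hs$positions), length(hs$phi))
  expect_true(all(hs$fraction_ge >= 0 & hs$fraction_ge <= 1))
  expect_true(all(diff(hs$fraction_ge) <= 0))  # monotone in the threshold
  pd <- path_density(ens, seq(-2.5, 2.5, length.out = 101))
  dq <- diff(pd$q)[1]
  expect_equal(sum(pd$lower + pd$upper) * dq, 1, tolerance = 1e-10)
  # symmetric model: lower-state density symmetric within sampling error
  asym <- sum(abs(pd$lower - rev(pd$lower))) / sum(pd$lower)
  expect_lt(asym, 0.35)
  # chain weighting: ensemble means use the chain with repeats
  tau <- transition_times(ens)
  expect_length(tau, length(ch))
  expect_equal(mean(tau),
               mean(vapply(ens$summaries[ch], function(s) s$tau,
                           numeric(1))))
})

test_that("mean transition time falls with temperature for adiabatic paths", {
  set.seed(31)
  m <- default_model()
  taus <- vapply(c(2000, 6000), function(Ti) {
    cfg <- tps_config(temperature = Ti, n_paths = 250L)
    ens <- run_tps(make_initial_path(m, config = cfg), config = cfg,
                   model = m)
    nh <- hop_statistics(ens)$hops_per_path
    tau <- transition_times(ens)
    mean(tau[nh == 0])
  }, numeric(1))
  expect_gt(taus[1], taus[2])
})
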