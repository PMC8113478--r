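test_that("the delay SSA reproduces the exact time-dependent law of constitutive expression", {
  rho <- 1; tau <- 5
  net <- model_I(rho, tau)
  times <- c(1, 2.5, 5, 10, 20)
  ens <- simulate_delay_ssa(net, times, n_traj = 10000, seed = 7)
  H <- snapshots_from_ensemble(ens, N = 20L)
  for (t in times) {
    emp <- H$prob[H$time == t]
    ex <- model1_pmf(rho, tau, t, N = 20)
    expect_lt(hellinger(emp, ex), 0.03)
  }
  # goodness of fit not rejected at alpha = 0.01 across the grid
  for (t in c(2.5, 10, 20)) {
    counts <- emp_counts <- round(H$prob[H$time == t] * 10000)
    p <- dpois(0:20, rho * min(t, tau))
    # lump the tail so expected counts stay reasonable
    keep <- which(p * 10000 >= 5)
    hi <- max(keep)
    obs <- c(counts[seq_len(hi)], sum(counts[-seq_len(hi)]))
    pr <- c(p[seq_len(hi)], 1 - sum(p[seq_len(hi)]))
    gof <- suppressWarnings(stats::chisq.test(obs, p = pr))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("ensembles are reproducible given the seed and inert without propensity", {
  net <- model_I(1, 5)
  e1 <- simulate_delay_ssa(net, c(1, 3, 7), n_traj = 200, seed = 11)
  e2 <- simulate_delay_ssa(net, c(1, 3, 7), n_traj = 200, seed = 11)
  expect_identical(e1, e2)
  e3 <- simulate_delay_ssa(net, c(1, 3, 7), n_traj = 200, seed = 12)
  expect_false(identical(e1$N, e3$N))
  # zero-rate network: state constant over time
  zero <- delay_network(
    species = "N",
    channels = list(reaction_channel(
      "production", list(kind = "const", rate = "rho"),
      init_stoich = c(N = 1L), completion_stoich = c(N = -1L),
      delay = delay_spec("fixed", 5))),
    params = list(rho = 0, tau = 5))
  ez <- simulate_delay_ssa(zero, c(1, 10), n_traj = 50, seed = 1,
                           init_state = c(N = 3L))
  expect_true(all(ez$N == 3))
})

test_that("with the delay beyond the horizon the counts are a pure Poisson process", {
  net <- model_I(1.5, 1e6)
  ens <- simulate_delay_ssa(net, c(4, 8), n_traj = 20000, seed = 9)
  H <- snapshots_from_ensemble(ens, N = 30L)
  for (t in c(4, 8))
    expect_lt(hellinger(H$prob[H$time == t], dpois(0:30, 1.5 * t)), 0.03)
})

test_that("lognormal delays preserve the stationary Poisson law with mean rho*tau", {
  # molecules in service of an M/G/infinity queue are Poisson(rho * E[delay])
  net <- model_I(1, 4, delay = delay_spec("lognormal", tau_mean = 4,
                                          sigma_log = 0.5))
  ens <- simulate_delay_ssa(net, c(30), n_traj = 10000, seed = 10)
  H <- snapshots_from_ensemble(ens, N = 16L)
  expect_lt(abs(mean(ens$N[ens$time == 30]) - 4), 4 * sqrt(4 / 10000))
  expect_lt(hellinger(H$prob, dpois(0:16, 4)), 0.03)
})

test_that("snapshot histograms are normalised empirical frequencies", {
  net <- model_I(1, 5)
  ens <- simulate_delay_ssa(net, c(2, 6), n_traj = 500, seed = 3)
  H <- snapshots_from_ensemble(ens, N = 15L)
  sums <- tapply(H$prob, H$time, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # a single trajectory gives an indicator histogram
  one <- simulate_delay_ssa(net, c(6), n_traj = 1, seed = 4)
  H1 <- snapshots_from_ensemble(one, N = 10L)
  expect_equal(sum(H1$prob == 1), 1)
  expect_equal(which(H1$prob == 1) - 1L, one$N[1])
  # tail aggregation warns
  expect_warning(snapshots_from_ensemble(ens, N = 2L), "aggregat")
  expect_error(snapshots_from_ensemble(ens[0, ]), "empty")
})

test_that("marginalization preserves mass and matches direct histogramming", {
  net <- feedback_model(tau = 5, d_Y = 0.5,
                        params = list(k1 = 1.5, K1 = 2, h1 = 3, k2 = 0))
  ens <- simulate_delay_ssa(net, c(5, 15), n_traj = 2000, seed = 6)
  H <- suppressWarnings(snapshots_from_ensemble(ens, N = c(X = 15, Y = 10)))
  HY <- marginalize(H, "Y")
  sums <- tapply(HY$prob, HY$time, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # the marginal equals the directly histogrammed Y counts
  direct <- snapshots_from_counts(
    data.frame(trajectory = ens$trajectory, time = ens$time, Y = ens$Y),
    N = c(Y = 10))
  m1 <- dplyr::arrange(tibble::as_tibble(HY), time, Y)
  m2 <- dplyr::arrange(tibble::as_tibble(direct), time, Y)
  expect_equal(m1$prob, m2$prob)
  expect_error(marginalize(H, "Z"), "unknown species")
})
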