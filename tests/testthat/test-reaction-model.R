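test_that("preset constructors build the documented networks and reject bad rates", {
  net <- model_I(1, 5)
  expect_length(net$species, 1)
  expect_length(net$channels, 1)
  expect_equal(net$channels[[1]]$delay$kind, "fixed")
  expect_equal(net$channels[[1]]$delay$tau_mean, 5)
  expect_error(model_I(-1, 5), "rho")
  expect_error(model_I(1, 0), "tau")
  expect_error(model_II(0.1, -2, 5), "b")
  expect_error(model_III(1, 1, -1, 5), "> 0")

  net3 <- model_III(2.11, 0.0282, 0.609, 140)
  expect_equal(net3$gene_states, c("G", "Gstar"))
  expect_equal(channel_propensity(net3, "production", c(N = 3), "Gstar"), 0)
  expect_equal(channel_propensity(net3, "production", c(N = 3), "G"), 2.11)
})

test_that("validate_network reports inconsistencies without throwing", {
  expect_equal(nrow(validate_network(model_I(1, 5))), 0)
  # channel referencing a missing parameter
  bad <- model_I(1, 5)
  bad$channels[[1]]$propensity$rate <- "nonexistent"
  d <- validate_network(bad)
  expect_true(any(d$level == "error" & grepl("nonexistent", d$message)))
  # delayed channel with zero completion stoichiometry -> warning diagnostic
  odd <- model_I(1, 5)
  odd$channels[[1]]$completion_stoich <- c(N = 0L)
  d2 <- validate_network(odd)
  expect_true(any(d2$level == "warning" & grepl("completion", d2$message)))
})

test_that("networks round-trip through config serialization unchanged", {
  for (preset in c("model1", "model2", "model3", "feedback")) {
    net <- preset_network(preset)
    cfg <- network_to_config(net)
    back <- network_from_config(cfg)
    expect_identical(network_to_config(back), cfg, label = preset)
  }
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f), add = TRUE)
  net <- preset_network("model2")
  network_to_config(net, f)
  expect_identical(network_to_config(network_from_config(f)),
                   network_to_config(net))
  # function propensities cannot be serialised
  fb <- feedback_model(tau = 5, d_Y = 1, J1 = function(y) 2 / (1 + y))
  expect_error(network_to_config(fb), "serialis")
})

test_that("Model I trajectories start empty and reach mean rho*tau", {
  net <- model_I(1, 5)
  ens <- simulate_delay_ssa(net, c(0, 20), n_traj = 10000, seed = 2)
  expect_true(all(ens$N[ens$time == 0] == 0))
  m <- mean(ens$N[ens$time == 20])
  expect_lt(abs(m - 5), 4 * sqrt(5 / 10000))
})

test_that("burst statistics follow the geometric law with mean b", {
  # with the removal delay beyond the horizon, N(t) is a compound Poisson sum
  # of burst sizes: its mean alpha*b*t identifies the mean burst size
  alpha <- 0.5; b <- 3.46
  net <- model_II(alpha, b, tau = 1e5)
  ens <- simulate_delay_ssa(net, c(40), n_traj = 5000, seed = 3)
  n_tot <- sum(ens$N)                      # ~1e5 burst-size draws in total
  b_hat <- n_tot / (alpha * 40 * 5000)
  se <- sqrt(b * (1 + b) * 2 / (alpha * 40 * 5000))  # compound-Poisson var
  expect_lt(abs(b_hat - b), 5 * se)
})

test_that("Model III reduces to Model I when the OFF switch is slow", {
  net <- model_III(rho = 1, sigma_on = 5, sigma_off = 1e-7, tau = 5)
  ens <- simulate_delay_ssa(net, c(12), n_traj = 10000, seed = 4)
  H <- snapshots_from_ensemble(ens, N = 20L)
  h <- marginalize(H, "N")
  expect_lt(hellinger(h$prob, model1_pmf(1, 5, 12, N = 20)), 0.05)
})

test_that("Model III reduces to Model II in the bursty limit", {
  rho <- 2.11; sigma_on <- 0.282; sigma_off <- 10; tau <- 10
  net <- model_III(rho, sigma_on, sigma_off, tau)
  ens <- simulate_delay_ssa(net, c(15), n_traj = 10000, seed = 4,
                            init_gene_state = "Gstar")
  H <- marginalize(snapshots_from_ensemble(ens, N = 15L), "N")
  ex <- model2_pmf(alpha = sigma_on, b = rho / sigma_off, tau = tau,
                   t = 15, N = 15)
  expect_lt(hellinger(H$prob, ex), 0.05)
})

test_that("the promoter active fraction matches the two-state stationary law", {
  net <- model_III(2.11, 0.282, 0.609, 14)
  ens <- simulate_delay_ssa(net, seq(30, 60, by = 2), n_traj = 2000, seed = 5)
  frac <- mean(ens$gene_state == "G")
  p <- 0.282 / (0.282 + 0.609)
  expect_lt(abs(frac - p), 0.02)
})

test_that("the feedback loop without repression reduces to constitutive expression", {
  # K1 huge -> J1(Y) ~ k1 constant, X behaves as Model I(k1, tau)
  net <- feedback_model(tau = 5, d_Y = 0.5,
                        params = list(k1 = 1.2, K1 = 1e7, h1 = 2, k2 = 0))
  ens <- simulate_delay_ssa(net, c(18), n_traj = 8000, seed = 6)
  HX <- marginalize(suppressWarnings(
    snapshots_from_ensemble(ens, N = c(X = 18, Y = 25))), "X")
  expect_lt(hellinger(HX$prob, model1_pmf(1.2, 5, 18, N = 18)), 0.05)
  # conversion conservation: with slow Y degradation, Y counts the matured X
  net2 <- feedback_model(tau = 5, d_Y = 1e-7,
                         params = list(k1 = 1.2, K1 = 1e7, h1 = 2, k2 = 0))
  ens2 <- simulate_delay_ssa(net2, c(25), n_traj = 4000, seed = 7)
  mY <- mean(ens2$Y[ens2$time == 25])
  expect_lt(abs(mY - 1.2 * 20) / (1.2 * 20), 0.05)  # births in (0, t - tau]
})

test_that("strong delayed repression yields damped ensemble oscillations", {
  net <- feedback_model(tau = 7, d_Y = 0.5,
                        params = list(k1 = 1.5, K1 = 1.5, h1 = 4, k2 = 0))
  ens <- simulate_delay_ssa(net, seq(0.5, 35, by = 0.5), n_traj = 3000,
                            seed = 8)
  mx <- tapply(ens$X, ens$time, mean)
  d <- diff(mx)
  sign_changes <- sum(diff(sign(d[abs(d) > 5e-4])) != 0)
  expect_gte(sign_changes, 2)
  # a rising propensity triggers the repression warning, not an error
  expect_warning(feedback_model(tau = 5, d_Y = 1, J1 = function(y) 0.1 + 0.01 * y),
                 "repressive")
})
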