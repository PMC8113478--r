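test_that("the snapshot objective is the summed squared distance", {
  H <- cbind(dpois(0:5, 1), dpois(0:5, 2))
  expect_equal(snapshot_loss(H, H), 0)
  d0 <- c(1, 0, 0); d1 <- c(0, 1, 0)
  expect_equal(snapshot_loss(cbind(d0), cbind(d1)), 2)
})

test_that("training with zero epochs returns the initial network and objective", {
  net <- model_I(1, 4)
  ex <- sapply(c(1, 3, 6), function(t) as.numeric(model1_pmf(1, 4, t, N = 12)))
  H <- exact_hist(c(1, 3, 6), ex)
  fit <- train_nncme(net, H, space = state_space(net, N = 12),
                     config = training_config(epochs_max = 0, hidden = 8,
                                              seed = 7,
                                              loss_threshold = Inf))
  init <- nn_propensity(fit$space$size, fit$assembly$r, hidden = 8, seed = 7)
  expect_equal(fit$nn$W1, init$W1)
  expect_true(is.finite(fit$final_J))
})

test_that("training on birth-death data recovers the known linear removal propensity", {
  # data: exact transients of a Markovian birth-death process; the learned
  # propensity must match k*n wherever the solution carries mass
  rho <- 1; k <- 0.25
  net <- model_I(rho, 1 / k)
  sp <- state_space(net, N = 14)
  asm <- build_known_generator(net, sp)
  A <- as.matrix(assemble_A(asm, k * seq_len(14)))
  times <- seq(0, 16, by = 2)
  P0 <- c(1, rep(0, 14))
  ex <- sapply(times, function(t)
    as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% P0))
  H <- exact_hist(times, ex)
  fit <- train_nncme(net, H, space = sp,
                     config = training_config(epochs_max = 3000, hidden = 32,
                                              seed = 1))
  fp <- fitted_propensity(fit)
  Pend <- fit$P_snap[, ncol(fit$P_snap)]
  hi <- which(Pend[-1] > 1e-3)
  expect_true(all(abs(fp$g[hi] - k * hi) / (k * hi) < 0.1))
})

test_that("transient training honours its contracts on noisy data", {
  sh <- shared_model1_fit()
  fit <- sh$fit
  # best-so-far objective is what the fit reports
  expect_equal(fit$final_J, min(fit$loss_history$J))
  # P(0) = H(0) exactly
  H0 <- sh$H$prob[sh$H$time == 0]
  expect_equal(fit$P_snap[seq_along(H0), 1], H0)
  # mass conservation along the fitted trajectory
  expect_true(all(colSums(fit$P_snap) > 1 - 1e-4 & colSums(fit$P_snap) <= 1 + 1e-12))
  # reproducibility: identical seed, identical run
  cfg <- training_config(epochs_max = 40, hidden = 8, seed = 9)
  f1 <- train_nncme(sh$net, sh$H, config = cfg)
  f2 <- train_nncme(sh$net, sh$H, config = cfg)
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("the learned early-time removal propensity is near zero before the delay elapses", {
  sh <- shared_model1_fit()
  tau <- 5
  for (t in c(1, 2, 3)) {
    P <- predict(sh$fit, times = t)[, 1]
    g <- nn_forward(sh$fit$nn, P)
    hi <- which(P[-1] > 1e-2)
    expect_true(all(g[hi] < 0.1 * hi / tau),
                label = paste0("propensity at t = ", t))
  }
})

test_that("steady-state training on stationary data recovers first-order removal", {
  net <- model_I(1, 5)
  ens <- simulate_delay_ssa(net, c(6), n_traj = 5e4, seed = 4)
  H <- suppressWarnings(snapshots_from_ensemble(ens, N = 16L))
  fit <- train_nncme(net, H, space = state_space(net, N = 16), mode = "steady",
                     config = training_config(epochs_max = 2500, hidden = 32,
                                              seed = 2, lr = 3e-3))
  fp <- fitted_propensity(fit)
  hi <- which(fit$H_ss[-1] > 1e-3)
  expect_true(all(abs(fp$g[hi] - hi / 5) / (hi / 5) < 0.1))
  # the residual at return is below the best recorded objective history
  expect_equal(fit$final_J, min(fit$loss_history$J))
})

test_that("single-species partial training is ordinary training", {
  net <- model_I(1, 4)
  ex <- sapply(c(0, 2, 5), function(t) as.numeric(model1_pmf(1, 4, t, N = 10)))
  H <- exact_hist(c(0, 2, 5), ex)
  cfg <- training_config(epochs_max = 30, hidden = 8, seed = 3)
  f1 <- train_nncme(net, H, space = state_space(net, N = 10), config = cfg)
  f2 <- train_nncme(net, H, space = state_space(net, N = 10),
                    observed_species = "N", config = cfg)
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("runaway learning rates abort with guidance", {
  net <- model_I(2, 5)
  ex <- sapply(c(0, 4, 8), function(t) as.numeric(model1_pmf(2, 5, t, N = 18)))
  H <- exact_hist(c(0, 4, 8), ex)
  expect_error(
    train_nncme(net, H, space = state_space(net, N = 18),
                config = training_config(epochs_max = 400, hidden = 8,
                                         seed = 1, lr = 5)),
    "diverged|step size")
})

test_that("tidiers and plots expose the fit without recomputation", {
  sh <- shared_model1_fit()
  td <- tidy(sh$fit)
  expect_true(all(c("head", "n", "g", "r") %in% names(td)))
  expect_true(all(td$g >= 0))
  gl <- glance(sh$fit)
  expect_equal(gl$final_J, sh$fit$final_J)
  expect_s3_class(autoplot(sh$fit, "loss"), "ggplot")
  expect_s3_class(autoplot(sh$fit, "propensity"), "ggplot")
  expect_s3_class(autoplot(sh$fit, "fit"), "ggplot")
  expect_s3_class(autoplot(sh$H), "ggplot")
})
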