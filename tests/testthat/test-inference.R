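test_that("kinetic parameter specifications validate their bounds", {
  expect_error(kinetic_param("alpha", init = 0.5, lower = 1, upper = 2))
  expect_error(kinetic_param("alpha", init = 0.5, lower = -1, upper = 2))
  sp <- kinetic_param("b", init = 2, lower = 0.5, upper = 10)
  expect_true(sp$log)
})

test_that("inference without free parameters reduces to plain training", {
  net <- model_I(1, 4)
  ex <- sapply(c(0, 2, 5), function(t) as.numeric(model1_pmf(1, 4, t, N = 10)))
  H <- exact_hist(c(0, 2, 5), ex)
  cfg <- training_config(epochs_max = 25, hidden = 8, seed = 3)
  fit <- train_nncme(net, H, space = state_space(net, N = 10), config = cfg)
  inf <- infer_kinetics(net, list(), H, space = state_space(net, N = 10),
                        config = cfg)
  expect_equal(inf$final_J, fit$final_J, tolerance = 1e-12)
})

test_that("free parameters must enter the known generator", {
  net <- model_I(1, 4)
  ex <- sapply(c(0, 2, 5), function(t) as.numeric(model1_pmf(1, 4, t, N = 10)))
  H <- exact_hist(c(0, 2, 5), ex)
  expect_error(
    infer_kinetics(net, list(kinetic_param("tau", init = 3, lower = 1,
                                           upper = 10)),
                   H, space = state_space(net, N = 10),
                   config = training_config(epochs_max = 5, hidden = 4)),
    "does not enter the known generator")
})

test_that("kinetic gradients match finite differences through the cached generator", {
  net <- model_II(0.25, 2.5, 8)
  sp <- state_space(net, N = 12)
  asm <- build_known_generator(net, sp)
  cache <- nncme:::generator_cache(net, sp, c("alpha", "b"))
  gen <- nncme:::generator_at(cache, net$params)
  nn <- nncme:::nn_propensity(sp$size, asm$r, hidden = 6, seed = 3)
  P0 <- numeric(sp$size); P0[1] <- 1
  H <- cbind(dpois(0:12, 2), dpois(0:12, 3))
  H <- sweep(H, 2, colSums(H), "/")
  obs <- 0:12; snap <- c(15L, 30L)
  Dsl <- nncme:::sparse_slots(gen$D)
  gr <- nncme:::nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, P0, Dsl$p, Dsl$i,
                               Dsl$x, asm$src, asm$dst, asm$out, 0.04, snap,
                               H, obs, 0L, unname(gen$derivs), TRUE)
  Jat <- function(a, b) {
    n2 <- model_II(a, b, 8)
    D2 <- nncme:::sparse_slots(
      nncme:::generator_at(nncme:::generator_cache(n2, sp, character(0)),
                           n2$params)$D)
    nncme:::nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, P0, D2$p, D2$i, D2$x,
                           asm$src, asm$dst, asm$out, 0.04, snap, H, obs, 0L,
                           list(), FALSE)$J
  }
  h <- 1e-5
  fd_a <- (Jat(0.25 + h, 2.5) - Jat(0.25 - h, 2.5)) / (2 * h)
  fd_b <- (Jat(0.25, 2.5 + h) - Jat(0.25, 2.5 - h)) / (2 * h)
  expect_lt(abs(gr$gkin[1] - fd_a) / abs(fd_a), 1e-6)
  expect_lt(abs(gr$gkin[2] - fd_b) / abs(fd_b), 1e-6)
})

test_that("joint optimisation moves burst parameters toward the truth", {
  net <- model_II(0.25, 2.5, 8)
  ens <- simulate_delay_ssa(net, seq(0.4, 16, by = 0.4), n_traj = 3000,
                            seed = 14)
  H <- suppressWarnings(snapshots_from_ensemble(ens, N = 30L))
  cfg <- training_config(epochs_max = 700, hidden = 16, seed = 2, lr = 3e-3)
  inf <- infer_kinetics(net, list(kinetic_param("alpha", init = 0.12,
                                                lower = 0.02, upper = 2)),
                        H, config = cfg)
  est <- inf$params$alpha
  expect_lt(abs(est - 0.25) / 0.25, abs(0.12 - 0.25) / 0.25)
  expect_lt(abs(est - 0.25) / 0.25, 0.25)
  expect_false(tidy(inf)$at_bound[1])
})

test_that("quantile-quantile validation reports slope and intercept", {
  p <- dpois(0:30, 8)
  qq <- qq_validate(p, p)
  expect_equal(qq$slope, 1)
  expect_equal(qq$intercept, 0, tolerance = 1e-10)
  qq2 <- qq_validate(p, c(0, 0, dpois(0:28, 8)))
  expect_equal(qq2$slope, 1, tolerance = 1e-10)
  expect_equal(qq2$intercept, 2, tolerance = 1e-10)
  expect_error(qq_validate(c(1, rep(0, 5)), c(1, rep(0, 5))), "degenerate")
  expect_s3_class(autoplot(qq2), "ggplot")
})
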