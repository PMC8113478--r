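test_that("the constitutive-expression law is Poisson with a saturating window", {
  expect_equal(as.numeric(model1_pmf(1, 5, 0, N = 10)), c(1, rep(0, 10)))
  p1 <- model1_pmf(2, 5, 7, N = 40)
  expect_equal(sum((0:40) * p1), 10, tolerance = 1e-9)
  expect_equal(as.numeric(model1_pmf(2, 5, 7, N = 40)),
               as.numeric(model1_pmf(2, 5, 70, N = 40)))
})

test_that("the bursty-expression law matches a brute-force Monte-Carlo oracle", {
  alpha <- 0.2; b <- 3.46; tau <- 20
  set.seed(42)
  K <- rpois(2e5, alpha * tau)
  x <- vapply(K, function(k) if (k == 0) 0L else
    sum(rgeom(k, 1 / (1 + b))), integer(1))
  emp <- tabulate(x + 1L, nbins = 81) / 2e5
  ex <- model2_pmf(alpha, b, tau, t = 40, N = 80)
  expect_lt(hellinger(emp, ex), 0.01)
  # moments and limits
  expect_equal(sum((0:80) * ex) + attr(ex, "tail") * 80,
               alpha * b * tau, tolerance = 1e-3)
  expect_equal(as.numeric(model2_pmf(0.2, 0, 20, 40, N = 5)),
               c(1, rep(0, 5)))
  # automatic truncation keeps the tail below tolerance
  auto <- model2_pmf(alpha, b, tau, t = 40, tail_tol = 1e-10)
  expect_lt(attr(auto, "tail"), 1e-10)
})

test_that("bimodality bounds follow the analytic window and close at b = 1", {
  bd <- bimodality_bounds(0.5, 1)
  expect_equal(bd$tau_lower, 8)    # 4 / alpha
  expect_equal(bd$tau_upper, 8)
  expect_false(bd$feasible)
  bd2 <- bimodality_bounds(0.0282, 3.46)
  expect_equal(bd2$tau_lower, 91.4197, tolerance = 1e-4)
  expect_equal(bd2$tau_upper, 203.8659, tolerance = 1e-4)
  expect_true(bd2$feasible)
  expect_false(bimodality_bounds(1, 0.8)$feasible)
})

test_that("modality classification finds floored strict local maxima", {
  expect_equal(classify_modality(dpois(0:30, 5))$class, "unimodal")
  mix <- 0.5 * c(1, rep(0, 30)) + 0.5 * dpois(0:30, 8)
  md <- classify_modality(mix)
  expect_equal(md$class, "bimodal")
  expect_equal(md$modes[1], 0)
  expect_error(classify_modality(dpois(0:3, 10)), "outside the truncation")
  # inside the analytic window the bursty law is bimodal with a mode at zero
  pmf <- model2_pmf(0.0282, 3.46, 140, t = 280, N = 120)
  md2 <- classify_modality(pmf)
  expect_equal(md2$class, "bimodal")
  expect_equal(md2$modes[1], 0)
})

test_that("flux balance recovers first-order removal for Poisson input", {
  tau <- 5; rho <- 1.3
  P <- dpois(0:25, rho * tau)
  g <- effective_propensity_balance(P, alpha = rho, b = 0)
  expect_equal(g$g, g$n / tau, tolerance = 1e-10)
})

test_that("flux-balance propensities round-trip through the stationary solve", {
  ex <- model2_pmf(0.3, 3.46, 10, t = 20, N = 60)
  g <- effective_propensity_balance(ex, 0.3, 3.46)
  back <- stationary_from_propensity(g$g, 0.3, 3.46)
  expect_lt(0.5 * sum(abs(as.numeric(back) - as.numeric(ex) / sum(ex))), 1e-8)
  # masked where the pmf carries no mass
  short <- c(0.5, 0.5, 0, 0)
  gm <- effective_propensity_balance(short, 0.5, 0)
  expect_true(is.na(gm$g[2]))
})
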