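test_that("the known generator of constitutive expression is the lower-shift matrix", {
  rho <- 1.7
  net <- model_I(rho, 5)
  sp <- state_space(net, N = 2)
  asm <- build_known_generator(net, sp)
  expect_equal(as.matrix(asm$D),
               matrix(c(-rho, rho, 0, 0, -rho, rho, 0, 0, 0), 3, 3),
               ignore_attr = TRUE)
  expect_equal(as.numeric(Matrix::colSums(asm$D)), c(0, 0, 0))
})

test_that("state spaces enumerate gene-state-major with index 0 at the origin", {
  net1 <- model_I(1, 5)
  expect_equal(state_space(net1, N = 1)$size, 2L)
  net3 <- model_III(1, 1, 1, 5)
  expect_equal(state_space(net3, N = 9)$size,
               2L * state_space(net1, N = 9)$size)
  st <- nncme:::space_states(state_space(net3, N = 2))
  expect_equal(st$gene_state[1], "G")
  expect_equal(st$N[1], 0L)
  # automatic truncation lands near the Poisson tail cutoff
  sp_auto <- state_space(model_I(1, 5), N = NULL, tail_tol = 1e-8)
  expect_gte(sp_auto$N[["N"]], qpois(1 - 1e-8, 5))
  expect_lte(sp_auto$N[["N"]], 64L)
  expect_error(state_space(model_I(1, 500), N = NULL, hard_cap = 100),
               "set `N` manually")
})

test_that("burst jumps enter the generator at the geometric rates", {
  alpha <- 0.4; b <- 2.2
  net <- model_II(alpha, b, 5)
  sp <- state_space(net, N = 12)
  D <- as.matrix(build_known_generator(net, sp)$D)
  for (m in c(1, 3, 5))
    expect_equal(D[1 + m, 1], alpha * b^m / (1 + b)^(m + 1))
  expect_true(all(abs(Matrix::colSums(D)) < 1e-14))
})

test_that("assembling the learned part preserves column sums and positivity", {
  net <- model_I(1, 5)
  sp <- state_space(net, N = 10)
  asm <- build_known_generator(net, sp)
  A0 <- assemble_A(asm, rep(0, asm$n_out))
  expect_equal(as.matrix(A0), as.matrix(asm$D))
  g <- runif(asm$n_out)
  A <- assemble_A(asm, g)
  expect_equal(Matrix::colSums(A), Matrix::colSums(asm$D))
  offdiag <- as.matrix(A); diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
  expect_error(assemble_A(asm, -g), "negative")
  expect_error(assemble_A(asm, g[-1]), "mismatch")
})

test_that("first-order removal at rate 1/tau gives the conventional birth-death model", {
  net <- model_I(1, 5)
  sp <- state_space(net, N = 25)
  asm <- build_known_generator(net, sp)
  P <- fsp_steady_state(asm, nn = asm$r)
  expect_lt(0.5 * sum(abs(as.numeric(P) - dpois(0:25, 5))), 1e-8)
  expect_lt(attr(P, "residual"), 1e-10)
  # invariant to the starting point
  P2 <- fsp_steady_state(asm, nn = asm$r, P0 = dpois(0:25, 12) / sum(dpois(0:25, 12)))
  expect_lt(0.5 * sum(abs(as.numeric(P) - as.numeric(P2))), 1e-8)
})

test_that("transient integration agrees with the matrix exponential", {
  net <- model_I(1, 5)
  sp <- state_space(net, N = 25)
  asm <- build_known_generator(net, sp)
  g <- asm$r
  A <- as.matrix(assemble_A(asm, g))
  P0 <- c(1, rep(0, 25))
  Pe <- as.numeric(Matrix::expm(Matrix::Matrix(A * 3)) %*% P0)
  # RK4 is essentially exact; Euler is first order and halving dt halves the error
  Pr <- fsp_integrate(asm, g, P0, c(0, 3), stepper = "rk4", dt = 0.02)[, 2]
  expect_lt(max(abs(Pr - Pe)), 1e-8)
  e1 <- max(abs(fsp_integrate(asm, g, P0, c(0, 3), dt = 2e-3)[, 2] - Pe))
  e2 <- max(abs(fsp_integrate(asm, g, P0, c(0, 3), dt = 1e-3)[, 2] - Pe))
  expect_lt(e2, 1e-4)
  expect_gt(e1 / e2, 1.7)
  expect_lt(e1 / e2, 2.3)
  # probability mass is conserved by the reflecting FSP closure
  path <- fsp_integrate(asm, g, P0, seq(0, 10, by = 2), dt = 5e-3)
  expect_true(all(abs(colSums(path) - 1) < 1e-9))
  # a zero generator leaves the distribution untouched
  zero <- delay_network(
    species = "N",
    channels = list(reaction_channel(
      "production", list(kind = "const", rate = "rho"),
      init_stoich = c(N = 1L), completion_stoich = c(N = -1L),
      delay = delay_spec("fixed", 5))),
    params = list(rho = 0, tau = 5))
  asm0 <- build_known_generator(zero, state_space(zero, N = 5))
  Pz <- fsp_integrate(asm0, rep(0, asm0$n_out), dpois(0:5, 1) / sum(dpois(0:5, 1)),
                      c(0, 4), dt = 0.1)
  expect_equal(Pz[, 1], Pz[, 2])
})

test_that("a delayed channel cannot be declared known", {
  net <- model_I(1, 5)
  sp <- state_space(net, N = 5)
  expect_error(build_known_generator(net, sp, known = "production"),
               "learned")
})
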