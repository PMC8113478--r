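test_that("a zero-weight network is exactly first-order removal at rate 1/tau", {
  tau <- 5
  r <- (1:20) / tau
  nn <- nn_propensity(21, r, hidden = 8, seed = 1)
  nn$W1[] <- 0; nn$b1[] <- 0; nn$W2[] <- 0
  out <- nn_forward(nn, dpois(0:20, 5))
  expect_equal(out, r)
  expect_equal(out[10], 2)  # n = 10, tau = 5
})

test_that("outputs are nonnegative for arbitrary weights and inputs", {
  set.seed(99)
  for (rep in 1:20) {
    nn <- nn_propensity(12, (1:8) / 3, hidden = 5, seed = rep)
    nn$W1 <- nn$W1 * 40; nn$W2 <- nn$W2 * 40  # far from the small-init regime
    P <- runif(12); P <- P / sum(P)
    expect_true(all(nn_forward(nn, P) >= 0))
  }
  expect_error(nn_forward(nn_propensity(5, 1:3, hidden = 2), runif(9)),
               "n_in")
})

test_that("initial propensities start near the first-order baseline", {
  r <- (1:25) / 8
  devs <- vapply(1:10, function(s) {
    nn <- nn_propensity(26, r, hidden = 32, seed = s)
    max(abs(nn_forward(nn, dpois(0:25, 8)) - r) / r)
  }, numeric(1))
  expect_true(all(devs < 0.2))
  # deterministic given the seed, distinct across seeds
  expect_identical(nn_propensity(26, r, seed = 3), nn_propensity(26, r, seed = 3))
  expect_false(identical(nn_propensity(26, r, seed = 3)$W1,
                         nn_propensity(26, r, seed = 4)$W1))
})

test_that("model files round-trip losslessly through JSON", {
  nn <- nn_propensity(15, (1:9) / 4, hidden = 6, seed = 2)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_nn(nn, f)
  back <- read_nn(f)
  expect_equal(back, nn)
  P <- runif(15); P <- P / sum(P)
  expect_identical(nn_forward(nn, P), nn_forward(back, P))
  # version guard
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$version <- 99L
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(read_nn(f), "version")
})

test_that("backpropagated gradients match central finite differences", {
  net <- model_I(0.8, 4)
  sp <- state_space(net, N = 7)
  asm <- build_known_generator(net, sp)
  nn <- nncme:::nn_propensity(8, asm$r, hidden = 5, seed = 3)
  Dsl <- nncme:::sparse_slots(asm$D)
  P0 <- dpois(0:7, 1); P0 <- P0 / sum(P0)
  H <- cbind(dpois(0:7, 1.5), dpois(0:7, 2.2))
  H <- sweep(H, 2, colSums(H), "/")
  obs <- 0:7; snap <- c(10L, 20L)
  evalJ <- function(nn, grad = FALSE)
    nncme:::nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, P0, Dsl$p, Dsl$i, Dsl$x,
                           asm$src, asm$dst, asm$out, 0.05, snap, H, obs, 0L,
                           list(), grad)
  gr <- evalJ(nn, grad = TRUE)
  eps <- 1e-4
  set.seed(1)
  check_slot <- function(slot, gslot) {
    for (k in sample(length(nn[[slot]]), min(5, length(nn[[slot]])))) {
      np <- nn; np[[slot]][k] <- np[[slot]][k] + eps
      nm <- nn; nm[[slot]][k] <- nm[[slot]][k] - eps
      fd <- (evalJ(np)$J - evalJ(nm)$J) / (2 * eps)
      expect_lt(abs(fd - gr[[gslot]][k]) / max(abs(fd), 1e-8), 1e-5)
    }
  }
  check_slot("W1", "gW1")
  check_slot("W2", "gW2")
  check_slot("b1", "gb1")
})
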