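#' Specification of a free kinetic parameter
#'
#' @param name parameter name (must exist in the network's `params` and
#'   enter the known generator, e.g. the burst frequency or mean burst size).
#' @param init initial guess (inside the bounds).
#' @param lower,upper positive bounds.
#' @param log optimise on the log scale (default; kinetic rates are positive
#'   scale parameters).
#' @return a list of class `kinetic_param`.
#' @export
kinetic_param <- function(name, init, lower = init / 100, upper = init * 100,
                          log = TRUE) {
  stopifnot(lower > 0, upper > lower, init >= lower, init <= upper)
  structure(list(name = name, init = init, lower = lower, upper = upper,
                 log = log), class = "kinetic_param")
}

# shared pieces of a transient training problem that do not depend on the
# kinetic parameters
make_train_setup <- function(net, H, space, config, observed) {
  data_N <- attr(H, "N")
  data_gs <- attr(H, "gene_states")
  if (is.null(space)) {
    full_N <- setNames(rep(max(data_N), length(net$species)), net$species)
    full_N[names(data_N)] <- data_N
    full_N <- as.integer(ceiling(full_N * (1 + config$margin) + 2))
    space <- state_space(net, N = setNames(full_N, net$species))
  }
  asm0 <- build_known_generator(net, space)
  obs <- build_obs_map(space, data_N, observed, data_gs)
  hm <- hist_to_obs_matrix(H, obs, observed, data_gs)
  times <- hm$times
  dt <- config$dt
  if (is.null(dt)) {
    rate_scale <- max(abs(Matrix::diag(asm0$D))) + max(asm0$r, 1e-12)
    dt <- min(min(diff(times)) / 20, 0.05 / rate_scale)
  }
  rel <- times - times[1]
  snap_steps <- as.integer(round(rel / dt))
  snap_steps <- cummax(pmax(snap_steps, seq_along(snap_steps) - 1L))
  if (max(abs(rel - snap_steps * dt)) > 1e-6 * max(dt, 1e-12))
    dt <- rel[2] / snap_steps[2]
  P0 <- numeric(space$size)
  st <- space_states(space)
  gidx <- if (length(data_gs)) match(st$gene_state, data_gs) - 1L else 0L
  strides <- rev(cumprod(rev(c(obs$dims[-1L], 1L))))
  cnt <- as.matrix(st[, observed, drop = FALSE])
  inside <- rowSums(sweep(cnt, 2L, data_N[observed], ">")) == 0
  bin <- as.integer(cnt %*% strides) + gidx * as.integer(prod(obs$dims)) + 1L
  first <- !duplicated(bin) & inside
  P0[first] <- hm$H[bin[first], 1]
  list(space = space, asm = asm0, obs = obs, Hm = hm$H, times = times,
       dt = dt, snap_steps = snap_steps, P0 = P0, net = net)
}

# cached generator components for fast reassembly of D and its analytic
# parameter derivatives during joint optimisation
generator_cache <- function(net, space, free_names) {
  comps <- generator_components(net, space)
  for (nm in free_names) {
    touches <- any(vapply(comps, function(cp)
      identical(cp$rate, nm) || identical(cp$size, nm), logical(1)))
    if (!touches)
      stop("free parameter `", nm, "` does not enter the known generator ",
           "(only mass-action/burst rate and burst-size parameters can be ",
           "inferred)")
  }
  list(comps = comps, free = free_names, S = space$size)
}

generator_at <- function(cache, params) {
  D <- components_to_matrix(cache$comps, params, cache$S)
  derivs <- lapply(cache$free, function(nm) {
    w <- vapply(cache$comps, component_dweight, numeric(1),
                params = params, wrt = nm)
    sparse_slots(components_to_matrix(cache$comps, params, cache$S,
                                      weights = w))
  })
  names(derivs) <- cache$free
  list(D = D, derivs = derivs)
}

# joint ADAM over network weights and (log) kinetic parameters
joint_adam <- function(setup, nn, params, specs, loss_type, Hmat, epochs,
                       config, verbose = 0) {
  free_names <- names(specs)
  phi <- vapply(free_names, function(nm)
    if (specs[[nm]]$log) log(params[[nm]]) else params[[nm]], numeric(1))
  theta <- nn_flatten(nn)
  np <- length(theta)
  adam <- adam_init(np + length(phi))
  best <- list(J = Inf, theta = theta, phi = phi)
  hist_J <- numeric(epochs)
  J0 <- NA_real_
  used <- 0L
  cache <- generator_cache(setup$net, setup$space, free_names)
  for (ep in seq_len(max(epochs, 1L))) {
    for (q in seq_along(free_names)) {
      nm <- free_names[q]
      params[[nm]] <- if (specs[[nm]]$log) exp(phi[q]) else phi[q]
    }
    gen <- generator_at(cache, params)
    Dsl <- sparse_slots(gen$D)
    nn <- nn_unflatten(nn, theta)
    gr <- nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, setup$P0,
                         Dsl$p, Dsl$i, Dsl$x,
                         setup$asm$src, setup$asm$dst, setup$asm$out,
                         setup$dt, setup$snap_steps, Hmat,
                         setup$obs$map, loss_type, unname(gen$derivs), TRUE)
    J <- gr$J
    hist_J[ep] <- J; used <- ep
    if (ep == 1) J0 <- J
    if (is.finite(J) && J < best$J) best <- list(J = J, theta = theta, phi = phi)
    if (!is.finite(J)) stop("objective became non-finite during inference")
    if (verbose > 0 && ep %% verbose == 0)
      message("epoch ", ep, " J = ", signif(J, 6), "  ",
              paste(free_names, signif(vapply(free_names, function(nm)
                params[[nm]], numeric(1)), 4), collapse = " "))
    if (epochs == 0L) break
    gphi <- vapply(seq_along(free_names), function(q) {
      g <- gr$gkin[q]
      if (specs[[free_names[q]]]$log) g * exp(phi[q]) else g
    }, numeric(1))
    grad <- c(as.numeric(gr$gW1), as.numeric(gr$gb1), as.numeric(gr$gW2), gphi)
    adam <- adam_step(adam, grad, lr = config$lr, beta1 = config$beta1,
                      beta2 = config$beta2, eps = config$eps)
    theta <- theta + adam$delta[seq_len(np)]
    phi <- phi + adam$delta[np + seq_along(phi)]
    for (q in seq_along(free_names)) {
      sp <- specs[[free_names[q]]]
      rng <- if (sp$log) log(c(sp$lower, sp$upper)) else c(sp$lower, sp$upper)
      phi[q] <- min(max(phi[q], rng[1]), rng[2])
    }
  }
  for (q in seq_along(free_names)) {
    nm <- free_names[q]
    params[[nm]] <- if (specs[[nm]]$log) exp(best$phi[q]) else best$phi[q]
  }
  list(nn = nn_unflatten(nn, best$theta), params = params, J = best$J,
       loss_history = hist_J[seq_len(used)], theta = best$theta,
       phi = best$phi)
}

#' Joint inference of kinetic parameters and the NN-CME
#'
#' Treats unknown kinetic parameters of the known generator exactly like
#' network coefficients: ADAM simultaneously updates the network weights and
#' the (log-transformed) kinetic parameters to minimise the snapshot
#' objective, returning point estimates together with the co-trained NN-CME.
#'
#' @param net a [delay_network()] whose `params` hold the assumed/initial
#'   values (overridden by each [kinetic_param()]'s `init`).
#' @param free_params list of [kinetic_param()] specifications.
#' @param H a `snapshot_histogram` of the training data.
#' @param space optional [state_space()].
#' @param config a [training_config()].
#' @param verbose print progress every `verbose` epochs.
#' @return an object of class `nncme_inference` with `estimates` (tibble),
#'   the fitted network, the training setup (reused by
#'   [profile_likelihood()]), and the loss history.
#' @export
infer_kinetics <- function(net, free_params, H, space = NULL,
                           config = training_config(), verbose = 0) {
  if (inherits(free_params, "kinetic_param")) free_params <- list(free_params)
  specs <- setNames(free_params, vapply(free_params, `[[`, "", "name"))
  observed <- attr(H, "species")
  setup <- make_train_setup(net, H, space, config, observed)
  nn <- nn_propensity(setup$space$size, setup$asm$r, hidden = config$hidden,
                      seed = config$seed)
  params <- net$params
  for (nm in names(specs)) params[[nm]] <- specs[[nm]]$init
  res <- joint_adam(setup, nn, params, specs, 0L, setup$Hm,
                    config$epochs_max, config, verbose)
  est <- purrr::map_dfr(names(specs), function(nm) {
    sp <- specs[[nm]]
    v <- res$params[[nm]]
    tibble::tibble(param = nm, estimate = v, init = sp$init,
                   lower = sp$lower, upper = sp$upper,
                   at_bound = v <= sp$lower * (1 + 1e-6) ||
                     v >= sp$upper * (1 - 1e-6))
  })
  counts <- counts_matrix(H, setup)
  structure(list(estimates = est, nn = res$nn, params = res$params,
                 specs = specs, setup = setup, final_J = res$J,
                 loss_history = tibble::tibble(epoch = seq_along(res$loss_history),
                                               J = res$loss_history),
                 counts = counts, config = config, net = net),
            class = "nncme_inference")
}

counts_matrix <- function(H, setup) {
  ns <- attr(H, "n_samples")
  sweep(setup$Hm, 2L, as.numeric(ns[as.character(setup$times)]), `*`)
}

#' Profile likelihood and 95% confidence interval for an inferred parameter
#'
#' The pseudo-log-likelihood is a composite multinomial log-likelihood of
#' the observed per-snapshot counts under the model's snapshot
#' distributions. Because the same cells are recorded at every snapshot
#' (live-cell-style data, and exactly how the simulator produces
#' ensembles), the per-snapshot count vectors are not independent; treating
#' them as such would overstate the information by roughly the number of
#' snapshots. The composite likelihood is therefore scaled by `1 / N_shots`,
#' so the effective number of independent observations equals the number of
#' cells.
#'
#' For each grid value the parameter is fixed and all other unknowns
#' (network weights and remaining kinetic parameters) are re-optimised on
#' this objective. Every grid point is restarted from the joint optimum with
#' an identical epoch budget (rather than chaining warm starts along the
#' grid), so the residual optimisation error is comparable across the grid
#' and does not accumulate into a spurious trend. A quadratic in the
#' log-parameter is fitted to the profiled deviance to smooth that residual
#' noise; the 95% interval is the likelihood-ratio set
#' `2 (lhat - l(value)) <= qchisq(0.95, 1) = 3.84` of the smoothed profile,
#' with endpoints flagged open when the grid fails to bracket a crossing.
#'
#' @param inf an [infer_kinetics()] result.
#' @param param name of the profiled parameter.
#' @param grid grid of parameter values spanning the estimate (default: a
#'   multiplicative grid `estimate * exp(seq(-span, span, length n_grid))`).
#' @param n_grid,span default grid size and log half-width.
#' @param epochs re-optimisation epochs per grid point.
#' @param refine_epochs epochs used to refine the joint optimum on the
#'   composite-likelihood objective before profiling.
#' @return an object of class `profile_likelihood`: tibble of grid values,
#'   profile log-likelihoods and (raw and smoothed) deviances, the
#'   estimate, and `ci95`.
#' @export
profile_likelihood <- function(inf, param, grid = NULL, n_grid = 7,
                               span = 0.5, epochs = 400, refine_epochs = 600) {
  stopifnot(param %in% names(inf$specs))
  est <- inf$params[[param]]
  if (is.null(grid)) grid <- est * exp(seq(-span, span, length.out = n_grid))
  grid <- sort(unique(grid))
  counts <- inf$counts / ncol(inf$counts)  # composite-likelihood scaling
  cfg <- inf$config
  cfg$lr <- cfg$lr / 2  # gentler steps for refits near the optimum
  # refine the unconstrained optimum on the composite objective
  full <- joint_adam(inf$setup, inf$nn, inf$params, inf$specs, 1L, counts,
                     refine_epochs, cfg)
  l_hat <- -full$J
  est <- full$params[[param]]

  other <- inf$specs[setdiff(names(inf$specs), param)]
  prof <- vapply(grid, function(v) {
    params <- full$params
    params[[param]] <- v
    res <- joint_adam(inf$setup, full$nn, params, other, 1L, counts, epochs,
                      cfg)
    -res$J
  }, numeric(1))
  l_hat <- max(l_hat, max(prof))
  dev <- 2 * (l_hat - prof)
  # smooth the optimisation noise with a local quadratic in log(value):
  # only points near the minimum inform the curvature (the far arms of a
  # profile need not be parabolic and would bias the vertex)
  lx <- log(grid)
  thr0 <- stats::qchisq(0.95, 1)
  local_pts <- which(dev <= 10 * thr0)
  if (length(local_pts) < 4)
    local_pts <- order(dev)[seq_len(min(4, length(dev)))]
  qfit <- lm(dev ~ lx + I(lx^2), subset = local_pts)
  cf <- coef(qfit)
  dev_s <- if (is.na(cf[3]) || cf[3] <= 0) dev else {
    pmax(unname(cf[1] + cf[2] * lx + cf[3] * lx^2), 0)
  }
  dev_s <- dev_s - min(dev_s)
  thr <- stats::qchisq(0.95, 1)
  ci <- c(NA_real_, NA_real_)
  open <- c(FALSE, FALSE)
  if (!is.na(cf[3]) && cf[3] > 0) {
    # analytic roots of the smoothed parabola at the threshold
    vertex <- -cf[2] / (2 * cf[3])
    half <- sqrt(thr / cf[3])
    ci <- exp(c(vertex - half, vertex + half))
    # a vertex outside the scanned grid means the refits kept improving all
    # the way to an edge: the crossing on that side was not bracketed
    open[1] <- ci[1] < min(grid) * (1 - 1e-9)
    open[2] <- ci[2] > max(grid) * (1 + 1e-9)
    ci[1] <- min(max(ci[1], min(grid)), est)
    ci[2] <- max(min(ci[2], max(grid)), est)
    if (vertex < log(min(grid))) open[1] <- TRUE
    if (vertex > log(max(grid))) open[2] <- TRUE
  } else {
    inside <- which(dev_s <= thr)
    if (length(inside) > 0) {
      ci <- grid[range(inside)]
      open <- c(min(inside) == 1, max(inside) == length(grid))
    }
  }
  structure(list(param = param, estimate = est,
                 profile = tibble::tibble(value = grid, loglik = prof,
                                          deviance = dev,
                                          deviance_smooth = dev_s),
                 ci95 = ci, ci_open = open, l_hat = l_hat),
            class = "profile_likelihood")
}

#' Quantile-quantile comparison of two discrete distributions
#'
#' Matches the quantiles of two pmfs on a shared support at probability
#' levels `0.01..0.99` and reports the least-squares slope and intercept of
#' the quantile pairs (slope 1, intercept 0 for identical distributions).
#'
#' @param p,q probability vectors on `0..N` (padded to common length).
#' @param levels probability levels.
#' @return a list of class `qq_validation` with the `quantiles` tibble,
#'   `slope` and `intercept`.
#' @export
qq_validate <- function(p, q, levels = seq(0.01, 0.99, by = 0.01)) {
  p <- as.numeric(p); q <- as.numeric(q)
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p))); q <- c(q, rep(0, n - length(q)))
  qf <- function(pr, l) {
    cdf <- cumsum(pr) / sum(pr)
    vapply(l, function(x) which(cdf >= x - 1e-12)[1] - 1L, integer(1))
  }
  qp <- qf(p, levels); qq <- qf(q, levels)
  if (length(unique(qp)) < 2 || length(unique(qq)) < 2)
    stop("degenerate distribution in qq_validate")
  fit <- lm(qq ~ qp)
  structure(list(quantiles = tibble::tibble(level = levels, p = qp, q = qq),
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
            class = "qq_validation")
}
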