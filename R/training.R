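#' Squared-distance training objective between histograms and a solution
#'
#' `J = sum_j || H(t_j) - P(t_j) ||_2^2` over the snapshots the two share.
#'
#' @param H matrix of histogram probability vectors (bins x snapshots) or a
#'   `snapshot_histogram`.
#' @param P matrix of model probability vectors with matching shape.
#' @return nonnegative scalar.
#' @export
snapshot_loss <- function(H, P) {
  if (inherits(H, "snapshot_histogram"))
    H <- matrix(H$prob, ncol = length(unique(H$time)))
  H <- as.matrix(H); P <- as.matrix(P)
  if (!all(dim(H) == dim(P)))
    stop("histogram and solution shapes differ: ", paste(dim(H), collapse = "x"),
         " vs ", paste(dim(P), collapse = "x"))
  sum((H - P)^2)
}

#' Training configuration defaults
#'
#' @param dt Euler step; `NULL` selects
#'   `min(snapshot spacing / 20, 0.05 / max propensity scale)`.
#' @param stepper currently `"euler"` (the scheme that is differentiated).
#' @param epochs_max maximal ADAM epochs.
#' @param loss_threshold stop when the objective falls below this (defaults
#'   to `1e-5 * N_shots` at train time when `NULL`).
#' @param lr,beta1,beta2,eps ADAM hyperparameters.
#' @param weight_decay decoupled weight decay per epoch (AdamW-style),
#'   applied to the network weights only, never to kinetic parameters.
#'   Shrinking the weights pulls the learned propensities toward the fixed
#'   first-order baseline `r_n = n / tau`, which suppresses sampling-noise
#'   wiggles when training on small-sample histograms.
#' @param hidden hidden-layer width (tests and examples use narrower nets
#'   than the 128 default for speed).
#' @param seed initialisation seed.
#' @param margin extra state-space headroom above the data truncation, as a
#'   fraction of it.
#' @return a list of class `training_config`.
#' @export
training_config <- function(dt = NULL, stepper = "euler", epochs_max = 5000L,
                            loss_threshold = NULL, lr = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8, hidden = 128L,
                            seed = 1L, margin = 0.25, weight_decay = 0) {
  structure(list(dt = dt, stepper = stepper, epochs_max = as.integer(epochs_max),
                 loss_threshold = loss_threshold, lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, hidden = as.integer(hidden),
                 seed = as.integer(seed), margin = margin,
                 weight_decay = weight_decay),
            class = "training_config")
}

# build the observation map: each state-space index -> observed bin, where
# observed bins enumerate the (possibly marginal) data space with counts
# clipped at the data truncation
build_obs_map <- function(space, data_N, observed, data_gs) {
  st <- space_states(space)
  obs_dims <- data_N[observed] + 1L
  strides <- rev(cumprod(rev(c(obs_dims[-1L], 1L))))
  cnt <- as.matrix(st[, observed, drop = FALSE])
  cnt <- pmin(cnt, matrix(rep(data_N[observed], each = nrow(cnt)),
                          ncol = length(observed)))
  bin <- as.integer(cnt %*% strides)
  n_bins <- prod(obs_dims)
  if (length(data_gs)) {
    gidx <- match(st$gene_state, data_gs) - 1L
    bin <- bin + gidx * n_bins
    n_bins <- n_bins * length(data_gs)
  }
  list(map = bin, n_bins = as.integer(n_bins), dims = obs_dims)
}

# align a snapshot_histogram with the obs-bin enumeration -> bins x times
hist_to_obs_matrix <- function(hist, obs, observed, data_gs) {
  times <- unique(hist$time)
  H <- matrix(0, nrow = obs$n_bins, ncol = length(times))
  strides <- rev(cumprod(rev(c(obs$dims[-1L], 1L))))
  cnt <- as.matrix(hist[, observed, drop = FALSE])
  bin <- as.integer(cnt %*% strides)
  if (length(data_gs)) {
    gidx <- match(hist$gene_state, data_gs) - 1L
    bin <- bin + gidx * (obs$n_bins / length(data_gs))
  }
  H[cbind(bin + 1L, match(hist$time, times))] <- hist$prob
  list(H = H, times = times)
}

#' Train the NN-CME on snapshot histograms
#'
#' The three-step training loop: the delay-model histograms `H(t_j)` are the
#' data; the NN-CME is integrated by explicit Euler from `P(t_1) = H(t_1)`
#' (transient mode), re-evaluating the propensity network on the current
#' probability vector at every step; the squared-distance objective over the
#' snapshots is minimised by ADAM, with gradients obtained by exact
#' backpropagation through the unrolled integration. In steady mode the
#' objective is instead the collocation residual `|| A_theta(H) H ||^2` at
#' the single stationary histogram. When `observed_species` is a strict
#' subset of the network's species, the objective compares the corresponding
#' marginal of the integrated joint solution with the (marginal) data.
#'
#' @param net a [delay_network()].
#' @param H a `snapshot_histogram` (one time point for `mode = "steady"`).
#' @param space optional [state_space()]; defaults to the data truncation
#'   plus `margin` headroom per species.
#' @param mode `"transient"` or `"steady"`.
#' @param observed_species species present in `H` (default: all of them).
#' @param P0 initial probability vector on the full space for partial
#'   observation (default: point mass on the all-zero state in the first
#'   gene state); ignored when the data are fully observed, in which case
#'   `P(t_1) = H(t_1)`.
#' @param config a [training_config()].
#' @param verbose print the objective every `verbose` epochs (0: silent).
#' @return an object of class `nncme_fit`: the trained network (`nn`, at the
#'   best objective seen), `assembly`, `loss_history` tibble, fitted snapshot
#'   distributions, convergence flag, and the configuration.
#' @export
train_nncme <- function(net, H, space = NULL,
                        mode = c("transient", "steady"),
                        observed_species = NULL, P0 = NULL,
                        config = training_config(), verbose = 0) {
  mode <- match.arg(mode)
  observed <- observed_species %||% attr(H, "species")
  if (length(observed) == 0) stop("`observed_species` must be nonempty")
  if (!all(observed %in% net$species)) stop("unknown observed species")
  data_N <- attr(H, "N")
  data_gs <- attr(H, "gene_states")
  if (is.null(space)) {
    full_N <- setNames(rep(max(data_N), length(net$species)), net$species)
    full_N[names(data_N)] <- data_N
    full_N <- as.integer(ceiling(full_N * (1 + config$margin) + 2))
    space <- state_space(net, N = setNames(full_N, net$species))
  }
  asm <- build_known_generator(net, space)
  nn <- nn_propensity(space$size, asm$r, hidden = config$hidden,
                      seed = config$seed)
  if (mode == "steady") {
    return(train_steady_impl(net, H, asm, nn, observed, config, verbose))
  }

  obs <- build_obs_map(space, data_N, observed, data_gs)
  hm <- hist_to_obs_matrix(H, obs, observed, data_gs)
  times <- hm$times
  if (length(times) < 2) stop("transient training needs >= 2 snapshots")
  nshot <- length(times)

  fully_observed <- setequal(observed, net$species) &&
    length(data_gs) == length(space$gene_states)
  if (is.null(P0)) {
    if (fully_observed) {
      # embed H(t_1) into the (larger) model space
      P0 <- numeric(space$size)
      st <- space_states(space)
      gidx <- if (length(data_gs)) match(st$gene_state, data_gs) - 1L else 0L
      strides <- rev(cumprod(rev(c(obs$dims[-1L], 1L))))
      cnt <- as.matrix(st[, observed, drop = FALSE])
      inside <- rowSums(sweep(cnt, 2L, data_N[observed], ">")) == 0
      bin <- as.integer(cnt %*% strides) + gidx * as.integer(prod(obs$dims)) + 1L
      first <- !duplicated(bin) & inside
      P0[first] <- hm$H[bin[first], 1]
    } else {
      P0 <- numeric(space$size)
      P0[1] <- 1
    }
  }
  stopifnot(abs(sum(P0) - 1) < 1e-8)

  # uniform Euler grid hitting every snapshot time
  dt <- config$dt
  if (is.null(dt)) {
    rate_scale <- max(abs(Matrix::diag(asm$D))) + max(asm$r, 1e-12)
    dt <- min(min(diff(times)) / 20, 0.05 / rate_scale)
  }
  rel <- (times - times[1])
  snap_steps <- as.integer(round(rel / dt))
  snap_steps <- cummax(pmax(snap_steps, seq_along(snap_steps) - 1L))
  if (max(abs(rel - snap_steps * dt)) > 1e-6 * max(dt, 1e-12))
    dt <- rel[2] / snap_steps[2]  # snap to an exact divisor of the spacing

  Dsl <- sparse_slots(asm$D)
  loss_threshold <- config$loss_threshold %||% (1e-5 * nshot)

  theta <- nn_flatten(nn)
  adam <- adam_init(length(theta))
  hist_J <- numeric(config$epochs_max)
  best <- list(J = Inf, theta = theta)
  J0 <- NA_real_
  epochs <- 0L
  if (config$epochs_max == 0L) {
    ev <- nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, P0, Dsl$p, Dsl$i, Dsl$x,
                         asm$src, asm$dst, asm$out, dt, snap_steps, hm$H,
                         obs$map, 0L, list(), FALSE)
    best <- list(J = ev$J, theta = theta)
  }
  for (ep in seq_len(config$epochs_max)) {
    nn <- nn_unflatten(nn, theta)
    gr <- nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, P0,
                         Dsl$p, Dsl$i, Dsl$x,
                         asm$src, asm$dst, asm$out, dt, snap_steps, hm$H,
                         obs$map, 0L, list(), TRUE)
    J <- gr$J
    hist_J[ep] <- J
    epochs <- ep
    if (ep == 1) J0 <- J
    if (is.finite(J) && J < best$J) best <- list(J = J, theta = theta)
    if (!is.finite(J) || J > 10 * J0)
      stop("training diverged (J = ", signif(J, 4),
           "); lower the learning rate or reduce `dt`")
    if (verbose > 0 && ep %% verbose == 0)
      message("epoch ", ep, "  J = ", signif(J, 6))
    if (J < loss_threshold) break
    grad <- c(as.numeric(gr$gW1), as.numeric(gr$gb1), as.numeric(gr$gW2))
    adam <- adam_step(adam, grad, lr = config$lr, beta1 = config$beta1,
                      beta2 = config$beta2, eps = config$eps)
    theta <- theta + adam$delta - config$lr * config$weight_decay * theta
  }
  nn <- nn_unflatten(nn, best$theta)
  fin <- nncme_grad_cpp(nn$W1, nn$b1, nn$W2, nn$r, P0, Dsl$p, Dsl$i, Dsl$x,
                        asm$src, asm$dst, asm$out, dt, snap_steps, hm$H,
                        obs$map, 0L, list(), FALSE)
  structure(list(nn = nn, assembly = asm, space = space, net = net,
                 mode = "transient", times = times, dt = dt,
                 snap_steps = snap_steps, P0 = P0,
                 H = hm$H, obs = obs, observed = observed,
                 data_gs = data_gs,
                 P_snap = fin$P_snap, final_J = best$J,
                 loss_history = tibble::tibble(epoch = seq_len(epochs),
                                               J = hist_J[seq_len(epochs)]),
                 converged = best$J < loss_threshold,
                 config = config),
            class = "nncme_fit")
}

train_steady_impl <- function(net, H, asm, nn, observed, config, verbose) {
  if (!setequal(observed, net$species))
    stop("steady-state training requires fully observed species")
  space <- asm$space
  data_gs <- attr(H, "gene_states")
  if (length(unique(H$time)) != 1)
    stop("steady-state training expects a single stationary histogram")
  st <- space_states(space)
  gidx <- if (length(data_gs)) match(st$gene_state, data_gs) - 1L else 0L
  Hvec <- numeric(space$size)
  cnt_h <- as.matrix(H[, observed, drop = FALSE])
  gh <- if (length(data_gs)) match(H$gene_state, data_gs) - 1L else 0L
  Hvec[space_index(space, cnt_h, gh)] <- H$prob

  Dsl_H <- as.numeric(asm$D %*% Hvec)
  srcp <- asm$src + 1L; dstp <- asm$dst + 1L; outp <- asm$out + 1L
  Hsrc <- Hvec[srcp]
  S <- space$size
  loss_threshold <- config$loss_threshold %||% 1e-10

  theta <- nn_flatten(nn)
  adam <- adam_init(length(theta))
  hist_J <- numeric(config$epochs_max)
  best <- list(J = Inf, theta = theta)
  epochs <- 0L
  for (ep in seq_len(config$epochs_max)) {
    nn <- nn_unflatten(nn, theta)
    fwd <- nn_forward_full(nn, Hvec)
    f <- fwd$g[outp] * Hsrc
    res <- Dsl_H + rowsum_fast(f, dstp, S) - rowsum_fast(f, srcp, S)
    J <- sum(res^2)
    hist_J[ep] <- J; epochs <- ep
    if (J < best$J) best <- list(J = J, theta = theta)
    if (verbose > 0 && ep %% verbose == 0)
      message("epoch ", ep, "  residual J = ", signif(J, 6))
    if (J < loss_threshold) break
    dg <- rowsum_fast(2 * (res[dstp] - res[srcp]) * Hsrc, outp, nn$n_out)
    bk <- nn_backward(nn, Hvec, fwd, dg)
    grad <- c(as.numeric(bk$W1), bk$b1, as.numeric(bk$W2))
    adam <- adam_step(adam, grad, lr = config$lr, beta1 = config$beta1,
                      beta2 = config$beta2, eps = config$eps)
    theta <- theta + adam$delta
  }
  nn <- nn_unflatten(nn, best$theta)
  structure(list(nn = nn, assembly = asm, space = space, net = net,
                 mode = "steady", H_ss = Hvec, final_J = best$J,
                 loss_history = tibble::tibble(epoch = seq_len(epochs),
                                               J = hist_J[seq_len(epochs)]),
                 converged = best$J < loss_threshold,
                 config = config),
            class = "nncme_fit")
}

sparse_slots <- function(D) {
  D <- methods::as(D, "CsparseMatrix")
  list(p = D@p, i = D@i, x = D@x)
}

#' Learned propensities of a fitted NN-CME
#'
#' Evaluates the trained network on a probability vector (default: the last
#' fitted snapshot for transient fits, the stationary data for steady fits)
#' and returns the effective removal propensity per count level and head.
#'
#' @param fit an `nncme_fit`.
#' @param P optional probability vector to evaluate on.
#' @return tibble with columns `head`, `n`, `g`, and the baseline `r`.
#' @export
fitted_propensity <- function(fit, P = NULL) {
  if (is.null(P))
    P <- if (fit$mode == "steady") fit$H_ss else fit$P_snap[, ncol(fit$P_snap)]
  g <- nn_forward(fit$nn, P)
  heads <- fit$assembly$heads
  out <- purrr::map_dfr(names(heads), function(nm) {
    hd <- heads[[nm]]
    gs_names <- if (hd$n_heads > 1) fit$space$gene_states else nm
    purrr::map_dfr(seq_len(hd$n_heads), function(k) {
      idx <- hd$offset + (k - 1L) * hd$n_per_head + seq_len(hd$n_per_head)
      tibble::tibble(head = gs_names[k], n = seq_len(hd$n_per_head),
                     g = g[idx], r = fit$assembly$r[idx])
    })
  })
  out
}

#' Predict NN-CME snapshot distributions at given times
#'
#' Integrates the fitted NN-CME from its training initial condition to the
#' requested times with the training step size and scheme.
#'
#' @param object an `nncme_fit` (transient mode).
#' @param times increasing times (>= the training initial time).
#' @param ... unused.
#' @return matrix `space$size x length(times)`.
#' @export
predict.nncme_fit <- function(object, times = NULL, ...) {
  if (object$mode == "steady") {
    return(as.numeric(fsp_steady_state(object$assembly, object$nn)))
  }
  times <- times %||% object$times
  t_grid <- c(object$times[1], times[times > object$times[1]])
  out <- fsp_integrate(object$assembly, object$nn, object$P0, t_grid,
                       stepper = "euler", dt = object$dt)
  out[, match(times, t_grid), drop = FALSE]
}
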