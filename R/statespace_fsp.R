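#' Truncated state space for finite state projection
#'
#' Enumerates the truncated state space: gene-state-major, then species
#' counts in row-major order (first species slowest), so that index 0 is the
#' first gene state with all counts zero. With `N = NULL` the truncation is
#' chosen automatically: starting from a small guess, the per-species bound
#' is doubled until the steady-state solution of the baseline model (the
#' known generator plus first-order removal at rate `1/tau`, the
#' zero-weight-network limit) changes by less than `tail_tol` in total
#' variation.
#'
#' @param net a [delay_network()].
#' @param N truncation: scalar or named per-species vector of maximal counts,
#'   or `NULL` for automatic selection.
#' @param tail_tol total-variation tolerance for automatic selection.
#' @param hard_cap refuse automatic truncations beyond this many states.
#' @return an object of class `state_space`.
#' @export
state_space <- function(net, N = NULL, tail_tol = 1e-8, hard_cap = 2e5) {
  species <- net$species
  if (!is.null(N)) {
    if (length(N) == 1L) N <- setNames(rep(N, length(species)), species)
    return(new_state_space(net, setNames(as.integer(N[species]), species)))
  }
  N_try <- setNames(rep(8L, length(species)), species)
  prev <- NULL
  repeat {
    sp <- new_state_space(net, N_try)
    if (sp$size > hard_cap)
      stop("automatic truncation exceeded ", hard_cap,
           " states; set `N` manually")
    asm <- build_known_generator(net, sp)
    P <- fsp_steady_state(asm, nn = asm$r)
    if (!is.null(prev)) {
      # compare on the common (smaller) support by embedding
      common <- embed_pmf(prev$P, prev$space, sp)
      if (0.5 * sum(abs(common - as.numeric(P))) < tail_tol) return(prev$space)
    }
    prev <- list(space = sp, P = P)
    N_try <- N_try * 2L
  }
}

new_state_space <- function(net, N) {
  dims <- N + 1L
  n_gs <- max(1L, length(net$gene_states))
  k <- length(dims)
  strides <- rev(cumprod(rev(c(dims[-1L], 1L))))
  structure(list(species = net$species, gene_states = net$gene_states,
                 N = N, dims = dims, n_gs = n_gs,
                 strides = as.integer(strides),
                 block = as.integer(prod(dims)),
                 size = as.integer(n_gs * prod(dims))),
            class = "state_space")
}

# 1-based linear index from a matrix of counts (rows = states) + gene index
space_index <- function(space, counts, gidx = 0L) {
  counts <- matrix(as.integer(counts), ncol = length(space$dims))
  as.integer(counts %*% space$strides) + gidx * space$block + 1L
}

# tibble of all states in enumeration order
space_states <- function(space) {
  k <- length(space$dims)
  grid <- expand.grid(rev(lapply(space$dims, function(d) 0:(d - 1L))),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(k)), drop = FALSE]
  names(grid) <- space$species
  if (length(space$gene_states)) {
    grid <- do.call(rbind, replicate(space$n_gs, grid, simplify = FALSE))
    grid$gene_state <- rep(space$gene_states, each = space$block)
    grid <- grid[, c("gene_state", space$species), drop = FALSE]
  }
  tibble::as_tibble(grid)
}

# embed a pmf on a smaller truncation into a bigger space (zero-padded)
embed_pmf <- function(P, from, to) {
  st <- space_states(from)
  gidx <- if (length(from$gene_states)) match(st$gene_state, to$gene_states) - 1L else 0L
  idx <- space_index(to, as.matrix(st[, from$species, drop = FALSE]), gidx)
  out <- numeric(to$size)
  out[idx] <- as.numeric(P)
  out
}

#' Assemble the known part of the NN-CME generator
#'
#' Builds the sparse generator `D` containing every instantaneous event:
#' non-delayed channels, gene-state switching, and the initiation side of
#' delayed channels (single-molecule production shifts, or geometric burst
#' jumps of size `m` at rate `alpha * b^m / (1+b)^(m+1)`). Transitions that
#' would leave the truncation are dropped together with their diagonal
#' compensation (finite state projection closure), so every column of `D`
#' sums to zero. The delayed completions are *not* in `D`: they define the
#' learned-channel template — one removal transition per state with a
#' positive count of the delayed species, with one propensity output per
#' (gene state, count level) and fixed output biases `r_n = n / tau`.
#'
#' @param net a [delay_network()].
#' @param space a [state_space()] for `net`.
#' @param known optional channel names to treat as known; listing a delayed
#'   channel's completion as known is an error (delayed completions must be
#'   learned). Default: all initiations and non-delayed channels.
#' @return an object of class `generator_assembly` with elements `D` (sparse
#'   dgCMatrix), the learned-template index vectors `src`, `dst`, `out`
#'   (0-based), `n_out`, fixed biases `r`, and bookkeeping fields.
#' @export
build_known_generator <- function(net, space, known = NULL) {
  if (!is.null(known)) {
    for (nm in known) {
      ch <- net$channels[[match(nm, vapply(net$channels, `[[`, "", "name"))]]
      if (ch$delay$kind != "none")
        stop("delayed channel `", nm, "` cannot be treated as known: its ",
             "completion must be learned (or pre-eliminated)")
    }
  }
  comps <- generator_components(net, space)
  D <- components_to_matrix(comps, net$params, space$size)

  st <- as.matrix(space_states(space)[, space$species, drop = FALSE])
  n_states <- space$size
  gs_of <- rep(seq_len(space$n_gs) - 1L, each = space$block)

  # learned-channel template from delayed completions
  src <- integer(0); dst <- integer(0); outi <- integer(0)
  r <- numeric(0); heads <- list()
  n_out <- 0L
  for (ch in net$channels) {
    if (ch$delay$kind == "none") next
    comp <- stoich_vec(net, ch$completion_stoich)
    rem <- which(comp == -1L)
    if (length(rem) != 1L || any(comp < -1L) || sum(comp == 1L) > 1L ||
        any(!comp %in% c(-1L, 0L, 1L)))
      stop("learned completions must remove exactly one molecule of one ",
           "species (optionally producing one of another)")
    Nr <- space$N[[rem]]
    tau <- ch$delay$tau_mean
    cnt <- st[, rem]
    # target: apply completion stoich; a produced species at its boundary is
    # aggregated into the top bin so removal flux is conserved
    newc <- sweep(st, 2L, as.numeric(comp), `+`)
    newc <- pmin(newc, matrix(rep(space$N, each = n_states), ncol = ncol(st)))
    ok <- cnt >= 1L
    from <- which(ok)
    to <- space_index(space, newc[ok, , drop = FALSE], gs_of[ok])
    out_local <- (gs_of[ok]) * Nr + cnt[ok]  # 1-based within channel block
    src <- c(src, from - 1L)
    dst <- c(dst, to - 1L)
    outi <- c(outi, n_out + out_local - 1L)
    r <- c(r, rep(seq_len(Nr) / tau, times = space$n_gs))
    heads[[ch$name]] <- list(offset = n_out, n_per_head = Nr,
                             n_heads = space$n_gs, tau = tau,
                             species = space$species[rem])
    n_out <- n_out + space$n_gs * Nr
  }

  structure(list(space = space, net = net, D = D, components = comps,
                 src = src, dst = dst, out = outi,
                 n_out = n_out, r = r, heads = heads),
            class = "generator_assembly")
}

# decompose the known generator into sparse components with scalar weights:
# D(params) = sum_k w_k(params) * U_k. `rate` components have w = one rate
# parameter (unit-rate triplets include any linear count factor); `burst`
# components (one per jump size m) have w = alpha * b^m / (1+b)^(m+1);
# `fixed` components (hill/func propensities) have w = 1 with the parameters
# baked in. This makes reassembly and analytic parameter derivatives cheap
# during joint inference.
generator_components <- function(net, space) {
  st <- as.matrix(space_states(space)[, space$species, drop = FALSE])
  n_states <- space$size
  gs_of <- rep(seq_len(space$n_gs) - 1L, each = space$block)

  shift_targets <- function(stoich, gs_to = NULL) {
    newc <- sweep(st, 2L, as.numeric(stoich), `+`)
    inb <- rowSums(newc < 0) == 0 &
      rowSums(sweep(newc, 2L, space$N, ">")) == 0
    gs_new <- if (is.null(gs_to)) gs_of else rep(gs_to, n_states)
    list(idx = ifelse(inb, space_index(space, pmax(newc, 0L), gs_new),
                      NA_integer_),
         inb = inb)
  }
  active_mask <- function(ch) {
    act <- rep(TRUE, n_states)
    if (!is.na(ch$gene_state))
      act <- gs_of == (match(ch$gene_state, net$gene_states) - 1L)
    if (!is.na(ch$gene_from))
      act <- gs_of == (match(ch$gene_from, net$gene_states) - 1L)
    act
  }
  make_comp <- function(from, to, x_unit, kind, ch, rate = NULL, size = NULL,
                        m = NA_integer_) {
    keep <- x_unit > 0
    from <- from[keep]; to <- to[keep]; x_unit <- x_unit[keep]
    if (length(from) == 0) return(NULL)
    list(i = c(to, from), j = c(from, from), x = c(x_unit, -x_unit),
         kind = kind, channel = ch$name, rate = rate, size = size, m = m)
  }
  comps <- list()
  for (ch in net$channels) {
    pr <- ch$propensity
    act <- active_mask(ch)
    gs_to <- if (!is.na(ch$gene_to)) match(ch$gene_to, net$gene_states) - 1L
             else NULL
    if (pr$kind == "burst") {
      for (m in seq_len(max(space$N))) {
        tg <- shift_targets(m * stoich_vec(net, ch$init_stoich), gs_to)
        keep <- tg$inb & act
        cp <- make_comp(which(keep), tg$idx[keep],
                        rep(1, sum(keep)), "burst", ch,
                        rate = pr$rate, size = pr$size, m = m)
        if (!is.null(cp)) comps[[length(comps) + 1L]] <- cp
      }
    } else {
      stoich <- stoich_vec(net, ch$init_stoich)
      if (all(stoich == 0) && is.null(gs_to)) next
      x_unit <- switch(pr$kind,
        const = as.numeric(act),
        linear = st[, pr$species] * act,
        hill = (net$params[[pr$k]] /
                  (1 + (st[, pr$species] / net$params[[pr$K]])^net$params[[pr$h]])) * act,
        func = vapply(st[, pr$species], pr$f, numeric(1)) * act,
        stop("unknown propensity kind: ", pr$kind))
      kind <- if (pr$kind %in% c("const", "linear")) "rate" else "fixed"
      tg <- shift_targets(stoich, gs_to)
      x_unit[!tg$inb] <- 0
      cp <- make_comp(which(tg$inb & x_unit > 0), tg$idx[tg$inb & x_unit > 0],
                      x_unit[tg$inb & x_unit > 0], kind, ch,
                      rate = if (kind == "rate") pr$rate else NULL)
      if (!is.null(cp)) comps[[length(comps) + 1L]] <- cp
    }
  }
  comps
}

component_weight <- function(cp, params) {
  switch(cp$kind,
    fixed = 1,
    rate = params[[cp$rate]],
    burst = {
      b <- params[[cp$size]]
      params[[cp$rate]] * b^cp$m / (1 + b)^(cp$m + 1)
    })
}

# d weight / d params[[wrt]] (analytic)
component_dweight <- function(cp, params, wrt) {
  if (cp$kind == "rate")
    return(if (identical(cp$rate, wrt)) 1 else 0)
  if (cp$kind == "burst") {
    b <- params[[cp$size]]
    qm <- b^cp$m / (1 + b)^(cp$m + 1)
    if (identical(cp$rate, wrt)) return(qm)
    if (identical(cp$size, wrt))
      return(params[[cp$rate]] * qm * (cp$m / b - (cp$m + 1) / (1 + b)))
    return(0)
  }
  0
}

components_to_matrix <- function(comps, params, S, weights = NULL) {
  if (length(comps) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(S, S)))
  if (is.null(weights))
    weights <- vapply(comps, component_weight, numeric(1), params = params)
  keep <- which(weights != 0)
  if (length(keep) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(S, S)))
  i <- unlist(lapply(comps[keep], `[[`, "i"))
  j <- unlist(lapply(comps[keep], `[[`, "j"))
  x <- unlist(lapply(seq_along(keep), function(q)
    weights[keep[q]] * comps[[keep[q]]]$x))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(S, S))
}

# evaluate the learned propensity vector for an assembly: `nn` may be a
# numeric vector (fixed propensities), a function(P) -> g, or an
# nn_propensity object
eval_propensity <- function(nn, P, assembly) {
  g <- if (is.numeric(nn)) nn
       else if (inherits(nn, "nn_propensity")) nn_forward(nn, P)
       else nn(P)
  if (length(g) != assembly$n_out)
    stop("propensity vector has length ", length(g), ", expected ",
         assembly$n_out)
  if (any(g < -1e-12)) stop("negative learned propensity")
  pmax(g, 0)
}

#' Assemble the full NN-CME transition matrix
#'
#' `A = D + N_g` where the learned part `N_g` moves one molecule along each
#' template transition with propensity `g[out]`; its columns sum to zero, so
#' the column sums of `A` equal those of `D`.
#'
#' @param assembly a [build_known_generator()] result.
#' @param g nonnegative learned propensity vector of length `assembly$n_out`.
#' @return sparse `dgCMatrix`.
#' @export
assemble_A <- function(assembly, g) {
  if (length(g) != assembly$n_out) stop("dimension mismatch")
  if (any(g < 0)) stop("negative propensity entries violate the contract")
  S <- assembly$space$size
  gv <- g[assembly$out + 1L]
  NG <- Matrix::sparseMatrix(i = c(assembly$dst, assembly$src) + 1L,
                             j = c(assembly$src, assembly$src) + 1L,
                             x = c(gv, -gv), dims = c(S, S))
  assembly$D + NG
}

#' Integrate the NN-CME forward in time
#'
#' Solves `dP/dt = (D + N_g(P)) P` with the learned propensities re-evaluated
#' on the current probability vector at every step (the network input is
#' `P(t)` itself, making the generator time-inhomogeneous through the
#' solution). Explicit Euler by default; classical RK4 optionally.
#'
#' @param assembly a [build_known_generator()] result.
#' @param nn learned propensities: numeric vector, `function(P)`, or an
#'   `nn_propensity` object.
#' @param P0 initial probability vector (sums to 1) on the assembly's space.
#' @param t_grid increasing times at which the solution is returned (the
#'   first entry is the initial time).
#' @param stepper `"euler"` or `"rk4"`.
#' @param dt step size; default `min(min diff(t_grid)/20, 0.05/max rate)`.
#' @param leak_tol warn if total mass drifts more than this from 1.
#' @return matrix `space$size x length(t_grid)` of probability vectors.
#' @export
fsp_integrate <- function(assembly, nn, P0, t_grid,
                          stepper = c("euler", "rk4"), dt = NULL,
                          leak_tol = 1e-4) {
  stepper <- match.arg(stepper)
  P <- as.numeric(P0)
  if (abs(sum(P) - 1) > 1e-8) stop("P0 must sum to 1")
  if (is.null(dt)) {
    rate_scale <- max(abs(Matrix::diag(assembly$D))) +
      max(assembly$r, 1e-12)
    dt <- min(min(diff(t_grid)) / 20, 0.05 / rate_scale)
  }
  rhs <- function(P) {
    g <- eval_propensity(nn, P, assembly)
    f <- g[assembly$out + 1L] * P[assembly$src + 1L]
    dP <- as.numeric(assembly$D %*% P)
    dP_gain <- rowsum_fast(f, assembly$dst + 1L, length(P))
    dP_loss <- rowsum_fast(f, assembly$src + 1L, length(P))
    dP + dP_gain - dP_loss
  }
  out <- matrix(0, nrow = length(P), ncol = length(t_grid))
  out[, 1] <- P
  t <- t_grid[1]
  for (j in seq_along(t_grid)[-1]) {
    while (t < t_grid[j] - 1e-12) {
      h <- min(dt, t_grid[j] - t)
      if (stepper == "euler") {
        P <- P + h * rhs(P)
      } else {
        k1 <- rhs(P); k2 <- rhs(P + h / 2 * k1)
        k3 <- rhs(P + h / 2 * k2); k4 <- rhs(P + h * k3)
        P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t <- t + h
      mn <- min(P)
      if (mn < 0) {
        if (mn < -1e-8)
          stop("negative probabilities beyond tolerance (min = ", signif(mn, 3),
               "); reduce the step size `dt`")
        P[P < 0] <- 0
        P <- P / sum(P)
      }
    }
    if (abs(sum(P) - 1) > leak_tol)
      warning("FSP mass leak exceeds leak_tol at t = ", t_grid[j])
    out[, j] <- P
  }
  out
}

rowsum_fast <- function(x, idx, n) {
  out <- numeric(n)
  tab <- rowsum(x, idx)
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

#' Steady state of the NN-CME
#'
#' Solves `A_g(P) P = 0` (with normalisation) by damped null-space iteration:
#' at each iterate the propensities are frozen at the current `P`, the
#' null vector of the resulting generator is found by a sparse linear solve
#' with the normalisation row appended, and the new iterate is a damped
#' mixture. For state-independent propensities this converges in one step.
#'
#' @param assembly a [build_known_generator()] result.
#' @param nn learned propensities (vector, function, or `nn_propensity`).
#' @param tol convergence tolerance on the residual `max |A P|`.
#' @param damp damping weight on the new null vector.
#' @param max_iter maximal iterations.
#' @param P0 optional initial probability vector (default uniform).
#' @return a `pmf` vector on the assembly's space with attribute `residual`.
#' @export
fsp_steady_state <- function(assembly, nn, tol = 1e-10, damp = 0.5,
                             max_iter = 200, P0 = NULL) {
  S <- assembly$space$size
  P <- if (is.null(P0)) rep(1 / S, S) else as.numeric(P0)
  for (it in seq_len(max_iter)) {
    g <- eval_propensity(nn, P, assembly)
    A <- assemble_A(assembly, g)
    M <- A
    M[S, ] <- 1
    x <- tryCatch(as.numeric(Matrix::solve(M, c(rep(0, S - 1), 1))),
                  error = function(e) NULL)
    if (is.null(x)) {  # singular with normalisation in last row: perturb
      M <- A + Matrix::Diagonal(S, 1e-14)
      M[S, ] <- 1
      x <- as.numeric(Matrix::solve(M, c(rep(0, S - 1), 1)))
    }
    x <- pmax(x, 0)
    x <- x / sum(x)
    P_new <- (1 - damp) * P + damp * x
    res <- max(abs(as.numeric(A %*% P_new)))
    P <- P_new
    if (res < tol) {
      out <- new_pmf(P)
      attr(out, "residual") <- res
      return(out)
    }
  }
  stop("steady-state iteration did not converge: residual = ", signif(res, 3))
}
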