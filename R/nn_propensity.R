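#' Single-hidden-layer propensity network
#'
#' The learned removal propensities are produced by a perceptron with one
#' hidden layer: `g = relu(W2 tanh(W1 P + b1) + r)`, taking the current
#' probability vector `P` (length `n_in`) as input and emitting one
#' propensity per output unit (count level, per promoter-state head). The
#' output biases `r_n = n / tau` are fixed (never updated): a zero-weight
#' network is exactly first-order removal at rate `1/tau`, so the network
#' learns a residual correction to that baseline (ResNet-style), which also
#' keeps the outputs nonnegative through the final relu.
#'
#' @param n_in input dimension (truncated state-space size).
#' @param r fixed output bias vector (`n/tau` per head, as produced by
#'   [build_known_generator()]); its length sets the output dimension.
#' @param hidden hidden-layer width.
#' @param seed integer seed for the random initialisation.
#' @param init_scale weights are drawn uniformly in
#'   `+/- init_scale / sqrt(fan_in)`, so initial outputs stay near the
#'   first-order baseline `r`.
#' @return an object of class `nn_propensity`.
#' @export
nn_propensity <- function(n_in, r, hidden = 128L, seed = 1L,
                          init_scale = 0.1) {
  stopifnot(hidden >= 1, n_in >= 1, length(r) >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  n_out <- length(r)
  W1 <- matrix(runif(hidden * n_in, -1, 1) * init_scale / sqrt(n_in),
               nrow = hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(runif(n_out * hidden, -1, 1) * init_scale / sqrt(hidden),
               nrow = n_out)
  structure(list(W1 = W1, b1 = b1, W2 = W2, r = as.numeric(r),
                 hidden = as.integer(hidden), n_in = as.integer(n_in),
                 n_out = as.integer(n_out), seed = as.integer(seed)),
            class = "nn_propensity")
}

#' Evaluate the propensity network
#'
#' @param nn an [nn_propensity()] object.
#' @param P input probability vector (length `nn$n_in`).
#' @return nonnegative propensity vector of length `nn$n_out` (the propensity
#'   for removal out of the zero-count state is structurally zero and is not
#'   an output).
#' @export
nn_forward <- function(nn, P) {
  if (length(P) != nn$n_in)
    stop("input length ", length(P), " does not match n_in = ", nn$n_in)
  h <- tanh(as.numeric(nn$W1 %*% P) + nn$b1)
  pmax(as.numeric(nn$W2 %*% h) + nn$r, 0)
}

# forward pass keeping intermediates, and backward pass returning parameter
# gradients plus the input gradient, given dJ/dg
nn_forward_full <- function(nn, P) {
  a <- as.numeric(nn$W1 %*% P) + nn$b1
  h <- tanh(a)
  lin <- as.numeric(nn$W2 %*% h) + nn$r
  list(h = h, lin = lin, g = pmax(lin, 0))
}

nn_backward <- function(nn, P, fwd, dg) {
  v <- dg * (fwd$lin > 0)
  dW2 <- tcrossprod(v, fwd$h)
  dh <- as.numeric(crossprod(nn$W2, v))
  da <- dh * (1 - fwd$h^2)
  dW1 <- tcrossprod(da, P)
  list(W1 = dW1, b1 = da, W2 = dW2,
       dP = as.numeric(crossprod(nn$W1, da)))
}

# flatten / unflatten trainable parameters (r is fixed, excluded)
nn_flatten <- function(nn) c(as.numeric(nn$W1), nn$b1, as.numeric(nn$W2))

nn_unflatten <- function(nn, theta) {
  n1 <- length(nn$W1); nb <- length(nn$b1); n2 <- length(nn$W2)
  nn$W1 <- matrix(theta[seq_len(n1)], nrow = nn$hidden)
  nn$b1 <- theta[n1 + seq_len(nb)]
  nn$W2 <- matrix(theta[n1 + nb + seq_len(n2)], nrow = nn$n_out)
  nn
}

#' Write / read a propensity network as portable JSON
#'
#' The file stores the format version, the dimensions, the fixed biases and
#' all weights as plain JSON numbers (endianness-free text), so a model saved
#' on one machine loads identically anywhere.
#'
#' @param nn an `nn_propensity` object.
#' @param path file path.
#' @return `read_nn` returns the restored `nn_propensity`.
#' @export
write_nn <- function(nn, path) {
  obj <- list(format = "nncme-nn", version = 1L,
              n_in = nn$n_in, n_out = nn$n_out, hidden = nn$hidden,
              seed = nn$seed, r = nn$r,
              W1 = as.numeric(nn$W1), b1 = nn$b1, W2 = as.numeric(nn$W2))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nn
#' @export
read_nn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nncme-nn") || !identical(as.integer(obj$version), 1L))
    stop("unsupported model file format/version: ",
         obj$format %||% "?", " v", obj$version %||% "?")
  structure(list(W1 = matrix(obj$W1, nrow = obj$hidden),
                 b1 = obj$b1,
                 W2 = matrix(obj$W2, nrow = obj$n_out),
                 r = obj$r, hidden = as.integer(obj$hidden),
                 n_in = as.integer(obj$n_in), n_out = as.integer(obj$n_out),
                 seed = as.integer(obj$seed)),
            class = "nn_propensity")
}

# minimal ADAM optimiser state and update
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}
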