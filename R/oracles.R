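#' Exact distribution of constitutive transcription with delayed removal
#'
#' For production at rate `rho` with removal of each molecule exactly `tau`
#' after its birth, the molecules present at time `t` are precisely the
#' births in the window `(t - tau, t]`; births form a Poisson process, so the
#' count is Poisson with mean `rho * min(t, tau)` (stationary from `t = tau`
#' onwards).
#'
#' @param rho production rate.
#' @param tau removal delay.
#' @param t time (>= 0).
#' @param N truncation; `NULL` selects the smallest `N` with tail mass below
#'   `tail_tol`.
#' @param tail_tol tail-mass tolerance used when `N` is `NULL`.
#' @return a `pmf` object: numeric vector of probabilities on `0..N` with the
#'   (reported, not redistributed) truncation tail mass as attribute `tail`.
#' @export
model1_pmf <- function(rho, tau, t, N = NULL, tail_tol = 1e-10) {
  stopifnot(t >= 0)
  lam <- rho * min(t, tau)
  if (is.null(N)) N <- max(1L, qpois(1 - tail_tol, lam) + 2L)
  p <- dpois(0:N, lam)
  new_pmf(p)
}

new_pmf <- function(p) {
  structure(as.numeric(p), tail = max(0, 1 - sum(p)), class = "pmf")
}

#' Exact distribution of bursty transcription with delayed removal
#'
#' Burst events form a Poisson process at rate `alpha`; each event's
#' molecules (geometric size, mean `b`) are all removed one fixed delay `tau`
#' after the event. The molecules present at time `t` therefore belong to the
#' `K ~ Poisson(alpha * min(t, tau))` bursts in the window `(t - tau, t]`,
#' and the count is a compound Poisson of geometrics (Polya-Aeppli-type),
#' computed here as a Poisson mixture of negative binomials.
#'
#' @inheritParams model1_pmf
#' @param alpha burst frequency.
#' @param b mean burst size; burst sizes follow `P(i) = b^i/(1+b)^(i+1)`.
#' @return a `pmf` object on `0..N`.
#' @export
model2_pmf <- function(alpha, b, tau, t, N = NULL, tail_tol = 1e-10) {
  stopifnot(t >= 0, alpha > 0, b >= 0)
  lam <- alpha * min(t, tau)
  if (b == 0) {
    N <- N %||% 1L
    return(new_pmf(c(1, rep(0, N))))
  }
  if (is.null(N)) {
    # mean alpha*b*tau_eff; grow until tail small
    N <- max(4L, ceiling(lam * b + 10 * sqrt(max(lam * b * (1 + b), 1))))
    repeat {
      p <- polya_aeppli(lam, b, N)
      if (1 - sum(p) < tail_tol || N > 100000L) break
      N <- 2L * N
    }
    return(new_pmf(p))
  }
  new_pmf(polya_aeppli(lam, b, N))
}

polya_aeppli <- function(lam, b, N) {
  p <- 1 / (1 + b)
  kmax <- max(60, ceiling(lam + 12 * sqrt(lam) + 25))
  wk <- dpois(0:kmax, lam)
  out <- numeric(N + 1)
  out[1] <- wk[1]
  for (k in seq_len(kmax))
    out <- out + wk[k + 1] * dnbinom(0:N, size = k, prob = p)
  out
}

#' Delay window for delay-induced bimodality of bursty transcription
#'
#' For burst frequency `alpha` and mean burst size `b`, the steady-state
#' distribution of the bursty delay model develops a second mode (bimodality
#' with one mode at zero) exactly when the delay satisfies
#' `(2 + 2/b)/alpha < tau < (b + 1/b + 2)/alpha`, which is feasible only for
#' `b > 1`.
#'
#' @param alpha burst frequency (> 0).
#' @param b mean burst size (> 0).
#' @return a list with `tau_lower`, `tau_upper`, `feasible`.
#' @export
bimodality_bounds <- function(alpha, b) {
  stopifnot(alpha > 0, b > 0)
  lower <- (2 + 2 / b) / alpha
  upper <- (b + 1 / b + 2) / alpha
  list(tau_lower = lower, tau_upper = upper,
       feasible = b > 1 && lower < upper)
}

#' Classify the modality of a probability mass function
#'
#' Modes are local maxima of the pmf after ignoring bins below a probability
#' floor `eps` (which suppresses numerical ripples in near-zero tails). A
#' boundary bin counts as a mode when it exceeds its single neighbour.
#'
#' @param pmf numeric probability vector on `0..N` (mass inside the
#'   truncation must exceed 0.999).
#' @param eps probability floor below which bins are ignored.
#' @return a list with `class` (`"unimodal"`, `"bimodal"`, or `"multimodal"`)
#'   and `modes` (integer count values of the modes).
#' @export
classify_modality <- function(pmf, eps = 1e-4) {
  p <- as.numeric(pmf)
  if (sum(p) < 0.999)
    stop("more than 0.1% of the mass lies outside the truncation; increase N")
  n <- length(p)
  modes <- integer(0)
  i <- 1L
  while (i <= n) {
    if (p[i] < eps) { i <- i + 1L; next }
    # extend over a plateau of (numerically) equal values
    j <- i
    while (j < n && abs(p[j + 1] - p[i]) <= 1e-12 * max(p)) j <- j + 1L
    left <- if (i == 1L) -Inf else p[i - 1L]
    right <- if (j == n) -Inf else p[j + 1L]
    if (p[i] > left && p[i] > right) modes <- c(modes, i - 1L)
    i <- j + 1L
  }
  cls <- if (length(modes) <= 1L) "unimodal"
         else if (length(modes) == 2L) "bimodal" else "multimodal"
  list(class = cls, modes = modes)
}

#' Effective removal propensity by stationary flux balance
#'
#' Given a stationary distribution `P` of an effective master equation with
#' burst (or single) production input and one-at-a-time removal with
#' state-dependent propensity `g(n)`, summing the stationary equations for
#' `0..n-1` isolates the removal flux through the `n-1 | n` cut:
#' `g(n) P(n) = alpha * sum_{j < n} P(j) * Q(n - j)` where
#' `Q(k) = (b/(1+b))^k` is the burst-size tail probability (for Poisson
#' input, `b -> 0` limit, the right-hand side is `rho * P(n-1)` and for a
#' Poisson stationary law this reduces to `g(n) = n/tau` exactly).
#'
#' @param pmf_ss stationary pmf on `0..N`.
#' @param alpha burst (or production) rate.
#' @param b mean burst size; `b = 0` means single-molecule production at rate
#'   `alpha`.
#' @param mask_tol propensities at states with `P(n) <= mask_tol` are
#'   returned as `NA` (undefined rather than extrapolated; those bins carry
#'   no reliable flux information).
#' @return tibble with columns `n` (1..N) and `g` (propensity, `NA` where
#'   masked).
#' @export
effective_propensity_balance <- function(pmf_ss, alpha, b, mask_tol = 0) {
  P <- as.numeric(pmf_ss)
  N <- length(P) - 1L
  g <- rep(NA_real_, N)
  for (n in seq_len(N)) {
    flux <- if (b > 0) {
      r <- b / (1 + b)
      alpha * sum(P[1:n] * r^(n:1))
    } else {
      alpha * P[n]
    }
    if (P[n + 1] > mask_tol) g[n] <- flux / P[n + 1]
  }
  tibble::tibble(n = seq_len(N), g = g)
}

#' Stationary distribution of a burst-birth / state-dependent-death process
#'
#' Solves the stationary master equation with burst input (rate `alpha`,
#' geometric sizes of mean `b`) and removal propensity `g(n)`; used as the
#' round-trip check for [effective_propensity_balance()]. The recursion is
#' the same cut balance read forwards: `P(n) = flux(n) / g(n)`.
#'
#' @param g numeric removal propensity for `n = 1..N`.
#' @param alpha burst rate.
#' @param b mean burst size (`b = 0`: single-molecule input).
#' @return a `pmf` on `0..N` (normalised).
#' @export
stationary_from_propensity <- function(g, alpha, b) {
  N <- length(g)
  P <- numeric(N + 1)
  P[1] <- 1
  r <- if (b > 0) b / (1 + b) else 0
  for (n in seq_len(N)) {
    flux <- if (b > 0) alpha * sum(P[1:n] * r^(n:1)) else alpha * P[n]
    P[n + 1] <- flux / g[n]
  }
  new_pmf(P / sum(P))
}
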