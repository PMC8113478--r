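#' Hellinger distance between two probability mass functions
#'
#' `H(p, q) = sqrt(1 - sum_n sqrt(p_n q_n))` (Bhattacharyya form). Vectors of
#' different lengths are zero-padded; any mass missing from a truncated pmf
#' (`1 - sum`) is compared as one extra tail bin, which keeps the metric a
#' true distance on the completed space.
#'
#' @param p,q probability vectors (sums must not exceed 1 by more than
#'   `1e-6`; deficits are treated as truncation tail mass).
#' @return value in `[0, 1]`.
#' @export
hellinger <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (any(p < -1e-12) || any(q < -1e-12)) stop("negative probabilities")
  if (sum(p) > 1 + 1e-6 || sum(q) > 1 + 1e-6)
    stop("inputs are not (sub)normalised probability vectors")
  n <- max(length(p), length(q))
  p <- c(pmax(p, 0), rep(0, n - length(p)))
  q <- c(pmax(q, 0), rep(0, n - length(q)))
  bc <- sum(sqrt(p * q)) + sqrt(max(0, 1 - sum(p)) * max(0, 1 - sum(q)))
  sqrt(max(0, 1 - bc))
}

#' Linearity of an effective propensity
#'
#' Squared Pearson correlation between the count `n` and the propensity
#' `g(n)` over the supplied range: 1 for an exactly linear propensity, 0 for
#' a constant one.
#'
#' @param n count values (>= 3 distinct values).
#' @param g propensity values.
#' @return `R^2` in `[0, 1]`.
#' @export
r2_linearity <- function(n, g) {
  keep <- is.finite(n) & is.finite(g)
  n <- n[keep]; g <- g[keep]
  if (length(unique(n)) < 3) stop("need at least 3 distinct count values")
  if (sd(g) == 0) return(0)
  stats::cor(n, g)^2
}

#' Fit a Hill function to an effective propensity
#'
#' Least-squares fit of `g(n) = gmax n^h / (K^h + n^h)` over the requested
#' count range (by default the smallest prefix of counts holding 99% of the
#' stationary mass — the relevant molecule-number range), with multiple
#' starts over the Hill coefficient to avoid local minima.
#'
#' @param n count values.
#' @param g nonnegative propensity values.
#' @param range optional integer range `c(lo, hi)` restricting the fit.
#' @param starts Hill-coefficient starting values.
#' @return a list of class `hill_fit` with `gmax`, `K`, `h`, `r2`, `range`.
#' @export
fit_hill <- function(n, g, range = NULL, starts = c(0.3, 1, 3)) {
  keep <- is.finite(g)
  if (!is.null(range)) keep <- keep & n >= range[1] & n <= range[2]
  n <- n[keep]; g <- g[keep]
  if (any(g < 0)) stop("propensities must be nonnegative on the fit range")
  df <- data.frame(n = n, g = g)
  best <- NULL
  for (h0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(g ~ gmax * n^h / (K^h + n^h), data = df,
                        start = list(gmax = max(g) * 1.5,
                                     K = max(median(n), 1), h = h0),
                        lower = c(1e-10, 1e-10, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("Hill fit failed to converge on the requested range")
  cf <- coef(best$fit)
  tss <- sum((g - mean(g))^2)
  structure(list(gmax = unname(cf["gmax"]), K = unname(cf["K"]),
                 h = unname(cf["h"]),
                 r2 = if (tss > 0) 1 - best$rss / tss else 1,
                 range = range(n)),
            class = "hill_fit")
}

#' Count range holding a given probability mass
#'
#' Smallest prefix `0..n` of the support whose cumulative probability reaches
#' `mass`.
#'
#' @param pmf probability vector on `0..N`.
#' @param mass target cumulative mass.
#' @return upper count bound (integer).
#' @export
mass_range <- function(pmf, mass = 0.99) {
  which(cumsum(as.numeric(pmf)) >= mass)[1] - 1L
}

#' Phase diagram of delay-induced bimodality for bursty transcription
#'
#' Samples parameter points, classifies the modality of the exact (or
#' NN-CME) steady-state distribution, and compares each classification with
#' the analytic bimodality window of [bimodality_bounds()]. Points whose
#' delay lies within `boundary_margin` (relative) of either boundary are
#' flagged, mirroring the expected disagreement right at a phase boundary.
#'
#' @param alpha burst frequency.
#' @param b_range,tau_range ranges sampled log-uniformly.
#' @param n_points number of sampled parameter points.
#' @param seed sampling seed.
#' @param classify function `(b, tau) -> pmf` used for classification
#'   (default: the exact steady-state law [model2_pmf()]; pass a closure
#'   around a trained model to use NN-CME distributions instead).
#' @param boundary_margin relative distance to a boundary below which a
#'   point is flagged as near-boundary.
#' @return tibble with columns `b`, `tau`, `modality`, `predicted_bimodal`,
#'   `observed_bimodal`, `agrees`, `near_boundary`.
#' @export
phase_diagram <- function(alpha, b_range = c(0.5, 10), tau_range = c(10, 1000),
                          n_points = 200, seed = 1L, classify = NULL,
                          boundary_margin = 0.05) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  b <- exp(runif(n_points, log(b_range[1]), log(b_range[2])))
  tau <- exp(runif(n_points, log(tau_range[1]), log(tau_range[2])))
  if (is.null(classify))
    classify <- function(b, tau) model2_pmf(alpha, b, tau, t = 2 * tau)
  rows <- purrr::map_dfr(seq_len(n_points), function(i) {
    pmf <- classify(b[i], tau[i])
    md <- classify_modality(pmf)
    bd <- bimodality_bounds(alpha, b[i])
    pred <- bd$feasible && tau[i] > bd$tau_lower && tau[i] < bd$tau_upper
    near <- bd$feasible &&
      (abs(tau[i] - bd$tau_lower) < boundary_margin * bd$tau_lower ||
         abs(tau[i] - bd$tau_upper) < boundary_margin * bd$tau_upper)
    tibble::tibble(b = b[i], tau = tau[i], modality = md$class,
                   predicted_bimodal = pred,
                   observed_bimodal = md$class == "bimodal",
                   agrees = pred == (md$class == "bimodal"),
                   near_boundary = near)
  })
  rows
}

#' Generate the canned small snapshot fixtures
#'
#' Writes deterministic, seed-stamped snapshot CSV files (one row per cell:
#' `trajectory`, `time`, species columns) for the four preset models at test
#' scale, plus a JSON manifest with the seeds and parameters used.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @param n_traj trajectories per model.
#' @return tibble manifest (also written as `manifest.json`).
#' @export
fixture_suite <- function(dir, seed = 1L, n_traj = 1000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    model1 = list(net = preset_network("model1"), t_max = 20),
    model2 = list(net = preset_network("model2", alpha = 0.2, b = 3.46,
                                       tau = 20), t_max = 40),
    model3 = list(net = preset_network("model3", rho = 2.11, sigma_on = 0.282,
                                       sigma_off = 0.609, tau = 14),
                  t_max = 28),
    feedback = list(net = preset_network("feedback"), t_max = 30))
  manifest <- purrr::imap_dfr(specs, function(sp, nm) {
    times <- seq(0, sp$t_max, length.out = 11)[-1]
    s <- seed + match(nm, names(specs))
    ens <- simulate_delay_ssa(sp$net, times, n_traj = n_traj, seed = s)
    path <- file.path(dir, paste0(nm, "_snapshots.csv"))
    write.csv(as.data.frame(ens), path, row.names = FALSE)
    tibble::tibble(model = nm, file = basename(path), seed = s,
                   n_traj = n_traj, t_max = sp$t_max)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}
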