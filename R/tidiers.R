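#' Tidy a fitted NN-CME
#'
#' Returns the learned effective removal propensities per count level (and
#' promoter-state head), alongside the fixed first-order baseline `n / tau`.
#'
#' @param x an `nncme_fit`.
#' @param ... passed to [fitted_propensity()].
#' @return a tibble with columns `head`, `n`, `g`, `r`.
#' @export
tidy.nncme_fit <- function(x, ...) fitted_propensity(x, ...)

#' One-row summary of a fitted NN-CME
#'
#' @param x an `nncme_fit`.
#' @param ... unused.
#' @return a one-row tibble: mode, final objective, epochs run, convergence
#'   flag, state-space size, hidden width.
#' @export
glance.nncme_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, final_J = x$final_J,
                 epochs = nrow(x$loss_history), converged = x$converged,
                 n_states = x$space$size, hidden = x$nn$hidden)
}

#' @export
print.nncme_fit <- function(x, ...) {
  cat("<nncme_fit> ", x$mode, " training, ", nrow(x$loss_history),
      " epochs, final J = ", signif(x$final_J, 4),
      if (x$converged) " (converged)" else " (epoch limit)", "\n", sep = "")
  invisible(x)
}

#' Plot a fitted NN-CME
#'
#' `what = "loss"` shows the training objective per epoch (log scale);
#' `what = "propensity"` shows the learned removal propensity against the
#' first-order baseline `n / tau`; `what = "fit"` overlays the fitted
#' snapshot distributions on the training histograms (transient fits).
#'
#' @param object an `nncme_fit`.
#' @param what one of `"loss"`, `"propensity"`, `"fit"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nncme_fit <- function(object, what = c("loss", "propensity", "fit"),
                               ...) {
  what <- match.arg(what)
  if (what == "loss") {
    return(ggplot2::ggplot(object$loss_history,
                           ggplot2::aes(x = .data$epoch, y = .data$J)) +
             ggplot2::geom_line() + ggplot2::scale_y_log10() +
             ggplot2::labs(x = "epoch", y = "objective J"))
  }
  if (what == "propensity") {
    df <- fitted_propensity(object)
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
             ggplot2::geom_line(ggplot2::aes(y = .data$r),
                                linetype = "dashed", colour = "grey50") +
             ggplot2::geom_point(ggplot2::aes(y = .data$g)) +
             ggplot2::facet_wrap(~head) +
             ggplot2::labs(x = "molecule number n",
                           y = "effective removal propensity"))
  }
  if (object$mode != "transient") stop("`what = \"fit\"` needs a transient fit")
  nshot <- ncol(object$H)
  obs_P <- rowsum(object$P_snap, object$obs$map)
  df <- tibble::tibble(
    time = rep(object$times, each = nrow(object$H)),
    n = rep(seq_len(nrow(object$H)) - 1L, nshot),
    data = as.numeric(object$H),
    model = as.numeric(obs_P))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$data), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "red") +
    ggplot2::facet_wrap(~time, scales = "free_y") +
    ggplot2::labs(x = "count", y = "probability")
}

#' Tidy an inference result
#'
#' @param x an `nncme_inference`.
#' @param ... unused.
#' @return tibble of parameter estimates with bounds and bound flags.
#' @export
tidy.nncme_inference <- function(x, ...) x$estimates

#' @export
glance.nncme_inference <- function(x, ...) {
  tibble::tibble(final_J = x$final_J, epochs = nrow(x$loss_history),
                 n_free = nrow(x$estimates))
}

#' @export
print.nncme_inference <- function(x, ...) {
  cat("<nncme_inference> final J =", signif(x$final_J, 4), "\n")
  print(x$estimates)
  invisible(x)
}

#' Plot a profile likelihood
#'
#' Deviance `2 (lhat - l)` against the parameter value with the 95%
#' chi-squared threshold and interval endpoints.
#'
#' @param object a `profile_likelihood`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.profile_likelihood <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$value, y = .data$deviance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = stats::qchisq(0.95, 1),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ci95, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$param, y = "deviance")
}

#' @export
print.profile_likelihood <- function(x, ...) {
  cat("<profile_likelihood> ", x$param, ": estimate ", signif(x$estimate, 4),
      ", 95% CI [", signif(x$ci95[1], 4), ", ", signif(x$ci95[2], 4), "]",
      if (any(x$ci_open)) " (open endpoint)", "\n", sep = "")
  invisible(x)
}

#' Plot a quantile-quantile validation
#'
#' @param object a `qq_validation` from [qq_validate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qq_validation <- function(object, ...) {
  ggplot2::ggplot(object$quantiles, ggplot2::aes(x = .data$p, y = .data$q)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "model quantile", y = "reference quantile")
}

#' Plot snapshot histograms
#'
#' @param object a `snapshot_histogram` (single species).
#' @param ... unused.
#' @return a ggplot object faceted by time.
#' @export
autoplot.snapshot_histogram <- function(object, ...) {
  species <- attr(object, "species")
  if (length(species) != 1)
    stop("autoplot supports single-species histograms; marginalize() first")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[species]],
                                       y = .data$prob)) +
    ggplot2::geom_col() + ggplot2::facet_wrap(~time) +
    ggplot2::labs(x = species, y = "probability")
}
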