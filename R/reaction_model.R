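#' Delay specification for a reaction channel
#'
#' Describes when the completion (delayed) part of a reaction channel fires,
#' relative to the initiation event. A `"fixed"` delay fires exactly
#' `tau_mean` time units after initiation; a `"lognormal"` delay draws each
#' molecule's delay from a lognormal distribution parameterised by its mean
#' `tau_mean` and log-scale shape `sigma_log`, so that sweeps which increase
#' the delay variance at constant mean are one-parameter sweeps in
#' `sigma_log`.
#'
#' @param kind one of `"none"`, `"fixed"`, `"lognormal"`.
#' @param tau_mean mean delay (time units); required unless `kind = "none"`.
#' @param sigma_log lognormal shape parameter (standard deviation of the log
#'   delay); only used for `kind = "lognormal"`.
#' @return an object of class `delay_spec`.
#' @export
delay_spec <- function(kind = c("none", "fixed", "lognormal"),
                       tau_mean = NULL, sigma_log = 0) {
  kind <- match.arg(kind)
  if (kind != "none") {
    if (is.null(tau_mean) || !is.numeric(tau_mean) || tau_mean <= 0)
      stop("`tau_mean` must be a positive time for a ", kind, " delay")
  }
  if (kind == "lognormal" && (!is.numeric(sigma_log) || sigma_log < 0))
    stop("`sigma_log` must be >= 0")
  structure(list(kind = kind,
                 tau_mean = if (kind == "none") NA_real_ else as.numeric(tau_mean),
                 sigma_log = if (kind == "lognormal") as.numeric(sigma_log) else 0),
            class = "delay_spec")
}

# lognormal with mean tau_mean and sdlog sigma: meanlog = log(mean) - sigma^2/2
delay_meanlog <- function(spec) log(spec$tau_mean) - spec$sigma_log^2 / 2

#' Reaction channel of a delayed stochastic reaction network
#'
#' A channel fires with a state-dependent propensity; on firing its
#' `init_stoich` is applied immediately, and, for delayed channels, its
#' `completion_stoich` is applied once per initiated molecule after the delay
#' given by `delay`. Burst channels apply `init_stoich` once per molecule of a
#' geometrically distributed burst and schedule one completion per molecule.
#'
#' Supported propensity descriptions (all parameters are referenced by name
#' into the network's `params` list so that networks serialise cleanly):
#' \describe{
#'   \item{const}{`list(kind = "const", rate = "<param>")` — mass-action
#'     zeroth order.}
#'   \item{linear}{`list(kind = "linear", rate = "<param>", species = "<sp>")`
#'     — first order in one species.}
#'   \item{burst}{`list(kind = "burst", rate = "<param>", size = "<param>")` —
#'     burst events at the given rate with geometric size distribution
#'     `P(i) = b^i / (1 + b)^(i + 1)`, `i >= 0`, where `b` is the mean size.}
#'   \item{hill}{`list(kind = "hill", k = "<param>", K = "<param>",
#'     h = "<param>", species = "<sp>")` — repressive Hill function
#'     `k / (1 + (x / K)^h)` of one species count.}
#'   \item{func}{`list(kind = "func", f = <function(count)>, species = "<sp>")`
#'     — arbitrary nonnegative function of one species count (not
#'     serialisable to config files).}
#' }
#'
#' @param name channel name.
#' @param propensity propensity description list (see Details).
#' @param init_stoich named integer vector over species applied at firing.
#' @param completion_stoich named integer vector applied after the delay;
#'   omit (or all-zero) for non-delayed channels.
#' @param delay a [delay_spec()].
#' @param gene_state optional gene-state name the channel requires.
#' @param gene_from,gene_to optional gene-state switch performed at firing.
#' @return an object of class `reaction_channel`.
#' @export
reaction_channel <- function(name, propensity, init_stoich = NULL,
                             completion_stoich = NULL,
                             delay = delay_spec("none"),
                             gene_state = NA_character_,
                             gene_from = NA_character_,
                             gene_to = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(propensity) || is.null(propensity$kind))
    stop("`propensity` must be a list with a `kind` element")
  structure(list(name = name, propensity = propensity,
                 init_stoich = init_stoich,
                 completion_stoich = completion_stoich,
                 delay = delay, gene_state = gene_state,
                 gene_from = gene_from, gene_to = gene_to),
            class = "reaction_channel")
}

#' Delayed stochastic reaction network
#'
#' @param species character vector of species names (ordered; this order
#'   defines stoichiometry vectors and state enumeration).
#' @param channels list of [reaction_channel()] objects.
#' @param params named list of kinetic parameter values.
#' @param gene_states optional character vector of promoter/gene states; the
#'   first entry is the initial (reference) state.
#' @return an object of class `delay_network`.
#' @export
delay_network <- function(species, channels, params, gene_states = character(0)) {
  stopifnot(is.character(species), length(species) >= 1L)
  net <- structure(list(species = species, gene_states = gene_states,
                        channels = channels, params = params),
                   class = "delay_network")
  diag <- validate_network(net)
  bad <- diag[diag$level == "error", , drop = FALSE]
  if (nrow(bad) > 0)
    stop("invalid network: ", paste(bad$message, collapse = "; "))
  net
}

#' @export
print.delay_network <- function(x, ...) {
  cat("<delay_network> ", length(x$species), " species (",
      paste(x$species, collapse = ", "), ")",
      if (length(x$gene_states)) paste0(", gene states: ",
                                        paste(x$gene_states, collapse = ", ")),
      "\n", sep = "")
  for (ch in x$channels) {
    cat("  ", ch$name, ": ", ch$propensity$kind,
        if (ch$delay$kind != "none")
          paste0(" [", ch$delay$kind, " delay, tau = ", ch$delay$tau_mean, "]"),
        "\n", sep = "")
  }
  invisible(x)
}

stoich_vec <- function(net, named) {
  v <- setNames(integer(length(net$species)), net$species)
  if (!is.null(named)) v[names(named)] <- as.integer(named)
  v
}

#' Evaluate a channel propensity at a state
#'
#' @param net a [delay_network()].
#' @param channel a channel of `net` (or its name).
#' @param state named integer vector of species counts.
#' @param gene_state current gene-state name (if the network has gene states).
#' @return the (nonnegative) propensity value.
#' @export
channel_propensity <- function(net, channel, state, gene_state = NULL) {
  if (is.character(channel))
    channel <- net$channels[[match(channel, vapply(net$channels, `[[`, "", "name"))]]
  pr <- channel$propensity
  p <- net$params
  if (!is.na(channel$gene_state) && !identical(gene_state, channel$gene_state))
    return(0)
  if (!is.na(channel$gene_from) && !identical(gene_state, channel$gene_from))
    return(0)
  val <- switch(pr$kind,
    const  = p[[pr$rate]],
    linear = p[[pr$rate]] * state[[pr$species]],
    burst  = p[[pr$rate]],
    hill   = p[[pr$k]] / (1 + (state[[pr$species]] / p[[pr$K]])^p[[pr$h]]),
    func   = pr$f(state[[pr$species]]),
    stop("unknown propensity kind: ", pr$kind))
  as.numeric(val)
}

#' Constitutive transcription with delayed removal (Model I)
#'
#' Nascent RNA molecules are produced one at a time at rate `rho` (polymerase
#' binding as a Poisson process) and each molecule is removed exactly `tau`
#' time units after its birth (elongation plus termination modelled as a
#' deterministic delay).
#'
#' @param rho production rate (> 0, per unit time).
#' @param tau removal delay (> 0, time units).
#' @param delay optional [delay_spec()] overriding the fixed delay (e.g. a
#'   lognormal delay with mean `tau`).
#' @return a [delay_network()] with one species `"N"`.
#' @export
model_I <- function(rho, tau, delay = NULL) {
  if (!is.numeric(rho) || rho <= 0) stop("`rho` must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0")
  if (is.null(delay)) delay <- delay_spec("fixed", tau_mean = tau)
  delay_network(
    species = "N",
    channels = list(reaction_channel(
      "production", list(kind = "const", rate = "rho"),
      init_stoich = c(N = 1L), completion_stoich = c(N = -1L),
      delay = delay)),
    params = list(rho = rho, tau = tau))
}

#' Bursty transcription with delayed removal (Model II)
#'
#' Burst events occur at rate `alpha`; each event produces `i` molecules with
#' geometric probability `b^i / (1 + b)^(i + 1)` (mean burst size `b`), and
#' every molecule of the burst is removed one delay after the event. For a
#' fixed delay all molecules of a burst share the scheduled removal time; for
#' a lognormal delay each molecule draws its own delay.
#'
#' @param alpha burst frequency (> 0, per unit time).
#' @param b mean burst size (> 0, dimensionless).
#' @param tau removal delay (> 0, time units).
#' @param delay optional [delay_spec()] overriding the fixed delay.
#' @return a [delay_network()] with one species `"N"`.
#' @export
model_II <- function(alpha, b, tau, delay = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  if (!is.numeric(b) || b <= 0) stop("`b` must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0")
  if (is.null(delay)) delay <- delay_spec("fixed", tau_mean = tau)
  delay_network(
    species = "N",
    channels = list(reaction_channel(
      "burst", list(kind = "burst", rate = "alpha", size = "b"),
      init_stoich = c(N = 1L), completion_stoich = c(N = -1L),
      delay = delay)),
    params = list(alpha = alpha, b = b, tau = tau))
}

#' Telegraph (two-state) transcription with delayed removal (Model III)
#'
#' The promoter switches between an active state `G` and an inactive state
#' `Gstar`; polymerase binding (production of nascent RNA at rate `rho`)
#' occurs only in the active state; each molecule is removed a delay `tau`
#' after its birth. For `sigma_off >> sigma_on` the model approaches the
#' bursty Model II with burst frequency `sigma_on` and mean burst size
#' `rho / sigma_off`; for `sigma_off -> 0` it approaches Model I.
#'
#' @param rho production rate in the active state (> 0).
#' @param sigma_on activation rate `Gstar -> G` (> 0).
#' @param sigma_off inactivation rate `G -> Gstar` (> 0).
#' @param tau removal delay (> 0).
#' @param delay optional [delay_spec()] overriding the fixed delay.
#' @return a [delay_network()] with species `"N"` and gene states
#'   `c("G", "Gstar")` (active state first).
#' @export
model_III <- function(rho, sigma_on, sigma_off, tau, delay = NULL) {
  for (v in c(rho, sigma_on, sigma_off, tau))
    if (!is.numeric(v) || v <= 0) stop("all Model III parameters must be > 0")
  if (is.null(delay)) delay <- delay_spec("fixed", tau_mean = tau)
  delay_network(
    species = "N", gene_states = c("G", "Gstar"),
    channels = list(
      reaction_channel("production", list(kind = "const", rate = "rho"),
                       init_stoich = c(N = 1L), completion_stoich = c(N = -1L),
                       delay = delay, gene_state = "G"),
      reaction_channel("deactivate", list(kind = "const", rate = "sigma_off"),
                       gene_from = "G", gene_to = "Gstar"),
      reaction_channel("activate", list(kind = "const", rate = "sigma_on"),
                       gene_from = "Gstar", gene_to = "G")),
    params = list(rho = rho, sigma_on = sigma_on, sigma_off = sigma_off,
                  tau = tau))
}

#' Delayed negative feedback loop
#'
#' A protein `X` is produced with a `Y`-dependent (repressed) propensity
#' `J1(Y) + J2(Y)`; each `X` molecule matures into `Y` exactly `tau` time
#' units after its birth (delayed conversion `X -> Y`), and `Y` is degraded by
#' a first-order channel at rate `d_Y` (an explicit removal channel for the
#' mature protein is required for stationarity). `J1` and `J2` default to
#' repressive Hill functions `k / (1 + (Y / K)^h)` with parameters
#' `(k1, K1, h1)` and `(k2, K2, h2)`; arbitrary nonincreasing functions may be
#' supplied instead.
#'
#' @param tau maturation delay (> 0).
#' @param d_Y first-order degradation rate of `Y` (> 0).
#' @param params named list with elements `k1, K1, h1, k2, K2, h2` for the
#'   default Hill forms (any subset; missing values default to
#'   `k2 = 0`, i.e. a single transcription channel).
#' @param J1,J2 optional functions of the `Y` count overriding the Hill forms
#'   (must be nonnegative; a warning is emitted if they increase in `Y`).
#' @return a [delay_network()] with species `c("X", "Y")`.
#' @export
feedback_model <- function(tau, d_Y,
                           params = list(k1 = 2, K1 = 4, h1 = 2,
                                         k2 = 0, K2 = 4, h2 = 2),
                           J1 = NULL, J2 = NULL) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0")
  if (!is.numeric(d_Y) || d_Y <= 0) stop("`d_Y` must be > 0")
  defaults <- list(k1 = 2, K1 = 4, h1 = 2, k2 = 0, K2 = 4, h2 = 2)
  params <- modifyList(defaults, params)
  check_repressive <- function(f, label) {
    y <- 0:50
    v <- vapply(y, f, numeric(1))
    if (any(v < 0)) stop(label, " must be nonnegative")
    if (any(diff(v) > 1e-12))
      warning(label, " increases with Y; feedback is not repressive")
  }
  mk_channel <- function(label, f, kpar, Kpar, hpar) {
    if (!is.null(f)) {
      check_repressive(f, label)
      pr <- list(kind = "func", f = f, species = "Y")
    } else {
      pr <- list(kind = "hill", k = kpar, K = Kpar, h = hpar, species = "Y")
    }
    reaction_channel(label, pr,
                     init_stoich = c(X = 1L, Y = 0L),
                     completion_stoich = c(X = -1L, Y = 1L),
                     delay = delay_spec("fixed", tau_mean = tau))
  }
  channels <- list(mk_channel("tx1", J1, "k1", "K1", "h1"))
  if (!is.null(J2) || params$k2 > 0)
    channels <- c(channels, list(mk_channel("tx2", J2, "k2", "K2", "h2")))
  channels <- c(channels, list(
    reaction_channel("degY", list(kind = "linear", rate = "d_Y", species = "Y"),
                     init_stoich = c(X = 0L, Y = -1L))))
  delay_network(species = c("X", "Y"), channels = channels,
                params = c(params, list(d_Y = d_Y, tau = tau)))
}

#' Validate a delayed reaction network
#'
#' Pure report: checks stoichiometry lengths, parameter references, and delay
#' consistency, and returns a tibble of diagnostics (empty when the network is
#' valid). Never throws.
#'
#' @param net a [delay_network()] (or an unvalidated structure of the same
#'   shape).
#' @return a tibble with columns `level` (`"error"`/`"warning"`), `channel`,
#'   `message`.
#' @export
validate_network <- function(net) {
  out <- list()
  note <- function(level, channel, message)
    out[[length(out) + 1L]] <<- tibble::tibble(level = level, channel = channel,
                                               message = message)
  param_refs <- function(pr)
    unlist(pr[setdiff(names(pr), c("kind", "species", "f"))], use.names = FALSE)
  for (ch in net$channels) {
    for (st in list(ch$init_stoich, ch$completion_stoich)) {
      if (!is.null(st) && !all(names(st) %in% net$species))
        note("error", ch$name, "stoichiometry names outside species list")
    }
    for (ref in param_refs(ch$propensity)) {
      if (is.character(ref) && is.null(net$params[[ref]]))
        note("error", ch$name, paste0("missing parameter `", ref, "`"))
    }
    sp <- ch$propensity$species
    if (!is.null(sp) && !sp %in% net$species)
      note("error", ch$name, paste0("propensity references unknown species `",
                                    sp, "`"))
    comp <- stoich_vec(net, ch$completion_stoich)
    if (ch$delay$kind == "none" && any(comp != 0))
      note("error", ch$name, "completion stoichiometry nonzero without a delay")
    if (ch$delay$kind != "none" && all(comp == 0))
      note("warning", ch$name, "delayed channel with zero completion stoichiometry")
    for (gs in c(ch$gene_state, ch$gene_from, ch$gene_to)) {
      if (!is.na(gs) && !gs %in% net$gene_states)
        note("error", ch$name, paste0("unknown gene state `", gs, "`"))
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(level = character(), channel = character(),
                          message = character()))
  dplyr::bind_rows(out)
}

#' Serialize a network to a config list / YAML file
#'
#' The config schema has top-level keys `species`, `gene_states`, `params`,
#' and `channels`; each channel records its propensity description (by
#' parameter name), stoichiometries, delay, and gene-state fields. Networks
#' with `func`-kind propensities cannot be serialised.
#'
#' @param net a [delay_network()].
#' @param file optional path; when given, YAML is written there.
#' @return the config list, invisibly when `file` is given.
#' @export
network_to_config <- function(net, file = NULL) {
  for (ch in net$channels)
    if (ch$propensity$kind == "func")
      stop("channel `", ch$name, "` has a function propensity and cannot be ",
           "serialised; use a `hill` or tabulated form instead")
  cfg <- list(
    species = as.list(net$species),
    gene_states = as.list(net$gene_states),
    params = net$params,
    channels = lapply(net$channels, function(ch) {
      list(name = ch$name, propensity = ch$propensity,
           init_stoich = as.list(ch$init_stoich),
           completion_stoich = as.list(ch$completion_stoich),
           delay = list(kind = ch$delay$kind, tau_mean = ch$delay$tau_mean,
                        sigma_log = ch$delay$sigma_log),
           gene_state = ch$gene_state, gene_from = ch$gene_from,
           gene_to = ch$gene_to)
    }))
  if (!is.null(file)) {
    yaml::write_yaml(cfg, file)
    return(invisible(cfg))
  }
  cfg
}

#' Deserialize a network from a config list / YAML file
#'
#' @param cfg a config list as produced by [network_to_config()], or a path
#'   to a YAML file of that schema.
#' @return a [delay_network()].
#' @export
network_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  as_stoich <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    setNames(as.integer(unlist(x)), names(x))
  }
  chans <- lapply(cfg$channels, function(ch) {
    d <- ch$delay
    spec <- if (identical(d$kind, "none")) delay_spec("none") else
      delay_spec(d$kind, tau_mean = d$tau_mean, sigma_log = d$sigma_log %||% 0)
    reaction_channel(ch$name, ch$propensity,
                     init_stoich = as_stoich(ch$init_stoich),
                     completion_stoich = as_stoich(ch$completion_stoich),
                     delay = spec,
                     gene_state = ch$gene_state %||% NA_character_,
                     gene_from = ch$gene_from %||% NA_character_,
                     gene_to = ch$gene_to %||% NA_character_)
  })
  delay_network(species = unlist(cfg$species), channels = chans,
                params = cfg$params,
                gene_states = as.character(unlist(cfg$gene_states)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a) && !is.character(a))) b else a

#' Construct a preset network by name
#'
#' @param name one of `"model1"`, `"model2"`, `"model3"`, `"feedback"`.
#' @param ... parameters forwarded to the preset constructor
#'   ([model_I()], [model_II()], [model_III()], [feedback_model()]); defaults
#'   are supplied where omitted.
#' @return a [delay_network()].
#' @export
preset_network <- function(name, ...) {
  args <- list(...)
  switch(name,
    model1 = do.call(model_I, modifyList(list(rho = 1, tau = 10), args)),
    model2 = do.call(model_II, modifyList(list(alpha = 0.0282, b = 3.46,
                                               tau = 140), args)),
    model3 = do.call(model_III, modifyList(list(rho = 2.11, sigma_on = 0.0282,
                                                sigma_off = 0.609, tau = 140),
                                           args)),
    feedback = do.call(feedback_model, modifyList(list(tau = 6, d_Y = 0.8),
                                                  args)),
    stop("unknown preset `", name, "`"))
}
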