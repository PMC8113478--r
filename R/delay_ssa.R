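# compile a delay_network into the flat channel descriptors the C++ SSA core
# consumes; hill/func propensities are tabulated over 0..table_cap counts
compile_network <- function(net, table_cap = 4096L) {
  sp_idx <- function(s) match(s, net$species) - 1L
  gs_idx <- function(g) if (is.na(g)) -1L else match(g, net$gene_states) - 1L
  lapply(net$channels, function(ch) {
    pr <- ch$propensity
    kind <- switch(pr$kind, const = 0L, linear = 1L, burst = 2L,
                   hill = 3L, func = 3L,
                   stop("unknown propensity kind: ", pr$kind))
    tab <- numeric(0)
    species <- -1L
    rate <- 0
    bmean <- 0
    if (pr$kind %in% c("const", "linear", "burst"))
      rate <- as.numeric(net$params[[pr$rate]])
    if (pr$kind == "burst") bmean <- as.numeric(net$params[[pr$size]])
    if (pr$kind %in% c("linear", "hill", "func")) species <- sp_idx(pr$species)
    if (pr$kind == "hill") {
      x <- 0:table_cap
      tab <- net$params[[pr$k]] / (1 + (x / net$params[[pr$K]])^net$params[[pr$h]])
    }
    if (pr$kind == "func") tab <- vapply(0:table_cap, pr$f, numeric(1))
    d <- ch$delay
    list(kind = kind, rate = rate, bmean = bmean, species = species,
         table = tab,
         init = unname(stoich_vec(net, ch$init_stoich)),
         comp = unname(stoich_vec(net, ch$completion_stoich)),
         delay_kind = switch(d$kind, none = 0L, fixed = 1L, lognormal = 2L),
         tau = if (is.na(d$tau_mean)) 0 else d$tau_mean,
         meanlog = if (d$kind == "lognormal") delay_meanlog(d) else 0,
         sdlog = d$sigma_log,
         gene_req = gs_idx(ch$gene_state),
         gene_from = gs_idx(ch$gene_from),
         gene_to = gs_idx(ch$gene_to))
  })
}

#' Simulate a delayed reaction network with the exact delay SSA
#'
#' Exact stochastic simulation with a priority queue of scheduled delayed
#' completions: the next instantaneous firing time is drawn from the current
#' total propensity, and whenever the earliest queued completion precedes it
#' the simulation advances to the completion and redraws. States are recorded
#' at the requested times (the state immediately before any event at exactly
#' a record time).
#'
#' @param net a [delay_network()].
#' @param record_times strictly increasing vector of recording times.
#' @param n_traj number of independent trajectories (>= 1).
#' @param seed integer seed (the ensemble is reproducible given
#'   `(net, record_times, n_traj, seed)`).
#' @param init_state named integer vector of initial counts (default: all
#'   zero).
#' @param init_gene_state initial gene state name (default: the first listed,
#'   e.g. the active state for the telegraph model).
#' @return a tibble of class `delay_trajectories` with columns `trajectory`,
#'   `time`, one column per species, and `gene_state` when the network has
#'   gene states; the network and seed are kept as attributes.
#' @export
simulate_delay_ssa <- function(net, record_times, n_traj, seed = 1L,
                               init_state = NULL, init_gene_state = NULL) {
  stopifnot(n_traj >= 1, length(record_times) >= 1,
            all(diff(record_times) > 0), all(record_times >= 0))
  ns <- length(net$species)
  x0 <- setNames(integer(ns), net$species)
  if (!is.null(init_state)) x0[names(init_state)] <- as.integer(init_state)
  gs0 <- 0L
  if (length(net$gene_states)) {
    gname <- init_gene_state %||% net$gene_states[1]
    gs0 <- match(gname, net$gene_states) - 1L
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  arr <- ssa_run_cpp(compile_network(net), ns, length(net$gene_states),
                     as.numeric(record_times), as.integer(n_traj),
                     unname(x0), gs0)
  n_rec <- length(record_times)
  has_gs <- length(net$gene_states) > 0
  n_cols <- ns + has_gs
  m <- matrix(as.integer(arr), nrow = n_cols)  # columns: (time within traj)
  df <- tibble::tibble(
    trajectory = rep(seq_len(n_traj), each = n_rec),
    time = rep(as.numeric(record_times), times = n_traj))
  for (s in seq_len(ns)) df[[net$species[s]]] <- m[s, ]
  if (has_gs) df$gene_state <- net$gene_states[m[ns + 1L, ] + 1L]
  structure(df, class = c("delay_trajectories", class(df)),
            net = net, seed = seed)
}

#' Empirical snapshot histograms from a trajectory ensemble
#'
#' Converts an ensemble into per-time empirical distributions on a truncated
#' state space (the paper-style training data `H(t)`): for each requested
#' time the species counts across trajectories are tabulated into
#' probabilities on `0..N` per species (jointly for multi-species networks),
#' stratified by gene state when present. Counts above `N` are aggregated
#' into the top bin with a warning.
#'
#' @param ens a `delay_trajectories` tibble from [simulate_delay_ssa()].
#' @param times subset of the ensemble's record times (default: all).
#' @param N truncation (scalar, or named per-species vector); default: the
#'   maximum observed count per species.
#' @return a tibble of class `snapshot_histogram` with columns `time`, one
#'   count column per species, `gene_state` (when present), and `prob`; the
#'   truncation, per-time sample sizes, species names, and provenance seed
#'   are attributes.
#' @export
snapshots_from_ensemble <- function(ens, times = NULL, N = NULL) {
  if (nrow(ens) == 0) stop("empty ensemble")
  net <- attr(ens, "net")
  species <- net$species
  if (is.null(times)) times <- unique(ens$time)
  if (!all(times %in% unique(ens$time)))
    stop("`times` must be a subset of the ensemble's record times")
  has_gs <- "gene_state" %in% names(ens)
  maxobs <- vapply(species, function(s) max(ens[[s]]), numeric(1))
  if (is.null(N)) N <- maxobs
  if (length(N) == 1L) N <- setNames(rep(N, length(species)), species)
  N <- setNames(as.integer(N[species]), species)
  if (any(maxobs > N))
    warning("counts above the truncation were aggregated into bin N")
  sub <- ens[ens$time %in% times, , drop = FALSE]
  for (s in species) sub[[s]] <- pmin(sub[[s]], N[[s]])
  grid <- expand.grid(c(list(time = as.numeric(times)),
                        if (has_gs) list(gene_state = net$gene_states),
                        lapply(N, function(n) 0:n)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- tibble::as_tibble(grid[, c("time", species,
                                     if (has_gs) "gene_state"), drop = FALSE])
  tab <- dplyr::count(sub, dplyr::across(dplyr::all_of(
    c("time", species, if (has_gs) "gene_state"))))
  n_samples <- dplyr::count(sub, .data$time, name = "n_samples")
  out <- dplyr::left_join(grid, tab,
                          by = c("time", species, if (has_gs) "gene_state"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::left_join(out, n_samples, by = "time")
  out$prob <- out$n / out$n_samples
  ns_vec <- setNames(n_samples$n_samples, n_samples$time)
  out <- dplyr::arrange(out, .data$time)
  out$n <- NULL
  out$n_samples <- NULL
  structure(out, class = c("snapshot_histogram", class(out)),
            N = N, species = species, gene_states = net$gene_states,
            n_samples = ns_vec, seed = attr(ens, "seed"))
}

#' Marginalize a snapshot histogram over unobserved species
#'
#' Sums probabilities over all species not listed in `observed` (and over
#' gene states); total mass per time point is preserved.
#'
#' @param hist a `snapshot_histogram`.
#' @param observed character vector of retained species names.
#' @return a `snapshot_histogram` over the observed species only.
#' @export
marginalize <- function(hist, observed) {
  species <- attr(hist, "species")
  if (!all(observed %in% species)) stop("unknown species in `observed`")
  out <- dplyr::summarise(
    dplyr::group_by(hist, dplyr::across(dplyr::all_of(c("time", observed)))),
    prob = sum(.data$prob), .groups = "drop")
  structure(tibble::as_tibble(out),
            class = c("snapshot_histogram", class(tibble::tibble())),
            N = attr(hist, "N")[observed], species = observed,
            gene_states = character(0),
            n_samples = attr(hist, "n_samples"), seed = attr(hist, "seed"))
}

#' Build a snapshot histogram directly from a data frame of counts
#'
#' Convenience for snapshot data read from delimited text (columns: `time`,
#' one column per species, one row per cell); see the README for the format.
#'
#' @param df data frame with a `time` column and one integer column per
#'   species.
#' @param species species column names (default: all non-`time` columns).
#' @param N truncation as in [snapshots_from_ensemble()].
#' @return a `snapshot_histogram`.
#' @export
snapshots_from_counts <- function(df, species = setdiff(names(df), c("time", "trajectory", "gene_state")),
                                  N = NULL) {
  ens <- tibble::as_tibble(df)
  if (is.null(ens$trajectory)) ens$trajectory <- seq_len(nrow(ens))
  ens <- structure(ens, class = c("delay_trajectories", class(ens)),
                   net = list(species = species, gene_states = character(0)),
                   seed = NA_integer_)
  snapshots_from_ensemble(ens, N = N)
}

# snapshot histogram -> dense matrix (space enumeration x time), aligned with
# a truncated state space (see state_space())
hist_to_matrix <- function(hist, space) {
  species <- attr(hist, "species")
  gs <- attr(hist, "gene_states")
  times <- unique(hist$time)
  H <- matrix(0, nrow = space$size, ncol = length(times))
  counts <- as.matrix(hist[, species, drop = FALSE])
  gidx <- if (length(gs)) match(hist$gene_state, gs) - 1L else 0L
  idx <- space_index(space, counts, gidx)
  tcol <- match(hist$time, times)
  H[cbind(idx, tcol)] <- hist$prob
  list(H = H, times = times)
}
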