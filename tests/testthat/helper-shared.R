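# shared fixtures, computed lazily and cached for the duration of a test file
.shared <- new.env(parent = emptyenv())

shared <- function(name, fn) {
  if (is.null(.shared[[name]])) .shared[[name]] <- fn()
  .shared[[name]]
}

# wrap a bins x times probability matrix as a snapshot_histogram (used to
# train on exact, noise-free distributions)
exact_hist <- function(times, mat, species = "N", n_samples = 1e9) {
  N <- nrow(mat) - 1L
  df <- tibble::tibble(
    time = rep(times, each = N + 1L),
    n = rep(0:N, length(times)),
    prob = as.numeric(mat))
  names(df)[2] <- species
  structure(df, class = c("snapshot_histogram", class(tibble::tibble())),
            N = stats::setNames(N, species), species = species,
            gene_states = character(0),
            n_samples = stats::setNames(rep(n_samples, length(times)), times),
            seed = NA_integer_)
}

# a small trained Model I transient fit on noisy histograms, reused by
# several training-contract tests
shared_model1_fit <- function() {
  shared("model1_fit", function() {
    net <- model_I(2, 5)
    times <- seq(0, 18, by = 2)
    ens <- simulate_delay_ssa(net, times, n_traj = 1000, seed = 5)
    H <- snapshots_from_ensemble(ens, N = 22L)
    fit <- train_nncme(net, H, config = training_config(
      epochs_max = 2000, hidden = 16, seed = 1))
    list(net = net, times = times, ens = ens, H = H, fit = fit)
  })
}
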