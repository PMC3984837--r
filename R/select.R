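#' Joint EEG channel selection and classifier tuning
#'
#' The top-level fitting function: preprocesses the epochs (zero-phase
#' band-pass, baseline correction, block-average decimation), then runs
#' the hybrid real-binary particle swarm over the 65-dimensional space of
#' one regularization coordinate (`lambda = 10^(5a)`, `a` in `[-1, 1]`)
#' and one inclusion bit per channel, scoring each feasible configuration
#' by 10-fold stratified cross-validation of the regularized Fisher
#' discriminant and the weighted accuracy/channel-count aggregate.
#'
#' Run this on training trials only; evaluate the returned configuration
#' on held-out data with [train_final_and_test()].
#'
#' @param epochs An `erp_epochs` object (training trials).
#' @param weights A [fitness_weights()] (or preset name, e.g. `"case7"`).
#' @param preproc A [preproc_spec()].
#' @param control A [swarm_config()].
#' @param folds,fold_seed Cross-validation configuration; folds are
#'   frozen once for the whole search.
#' @param verbose Print per-iteration progress.
#' @return An `mhpso` object (see [mhpso_search()]) augmented with
#'   `channel_names`, `weights`, `fold_seed` and the matched `call`;
#'   `coef()` returns the decoded `(lambda, channels)`.
#' @examples
#' \donttest{
#' ds <- simulate_oddball(protocol_spec(n_directions = 2,
#'                                      trials_per_session = 50),
#'                        erp_spec(informative_channels = c(2, 5),
#'                                 amplitude = 8, noise_sd = 6),
#'                        seed = 1, n_channels = 8)
#' fit <- select_channels(ds, weights = "case7",
#'                        control = swarm_config(n_particles = 10,
#'                                               max_iter = 15, seed = 1))
#' summary(fit)
#' }
#' @export
select_channels <- function(epochs, weights = fitness_weights("case7"),
                            preproc = preproc_spec(),
                            control = swarm_config(), folds = 10L,
                            fold_seed = 1L, verbose = FALSE) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (is.character(weights)) weights <- fitness_weights(weights)
  features <- preprocess_epochs(epochs, preproc)
  fitness <- make_fitness(features, epochs$labels, weights = weights,
                          folds = folds, fold_seed = fold_seed)
  res <- mhpso_search(fitness, n_bits = length(epochs$channel_names),
                      config = control, verbose = verbose)
  res$channel_names <- epochs$channel_names
  res$weights <- weights
  res$fold_seed <- fold_seed
  res$preproc <- preproc
  res$call <- match.call()
  res
}

#' @export
coef.mhpso <- function(object, ...) {
  list(lambda = object$lambda, channels = object$channels)
}
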