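# Small seeded datasets shared across tests.

tiny_protocol <- function(trials = 50L, directions = 2L)
  protocol_spec(n_directions = directions, trials_per_session = trials)

# Clearly separable 2-class Gaussian feature set for classifier tests.
gaussian_features <- function(n_per_class = 50, p = 5, delta = 3, seed = 1) {
  set.seed(seed)
  Z <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = delta / sqrt(p)),
                    n_per_class))
  y <- rep(c(-1L, 1L), each = n_per_class)
  list(Z = Z, y = y)
}

# Feature matrix wrapper around a plain matrix with one feature per
# "channel", for fitness-level tests that bypass preprocessing.
as_fm <- function(Z, n_per_channel = 1L) {
  n_ch <- ncol(Z) / n_per_channel
  structure(list(values = Z, n_per_channel = as.integer(n_per_channel),
                 channel_ids = seq_len(n_ch),
                 channel_names = paste0("Ch", seq_len(n_ch))),
            class = "feature_matrix")
}

# Trivially separable per-channel features: informative channels carry a
# large class mean shift, others pure noise.
separable_fm <- function(n = 200, n_channels = 8, informative = c(2, 5),
                         shift = 6, npc = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), length.out = n)[sample.int(n)]
  Z <- matrix(rnorm(n * n_channels * npc), n)
  for (ch in informative) {
    cols <- (ch - 1L) * npc + seq_len(npc)
    Z[y == 1L, cols] <- Z[y == 1L, cols] + shift
  }
  list(fm = as_fm(Z, npc), y = y)
}
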