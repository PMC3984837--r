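#' Biosemi 64-channel montage labels
#'
#' Standard 10-20 labels in the Biosemi A1-A32 / B1-B32 ordering, used as
#' the default channel naming of simulated datasets.  Purely cosmetic: the
#' selection machinery works on channel indices.
#'
#' @return Character vector of length 64.
#' @export
biosemi64_montage <- function() {
  c("Fp1", "AF7", "AF3", "F1",  "F3",  "F5",  "F7",  "FT7",
    "FC5", "FC3", "FC1", "C1",  "C3",  "C5",  "T7",  "TP7",
    "CP5", "CP3", "CP1", "P1",  "P3",  "P5",  "P7",  "P9",
    "PO7", "PO3", "O1",  "Iz",  "Oz",  "POz", "Pz",  "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz",  "F2",  "F4",
    "F6",  "F8",  "FT8", "FC6", "FC4", "FC2", "FCz", "Cz",
    "C2",  "C4",  "C6",  "T8",  "TP8", "CP6", "CP4", "CP2",
    "P2",  "P4",  "P6",  "P8",  "P10", "PO8", "PO4", "O2")
}

#' Oddball stimulation protocol
#'
#' Describes the auditory oddball design emulated by the generator: 6
#' virtual-sound directions, 2 sessions per direction, 150 trials per
#' session of which exactly 20% are targets, a 300 ms stimulus followed by
#' 800 ms of silence, and epochs spanning \[-100, 1000) ms around stimulus
#' onset.
#'
#' @param n_directions Number of stimulus directions (one is the target
#'   direction of any given session).
#' @param sessions_per_direction Recording sessions per direction.
#' @param trials_per_session Trials in one session.
#' @param target_fraction Fraction of target trials per session;
#'   `trials_per_session * target_fraction` must be a whole number (the
#'   target count is exact by design, not Bernoulli-sampled).
#' @param stimulus_ms,silence_ms Stimulus and inter-stimulus durations (ms).
#' @param epoch_window_ms Epoch extent relative to stimulus onset (ms),
#'   half-open `[from, to)`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_directions = 6L, sessions_per_direction = 2L,
                          trials_per_session = 150L, target_fraction = 0.20,
                          stimulus_ms = 300, silence_ms = 800,
                          epoch_window_ms = c(-100, 1000), fs = 250) {
  n_targets <- trials_per_session * target_fraction
  if (abs(n_targets - round(n_targets)) > 1e-9)
    stop("trials_per_session * target_fraction must be an integer, got ",
         n_targets)
  if (length(epoch_window_ms) != 2L || diff(epoch_window_ms) <= 0)
    stop("epoch_window_ms must be an increasing interval")
  if (fs <= 0) stop("fs must be positive")
  structure(list(
    n_directions = as.integer(n_directions),
    sessions_per_direction = as.integer(sessions_per_direction),
    trials_per_session = as.integer(trials_per_session),
    target_fraction = target_fraction,
    stimulus_ms = stimulus_ms, silence_ms = silence_ms,
    epoch_window_ms = as.numeric(epoch_window_ms), fs = fs
  ), class = "protocol_spec")
}

#' Synthetic event-related potential description
#'
#' Controls the P300-like deflection injected on target trials and the
#' background noise.  The deflection is a Gaussian bump in time (peak
#' latency ~350 ms, width ~120 ms, amplitude in microvolts) added only on
#' the informative channels; noise is Gaussian, optionally 1/f-shaped,
#' independent across channels and trials.
#'
#' @param informative_channels Integer indices (1-based) of channels that
#'   carry the evoked response.
#' @param p300_peak_ms Peak latency of the deflection (ms after onset).
#' @param p300_width_ms Gaussian width (standard deviation, ms).
#' @param amplitude Peak amplitude in microvolts.
#' @param latency_jitter_sd_ms Per-trial Gaussian jitter of the peak (ms).
#' @param noise_sd Noise standard deviation per sample (microvolts).
#' @param noise_color_exponent Spectral slope of the noise power
#'   (0 = white, 1 = 1/f pink).
#' @return An object of class `erp_spec`.
#' @export
erp_spec <- function(informative_channels = c(31L, 32L, 47L, 48L),
                     p300_peak_ms = 350, p300_width_ms = 120, amplitude = 5,
                     latency_jitter_sd_ms = 0, noise_sd = 10,
                     noise_color_exponent = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (p300_width_ms <= 0) stop("p300_width_ms must be > 0")
  structure(list(
    informative_channels = sort(unique(as.integer(informative_channels))),
    p300_peak_ms = p300_peak_ms, p300_width_ms = p300_width_ms,
    amplitude = amplitude, latency_jitter_sd_ms = latency_jitter_sd_ms,
    noise_sd = noise_sd, noise_color_exponent = noise_color_exponent
  ), class = "erp_spec")
}

#' P300-like template waveform
#'
#' Gaussian bump: `amplitude * exp(-((t - peak)/width)^2 / 2)`.  The
#' maximum equals `amplitude` at the sample nearest `peak_ms` and the
#' waveform is negligible (< 1.2% of amplitude) beyond three widths.
#'
#' @param times_ms Monotone increasing vector of sample times (ms).
#' @param peak_ms Peak latency (ms).
#' @param width_ms Gaussian width (ms), must be positive.
#' @param amplitude Peak amplitude (microvolts).
#' @return Numeric vector, same length as `times_ms`.
#' @export
p300_template <- function(times_ms, peak_ms = 350, width_ms = 120,
                          amplitude = 5) {
  if (width_ms <= 0) stop("width_ms must be > 0")
  if (is.unsorted(times_ms, strictly = TRUE))
    stop("times_ms must be monotone increasing")
  g <- exp(-((times_ms - peak_ms) / width_ms)^2 / 2)
  # scale so the sample nearest the peak equals the amplitude exactly
  if (max(g) > 0) g <- g / max(g)
  amplitude * g
}

# Gaussian noise, optionally 1/f^exponent shaped by rescaling FFT
# amplitudes; gains normalized so the expected variance stays sd^2.
# x: n_samples x n_signals matrix of draws to shape in place.
shape_noise <- function(x, sd, exponent) {
  if (exponent == 0) return(x * sd)
  n <- nrow(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                       # symmetric frequency index
  g <- ifelse(f > 0, f^(-exponent / 2), 0)  # drop DC to keep power finite
  g <- g / sqrt(mean(g^2))
  xf <- stats::mvfft(x) * g
  Re(stats::mvfft(xf, inverse = TRUE)) / n * sd
}

epoch_times_ms <- function(protocol) {
  n <- round(diff(protocol$epoch_window_ms) / 1000 * protocol$fs)
  protocol$epoch_window_ms[1] + (seq_len(n) - 1) * 1000 / protocol$fs
}

#' Simulate one oddball recording session
#'
#' Generates `trials_per_session` epochs for a session in which
#' `target_direction` is attended.  Exactly
#' `round(target_fraction * trials_per_session)` trials are targets, at
#' seeded-random positions; the remaining trials are assigned uniformly to
#' the nontarget directions.  The evoked template is added only on target
#' trials and only on the informative channels; noise is independent across
#' trials and channels.  Identical seeds give bit-identical output.
#'
#' @param protocol A [protocol_spec()].
#' @param erp An [erp_spec()].
#' @param target_direction Attended direction, `1..n_directions`.
#' @param session_id Session index (metadata only).
#' @param seed Integer seed.
#' @param n_channels Montage size.
#' @return An `erp_epochs` object (see [erp_epochs()]).
#' @export
simulate_session <- function(protocol = protocol_spec(), erp = erp_spec(),
                             target_direction = 1L, session_id = 1L,
                             seed = 1L, n_channels = 64L) {
  if (target_direction < 1 || target_direction > protocol$n_directions)
    stop("target_direction out of range")
  if (any(erp$informative_channels > n_channels))
    stop("informative channel index exceeds channel count (", n_channels, ")")
  set.seed(seed)
  nt <- protocol$trials_per_session
  n_targets <- round(protocol$target_fraction * nt)
  times <- epoch_times_ms(protocol)
  ns <- length(times)

  target_pos <- sample.int(nt, n_targets)
  labels <- rep(-1L, nt)
  labels[target_pos] <- 1L
  direction <- rep(target_direction, nt)
  others <- setdiff(seq_len(protocol$n_directions), target_direction)
  if (length(others))
    direction[labels == -1L] <- sample(others, nt - n_targets, replace = TRUE)

  noise <- shape_noise(matrix(stats::rnorm(ns * nt * n_channels), nrow = ns),
                       erp$noise_sd, erp$noise_color_exponent)
  # samples x (trials*channels), trial-major columns -> trials x channels x samples
  data <- aperm(array(noise, dim = c(ns, nt, n_channels)), c(2, 3, 1))

  if (erp$amplitude > 0 && length(erp$informative_channels)) {
    jit <- if (erp$latency_jitter_sd_ms > 0)
      stats::rnorm(n_targets, 0, erp$latency_jitter_sd_ms) else numeric(n_targets)
    for (i in seq_len(n_targets)) {
      tmpl <- p300_template(times, erp$p300_peak_ms + jit[i],
                            erp$p300_width_ms, erp$amplitude)
      tr <- sort(target_pos)[i]
      for (ch in erp$informative_channels)
        data[tr, ch, ] <- data[tr, ch, ] + tmpl
    }
  }

  erp_epochs(data, labels, direction, session = rep(as.integer(session_id), nt),
             fs = protocol$fs, t0_ms = protocol$epoch_window_ms[1],
             channel_names = if (n_channels == 64L) biosemi64_montage()
                             else paste0("Ch", seq_len(n_channels)))
}

#' Simulate a full oddball dataset
#'
#' Concatenates `n_directions * sessions_per_direction` sessions (each
#' direction attended in turn, each measured `sessions_per_direction`
#' times) with distinct per-session sub-seeds derived from `seed`.  With
#' defaults this yields the standard 12-session, 1800-trial design.
#'
#' @inheritParams simulate_session
#' @return An `erp_epochs` object with per-trial direction and session
#'   metadata.
#' @export
simulate_oddball <- function(protocol = protocol_spec(), erp = erp_spec(),
                             seed = 1L, n_channels = 64L) {
  set.seed(seed)
  n_sessions <- protocol$n_directions * protocol$sessions_per_direction
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  parts <- vector("list", n_sessions)
  k <- 0L
  for (d in seq_len(protocol$n_directions)) {
    for (s in seq_len(protocol$sessions_per_direction)) {
      k <- k + 1L
      parts[[k]] <- simulate_session(protocol, erp, target_direction = d,
                                     session_id = s, seed = sub_seeds[k],
                                     n_channels = n_channels)
    }
  }
  do.call(bind_epochs, parts)
}

#' Epoched EEG container
#'
#' Holds a trials x channels x samples array of epoched EEG (microvolts)
#' with per-trial class labels (+1 target, -1 nontarget), stimulus
#' direction, session index, sampling rate, and the epoch start time
#' relative to stimulus onset.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param labels Integer vector in \{+1, -1\}, one per trial.
#' @param direction,session Integer metadata vectors, one per trial.
#' @param fs Sampling rate (Hz).
#' @param t0_ms Time of the first sample relative to stimulus onset (ms).
#' @param channel_names Character vector, one per channel.
#' @return An object of class `erp_epochs`.
#' @export
erp_epochs <- function(data, labels, direction, session, fs, t0_ms,
                       channel_names = NULL) {
  stopifnot(length(dim(data)) == 3L)
  nt <- dim(data)[1]
  if (length(labels) != nt || length(direction) != nt || length(session) != nt)
    stop("labels/direction/session must have one entry per trial")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must match channel count")
  structure(list(data = data, labels = as.integer(labels),
                 direction = as.integer(direction),
                 session = as.integer(session),
                 fs = fs, t0_ms = t0_ms, channel_names = channel_names),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoched EEG:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat(sprintf("  fs = %g Hz, epoch [%g, %g) ms\n", x$fs, x$t0_ms,
              x$t0_ms + d[3] * 1000 / x$fs))
  cat(sprintf("  targets: %d (%.1f%%), nontargets: %d\n",
              sum(x$labels == 1), 100 * mean(x$labels == 1),
              sum(x$labels == -1)))
  cat("  directions:", paste(sort(unique(x$direction)), collapse = " "),
      " sessions:", paste(sort(unique(x$session)), collapse = " "), "\n")
  invisible(x)
}

#' Subset trials of an epoch container
#'
#' @param x An `erp_epochs` object.
#' @param i Trial index vector.
#' @param ... Ignored.
#' @return An `erp_epochs` with the selected trials.
#' @export
`[.erp_epochs` <- function(x, i, ...) {
  erp_epochs(x$data[i, , , drop = FALSE], x$labels[i], x$direction[i],
             x$session[i], x$fs, x$t0_ms, x$channel_names)
}

#' Concatenate epoch containers trial-wise
#'
#' @param ... `erp_epochs` objects sharing fs, t0 and montage.
#' @return A single `erp_epochs` object.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  ref <- xs[[1]]
  for (x in xs[-1])
    if (x$fs != ref$fs || x$t0_ms != ref$t0_ms ||
        !identical(x$channel_names, ref$channel_names) ||
        dim(x$data)[3] != dim(ref$data)[3])
      stop("epoch containers are not compatible")
  nt <- sum(vapply(xs, function(x) dim(x$data)[1], 1L))
  d <- dim(ref$data)
  data <- array(NA_real_, c(nt, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    n <- dim(x$data)[1]
    data[at + seq_len(n), , ] <- x$data
    at <- at + n
  }
  erp_epochs(data,
             unlist(lapply(xs, `[[`, "labels")),
             unlist(lapply(xs, `[[`, "direction")),
             unlist(lapply(xs, `[[`, "session")),
             ref$fs, ref$t0_ms, ref$channel_names)
}

#' Sample times of an epoch container
#'
#' @param x An `erp_epochs` object.
#' @return Numeric vector of per-sample times in ms relative to onset.
#' @export
epoch_times <- function(x) {
  x$t0_ms + (seq_len(dim(x$data)[3]) - 1) * 1000 / x$fs
}

#' Write / read the epoch container as plain text
#'
#' Single-file text format: a JSON header line (prefixed `#erpselect-epochs `)
#' carrying labels, direction, session, fs, t0_ms and channel names,
#' followed by one tab-separated row per (trial, channel) in trial-major
#' order with the per-sample values.
#'
#' @param x An `erp_epochs` object.
#' @param path File path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   an `erp_epochs` object.
#' @export
write_epochs <- function(x, path) {
  d <- dim(x$data)
  meta <- list(trials = d[1], channels = d[2], samples = d[3],
               labels = x$labels, direction = x$direction,
               session = x$session, fs = x$fs, t0_ms = x$t0_ms,
               channel_names = x$channel_names)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#erpselect-epochs ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#erpselect-epochs "))
    stop("not an erpselect epochs file: ", path)
  meta <- jsonlite::fromJSON(sub("^#erpselect-epochs ", "", header))
  flat <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t",
                                      colClasses = "numeric"))
  dimnames(flat) <- NULL
  data <- aperm(array(t(flat), c(meta$samples, meta$channels, meta$trials)),
                c(3, 2, 1))
  erp_epochs(data, meta$labels, meta$direction, meta$session,
             meta$fs, meta$t0_ms, meta$channel_names)
}
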