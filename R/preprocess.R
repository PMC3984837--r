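#' Preprocessing parameters
#'
#' The standard epoch chain: zero-phase 3rd-order Butterworth band-pass
#' (0.1-8 Hz), baseline correction over the prestimulus window, and
#' block-average decimation by 10 of the post-stimulus window, yielding 25
#' temporal features per channel at 250 Hz.  Windows are half-open
#' (`[-100, 0)` baseline, `[0, 1000)` features) so sample counts are exact.
#'
#' @param band_low_hz,band_high_hz Band-pass cutoffs (Hz).
#' @param filter_order Butterworth order (applied forward and backward, so
#'   the effective magnitude order is twice this).
#' @param baseline_window_ms Prestimulus window, half-open (ms).
#' @param feature_window_ms Post-stimulus feature window, half-open (ms).
#' @param decim_factor Block size of the averaging decimation; must divide
#'   the feature-window sample count.
#' @return An object of class `preproc_spec`.
#' @export
preproc_spec <- function(band_low_hz = 0.1, band_high_hz = 8,
                         filter_order = 3, baseline_window_ms = c(-100, 0),
                         feature_window_ms = c(0, 1000), decim_factor = 10L) {
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz)
    stop("need 0 < band_low_hz < band_high_hz")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = filter_order,
                 baseline_window_ms = baseline_window_ms,
                 feature_window_ms = feature_window_ms,
                 decim_factor = as.integer(decim_factor)),
            class = "preproc_spec")
}

# Initial filter state for step-matched forward-backward filtering
# (direct form II transposed), i.e. the state that makes the filter's
# response to a constant input exactly constant.
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- rbind(-a[2:n] / a[1], cbind(diag(n - 2L), 0))  # companion matrix
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# One IIR pass over the columns of X (samples x signals), direct form II
# transposed, vectorized over signals.  zi0 is the per-unit-input initial
# state; the actual state is zi0 outer the first row of X.
iir_filter_mat <- function(b, a, X, zi0 = NULL) {
  n <- length(b)
  Z <- matrix(0, n - 1L, ncol(X))
  if (!is.null(zi0)) Z <- zi0 %o% X[1L, ]
  Y <- X
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    yt <- b[1] * xt + Z[1L, ]
    if (n > 2L)
      for (k in seq_len(n - 2L))
        Z[k, ] <- b[k + 1L] * xt + Z[k + 1L, ] - a[k + 1L] * yt
    Z[n - 1L, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# Zero-phase filtering of matrix columns with odd-reflection padding and
# step-matched initial conditions on both passes.
filtfilt_mat <- function(b, a, X) {
  npad <- 3L * (length(a) - 1L)
  ns <- nrow(X)
  if (ns <= npad)
    stop("epoch too short for zero-phase filtering: need more than ",
         npad, " samples, got ", ns)
  top <- 2 * matrix(X[1L, ], npad, ncol(X), byrow = TRUE) -
    X[(npad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(X[ns, ], npad, ncol(X), byrow = TRUE) -
    X[(ns - 1L):(ns - npad), , drop = FALSE]
  ext <- rbind(top, X, bot)
  zi0 <- lfilter_zi(b, a)
  Y <- iir_filter_mat(b, a, ext, zi0)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- iir_filter_mat(b, a, Y, zi0)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[npad + seq_len(ns), , drop = FALSE]
}

butter_ba <- function(spec, fs) {
  ny <- fs / 2
  if (spec$band_high_hz >= ny)
    stop("band_high_hz must be below the Nyquist frequency ", ny, " Hz")
  bt <- signal::butter(spec$filter_order,
                       c(spec$band_low_hz, spec$band_high_hz) / ny,
                       type = "pass")
  list(b = bt$b, a = bt$a)
}

#' Zero-phase band-pass filter of all epochs
#'
#' Applies the Butterworth band-pass of `spec` to every trial and channel
#' independently, forward and backward (zero phase), with odd-reflection
#' padding and step-matched initial conditions at both ends.  The output
#' has the same shape as the input.
#'
#' @param x An `erp_epochs` object.
#' @param spec A [preproc_spec()].
#' @return The filtered `erp_epochs`.
#' @export
bandpass_filter <- function(x, spec = preproc_spec()) {
  ba <- butter_ba(spec, x$fs)
  d <- dim(x$data)
  X <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])  # samples x (trials*channels)
  Y <- filtfilt_mat(ba$b, ba$a, X)
  x$data <- aperm(array(Y, c(d[3], d[1], d[2])), c(2, 3, 1))
  x
}

#' Baseline-correct all epochs
#'
#' Subtracts, per trial and channel, the mean over the (half-open)
#' baseline window from the whole epoch.
#'
#' @param x An `erp_epochs` object.
#' @param window_ms Baseline window `[from, to)` in ms.
#' @return The corrected `erp_epochs`.
#' @export
baseline_correct <- function(x, window_ms = c(-100, 0)) {
  tt <- epoch_times(x)
  sel <- tt >= window_ms[1] & tt < window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(x$data[, , sel, drop = FALSE], c(1, 2), mean)
  x$data <- x$data - array(base, dim(x$data))  # recycles over samples
  x
}

#' Decimate a signal by non-overlapping block averaging
#'
#' Output element k is the mean of input block
#' `[(k-1)*factor + 1, k*factor]`; the length must be divisible by the
#' factor (no partial blocks).
#'
#' @param signal Numeric vector.
#' @param factor Positive integer block size.
#' @return Numeric vector of length `length(signal) / factor`.
#' @export
decimate_by_averaging <- function(signal, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (length(signal) %% factor != 0L)
    stop("signal length ", length(signal), " is not divisible by factor ",
         factor)
  if (factor == 1L) return(signal)
  colMeans(matrix(signal, nrow = factor))
}

#' Assemble classifier feature vectors
#'
#' Per trial: the feature-window segment of each selected channel is
#' block-average decimated and the per-channel vectors are concatenated in
#' channel order, giving `feature window samples / decim_factor` features
#' per channel (25 at the defaults).  The input must already be filtered
#' and baseline-corrected; [preprocess_epochs()] enforces the full order.
#'
#' @param x An `erp_epochs` object (filtered, baseline-corrected).
#' @param spec A [preproc_spec()].
#' @param channels Ordered integer channel indices (or channel names).
#' @return A list of class `feature_matrix`: `values` (trials x features),
#'   `n_per_channel`, `channel_ids`, `channel_names`.
#' @export
extract_features <- function(x, spec = preproc_spec(), channels = NULL) {
  if (is.null(channels)) channels <- seq_along(x$channel_names)
  if (is.character(channels))
    channels <- match(channels, x$channel_names)
  channels <- as.integer(channels)
  if (length(channels) == 0L) stop("channel set must not be empty")
  if (any(is.na(channels)) || any(channels < 1L) ||
      any(channels > dim(x$data)[2]))
    stop("invalid channel indices")
  tt <- epoch_times(x)
  sel <- tt >= spec$feature_window_ms[1] & tt < spec$feature_window_ms[2]
  nwin <- sum(sel)
  if (nwin %% spec$decim_factor != 0L)
    stop("decim_factor must divide the feature-window sample count (",
         nwin, ")")
  npc <- nwin %/% spec$decim_factor
  nt <- dim(x$data)[1]
  values <- matrix(NA_real_, nt, npc * length(channels))
  for (j in seq_along(channels)) {
    seg <- x$data[, channels[j], sel, drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = nt)
    # block means along time for all trials at once
    dec <- t(colMeans(array(t(seg), c(spec$decim_factor, npc, nt))))
    values[, (j - 1L) * npc + seq_len(npc)] <- dec
  }
  structure(list(values = values, n_per_channel = npc,
                 channel_ids = channels,
                 channel_names = x$channel_names[channels]),
            class = "feature_matrix")
}

#' Full preprocessing chain
#'
#' Convenience wrapper enforcing the canonical order
#' filter -> baseline -> decimate/assemble.
#'
#' @inheritParams extract_features
#' @return A `feature_matrix` (see [extract_features()]).
#' @export
preprocess_epochs <- function(x, spec = preproc_spec(), channels = NULL) {
  x <- bandpass_filter(x, spec)
  x <- baseline_correct(x, spec$baseline_window_ms)
  extract_features(x, spec, channels)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "trials x", ncol(x$values),
      "features (", x$n_per_channel, "per channel,",
      length(x$channel_ids), "channels )\n")
  invisible(x)
}
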