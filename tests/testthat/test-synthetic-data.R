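test_that("template is a unimodal bump with the stated peak and decay", {
  tt <- seq(-100, 996, by = 4)
  w <- p300_template(tt, peak_ms = 350, width_ms = 120, amplitude = 5)
  expect_equal(max(w), 5)
  expect_equal(tt[which.max(w)], 348)  # sample nearest 350 ms on this grid
  expect_true(all(w >= 0))
  # value three widths past the peak: exp(-9/2) of the amplitude
  at <- which.min(abs(tt - (350 + 3 * 120)))
  expect_lte(w[at], 0.012 * 5)
  expect_equal(p300_template(tt, amplitude = 0), rep(0, length(tt)))
  expect_error(p300_template(tt, width_ms = 0), "width")
  expect_error(p300_template(rev(tt)), "monotone")
})

test_that("a session has the exact protocol counts and is seed-reproducible", {
  ds <- simulate_session(protocol_spec(), erp_spec(), target_direction = 3,
                         session_id = 2, seed = 7)
  expect_equal(dim(ds$data), c(150, 64, 275))
  expect_equal(sum(ds$labels == 1L), 30)          # exactly 20% targets
  expect_true(all(ds$direction[ds$labels == 1L] == 3))
  expect_true(all(ds$direction[ds$labels == -1L] != 3))
  expect_equal(ds$session, rep(2L, 150))
  ds2 <- simulate_session(protocol_spec(), erp_spec(), target_direction = 3,
                          session_id = 2, seed = 7)
  expect_identical(ds, ds2)                       # bit-identical under seed
  ds3 <- simulate_session(protocol_spec(), erp_spec(), target_direction = 3,
                          session_id = 2, seed = 8)
  expect_false(identical(ds$data, ds3$data))
})

test_that("informative channel indices outside the montage are rejected", {
  expect_error(simulate_session(tiny_protocol(),
                                erp_spec(informative_channels = 9),
                                seed = 1, n_channels = 8),
               "exceeds channel count")
})

test_that("full dataset concatenates all direction/session combinations", {
  ds <- simulate_oddball(seed = 5)
  expect_equal(length(ds$labels), 1800)
  tgt <- ds$labels == 1L
  expect_equal(length(unique(paste(ds$direction[tgt], ds$session[tgt]))), 12)
  expect_equal(mean(ds$labels == 1L), 0.20)
  expect_equal(ds$channel_names, biosemi64_montage())
})

test_that("single-session dataset equals the session generated from the derived sub-seed", {
  proto <- protocol_spec(n_directions = 1L, sessions_per_direction = 1L,
                         trials_per_session = 20L)
  erp <- erp_spec(informative_channels = 2, noise_color_exponent = 0)
  ds <- simulate_oddball(proto, erp, seed = 42, n_channels = 4)
  set.seed(42)
  sub <- sample.int(.Machine$integer.max - 1L, 1L)
  ses <- simulate_session(proto, erp, target_direction = 1L, session_id = 1L,
                          seed = sub, n_channels = 4)
  expect_identical(ds, ses)
})

test_that("signal lives only on informative channels; no signal at zero amplitude", {
  proto <- protocol_spec(n_directions = 2L, trials_per_session = 150L)
  erp <- erp_spec(informative_channels = c(2L, 4L), amplitude = 5,
                  noise_sd = 2, noise_color_exponent = 0)
  ds <- simulate_oddball(proto, erp, seed = 3, n_channels = 6)
  tt <- epoch_times(ds)
  tmpl <- p300_template(tt, 350, 120, 5)
  diff_mean <- apply(ds$data[ds$labels == 1L, , , drop = FALSE], c(2, 3), mean) -
    apply(ds$data[ds$labels == -1L, , , drop = FALSE], c(2, 3), mean)
  # noise SE of a class-mean difference, per (channel, sample)
  se <- 2 * sqrt(1 / sum(ds$labels == 1L) + 1 / sum(ds$labels == -1L))
  for (ch in 1:6) {
    resid <- if (ch %in% c(2L, 4L)) diff_mean[ch, ] - tmpl else diff_mean[ch, ]
    expect_lt(sqrt(mean(resid^2)), 4 * se)
  }

  flat <- simulate_oddball(proto, erp_spec(informative_channels = c(2L, 4L),
                                           amplitude = 0, noise_sd = 2,
                                           noise_color_exponent = 0),
                           seed = 3, n_channels = 6)
  dm0 <- apply(flat$data[flat$labels == 1L, , , drop = FALSE], c(2, 3), mean) -
    apply(flat$data[flat$labels == -1L, , , drop = FALSE], c(2, 3), mean)
  expect_lt(max(abs(rowMeans(dm0))), 4 * se / sqrt(length(tt)) * 10)
  expect_lt(sqrt(mean(dm0^2)), 2 * se)
})

test_that("white noise variance matches noise_sd^2 and 1/f noise is low-frequency heavy", {
  proto <- tiny_protocol(trials = 40L)
  white <- simulate_oddball(proto, erp_spec(1, amplitude = 0, noise_sd = 7,
                                            noise_color_exponent = 0),
                            seed = 9, n_channels = 2)
  v <- var(as.vector(white$data[, 1, ]))  # 40*2*2 sessions trials x 275 > 1e4
  expect_lt(abs(v - 49) / 49, 0.05)

  pink <- simulate_oddball(proto, erp_spec(1, amplitude = 0, noise_sd = 7,
                                           noise_color_exponent = 1),
                           seed = 9, n_channels = 2)
  # 1/f: variance preserved on average, spectrum tilted to low frequencies
  vp <- var(as.vector(pink$data[, 1, ]))
  expect_lt(abs(vp - 49) / 49, 0.25)
  x <- pink$data[1, 1, ]
  sp <- Mod(fft(x - mean(x)))[2:138]^2
  expect_gt(mean(sp[1:20]), mean(sp[118:137]))
})

test_that("epoch container round-trips through the text format", {
  ds <- simulate_oddball(tiny_protocol(trials = 10L),
                         erp_spec(informative_channels = 1:2),
                         seed = 2, n_channels = 3)
  path <- tempfile(fileext = ".tsv")
  write_epochs(ds, path)
  back <- read_epochs(path)
  expect_equal(back$data, ds$data, tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$direction, ds$direction)
  expect_identical(back$session, ds$session)
  expect_identical(back$channel_names, ds$channel_names)
  expect_equal(back$fs, ds$fs)
  unlink(path)
})

test_that("container validates shapes and subsets trials", {
  ds <- simulate_oddball(tiny_protocol(trials = 10L), erp_spec(1),
                         seed = 2, n_channels = 3)
  expect_error(erp_epochs(ds$data, ds$labels[-1], ds$direction, ds$session,
                          250, -100), "one entry per trial")
  sub <- ds[ds$labels == 1L]
  expect_true(all(sub$labels == 1L))
  expect_equal(dim(sub$data)[1], sum(ds$labels == 1L))
  expect_error(protocol_spec(trials_per_session = 10, target_fraction = 0.15),
               "integer")
})
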