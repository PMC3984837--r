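test_that("stratified split halves the standard design into disjoint exhaustive 900-trial sets", {
  ds <- simulate_oddball(seed = 21)
  sp <- stratified_split(ds, seed = 22)
  expect_equal(length(sp$idx_train), 900)
  expect_equal(length(sp$idx_test), 900)
  expect_equal(sort(c(sp$idx_train, sp$idx_test)), 1:1800)
  expect_length(intersect(sp$idx_train, sp$idx_test), 0)
  # class, direction and session proportions preserved per subset
  expect_equal(sum(sp$train$labels == 1L), 180)
  expect_equal(sum(sp$test$labels == 1L), 180)
  for (d in 1:6)
    expect_equal(sum(sp$train$direction == d), sum(sp$test$direction == d),
                 tolerance = 0.05)
  # per-stratum integer rounding: a 25-trial stratum splits 13/12 or 12/13
  small <- ds[1:25]
  sp2 <- stratified_split(small, seed = 1)
  expect_true(length(sp2$idx_train) %in% c(12, 13))
  # deterministic under seed
  sp3 <- stratified_split(ds, seed = 22)
  expect_identical(sp$idx_train, sp3$idx_train)
})

test_that("final training on informative channels classifies held-out data; no signal stays at chance", {
  proto <- protocol_spec(n_directions = 2, trials_per_session = 100)
  erp <- erp_spec(informative_channels = c(2, 5), amplitude = 8,
                  noise_sd = 10, noise_color_exponent = 0)
  ds <- simulate_oddball(proto, erp, seed = 31, n_channels = 8)
  sp <- stratified_split(ds, seed = 32)
  fin <- train_final_and_test(sp$train, sp$test, lambda = 10,
                              channels = c(2, 5))
  expect_gte(fin$gm, 0.95)
  expect_length(fin$scores, length(sp$idx_test))

  flat <- simulate_oddball(proto, erp_spec(informative_channels = c(2, 5),
                                           amplitude = 0, noise_sd = 10,
                                           noise_color_exponent = 0),
                           seed = 31, n_channels = 8)
  spf <- stratified_split(flat, seed = 32)
  fin0 <- train_final_and_test(spf$train, spf$test, 10, c(2, 5))
  expect_gte(fin0$gm, 0.30)
  expect_lte(fin0$gm, 0.70)

  # resubstitution diagnostic: training data scores at least close to the
  # CV estimate
  feats <- preprocess_epochs(sp$train)
  cvres <- cv_confusion(feats, sp$train$labels, channels = c(2, 5),
                        lambda = 10, fold_seed = 33)
  resub <- train_final_and_test(sp$train, sp$train, 10, c(2, 5))
  expect_gte(resub$gm, cvres$gm_accuracy - 0.05)
  expect_error(train_final_and_test(sp$train, sp$test, 10, integer()),
               "empty")
})

test_that("master list preserves counts, class purity and reuse across calls", {
  labels <- rep(c(1L, -1L), c(180, 720))
  ml <- build_master_list(labels, M_range = 2:10, seed = 41)
  for (M in 2:10) {
    part <- ml$lists[[as.character(M)]]
    expect_equal(nrow(part$tuples), 900)
    expect_equal(ncol(part$tuples), M)
    expect_equal(sum(part$labels == 1L), 180)
    # every tuple draws from its own class only
    expect_true(all(labels[part$tuples[part$labels == 1L, ]] == 1L))
    expect_true(all(labels[part$tuples[part$labels == -1L, ]] == -1L))
  }
  expect_identical(ml, build_master_list(labels, 2:10, seed = 41))
  expect_false(identical(ml, build_master_list(labels, 2:10, seed = 42)))
  expect_error(build_master_list(rep(1L, 10)), "both classes")
})

test_that("score averaging reproduces identical-trial scores and improves accuracy with M", {
  # degenerate master list: tuples repeating one index -> averaged score
  # equals the single-trial score
  model <- structure(list(mu_pos = 1, mu_neg = -1, var_pos = 1, var_neg = 1),
                     class = "fda")
  scores <- c(2, -3, 0.5, -0.2)
  labels <- c(1L, -1L, 1L, -1L)
  ml <- build_master_list(labels, M_range = 3, seed = 1)
  ml$lists[["3"]]$tuples <- matrix(rep(1:4, 3), 4)
  ml$lists[["3"]]$labels <- labels
  gm_avg <- averaged_trial_gm(scores, labels, model, ml, 3)
  pred1 <- erpselect:::classify_scores(scores, 1, -1, 1, 1)
  expect_equal(gm_avg, gm_accuracy(sum(pred1 == 1 & labels == 1),
                                   sum(pred1 == -1 & labels == -1), 2, 2))
  expect_error(averaged_trial_gm(scores, labels, model, ml, 7), "range")

  # signal-bearing data: averaging never loses much and typically gains
  proto <- protocol_spec(n_directions = 2, trials_per_session = 100)
  erp <- erp_spec(informative_channels = c(2, 5), amplitude = 12,
                  noise_sd = 10, noise_color_exponent = 1)
  deltas <- sapply(1:5, function(s) {
    ds <- simulate_oddball(proto, erp, seed = 50 + s, n_channels = 8)
    sp <- stratified_split(ds, seed = 60 + s)
    fin <- train_final_and_test(sp$train, sp$test, 10, c(2, 5))
    master <- build_master_list(sp$test$labels, c(2, 10), seed = 70 + s)
    g10 <- averaged_trial_gm(fin$scores, sp$test$labels, fin$model, master, 10)
    g10 - fin$gm
  })
  expect_true(all(deltas >= -0.02))
  expect_gt(mean(deltas), 0)
})

test_that("pareto front matches the all-pairs dominance oracle", {
  expect_equal(pareto_front(data.frame(n_channels = c(3, 5),
                                       gm_accuracy = c(0.8, 0.8))),
               data.frame(n_channels = 3, gm_accuracy = 0.8))
  single <- data.frame(n_channels = 7, gm_accuracy = 0.4)
  expect_equal(pareto_front(single), single)

  set.seed(77)
  pts <- data.frame(n_channels = sample(1:64, 200, replace = TRUE),
                    gm_accuracy = round(runif(200), 2))
  front <- pareto_front(pts)
  # brute-force O(n^2) dominance check over the deduplicated points
  u <- unique(pts)
  dominated <- sapply(seq_len(nrow(u)), function(i)
    any(u$gm_accuracy >= u$gm_accuracy[i] & u$n_channels <= u$n_channels[i] &
          (u$gm_accuracy > u$gm_accuracy[i] | u$n_channels < u$n_channels[i])))
  expect_equal(front[order(front$n_channels), ],
               u[!dominated, ][order(u$n_channels[!dominated]), ],
               ignore_attr = TRUE)
  # front is strictly increasing in accuracy as channels grow
  o <- order(front$n_channels)
  expect_true(all(diff(front$gm_accuracy[o]) > 0))
})

test_that("selection frequency counts gbest membership across results", {
  r1 <- structure(list(channels = c(1L, 3L)), class = "mhpso")
  r2 <- structure(list(channels = c(3L)), class = "mhpso")
  r3 <- structure(list(channels = c(2L, 3L)), class = "mhpso")
  r4 <- structure(list(channels = c(1L, 2L, 3L)), class = "mhpso")
  freq <- selection_frequency(list(r1, r2, r3, r4), 4)
  expect_equal(freq, c(0.5, 0.5, 1, 0))
  expect_error(selection_frequency(list(), 4), "at least one")
})
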