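test_that("particle decoding maps the real coordinate exponentially and bits to channels", {
  expect_equal(decode_particle(1, rep(1, 64))$lambda, 1e5)
  expect_equal(decode_particle(0, rep(1, 64))$lambda, 1)
  expect_equal(decode_particle(-1, rep(1, 64))$lambda, 1e-5)
  bits <- rep(0, 64); bits[3] <- 1
  expect_equal(decode_particle(0.2, bits)$channels, 3L)
  expect_equal(decode_particle(0, c(1, 0, 1, 1))$channels, c(1L, 3L, 4L))
})

test_that("feasibility requires an in-range real coordinate and a non-empty channel set", {
  one <- c(1, rep(0, 63))
  expect_true(is_feasible(0, one))
  expect_true(is_feasible(-1, one))
  expect_true(is_feasible(1, one))
  expect_false(is_feasible(1.2, one))
  expect_false(is_feasible(-1.01, one))
  expect_false(is_feasible(0, rep(0, 64)))
})

test_that("inertia ramps linearly from 0.9 to 0.4 for the real part and is 1 for bits", {
  cfg <- swarm_config(max_iter = 100)
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(100, cfg), 0.4)
  expect_equal(inertia_weight(50, cfg), 0.65)
  expect_equal(inertia_weight(37, cfg, "binary"), 1)
  expect_error(inertia_weight(101, cfg), "out of")
  expect_error(inertia_weight(-1, cfg), "out of")
})

test_that("velocity updates clamp componentwise and fix the converged state", {
  cfg <- swarm_config(seed = 1)
  x <- c(0.3, rep(1, 64))
  # converged: zero velocity at the shared best stays zero
  v <- update_velocity(x, rep(0, 65), x, x, t = 10, cfg)
  expect_equal(v, rep(0, 65))

  # clamping after any update
  set.seed(2)
  for (rep in 1:20) {
    x <- c(runif(1, -2, 2), rbinom(64, 1, 0.5))
    vv <- runif(65, -10, 10)
    p <- c(runif(1, -1, 1), rbinom(64, 1, 0.5))
    g <- c(runif(1, -1, 1), rbinom(64, 1, 0.5))
    v <- update_velocity(x, vv, p, g, t = sample(0:100, 1), cfg)
    expect_lte(abs(v[1]), cfg$v_max_real)
    expect_true(all(abs(v[-1]) <= cfg$v_max_binary))
  }

  # binary inertia 1: with no pulls, a binary velocity persists undamped
  cfg0 <- swarm_config(c1 = 1e-12, c2 = 1e-12, seed = 1)
  x <- c(0, rep(0, 64))
  v6 <- c(0, rep(6, 64))
  v <- update_velocity(x, v6, x, x, t = 50, cfg0)
  expect_equal(v[-1], rep(6, 64))
})

test_that("position updates add the real velocity and resample bits by the sigmoid rule", {
  set.seed(3)
  x <- update_position(c(0.5, rep(0, 4)), c(0.1, rep(0, 4)))
  expect_equal(x[1], 0.6)

  # v = 0 -> bits are 1 about half the time; v = 6 -> about S(6) = 0.9975
  n <- 20000
  set.seed(4)
  b0 <- replicate(50, update_position(c(0, rep(0, n / 50)),
                                      c(0, rep(0, n / 50)))[-1])
  expect_equal(mean(b0), 0.5, tolerance = 0.02)
  set.seed(5)
  b6 <- replicate(50, update_position(c(0, rep(0, n / 50)),
                                      c(0, rep(6, n / 50)))[-1])
  expect_equal(mean(b6), 1 / (1 + exp(-6)), tolerance = 0.005)
})

test_that("search on a flat landscape runs to max_iter; early stop reports the target iteration", {
  flat <- function(lambda, channels) 0.5
  cfg <- swarm_config(n_particles = 5, max_iter = 8, seed = 1)
  res <- mhpso_search(flat, n_bits = 6, config = cfg)
  expect_equal(res$terminated_by, "max_iter")
  expect_equal(res$iterations_run, 8)
  expect_equal(res$gbest_fitness, 0.5)
  expect_equal(max(res$history$iteration), 8)

  # a fitness that the very first feasible particle satisfies
  ones <- function(lambda, channels) 1
  res1 <- mhpso_search(ones, n_bits = 6,
                       config = swarm_config(n_particles = 5, max_iter = 50,
                                             seed = 1))
  expect_equal(res1$terminated_by, "target")
  expect_equal(res1$iterations_run, 1)
  expect_equal(nrow(res1$history), 5)
})

test_that("gbest is monotone, equals the feasible-history maximum, and ignores infeasible visits", {
  noisy <- function(lambda, channels)
    0.3 + 0.4 * sin(lambda) ^ 2 + 0.01 * length(channels)
  cfg <- swarm_config(n_particles = 8, max_iter = 25, seed = 42,
                      target_fitness = 2)  # never reached: full run
  res <- mhpso_search(noisy, n_bits = 10, config = cfg)
  h <- res$history
  gb <- tapply(h$gbest_fitness, h$iteration, max)
  expect_true(all(diff(gb) >= 0))
  expect_equal(res$gbest_fitness, max(h$fitness[h$feasible], na.rm = TRUE))
  expect_true(all(is.na(h$fitness[!h$feasible])))
  # recorded bits are always 0/1
  expect_true(all(res$history_bits %in% c(0, 1)))
})

test_that("identical configuration and seed reproduce the search exactly", {
  f <- function(lambda, channels) 1 / (1 + abs(log10(lambda))) *
    length(channels) / (1 + length(channels))
  cfg <- swarm_config(n_particles = 6, max_iter = 15, seed = 7)
  r1 <- mhpso_search(f, n_bits = 12, config = cfg)
  r2 <- mhpso_search(f, n_bits = 12, config = cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$gbest, r2$gbest)
  r3 <- mhpso_search(f, n_bits = 12,
                     config = swarm_config(n_particles = 6, max_iter = 15,
                                           seed = 8))
  expect_false(identical(r1$gbest, r3$gbest))
})

test_that("search optimizes the real coordinate alone to near the analytic optimum", {
  quad <- function(lambda, channels) 1 - (log10(lambda) / 5)^2  # 1 - a^2
  hits <- 0L
  for (s in 101:106) {
    res <- mhpso_search(quad, n_bits = 4,
                        config = swarm_config(seed = s, target_fitness = 2))
    if (res$gbest_fitness >= 0.999) hits <- hits + 1L
  }
  expect_gte(hits, 5)
})

test_that("channel-sparsity objective alone drives the swarm to a single channel", {
  hits <- 0L
  for (s in 101:106) {
    f2only <- function(lambda, channels) channel_objective(length(channels), 64)
    res <- mhpso_search(f2only, n_bits = 64, config = swarm_config(seed = s))
    if (res$gbest_fitness == 1 && length(res$channels) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 5)
})
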