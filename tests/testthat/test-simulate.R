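# Generative-model properties of the synthetic-data module.

test_that("zero autocorrelation gives i.i.d. zero-mean increments", {
  p <- crw_params(gamma = c(0, 0), theta = c(0.7, -1.1), process_sd = c(1, 1),
                  alpha_top = c(0, 0), alpha_sub = rbind(c(0, 0), c(0, 0)),
                  dive_mu = c(20, 100, 20), dive_sd = c(5, 20, 5))
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 10000,
                           true_params = p, seed = 1)
  set.seed(1)
  chain <- simulate_latent_chain(cfg)
  inc <- diff(chain$Y[-1, ])  # increments governed by the process (t >= 2)
  se <- 1 / sqrt(nrow(inc))
  expect_lt(abs(mean(inc[, 1])), 3 * se)
  expect_lt(abs(mean(inc[, 2])), 3 * se)
  expect_lt(abs(sd(inc[, 1]) - 1), 0.05)
})

test_that("full persistence with no noise gives a straight constant-step line", {
  p <- crw_params(gamma = c(1, 1), theta = c(0, 0),
                  process_sd = c(1e-12, 1e-12),
                  alpha_top = c(0, 0), alpha_sub = rbind(c(0, 0), c(0, 0)),
                  dive_mu = c(20, 100, 20), dive_sd = c(5, 20, 5))
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 50,
                           true_params = p, seed = 2)
  set.seed(2)
  chain <- simulate_latent_chain(cfg)
  steps <- diff(chain$Y)
  first <- steps[2, ]  # the first process-driven step
  for (i in 2:nrow(steps))
    expect_equal(steps[i, ], first, tolerance = 1e-6)
})

test_that("self-transition frequency matches the logistic closed form", {
  p <- default_params()
  p$alpha_top <- c(from_travel = 4, from_ars = -4)
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 10000,
                           true_params = p, seed = 3)
  set.seed(3)
  chain <- simulate_latent_chain(cfg)
  st <- chain$s_top
  expected <- plogis(4)  # 0.982: P(stay) from either state
  for (s in 1:2) {
    from_s <- which(st[-length(st)] == s)
    stay <- mean(st[from_s + 1L] == s)
    se <- sqrt(expected * (1 - expected) / length(from_s))
    expect_lt(abs(stay - expected), 3 * se + 1e-12)
  }
})

test_that("locked foraging depths match the truncated-normal mean", {
  p <- default_params()
  p$dive_mu["foraging"] <- 190
  p$dive_sd["foraging"] <- 40
  p$alpha_sub <- matrix(20, 2, 2,
                        dimnames = dimnames(p$alpha_sub))  # absorb in forage
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 2000,
                           true_params = p, dives_per_interval_rate = 5,
                           seed = 4)
  set.seed(4)
  dv <- simulate_dives(rep(2L, 2000), cfg)  # all ARS intervals
  keep <- dv$s_sub == 1L
  expect_gt(mean(keep), 0.99)  # absorbing after the first dive
  x <- dv$dives$depth[keep]
  target <- oracle_tnorm_mean(190, 40, 10)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - target), 3 * se)
})

test_that("a foraging-absorbing sub-chain keeps every ARS dive foraging", {
  p <- default_params()
  p$alpha_sub[2, ] <- c(20, 20)
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 200,
                           true_params = p, dives_per_interval_rate = 3,
                           seed = 5)
  set.seed(5)
  dv <- simulate_dives(rep(2L, 200), cfg)
  expect_true(all(dv$s_sub[-1] == 1L))
})

test_that("zero dive rate yields an empty but valid dataset", {
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 10,
                           dives_per_interval_rate = 0, seed = 6)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$dives), 0)
  expect_null(ds$truth$dives)
  expect_gt(nrow(ds$fixes), 0)
})

test_that("noiseless fixes lie exactly on the interpolated chord", {
  tiny <- setNames(rep(1e-12, 6), c("3", "2", "1", "0", "A", "B"))
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 40, seed = 7,
                           missing_interval_prob = 0)
  cfg$argos_sds <- tiny
  set.seed(7)
  chain <- simulate_latent_chain(cfg)
  fx <- degrade_to_argos(chain$Y, cfg)
  zx <- (1 - fx$j) * chain$Y[fx$t, 1] + fx$j * chain$Y[fx$t + 1L, 1]
  zy <- (1 - fx$j) * chain$Y[fx$t, 2] + fx$j * chain$Y[fx$t + 1L, 2]
  expect_lt(max(abs(fx$x - zx)), 1e-6)
  expect_lt(max(abs(fx$y - zy)), 1e-6)
  # convexity: every fix is on the segment between its bracketing nodes
  d01 <- sqrt(diff(chain$Y[, 1])^2 + diff(chain$Y[, 2])^2)[fx$t]
  da <- sqrt((fx$x - chain$Y[fx$t, 1])^2 + (fx$y - chain$Y[fx$t, 2])^2)
  db <- sqrt((fx$x - chain$Y[fx$t + 1L, 1])^2 +
               (fx$y - chain$Y[fx$t + 1L, 2])^2)
  expect_lt(max(abs(da + db - d01)), 1e-6)
})

test_that("class-B noise yields the isotropic-normal RMS error", {
  sds <- setNames(c(rep(1e-12, 5), 10), c("3", "2", "1", "0", "A", "B"))
  probs <- setNames(c(0, 0, 0, 0, 0, 1), c("3", "2", "1", "0", "A", "B"))
  cfg <- simulation_config(n_animals = 1, steps_per_animal = 1300,
                           fixes_per_interval_rate = 8,
                           argos_class_probs = probs,
                           missing_interval_prob = 0, seed = 8)
  cfg$argos_sds <- sds
  set.seed(8)
  chain <- simulate_latent_chain(cfg)
  fx <- degrade_to_argos(chain$Y, cfg)
  expect_gt(nrow(fx), 9000)
  zx <- (1 - fx$j) * chain$Y[fx$t, 1] + fx$j * chain$Y[fx$t + 1L, 1]
  zy <- (1 - fx$j) * chain$Y[fx$t, 2] + fx$j * chain$Y[fx$t + 1L, 2]
  rms <- sqrt(mean((fx$x - zx)^2 + (fx$y - zy)^2))
  expect_lt(abs(rms - 10 * sqrt(2)) / (10 * sqrt(2)), 0.02)
})

test_that("the same configuration reproduces byte-identical files", {
  cfg <- simulation_config(n_animals = 2, steps_per_animal = 20, seed = 9,
                           dives_per_interval_rate = 3)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in c("fixes.csv", "dives.csv", "truth.csv", "truth_dives.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("every simulated depth exceeds the dive-definition threshold", {
  cfg <- simulation_config(n_animals = 3, steps_per_animal = 50,
                           dives_per_interval_rate = 5, seed = 10)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$dives$depth_m > 10))
  # truth arrays: one top state per interval, one sub-state per dive
  expect_equal(nrow(ds$truth$intervals), 3 * 50)
  expect_equal(nrow(ds$truth$dives), nrow(ds$dives))
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulation_config(n_animals = 0), "n_animals")
  expect_error(simulation_config(fixes_per_interval_rate = 0), "rate")
  bad <- c("3" = 0.5, "2" = 0.5, "1" = 0.1, "0" = 0, "A" = 0, "B" = 0)
  expect_error(simulation_config(argos_class_probs = bad), "sum to 1")
  p <- default_params()
  p$gamma[1] <- NaN
  expect_error(simulation_config(true_params = p), "non-finite")
})
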