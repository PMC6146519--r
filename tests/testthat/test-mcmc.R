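# Sampler correctness: exact conditionals, degenerate limits, diagnostics.

test_that("invalid chain protocols are rejected", {
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "burnin")
  expect_error(mcmc_config(n_iter = 100, n_burnin = 99, thin = 4),
               "retained")
  expect_error(mcmc_config(thin = 0), "thin")
  cfg <- mcmc_config()
  expect_equal(cfg$n_retained, 500)  # (30000 - 28000) / 4
})

test_that("a fully symmetric model yields uniform state draws", {
  fx <- sim_track(T = 12, seed = 41, params = symmetric_params(),
                  dives_rate = 1)
  set.seed(42)
  dr <- ffbs_top(fx$track, fx$Y, fx$s_sub, symmetric_params(),
                 n_draws = 10000)
  freq <- colMeans(dr == 1L)
  se <- 0.5 / sqrt(nrow(dr))
  expect_true(all(abs(freq - 0.5) < 3 * se + 0.01))
})

test_that("overwhelming emissions pin the sampled path", {
  # tight, widely separated depth components: each dive's likelihood ratio
  # between candidate top states is astronomical, pinning the path
  p <- crw_params(gamma = c(0.9, 0.2), theta = c(0, 2.5),
                  process_sd = c(2, 2), alpha_top = c(2, -2),
                  alpha_sub = rbind(c(0, 0), c(4, -4)),
                  dive_mu = c(20, 200, 60), dive_sd = c(2, 4, 2))
  fx <- sim_track(T = 8, seed = 43, params = p, dives_rate = 6)
  # the construction only overwhelms when every interval carries dives
  stopifnot(all(1:8 %in% fx$track$dives$t))
  set.seed(44)
  dr <- ffbs_top(fx$track, fx$Y, fx$s_sub, p, n_draws = 1000)
  # the dominant path is drawn every single time
  expect_equal(nrow(unique(dr)), 1)
})

test_that("FFBS path frequencies match the enumerated posterior", {
  # diffuse regime so that many paths carry mass
  p <- crw_params(gamma = c(0.6, 0.3), theta = c(0, 1), process_sd = c(4, 4),
                  alpha_top = c(0.5, -0.5),
                  alpha_sub = rbind(c(0, 0), c(1, -1)),
                  dive_mu = c(25, 60, 35), dive_sd = c(20, 40, 25))
  fx <- sim_track(T = 5, seed = 45, params = p, dives_rate = 1)
  post <- enum_top_posterior(fx$track, fx$Y, fx$s_sub, p,
                             argos_error_table())
  set.seed(46)
  n <- 20000
  dr <- ffbs_top(fx$track, fx$Y, fx$s_sub, p, n_draws = n)
  key <- apply(dr, 1, paste, collapse = "")
  keys <- apply(post$paths, 1, paste, collapse = "")
  emp <- as.numeric(table(factor(key, levels = keys)))
  # chi-squared goodness of fit, pooling low-expectation paths
  big <- post$prob * n >= 5
  obs <- c(emp[big], sum(emp[!big]))
  exp_n <- c(post$prob[big], sum(post$prob[!big])) * n
  keep <- exp_n > 0
  stat <- sum((obs[keep] - exp_n[keep])^2 / exp_n[keep])
  pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("location sampling reproduces its closed-form full conditional", {
  # T = 2 track, no fixes except near-exact pins on the end nodes, gamma = 0:
  # the middle node's conditional is N(Y_3, sigma^2) per coordinate
  p <- crw_params(gamma = c(0.5, 0), theta = c(0, 0), process_sd = c(1, 1),
                  alpha_top = c(0, 0), alpha_sub = rbind(c(0, 0), c(0, 0)),
                  dive_mu = c(20, 100, 20), dive_sd = c(10, 10, 10))
  p$gamma <- c(travel = 0, ars = 0)
  track <- structure(list(
    animal = "a", g = 1L, start = utc("2016-03-01"), n_intervals = 2L,
    fixes = data.frame(t = c(1L, 2L), j = c(0, 1), x = c(0, 4), y = c(0, -2),
                       error_class = c("3", "3")),
    dives = data.frame(t = integer(0), u = integer(0),
                       timestamp = utc(character(0)), depth = numeric(0),
                       duration = numeric(0)),
    n_dropped_dives = 0L), class = "regular_track")
  et <- structure(setNames(c(1e-4, 0.6, 1.2, 4, 6, 9),
                           c("3", "2", "1", "0", "A", "B")),
                  class = "argos_error_table")
  latent <- list(list(Y = rbind(c(0, 0), c(1, 1), c(4, -2)),
                      s_top = c(1L, 1L), s_sub = integer(0)))
  set.seed(47)
  n_sweep <- 60000
  sc <- list(rep(2.5, 3))
  mid <- matrix(NA_real_, n_sweep, 2)
  for (i in seq_len(n_sweep)) {
    out <- sample_locations(list(track), latent, p, et, sc)
    latent <- out$latent
    mid[i, ] <- latent[[1]]$Y[2, ]
  }
  keep <- mid[seq(5001, n_sweep, by = 4), ]
  expect_lt(abs(mean(keep[, 1]) - 4), 0.05)
  expect_lt(abs(mean(keep[, 2]) - -2), 0.05)
  expect_lt(abs(var(keep[, 1]) - 1), 0.05)
  expect_lt(abs(var(keep[, 2]) - 1), 0.05)
})

test_that("zero-noise fixes drag the locations onto the observed path", {
  # straight-line truth observed essentially without error at every node
  T <- 6
  truth <- cbind(0:(T), 2 * (0:T))
  track <- structure(list(
    animal = "a", g = 1L, start = utc("2016-03-01"), n_intervals = T,
    fixes = data.frame(t = c(seq_len(T), T), j = c(rep(0, T), 1),
                       x = truth[, 1], y = truth[, 2],
                       error_class = rep("3", T + 1)),
    dives = data.frame(t = integer(0), u = integer(0),
                       timestamp = utc(character(0)), depth = numeric(0),
                       duration = numeric(0)),
    n_dropped_dives = 0L), class = "regular_track")
  et <- structure(setNames(c(1e-3, 0.6, 1.2, 4, 6, 9),
                           c("3", "2", "1", "0", "A", "B")),
                  class = "argos_error_table")
  p <- default_params()
  set.seed(48)
  latent <- list(list(Y = truth + matrix(rnorm(2 * (T + 1), 0, 0.5),
                                         ncol = 2),
                      s_top = rep(1L, T), s_sub = integer(0)))
  sc <- list(rep(3e-3, T + 1))
  for (i in 1:3000) {
    # occasional large moves to traverse the gap from the perturbed start
    s <- if (i %% 10 == 0) list(rep(0.2, T + 1)) else sc
    latent <- sample_locations(list(track), latent, p, et, s)$latent
  }
  rms <- sqrt(mean((latent[[1]]$Y - truth)^2))
  expect_lt(rms, 0.01)
  # degenerate proposal: zero step is always accepted, never moves
  frozen <- sample_locations(list(track), latent, p, et,
                             list(rep(0, T + 1)))
  expect_identical(frozen$latent[[1]]$Y, latent[[1]]$Y)
  expect_true(all(frozen$accept[[1]] == 1L))
})

test_that("parameters revert to their priors without data", {
  # an empty track set for a behavior: resting never occupied
  fx <- sim_track(T = 10, seed = 49, dives_rate = 0)
  latent <- list(list(Y = fx$Y, s_top = fx$s_top, s_sub = integer(0)))
  p <- default_params()
  pr <- default_priors()
  sc <- setNames(rep(0.3, 18), names(params_to_vec(p)))
  sc[c("mu_travel", "mu_forage", "mu_rest")] <- c(12, 60, 12)
  set.seed(50)
  mu_rest <- numeric(2000)
  for (i in seq_len(20000)) {
    p <- sample_parameters(list(fx$track), latent, p, pr, sc)$params
    if (i %% 10 == 0) mu_rest[i / 10] <- p$dive_mu["resting"]
  }
  ks <- suppressWarnings(ks.test(mu_rest, "punif", 0, 30))
  expect_gt(ks$p.value, 0.01)
})

test_that("conjugate-style recovery: fixed foraging states find their mean", {
  set.seed(51)
  depths <- rtnorm_depths <- 10 + abs(rnorm(400, 180, 40))  # around 190
  track <- structure(list(
    animal = "a", g = 1L, start = utc("2016-03-01"), n_intervals = 4L,
    fixes = data.frame(t = 1L, j = 0.5, x = 0, y = 0, error_class = "3"),
    dives = data.frame(t = rep(1:4, each = 100), u = rep(1:100, 4),
                       timestamp = utc("2016-03-01") + seq_len(400) * 60,
                       depth = depths, duration = 100),
    n_dropped_dives = 0L), class = "regular_track")
  latent <- list(list(Y = matrix(0, 5, 2), s_top = rep(2L, 4),
                      s_sub = rep(1L, 400)))
  p <- default_params()
  pr <- default_priors()
  sc <- setNames(rep(0.2, 18), names(params_to_vec(p)))
  sc[c("mu_forage", "sd_forage")] <- c(4, 0.1)
  draws <- numeric(1500)
  for (i in seq_len(3000)) {
    p <- sample_parameters(list(track), latent, p, pr, sc)$params
    if (i > 1500) draws[i - 1500] <- p$dive_mu["foraging"]
  }
  expect_lt(abs(mean(draws) - mean(depths)), 2 * sd(draws) + 1)
})

test_that("run_mcmc is deterministic and respects its support constraints", {
  fx <- sim_track(T = 25, seed = 52, dives_rate = 2, fixes_rate = 3)
  cfg <- mcmc_config(n_chains = 1, n_iter = 120, n_burnin = 60, thin = 2,
                     seed = 7)
  d1 <- run_mcmc(list(fx$track), cfg)
  d2 <- run_mcmc(list(fx$track), cfg)
  expect_identical(d1$chains[[1]]$params, d2$chains[[1]]$params)
  expect_identical(d1$chains[[1]]$s_top, d2$chains[[1]]$s_top)
  pm <- d1$chains[[1]]$params
  expect_true(all(pm[, "gamma_travel"] > pm[, "gamma_ars"]))
  expect_true(all(pm[, c("gamma_travel", "gamma_ars")] >= 0 &
                    pm[, c("gamma_travel", "gamma_ars")] <= 1))
  expect_true(all(pm[, "mu_forage"] >= 50 & pm[, "mu_forage"] <= 250))
  expect_true(all(pm[, c("mu_travel", "mu_rest")] >= 0 &
                    pm[, c("mu_travel", "mu_rest")] <= 30))
  expect_true(all(pm[, c("sd_travel", "sd_forage", "sd_rest")] > 0))
  expect_error(run_mcmc(list(), cfg), "empty")
})

test_that("the Gelman-Rubin statistic behaves across regimes", {
  expect_error(gelman_rubin(list(rnorm(100))), "chains")
  # identical constant chains: degenerate, not NaN
  r <- gelman_rubin(list(rep(1, 100), rep(1, 100)))
  expect_true(is.na(r))
  expect_true(attr(r, "degenerate"))
  # long i.i.d. chains: r-hat within a hair of 1
  set.seed(53)
  r2 <- gelman_rubin(list(rnorm(10000), rnorm(10000)))
  expect_gt(r2, 0.99)
  expect_lt(r2, 1.02)
  # disjoint supports: gross non-convergence
  r3 <- gelman_rubin(list(rnorm(1000, 0, 1), rnorm(1000, 100, 1)))
  expect_gt(r3, 10)
})
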