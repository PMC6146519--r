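# Cache shared across test blocks (e.g. the scaled synthetic fit reused by
# the convergence and decoding checks).
acc_cache <- new.env()

# Shared fixture builders and independent oracles. Oracles here are written
# against the model's closed forms (enumeration, truncated-normal moments),
# never against the code paths they check.

# Simulate one track's components and wrap them as a regular_track, keeping
# the latent truth alongside.
sim_track <- function(T, seed, params = default_params(), fixes_rate = 2,
                      dives_rate = 1.5, missing = 0, argos_sds = NULL) {
  cfg <- simulation_config(n_animals = 1, steps_per_animal = T,
                           true_params = params,
                           fixes_per_interval_rate = fixes_rate,
                           dives_per_interval_rate = dives_rate,
                           missing_interval_prob = missing, seed = seed)
  if (!is.null(argos_sds)) cfg$argos_sds <- argos_sds
  set.seed(seed)
  chain <- simulate_latent_chain(cfg)
  dvs <- simulate_dives(chain$s_top, cfg)
  fxs <- degrade_to_argos(chain$Y, cfg)
  track <- structure(list(
    animal = "a", g = 1L, start = cfg$start_time, n_intervals = as.integer(T),
    fixes = data.frame(t = fxs$t, j = fxs$j, x = fxs$x, y = fxs$y,
                       error_class = fxs$error_class),
    dives = data.frame(t = dvs$dives$t, u = dvs$dives$u,
                       timestamp = dvs$dives$timestamp,
                       depth = dvs$dives$depth,
                       duration = dvs$dives$duration),
    n_dropped_dives = 0L), class = "regular_track")
  list(track = track, Y = chain$Y, s_top = chain$s_top, s_sub = dvs$s_sub,
       config = cfg)
}

# Brute-force marginal likelihood: enumerate every top-state path and every
# sub-state assignment, sum the complete-data likelihoods.
enum_marginal_loglik <- function(track, Y, params, et) {
  T <- track$n_intervals
  D <- nrow(track$dives)
  tops <- as.matrix(expand.grid(rep(list(1:2), T)))
  subs <- if (D > 0) as.matrix(expand.grid(rep(list(1:2), D)))
          else matrix(integer(0), 1, 0)
  lls <- numeric(nrow(tops) * nrow(subs))
  i <- 0L
  for (a in seq_len(nrow(tops))) for (b in seq_len(nrow(subs))) {
    i <- i + 1L
    lls[i] <- complete_data_loglik(
      list(track),
      list(list(Y = Y, s_top = as.integer(tops[a, ]),
                s_sub = as.integer(subs[b, ]))),
      params, et)
  }
  m <- max(lls)
  m + log(sum(exp(lls - m)))
}

# Exact posterior over top-state paths with the sub-states held fixed.
enum_top_posterior <- function(track, Y, s_sub, params, et) {
  T <- track$n_intervals
  tops <- as.matrix(expand.grid(rep(list(1:2), T)))
  ll <- apply(tops, 1, function(st) complete_data_loglik(
    list(track), list(list(Y = Y, s_top = as.integer(st), s_sub = s_sub)),
    params, et))
  post <- exp(ll - max(ll))
  list(paths = tops, prob = post / sum(post))
}

# Mean of a normal truncated below, by the standard moment formula.
oracle_tnorm_mean <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  mu + sd * dnorm(a) / (1 - pnorm(a))
}

# Hand-built posterior-draws object for summary tests.
fake_draws <- function(s_top_draws, s_sub_draws, dive_t, dive_depth,
                       dive_time, animal = "a",
                       params_row = params_to_vec(default_params()),
                       start = as.POSIXct("2016-03-01", tz = "UTC")) {
  n_int <- ncol(s_top_draws)
  n_draw <- nrow(s_top_draws)
  pmat <- matrix(rep(params_row, each = n_draw), n_draw,
                 dimnames = list(NULL, names(params_row)))
  structure(list(
    chains = list(list(params = pmat, s_top = s_top_draws,
                       s_sub = s_sub_draws,
                       accept = list(y_rate = NA, p_rate = NA), seed = 1L)),
    param_names = names(params_row),
    data_map = list(
      intervals = data.frame(track = 1L, animal = animal, t = seq_len(n_int),
                             start = start + (seq_len(n_int) - 1) * 21600),
      dives = if (length(dive_t))
        data.frame(track = 1L, animal = animal, t = dive_t,
                   timestamp = dive_time, depth = dive_depth) else NULL,
      n_intervals = n_int, n_dives = length(dive_t)),
    config = NULL, priors = default_priors(), threshold = 10),
    class = "crw_draws")
}

params_to_vec <- function(p) {
  setNames(c(p$gamma, p$theta, p$process_sd, p$alpha_top,
             p$alpha_sub[1, ], p$alpha_sub[2, ], p$dive_mu, p$dive_sd),
           c("gamma_travel", "gamma_ars", "theta_travel", "theta_ars",
             "sigma_x", "sigma_y", "alpha_top_from_travel",
             "alpha_top_from_ars", "alpha_sub_travel_from_forage",
             "alpha_sub_travel_from_rest", "alpha_sub_ars_from_forage",
             "alpha_sub_ars_from_rest", "mu_travel", "mu_forage", "mu_rest",
             "sd_travel", "sd_forage", "sd_rest"))
}

# Parameters with both movement states identical and all three depth
# components identical: the state posterior is exactly symmetric.
symmetric_params <- function() {
  crw_params(gamma = c(0.5, 0.5), theta = c(0, 0), process_sd = c(2, 2),
             alpha_top = c(0, 0), alpha_sub = rbind(c(0, 0), c(0, 0)),
             dive_mu = c(60, 60, 60), dive_sd = c(25, 25, 25))
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Raw-fix data.frame builder for preprocessing tests.
raw_fixes <- function(animal, hours, x, y, class = "3",
                      t0 = utc("2016-03-01")) {
  data.frame(animal = rep_len(animal, length(hours)),
             timestamp = t0 + hours * 3600,
             x = rep_len(x, length(hours)), y = rep_len(y, length(hours)),
             error_class = rep_len(class, length(hours)))
}

raw_dives <- function(animal, hours, depth, duration,
                      t0 = utc("2016-03-01")) {
  data.frame(animal = animal, timestamp = t0 + hours * 3600,
             depth = depth, duration = duration, shape = 1)
}
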