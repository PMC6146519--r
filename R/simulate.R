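# Synthetic-data generator: draws tracks, dives and degraded Argos fixes from
# the exact generative model, so that preprocessing, inference, decoding and
# summaries are testable without tag data.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the observed data regime of a multi-animal austral-season
#' humpback deployment: 11 animals, ~27 days (107 six-hour intervals) each,
#' about 8 Argos fixes and 22 transmitted dives per interval before
#' filtering, with a realistic spread of Argos quality classes dominated by
#' the low-precision classes.
#'
#' @param n_animals number of simulated deployments.
#' @param steps_per_animal number of six-hour intervals per deployment.
#' @param true_params generative [crw_params].
#' @param fixes_per_interval_rate Poisson mean of Argos fixes per interval
#'   (must be > 0).
#' @param dives_per_interval_rate Poisson mean of dives per interval (>= 0).
#' @param argos_class_probs named probabilities over classes 3,2,1,0,A,B
#'   (must sum to 1 within 1e-12).
#' @param missing_interval_prob probability an interval transmits no fix.
#' @param argos_sds per-class noise sds used for degradation; defaults to the
#'   shipped [argos_error_table()].
#' @param origin,initial_sd initial-location prior: the first two nodes of
#'   each track are drawn `N(origin, initial_sd^2 I)` (km).
#' @param start_time deployment start of the first animal (UTC);
#'   deployments are staggered by `animal_spacing_days`.
#' @param animal_spacing_days days between consecutive deployment starts.
#' @param duration_meanlog,duration_sdlog lognormal dive-duration stub (s);
#'   schema-filling only, the model ignores durations.
#' @param dive_threshold truncation depth (m) of the depth emissions.
#' @param seed integer; fixes the full generated output bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_animals = 11,
                              steps_per_animal = 107,
                              true_params = default_params(),
                              fixes_per_interval_rate = 7.9,
                              dives_per_interval_rate = 22.4,
                              argos_class_probs = c("3" = 0.03, "2" = 0.07,
                                                    "1" = 0.12, "0" = 0.22,
                                                    "A" = 0.27, "B" = 0.29),
                              missing_interval_prob = 0.1,
                              argos_sds = argos_error_table(),
                              origin = c(0, 0),
                              initial_sd = 5,
                              start_time = as.POSIXct("2016-03-01 00:00:00",
                                                      tz = "UTC"),
                              animal_spacing_days = 3,
                              duration_meanlog = log(180),
                              duration_sdlog = 0.5,
                              dive_threshold = 10,
                              seed = 1L) {
  if (n_animals < 1) stop("n_animals must be >= 1", call. = FALSE)
  if (steps_per_animal < 2) stop("steps_per_animal must be >= 2",
                                 call. = FALSE)
  if (fixes_per_interval_rate <= 0)
    stop("fixes_per_interval_rate must be > 0", call. = FALSE)
  if (dives_per_interval_rate < 0)
    stop("dives_per_interval_rate must be >= 0", call. = FALSE)
  if (abs(sum(argos_class_probs) - 1) > 1e-12)
    stop("argos_class_probs must sum to 1", call. = FALSE)
  if (!setequal(names(argos_class_probs), .argos_classes))
    stop("argos_class_probs must cover classes 3,2,1,0,A,B", call. = FALSE)
  if (missing_interval_prob < 0 || missing_interval_prob >= 1)
    stop("missing_interval_prob must be in [0, 1)", call. = FALSE)
  validate_params(true_params)
  cfg <- list(n_animals = as.integer(n_animals),
              steps_per_animal = as.integer(steps_per_animal),
              true_params = true_params,
              fixes_per_interval_rate = fixes_per_interval_rate,
              dives_per_interval_rate = dives_per_interval_rate,
              argos_class_probs = argos_class_probs[.argos_classes],
              missing_interval_prob = missing_interval_prob,
              argos_sds = argos_sds,
              origin = origin,
              initial_sd = initial_sd,
              start_time = start_time,
              animal_spacing_days = animal_spacing_days,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              dive_threshold = dive_threshold,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the latent movement chain of one animal
#'
#' Draws the top-layer state sequence from its logistic transition law (the
#' first interval's state is uniform) and the node locations from the
#' switching correlated random walk: the first two nodes come from the
#' initial-location prior, and each later node is bivariate normal around the
#' state-dependent [process_mean()].
#'
#' Uses the current RNG state; seed via [simulate_dataset()] or `set.seed()`.
#'
#' @param config [simulation_config()].
#' @return List with `s_top` (length `T` states) and `Y`
#'   (`(T+1) x 2` node locations, km).
#' @export
simulate_latent_chain <- function(config) {
  p <- config$true_params
  validate_params(p)
  T <- config$steps_per_animal
  Y <- matrix(NA_real_, T + 1L, 2)
  Y[1, ] <- stats::rnorm(2, config$origin, config$initial_sd)
  Y[2, ] <- stats::rnorm(2, config$origin, config$initial_sd)
  s_top <- integer(T)
  s_top[1] <- 1L + stats::rbinom(1, 1, 0.5)
  for (t in 2:T) {
    p_travel <- stats::plogis(p$alpha_top[s_top[t - 1L]])
    s_top[t] <- if (stats::runif(1) < p_travel) 1L else 2L
    d <- process_mean(Y[t, ], Y[t - 1L, ], s_top[t], p)
    Y[t + 1L, ] <- stats::rnorm(2, d, p$process_sd)
  }
  list(s_top = s_top, Y = Y)
}

#' Simulate dive records along a state sequence
#'
#' Dive counts per interval are Poisson; dive times are uniform inside their
#' interval. The sub-state chain evolves dive-by-dive along the whole
#' deployment using the transition-logit row of the interval's current top
#' state (the first dive's sub-state is uniform). Depths are drawn from the
#' truncated-normal component of the emitting behavior: the traveling
#' component inside traveling intervals (where the sub-state is carried but
#' not emitted from) and the sub-state's component inside ARS intervals.
#' Durations and shape codes are schema-filling stubs the model ignores.
#'
#' @param s_top integer state sequence (1 = travel, 2 = ARS).
#' @param config [simulation_config()].
#' @param start_time deployment start (UTC).
#' @return List with `dives` (data.frame: `t`, `u`, `timestamp`, `depth`,
#'   `duration`, `shape`) and `s_sub` (one sub-state per dive).
#' @export
simulate_dives <- function(s_top, config, start_time = config$start_time) {
  if (length(s_top) == 0L) stop("empty state sequence", call. = FALSE)
  p <- config$true_params
  counts <- stats::rpois(length(s_top), config$dives_per_interval_rate)
  n <- sum(counts)
  if (n == 0L) {
    return(list(dives = data.frame(t = integer(0), u = integer(0),
                                   timestamp = as.POSIXct(character(0),
                                                          tz = "UTC"),
                                   depth = numeric(0), duration = numeric(0),
                                   shape = integer(0)),
                s_sub = integer(0)))
  }
  t_idx <- rep(seq_along(s_top), counts)
  offs <- stats::runif(n)
  ord <- order(t_idx, offs)
  t_idx <- t_idx[ord]; offs <- offs[ord]
  u <- stats::ave(seq_len(n), t_idx, FUN = seq_along)
  s_sub <- integer(n)
  depth <- numeric(n)
  for (i in seq_len(n)) {
    s <- s_top[t_idx[i]]
    if (i == 1L) {
      s_sub[i] <- 1L + stats::rbinom(1, 1, 0.5)
    } else {
      p_forage <- stats::plogis(p$alpha_sub[s, s_sub[i - 1L]])
      s_sub[i] <- if (stats::runif(1) < p_forage) 1L else 2L
    }
    b <- if (s == 1L) 1L else 1L + s_sub[i]
    depth[i] <- rtnorm(1, p$dive_mu[b], p$dive_sd[b], config$dive_threshold)
  }
  dives <- data.frame(
    t = t_idx, u = as.integer(u),
    timestamp = start_time + ((t_idx - 1) + offs) * 6 * 3600,
    depth = depth,
    duration = stats::rlnorm(n, config$duration_meanlog,
                             config$duration_sdlog),
    shape = sample(0:5, n, replace = TRUE)
  )
  list(dives = dives, s_sub = s_sub)
}

#' Degrade a latent trajectory to Argos-like fixes
#'
#' Fix counts per interval are Poisson (whole intervals silenced with
#' `missing_interval_prob`); fix times are uniform within the interval; each
#' fix observes the within-interval linear interpolation of the bracketing
#' nodes plus isotropic normal noise with the fix's class-specific sd, the
#' class drawn from `argos_class_probs`.
#'
#' @param Y `(T+1) x 2` latent node locations.
#' @param config [simulation_config()].
#' @param start_time deployment start (UTC).
#' @return Data.frame with `t`, `j`, `timestamp`, `x`, `y`, `error_class`.
#' @export
degrade_to_argos <- function(Y, config, start_time = config$start_time) {
  T <- nrow(Y) - 1L
  if (T < 1L) stop("need at least 2 latent locations", call. = FALSE)
  present <- stats::runif(T) >= config$missing_interval_prob
  counts <- ifelse(present, stats::rpois(T, config$fixes_per_interval_rate),
                   0L)
  n <- sum(counts)
  if (n == 0L) {
    return(data.frame(t = integer(0), j = numeric(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      x = numeric(0), y = numeric(0),
                      error_class = character(0)))
  }
  t_idx <- rep(seq_len(T), counts)
  j <- stats::runif(n)
  ord <- order(t_idx, j)
  t_idx <- t_idx[ord]; j <- j[ord]
  zx <- (1 - j) * Y[t_idx, 1] + j * Y[t_idx + 1L, 1]
  zy <- (1 - j) * Y[t_idx, 2] + j * Y[t_idx + 1L, 2]
  cls <- sample(names(config$argos_class_probs), n, replace = TRUE,
                prob = config$argos_class_probs)
  sd <- unclass(config$argos_sds)[cls]
  data.frame(t = t_idx, j = j,
             timestamp = start_time + ((t_idx - 1) + j) * 6 * 3600,
             x = zx + stats::rnorm(n, 0, sd),
             y = zy + stats::rnorm(n, 0, sd),
             error_class = cls)
}

#' Simulate a full multi-animal dataset
#'
#' Seeds the RNG from `config$seed` and draws, per animal, the latent chain,
#' the dive stream and the degraded Argos stream, with deployment starts
#' staggered across animals. The same configuration always yields
#' bit-identical output.
#'
#' @param config [simulation_config()].
#' @return Object of class `synthetic_dataset`: `fixes`, `dives`,
#'   `truth` (`$intervals` with per-interval states and node coordinates,
#'   `$dives` with per-dive sub-states), and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fixes <- list(); dives <- list(); truth_i <- list(); truth_d <- list()
  for (a in seq_len(config$n_animals)) {
    t0 <- config$start_time + (a - 1) * config$animal_spacing_days * 86400
    chain <- simulate_latent_chain(config)
    dv <- simulate_dives(chain$s_top, config, t0)
    fx <- degrade_to_argos(chain$Y, config, t0)
    id <- sprintf("sim%02d", a)
    T <- config$steps_per_animal
    if (nrow(fx)) fixes[[a]] <- data.frame(animal = id,
                                           timestamp = fx$timestamp,
                                           x_km = fx$x, y_km = fx$y,
                                           argos_class = fx$error_class)
    if (nrow(dv$dives))
      dives[[a]] <- data.frame(animal = id,
                               timestamp = dv$dives$timestamp,
                               depth_m = dv$dives$depth,
                               duration_s = dv$dives$duration,
                               shape = dv$dives$shape)
    truth_i[[a]] <- data.frame(animal = id, interval = seq_len(T),
                               start = t0 + (seq_len(T) - 1) * 6 * 3600,
                               s_top = .top_states[chain$s_top],
                               x_start = chain$Y[seq_len(T), 1],
                               y_start = chain$Y[seq_len(T), 2],
                               x_end = chain$Y[seq_len(T) + 1L, 1],
                               y_end = chain$Y[seq_len(T) + 1L, 2])
    if (nrow(dv$dives))
      truth_d[[a]] <- data.frame(animal = id, interval = dv$dives$t,
                                 order = dv$dives$u,
                                 timestamp = dv$dives$timestamp,
                                 s_sub = .sub_states[dv$s_sub])
  }
  empty_fix <- data.frame(animal = character(0),
                          timestamp = as.POSIXct(character(0), tz = "UTC"),
                          x_km = numeric(0), y_km = numeric(0),
                          argos_class = character(0))
  empty_dive <- data.frame(animal = character(0),
                           timestamp = as.POSIXct(character(0), tz = "UTC"),
                           depth_m = numeric(0), duration_s = numeric(0),
                           shape = integer(0))
  out <- list(fixes = if (length(fixes)) do.call(rbind, fixes) else empty_fix,
              dives = if (length(dives)) do.call(rbind, dives) else empty_dive,
              truth = list(
                intervals = do.call(rbind, truth_i),
                dives = if (length(truth_d)) do.call(rbind, truth_d) else NULL
              ),
              config = config)
  class(out) <- "synthetic_dataset"
  out
}
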