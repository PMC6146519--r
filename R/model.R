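# Model core: every density the sampler needs.
#
# Notation (per animal and track): latent planar locations Y_1..Y_{T+1} sit on
# the nodes of a grid of T six-hour intervals; the top-layer state S'_t of
# interval t governs the correlated-random-walk step from node t to node t+1
# and the dive emissions inside interval t. An Argos fix in interval t with
# interval fraction j is centered on (1-j)*Y_t + j*Y_{t+1}. The dive sub-state
# S''_u evolves dive-by-dive along the whole track with transition logits
# alpha_sub[S'_t(u), S''_{u-1}]; depths are emitted from the foraging/resting
# component inside ARS intervals and from the traveling component otherwise,
# each truncated below at the dive-definition depth.

#' Rotation matrix of the correlated random walk
#'
#' @param theta turning angle in radians.
#' @return 2x2 rotation matrix.
#' @export
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Expected next location of the movement process
#'
#' `d = Y_t + gamma_s * R(theta_s) (Y_t - Y_prev)`: the previous displacement,
#' damped by the state's autocorrelation and rotated by its mean turning
#' angle, added to the current location.
#'
#' @param y_t,y_prev length-2 planar locations (km).
#' @param state top state, `1`/`"travel"` or `2`/`"ars"`.
#' @param params [crw_params].
#' @return Length-2 planar point.
#' @export
process_mean <- function(y_t, y_prev, state, params) {
  s <- if (is.character(state)) match(state, .top_states) else as.integer(state)
  if (!all(is.finite(c(y_t, y_prev)))) stop("non-finite locations")
  d <- y_t + params$gamma[s] *
    drop(rotation_matrix(params$theta[s]) %*% (y_t - y_prev))
  as.numeric(d)
}

#' State-transition probability from a logit
#'
#' Inverse-logistic map used by both behavioral layers.
#'
#' @param alpha_logit finite logit.
#' @return Probability in (0, 1).
#' @export
transition_prob <- function(alpha_logit) {
  if (any(!is.finite(alpha_logit))) stop("non-finite logit")
  stats::plogis(alpha_logit)
}

#' Log-likelihood of one Argos fix
#'
#' Bivariate normal (independent coordinates) log density of the observed fix
#' around the within-interval linear interpolation of the bracketing latent
#' locations, with the class-specific standard deviation.
#'
#' @param fix length-2 observed planar location (km).
#' @param y_prev,y_t latent locations at the interval's start and end nodes.
#' @param j interval fraction in `[0, 1]`.
#' @param sd measurement sd (km), or an [argos_error_table()] together with
#'   `error_class`.
#' @param error_class optional Argos class looked up in `sd`.
#' @return Scalar log density.
#' @export
observation_loglik <- function(fix, y_prev, y_t, j, sd, error_class = NULL) {
  if (j < 0 || j > 1) stop("interval fraction j must be in [0, 1]")
  if (!is.null(error_class)) {
    if (!error_class %in% names(sd))
      stop("unknown Argos error class: ", error_class)
    sd <- sd[[error_class]]
  }
  z <- (1 - j) * y_prev + j * y_t
  sum(stats::dnorm(fix, z, sd, log = TRUE))
}

#' Log-likelihood of one dive depth
#'
#' Normal log density of the emitting component, truncated below at the
#' dive-definition depth and renormalized (transmitted records only exist for
#' submergences past that depth, so the emission support is `(threshold,
#' Inf)`). `truncated = FALSE` gives the plain normal density for sensitivity
#' checks.
#'
#' @param depth dive depth (m), `> threshold`.
#' @param behavior `"traveling"`, `"foraging"` or `"resting"` (or index 1:3).
#' @param params [crw_params].
#' @param threshold truncation depth (m), default 10.
#' @param truncated renormalize over `(threshold, Inf)`.
#' @return Log density (vectorized over `depth`).
#' @export
dive_loglik <- function(depth, behavior, params, threshold = 10,
                        truncated = TRUE) {
  b <- if (is.character(behavior)) match(behavior, .behaviors)
       else as.integer(behavior)
  if (any(is.na(b))) stop("unknown behavior")
  mu <- params$dive_mu[b]
  sd <- params$dive_sd[b]
  if (any(sd <= 0)) stop("dive_sd must be > 0")
  if (truncated) dtnorm_log(depth, mu, sd, threshold)
  else stats::dnorm(depth, mu, sd, log = TRUE)
}

# ---- vectorized per-track terms -------------------------------------------

# Per-step process log densities: entry t (t = 2..T) is the log density of
# Y_{t+1} given Y_t, Y_{t-1} and state s_top[t]; entry 1 is 0 (the first two
# nodes carry the initial-location prior, flat in inference).
process_term_vec <- function(Y, s_top, params) {
  T <- length(s_top)
  out <- numeric(T)
  if (T < 2) return(out)
  t_idx <- 2:T
  g <- params$gamma[s_top[t_idx]]
  th <- params$theta[s_top[t_idx]]
  dx <- Y[t_idx, 1] - Y[t_idx - 1, 1]
  dy <- Y[t_idx, 2] - Y[t_idx - 1, 2]
  mx <- Y[t_idx, 1] + g * (cos(th) * dx - sin(th) * dy)
  my <- Y[t_idx, 2] + g * (sin(th) * dx + cos(th) * dy)
  out[t_idx] <- stats::dnorm(Y[t_idx + 1, 1], mx, params$process_sd[1],
                             log = TRUE) +
    stats::dnorm(Y[t_idx + 1, 2], my, params$process_sd[2], log = TRUE)
  out
}

# As process_term_vec but for both candidate states: T x 2 matrix.
process_term_both <- function(Y, params) {
  T <- nrow(Y) - 1L
  out <- matrix(0, T, 2)
  if (T < 2) return(out)
  t_idx <- 2:T
  dx <- Y[t_idx, 1] - Y[t_idx - 1, 1]
  dy <- Y[t_idx, 2] - Y[t_idx - 1, 2]
  for (s in 1:2) {
    g <- params$gamma[s]; th <- params$theta[s]
    mx <- Y[t_idx, 1] + g * (cos(th) * dx - sin(th) * dy)
    my <- Y[t_idx, 2] + g * (sin(th) * dx + cos(th) * dy)
    out[t_idx, s] <- stats::dnorm(Y[t_idx + 1, 1], mx, params$process_sd[1],
                                  log = TRUE) +
      stats::dnorm(Y[t_idx + 1, 2], my, params$process_sd[2], log = TRUE)
  }
  out
}

# Per-fix observation log densities given latent nodes Y. fixes needs columns
# t, j, x, y and a per-fix sd vector.
obs_term_vec <- function(fixes, Y, fix_sd) {
  if (nrow(fixes) == 0L) return(numeric(0))
  zx <- (1 - fixes$j) * Y[fixes$t, 1] + fixes$j * Y[fixes$t + 1L, 1]
  zy <- (1 - fixes$j) * Y[fixes$t, 2] + fixes$j * Y[fixes$t + 1L, 2]
  stats::dnorm(fixes$x, zx, fix_sd, log = TRUE) +
    stats::dnorm(fixes$y, zy, fix_sd, log = TRUE)
}

# Dive emission log density matrix (n_dives x 2 candidate top states) given
# the current sub-states: column 1 = traveling component, column 2 = the
# sub-state's ARS component.
dive_emission_both <- function(depth, s_sub, params, threshold = 10) {
  cbind(dtnorm_log(depth, params$dive_mu[1], params$dive_sd[1], threshold),
        dtnorm_log(depth, params$dive_mu[1 + s_sub],
                   params$dive_sd[1 + s_sub], threshold))
}

# Sub-chain transition log probabilities for a track, for both candidate top
# states of the interval owning each transition: n_dives x 2 matrix (first
# dive of the track gets the uniform initial log 0.5 in both columns).
sub_transition_both <- function(s_sub, params) {
  n <- length(s_sub)
  out <- matrix(log(0.5), n, 2)
  if (n < 2) return(out)
  prev <- s_sub[-n]
  cur <- s_sub[-1]
  for (s in 1:2) {
    p_forage <- stats::plogis(params$alpha_sub[s, prev])
    out[-1, s] <- ifelse(cur == 1L, log(p_forage), log1p(-p_forage))
  }
  out
}

#' Complete-data log-likelihood of the nested model
#'
#' Joint log density of the latent locations, both discrete state layers, the
#' Argos fixes and the dive depths, given the parameters: the sum of the
#' process terms, the top-layer transition terms (with a uniform distribution
#' over the first interval's state), the sub-layer transition terms (uniform
#' over the first dive's sub-state), the observation terms and the truncated
#' depth-emission terms. Additive over tracks.
#'
#' @param tracks list of `regular_track` objects (see [regularize()]).
#' @param latent list parallel to `tracks`; each element has `Y`
#'   (`(T+1) x 2` node locations), `s_top` (length `T`) and `s_sub`
#'   (one per dive).
#' @param params [crw_params].
#' @param error_table [argos_error_table()].
#' @param threshold dive truncation depth (m).
#' @return Scalar log density (0 for an empty track list).
#' @export
complete_data_loglik <- function(tracks, latent, params,
                                 error_table = argos_error_table(),
                                 threshold = 10) {
  if (length(tracks) != length(latent))
    stop("tracks and latent differ in length")
  total <- 0
  for (k in seq_along(tracks)) {
    trk <- tracks[[k]]
    lat <- latent[[k]]
    T <- trk$n_intervals
    if (length(lat$s_top) != T || nrow(lat$Y) != T + 1L)
      stop("latent dimensions do not match track ", k)
    if (nrow(trk$dives) != length(lat$s_sub))
      stop("sub-state dimensions do not match dives in track ", k)
    total <- total + sum(process_term_vec(lat$Y, lat$s_top, params))
    # top-layer chain
    total <- total + log(0.5)
    if (T >= 2) {
      p_tr <- stats::plogis(params$alpha_top[lat$s_top[-T]])
      total <- total + sum(ifelse(lat$s_top[-1] == 1L, log(p_tr),
                                  log1p(-p_tr)))
    }
    fix_sd <- unclass(error_table)[trk$fixes$error_class]
    total <- total + sum(obs_term_vec(trk$fixes, lat$Y, fix_sd))
    if (nrow(trk$dives) > 0L) {
      st <- sub_transition_both(lat$s_sub, params)
      s_of_dive <- lat$s_top[trk$dives$t]
      total <- total + sum(st[cbind(seq_len(nrow(st)), s_of_dive)])
      em <- dive_emission_both(trk$dives$depth, lat$s_sub, params, threshold)
      total <- total + sum(em[cbind(seq_len(nrow(em)), s_of_dive)])
    }
  }
  total
}

#' Marginal log-likelihood over both discrete state layers
#'
#' Exact forward recursion that marginalizes the top-layer state sequence and
#' every dive's sub-state jointly, conditional on the latent locations and
#' parameters. The filter runs over the pair (current top state, most recent
#' sub-state), alternating top-layer transition/process updates between
#' intervals with dive-by-dive sub-chain updates inside intervals. Includes
#' the same constant terms (initial state distributions, observation terms)
#' as [complete_data_loglik()], so that
#' `exp(forward_loglik)` equals the sum of `exp(complete_data_loglik)` over
#' all discrete state paths.
#'
#' @inheritParams complete_data_loglik
#' @param track one `regular_track`.
#' @param Y `(T+1) x 2` latent node locations.
#' @return Scalar log marginal likelihood.
#' @export
forward_loglik <- function(track, Y, params,
                           error_table = argos_error_table(),
                           threshold = 10) {
  T <- track$n_intervals
  pt <- process_term_both(Y, params)
  # log P(next top | prev top): rows prev, cols next
  p_tr <- stats::plogis(params$alpha_top)
  ltop <- cbind(log(p_tr), log1p(-p_tr))
  # filter over (s_top, last sub-state); start: uniform top and sub priors.
  # Until the first dive is seen the sub-state column is a placeholder with a
  # uniform distribution; the first dive itself draws its sub-state from the
  # uniform initial law (matching complete_data_loglik), later dives from the
  # transition law.
  M <- matrix(-Inf, 2, 2)
  seen_dive <- FALSE
  for (t in seq_len(T)) {
    A <- matrix(-Inf, 2, 2)
    if (t == 1L) {
      A[] <- log(0.5) + log(0.5)
    } else {
      for (s in 1:2) for (p in 1:2)
        A[s, p] <- logsumexp(M[, p] + ltop[, s])
    }
    A <- A + pt[t, ][row(A)]
    dv <- which(track$dives$t == t)
    for (u in dv) {
      depth <- track$dives$depth[u]
      B <- matrix(-Inf, 2, 2)
      em_travel <- dtnorm_log(depth, params$dive_mu[1], params$dive_sd[1],
                              threshold)
      for (s in 1:2) {
        p_forage <- stats::plogis(params$alpha_sub[s, ])  # by prev sub
        for (cc in 1:2) {
          ltr <- if (!seen_dive) rep(log(0.5), 2)
                 else if (cc == 1L) log(p_forage) else log1p(-p_forage)
          em <- if (s == 1L) em_travel
                else dtnorm_log(depth, params$dive_mu[1 + cc],
                                params$dive_sd[1 + cc], threshold)
          B[s, cc] <- logsumexp(A[s, ] + ltr) + em
        }
      }
      A <- B
      seen_dive <- TRUE
    }
    M <- A
  }
  fix_sd <- unclass(error_table)[track$fixes$error_class]
  logsumexp(as.numeric(M)) + sum(obs_term_vec(track$fixes, Y, fix_sd))
}
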