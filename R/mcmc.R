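# Posterior sampling: forward filtering-backward sampling for both discrete
# state layers, per-node adaptive Metropolis for the latent locations, and
# Metropolis-within-Gibbs for the parameters.

#' MCMC configuration
#'
#' Defaults mirror the chain protocol of the motivating analysis: 2 chains of
#' 30,000 iterations, the first 28,000 discarded as burn-in, and the
#' remaining 2,000 thinned by 4 (500 retained draws per chain).
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations (`< n_iter`); proposal scales adapt
#'   only during burn-in and are frozen afterwards.
#' @param thin thinning stride for retained draws.
#' @param seed master seed; chain `c` uses `seed + 10007 * (c - 1)` so adding
#'   chains never reshuffles earlier ones.
#' @param adapt_window iterations between proposal-scale adaptations.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 30000, n_burnin = 28000,
                        thin = 4, seed = 1L, adapt_window = 50) {
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  n_retained <- floor((n_iter - n_burnin) / thin)
  if (n_retained < 1) stop("no retained draws requested", call. = FALSE)
  if (n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window),
                 n_retained = as.integer(n_retained)),
            class = "mcmc_config")
}

# log transition matrix of the top layer: rows = previous state, cols = next.
top_ltrans <- function(params) {
  p_tr <- stats::plogis(params$alpha_top)
  cbind(log(p_tr), log1p(-p_tr))
}

#' Draw top-layer state paths from their exact full conditional
#'
#' Forward filtering-backward sampling over one track's intervals, given the
#' latent locations and the current dive sub-states. The per-interval
#' emission combines the state-dependent process term with the interval's
#' dive-depth and sub-chain transition terms.
#'
#' @param track a `regular_track`.
#' @param Y `(T+1) x 2` latent node locations.
#' @param s_sub current sub-state per dive.
#' @param params [crw_params].
#' @param n_draws number of independent paths to draw.
#' @param threshold dive truncation depth (m).
#' @return Integer matrix `n_draws x T` of states (1 travel, 2 ARS).
#' @export
ffbs_top <- function(track, Y, s_sub, params, n_draws = 1, threshold = 10) {
  T <- track$n_intervals
  loge <- process_term_both(Y, params)
  nd <- nrow(track$dives)
  if (nd > 0L) {
    em <- dive_emission_both(track$dives$depth, s_sub, params, threshold)
    st <- sub_transition_both(s_sub, params)
    contrib <- em + st
    for (s in 1:2) {
      agg <- rowsum(contrib[, s], track$dives$t)
      loge[as.integer(rownames(agg)), s] <-
        loge[as.integer(rownames(agg)), s] + agg[, 1]
    }
  }
  ltop <- top_ltrans(params)
  l11 <- ltop[1, 1]; l21 <- ltop[2, 1]; l12 <- ltop[1, 2]; l22 <- ltop[2, 2]
  f <- .fwd_pair_cpp(loge[, 1], loge[, 2], rep(l11, T), rep(l21, T),
                     rep(l12, T), rep(l22, T))
  f1 <- f$f1; f2 <- f$f2
  if (anyNA(f1) || anyNA(f2)) stop("NaN in forward filter", call. = FALSE)
  draws <- matrix(1L, n_draws, T)
  p_last <- stats::plogis(f1[T] - f2[T])
  draws[, T] <- 2L - (stats::runif(n_draws) < p_last)
  if (T >= 2) {
    # P(travel | next state), vectorized over t for both candidate values
    p_next1 <- stats::plogis(f1 + l11 - f2 - l21)[-T]
    p_next2 <- stats::plogis(f1 + l12 - f2 - l22)[-T]
    if (n_draws == 1L) {
      draws[1, ] <- .bwd_sample_cpp(p_next1, p_next2, stats::runif(T - 1),
                                    draws[1, T])
    } else {
      for (t in (T - 1):1) {
        is1 <- draws[, t + 1] == 1L
        p <- p_next2[t] + (p_next1[t] - p_next2[t]) * is1
        draws[, t] <- 2L - (stats::runif(n_draws) < p)
      }
    }
  }
  draws
}

#' Draw dive sub-state paths from their exact full conditional
#'
#' Forward filtering-backward sampling over one track's whole dive sequence,
#' given the top-layer states. The sub-chain runs across interval boundaries;
#' the transition row is indexed by the interval's current top state, and
#' emissions are active only inside ARS intervals (traveling dives are
#' emitted from the traveling component, which does not depend on the
#' sub-state).
#'
#' @inheritParams ffbs_top
#' @param s_top current top state per interval.
#' @return Integer matrix `n_draws x n_dives` (1 forage, 2 rest); zero
#'   columns when the track has no dives.
#' @export
ffbs_sub <- function(track, s_top, params, n_draws = 1, threshold = 10) {
  n <- nrow(track$dives)
  if (n == 0L) return(matrix(integer(0), n_draws, 0))
  s_of <- s_top[track$dives$t]
  depth <- track$dives$depth
  em <- matrix(0, n, 2)
  ars <- s_of == 2L
  if (any(ars)) {
    em[ars, 1] <- dtnorm_log(depth[ars], params$dive_mu[2],
                             params$dive_sd[2], threshold)
    em[ars, 2] <- dtnorm_log(depth[ars], params$dive_mu[3],
                             params$dive_sd[3], threshold)
  }
  # per-dive transition log probabilities, precomputed by the interval's top
  # state: lpX[u] = log P(sub_u = forage | prev = X), lqX the resting row
  p_forage <- stats::plogis(params$alpha_sub)  # 2x2 [top state, prev sub]
  lp <- log(p_forage); lq <- log1p(-p_forage)
  lp1 <- lp[s_of, 1]; lp2 <- lp[s_of, 2]
  lq1 <- lq[s_of, 1]; lq2 <- lq[s_of, 2]
  f <- .fwd_pair_cpp(em[, 1], em[, 2], lp1, lp2, lq1, lq2)
  f1 <- f$f1; f2 <- f$f2
  if (anyNA(f1) || anyNA(f2)) stop("NaN in forward filter", call. = FALSE)
  draws <- matrix(1L, n_draws, n)
  p_last <- stats::plogis(f1[n] - f2[n])
  draws[, n] <- 2L - (stats::runif(n_draws) < p_last)
  if (n >= 2) {
    # P(forage | next sub-state), vectorized over u; index u holds the
    # transition into dive u+1
    pf <- stats::plogis(f1[-n] + lp1[-1] - f2[-n] - lp2[-1])
    pr <- stats::plogis(f1[-n] + lq1[-1] - f2[-n] - lq2[-1])
    if (n_draws == 1L) {
      draws[1, ] <- .bwd_sample_cpp(pf, pr, stats::runif(n - 1),
                                    draws[1, n])
    } else {
      for (u in (n - 1):1) {
        is1 <- draws[, u + 1] == 1L
        p <- pr[u] + (pf[u] - pr[u]) * is1
        draws[, u] <- 2L - (stats::runif(n_draws) < p)
      }
    }
  }
  draws
}

#' One Gibbs pass over both discrete state layers
#'
#' Samples every track's top-layer path given the sub-states, then every
#' track's sub-state path given the new top-layer states, each from its exact
#' full conditional.
#'
#' @param tracks list of `regular_track` objects.
#' @param latent list parallel to `tracks` with `Y`, `s_top`, `s_sub`.
#' @param params [crw_params].
#' @param threshold dive truncation depth (m).
#' @return The updated `latent` list.
#' @export
sample_states_ffbs <- function(tracks, latent, params, threshold = 10) {
  for (k in seq_along(tracks)) {
    latent[[k]]$s_top <- as.integer(ffbs_top(tracks[[k]], latent[[k]]$Y,
                                             latent[[k]]$s_sub, params,
                                             threshold = threshold)[1, ])
    latent[[k]]$s_sub <- as.integer(ffbs_sub(tracks[[k]],
                                             latent[[k]]$s_top, params,
                                             threshold = threshold)[1, ])
  }
  latent
}

#' Metropolis update of the latent locations
#'
#' Random-walk Metropolis on each grid-node location, targeting its full
#' conditional from the process and observation terms. Nodes are updated in
#' three interleaved batches (every third node), which makes the per-node
#' accept/reject decisions exact and independent because a node's conditional
#' only involves terms within two nodes of it. Per-node proposal scales
#' adapt during burn-in.
#'
#' @inheritParams sample_states_ffbs
#' @param error_table [argos_error_table()].
#' @param scales list (per track) of per-node proposal sds; defaults to 1 km.
#' @return List with updated `latent`, `scales` untouched, and per-track
#'   acceptance counts `accept` / proposal counts `n_prop`.
#' @export
sample_locations <- function(tracks, latent, params,
                             error_table = argos_error_table(),
                             scales = NULL) {
  out_acc <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    trk <- tracks[[k]]
    Y <- latent[[k]]$Y
    s_top <- latent[[k]]$s_top
    N <- nrow(Y)
    T <- trk$n_intervals
    sc <- if (is.null(scales)) rep(1, N) else scales[[k]]
    fix_sd <- unclass(error_table)[trk$fixes$error_class]
    acc <- rep(0L, N)
    for (offset in 0:2) {
      idx <- which(((seq_len(N) - 1L) %% 3L) == offset)
      prop_Y <- Y
      prop_Y[idx, ] <- Y[idx, ] +
        matrix(stats::rnorm(2 * length(idx)), ncol = 2) * sc[idx]
      dpt <- process_term_vec(prop_Y, s_top, params) -
        process_term_vec(Y, s_top, params)
      dobs <- obs_term_vec(trk$fixes, prop_Y, fix_sd) -
        obs_term_vec(trk$fixes, Y, fix_sd)
      delta <- numeric(N)
      for (shift in -1:1) {
        terms <- idx + shift
        okt <- terms >= 1L & terms <= T
        delta[idx[okt]] <- delta[idx[okt]] + dpt[terms[okt]]
      }
      if (nrow(trk$fixes)) {
        member <- logical(N); member[idx] <- TRUE
        owner <- ifelse(member[trk$fixes$t], trk$fixes$t,
                        ifelse(member[pmin(trk$fixes$t + 1L, N)],
                               trk$fixes$t + 1L, NA_integer_))
        keep <- !is.na(owner)
        if (any(keep)) {
          agg <- rowsum(dobs[keep], owner[keep])
          delta[as.integer(rownames(agg))] <-
            delta[as.integer(rownames(agg))] + agg[, 1]
        }
      }
      accept <- log(stats::runif(length(idx))) < delta[idx]
      Y[idx[accept], ] <- prop_Y[idx[accept], ]
      acc[idx[accept]] <- acc[idx[accept]] + 1L
    }
    latent[[k]]$Y <- Y
    out_acc[[k]] <- acc
  }
  list(latent = latent, accept = out_acc)
}

# sufficient statistics of the discrete chains
state_counts <- function(tracks, latent) {
  n_top <- matrix(0, 2, 2)  # [prev, next]
  n_sub <- array(0, c(2, 2, 2))  # [top state, prev sub, next sub]
  for (k in seq_along(tracks)) {
    st <- latent[[k]]$s_top
    T <- length(st)
    if (T >= 2) {
      code <- (st[-T] - 1L) * 2L + st[-1]
      n_top <- n_top + matrix(tabulate(code, 4L), 2, 2, byrow = TRUE)
    }
    ss <- latent[[k]]$s_sub
    n <- length(ss)
    if (n >= 2) {
      s_of <- st[tracks[[k]]$dives$t][-1]
      code <- (s_of - 1L) * 4L + (ss[-n] - 1L) * 2L + ss[-1]
      cnt8 <- tabulate(code, 8L)
      n_sub <- n_sub + aperm(array(cnt8, c(2, 2, 2)), c(3, 2, 1))
    }
  }
  list(top = n_top, sub = n_sub)
}

logit_chain_ll <- function(a, n_to_1, n_to_2) {
  n_to_1 * stats::plogis(a, log.p = TRUE) +
    n_to_2 * stats::plogis(-a, log.p = TRUE)
}

# depths grouped by emitting behavior (1 traveling, 2 foraging, 3 resting)
depths_by_behavior <- function(tracks, latent) {
  out <- list(numeric(0), numeric(0), numeric(0))
  for (k in seq_along(tracks)) {
    dv <- tracks[[k]]$dives
    if (!nrow(dv)) next
    s_of <- latent[[k]]$s_top[dv$t]
    b <- ifelse(s_of == 1L, 1L, 1L + latent[[k]]$s_sub)
    for (i in 1:3) out[[i]] <- c(out[[i]], dv$depth[b == i])
  }
  out
}

#' Metropolis-within-Gibbs update of the model parameters
#'
#' Updates, in turn: the autocorrelations `gamma` (respecting the ordering
#' constraint), turning angles `theta` (random walk wrapped onto the circle),
#' process sds (log-scale random walk with Jacobian), both transition-logit
#' sets (using the chains' sufficient transition counts), and the depth
#' means and sds (bounded by their prior supports). Proposals falling outside
#' the prior support are auto-rejected.
#'
#' @inheritParams sample_locations
#' @param priors [default_priors()].
#' @param scales named numeric vector of proposal sds per parameter.
#' @param threshold dive truncation depth (m).
#' @return List with updated `params` and per-parameter acceptance
#'   indicators `accept`.
#' @export
sample_parameters <- function(tracks, latent, params,
                              priors = default_priors(), scales = NULL,
                              threshold = 10) {
  pn <- param_names()
  if (is.null(scales)) scales <- stats::setNames(rep(0.1, length(pn)), pn)
  accept <- stats::setNames(rep(FALSE, length(pn)), pn)
  adapt_count <- stats::setNames(rep(1L, length(pn)), pn)
  cnt <- state_counts(tracks, latent)
  depths <- depths_by_behavior(tracks, latent)

  move_ll <- function(p) {
    s <- 0
    for (k in seq_along(tracks))
      s <- s + sum(process_term_vec(latent[[k]]$Y, latent[[k]]$s_top, p))
    s
  }
  cur_move <- move_ll(params)
  cur_prior <- log_prior(params, priors)

  # gamma and theta and process_sd share the movement likelihood
  for (nm in c("gamma_travel", "gamma_ars", "theta_travel", "theta_ars",
               "sigma_x", "sigma_y")) {
    prop <- params
    jac <- 0
    if (nm == "gamma_travel") prop$gamma[1] <- params$gamma[1] +
        stats::rnorm(1, 0, scales[nm])
    if (nm == "gamma_ars") prop$gamma[2] <- params$gamma[2] +
        stats::rnorm(1, 0, scales[nm])
    if (nm == "theta_travel") prop$theta[1] <-
        wrap_angle(params$theta[1] + stats::rnorm(1, 0, scales[nm]))
    if (nm == "theta_ars") prop$theta[2] <-
        wrap_angle(params$theta[2] + stats::rnorm(1, 0, scales[nm]))
    if (nm == "sigma_x") {
      prop$process_sd[1] <- params$process_sd[1] *
        exp(stats::rnorm(1, 0, scales[nm]))
      jac <- log(prop$process_sd[1]) - log(params$process_sd[1])
    }
    if (nm == "sigma_y") {
      prop$process_sd[2] <- params$process_sd[2] *
        exp(stats::rnorm(1, 0, scales[nm]))
      jac <- log(prop$process_sd[2]) - log(params$process_sd[2])
    }
    prop_prior <- log_prior(prop, priors)
    if (is.finite(prop_prior)) {
      prop_move <- move_ll(prop)
      if (log(stats::runif(1)) <
            prop_move + prop_prior + jac - cur_move - cur_prior) {
        params <- prop; cur_move <- prop_move; cur_prior <- prop_prior
        accept[nm] <- TRUE
      }
    }
  }

  # top transition logits: independent given transition counts
  for (s in 1:2) {
    nm <- c("alpha_top_from_travel", "alpha_top_from_ars")[s]
    a0 <- params$alpha_top[s]
    a1 <- a0 + stats::rnorm(1, 0, scales[nm])
    d <- logit_chain_ll(a1, cnt$top[s, 1], cnt$top[s, 2]) -
      logit_chain_ll(a0, cnt$top[s, 1], cnt$top[s, 2]) +
      stats::dnorm(a1, 0, priors$alpha_sd, log = TRUE) -
      stats::dnorm(a0, 0, priors$alpha_sd, log = TRUE)
    if (log(stats::runif(1)) < d) {
      params$alpha_top[s] <- a1; accept[nm] <- TRUE
    }
  }
  # dive emission parameters
  cur_prior <- log_prior(params, priors)
  for (b in 1:3) {
    x <- depths[[b]]
    nm <- paste0("mu_", c("travel", "forage", "rest")[b])
    prop <- params
    prop$dive_mu[b] <- params$dive_mu[b] + stats::rnorm(1, 0, scales[nm])
    prop_prior <- log_prior(prop, priors)
    if (is.finite(prop_prior)) {
      d <- sum(dtnorm_log(x, prop$dive_mu[b], prop$dive_sd[b], threshold)) -
        sum(dtnorm_log(x, params$dive_mu[b], params$dive_sd[b], threshold)) +
        prop_prior - cur_prior
      if (log(stats::runif(1)) < d) {
        params <- prop; cur_prior <- prop_prior; accept[nm] <- TRUE
      }
    }
    nm <- paste0("sd_", c("travel", "forage", "rest")[b])
    prop <- params
    prop$dive_sd[b] <- params$dive_sd[b] * exp(stats::rnorm(1, 0, scales[nm]))
    jac <- log(prop$dive_sd[b]) - log(params$dive_sd[b])
    prop_prior <- log_prior(prop, priors)
    if (is.finite(prop_prior)) {
      d <- sum(dtnorm_log(x, prop$dive_mu[b], prop$dive_sd[b], threshold)) -
        sum(dtnorm_log(x, params$dive_mu[b], params$dive_sd[b], threshold)) +
        prop_prior - cur_prior + jac
      if (log(stats::runif(1)) < d) {
        params <- prop; cur_prior <- prop_prior; accept[nm] <- TRUE
      }
    }
  }

  # sub-chain transition logits, updated against the marginal likelihood
  # with the dive sub-states integrated out by the forward algorithm
  # (partially collapsed update). The sub-chain carries no emissions inside
  # traveling intervals, so conditioning on the current sub-state draw would
  # couple the traveling-row logits to essentially arbitrary latent labels
  # and mix very slowly; marginally their posterior is close to the prior
  # and a mixture of an adapted random walk with prior-independence
  # proposals traverses it in a few steps. This update runs last in the
  # block: the sub-states are redrawn from their exact conditional (FFBS) at
  # the start of the next iteration before anything conditions on them.
  em_list <- vector("list", length(tracks))
  sof_list <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    dv <- tracks[[k]]$dives
    n <- nrow(dv)
    em <- matrix(0, n, 2)
    if (n) {
      s_of <- latent[[k]]$s_top[dv$t]
      ars <- s_of == 2L
      if (any(ars)) {
        em[ars, 1] <- dtnorm_log(dv$depth[ars], params$dive_mu[2],
                                 params$dive_sd[2], threshold)
        em[ars, 2] <- dtnorm_log(dv$depth[ars], params$dive_mu[3],
                                 params$dive_sd[3], threshold)
      }
      sof_list[[k]] <- s_of
    }
    em_list[[k]] <- em
  }
  sub_names <- c("alpha_sub_travel_from_forage", "alpha_sub_travel_from_rest",
                 "alpha_sub_ars_from_forage", "alpha_sub_ars_from_rest")
  cur_marg <- sub_chain_marginal(em_list, sof_list, params)
  for (s in 1:2) for (p in 1:2) {
    nm <- sub_names[(s - 1) * 2 + p]
    a0 <- params$alpha_sub[s, p]
    from_prior <- stats::runif(1) < 0.5
    prop <- params
    if (from_prior) {
      prop$alpha_sub[s, p] <- stats::rnorm(1, 0, priors$alpha_sd)
      dprior <- 0  # prior cancels against the independence proposal density
      adapt_count[nm] <- 0L
    } else {
      prop$alpha_sub[s, p] <- a0 + stats::rnorm(1, 0, scales[nm])
      dprior <- stats::dnorm(prop$alpha_sub[s, p], 0, priors$alpha_sd,
                             log = TRUE) -
        stats::dnorm(a0, 0, priors$alpha_sd, log = TRUE)
    }
    prop_marg <- sub_chain_marginal(em_list, sof_list, prop)
    if (log(stats::runif(1)) < prop_marg - cur_marg + dprior) {
      params <- prop
      cur_marg <- prop_marg
      accept[nm] <- !from_prior
    }
  }
  list(params = params, accept = accept, adapt_count = adapt_count)
}

# Marginal log-likelihood of the dive sub-chain: emissions and transitions
# with every sub-state path summed out by the forward recursion. Emission
# terms inside traveling intervals are constant in the sub-state and omitted
# (they cancel in all ratios this function feeds).
sub_chain_marginal <- function(em_list, sof_list, params) {
  p_forage <- stats::plogis(params$alpha_sub)
  lp <- log(p_forage); lq <- log1p(-p_forage)
  total <- 0
  for (k in seq_along(em_list)) {
    em <- em_list[[k]]
    n <- nrow(em)
    if (n == 0L) next
    s_of <- sof_list[[k]]
    total <- total + .fwd_pair_loglik_cpp(em[, 1], em[, 2],
                                          lp[s_of, 1], lp[s_of, 2],
                                          lq[s_of, 1], lq[s_of, 2])
  }
  total
}

param_names <- function() {
  c("gamma_travel", "gamma_ars", "theta_travel", "theta_ars",
    "sigma_x", "sigma_y", "alpha_top_from_travel", "alpha_top_from_ars",
    "alpha_sub_travel_from_forage", "alpha_sub_travel_from_rest",
    "alpha_sub_ars_from_forage", "alpha_sub_ars_from_rest",
    "mu_travel", "mu_forage", "mu_rest", "sd_travel", "sd_forage", "sd_rest")
}

params_to_vector <- function(p) {
  stats::setNames(c(p$gamma, p$theta, p$process_sd, p$alpha_top,
                    p$alpha_sub[1, ], p$alpha_sub[2, ], p$dive_mu, p$dive_sd),
                  param_names())
}

vector_to_params <- function(v) {
  crw_params(gamma = v[1:2], theta = v[3:4], process_sd = v[5:6],
             alpha_top = v[7:8],
             alpha_sub = rbind(v[9:10], v[11:12]),
             dive_mu = v[13:15], dive_sd = v[16:18])
}

# Deterministic initialization. Locations start at time-interpolated fixes.
# Top states start from the dive profile where it is decisive - an interval
# holding a deep (>= 100 m) dive is a foraging interval, hence ARS - and from
# a step-length threshold otherwise (long apparent steps suggest traveling).
# Sub-states start from a 50 m depth split. The two shallow depth components
# start apart (traveling at 10 m, resting at 25 m) so the sampler begins in
# the basin where resting is the deeper of the two shallow behaviors; with
# symmetric starts the first sweeps can attach both components to the same
# depth cluster and lock a relabeled mode.
init_state <- function(tracks, priors) {
  latent <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    trk <- tracks[[k]]
    T <- trk$n_intervals
    node_h <- (seq_len(T + 1L) - 1) * 6
    fix_h <- (trk$fixes$t - 1 + trk$fixes$j) * 6
    Y <- cbind(stats::approx(fix_h, trk$fixes$x, node_h, rule = 2,
                             ties = mean)$y,
               stats::approx(fix_h, trk$fixes$y, node_h, rule = 2,
                             ties = mean)$y)
    steps <- sqrt(diff(Y[, 1])^2 + diff(Y[, 2])^2)
    s_top <- ifelse(steps > stats::median(steps), 1L, 2L)
    if (nrow(trk$dives)) {
      deep <- unique(trk$dives$t[trk$dives$depth >= 100])
      s_top[deep] <- 2L
      s_sub <- ifelse(trk$dives$depth >= 50, 1L, 2L)
    } else {
      s_sub <- integer(0)
    }
    latent[[k]] <- list(Y = Y, s_top = as.integer(s_top),
                        s_sub = as.integer(s_sub))
  }
  params <- crw_params(gamma = c(0.8, 0.2), theta = c(0, 0),
                       process_sd = c(priors$process_sd_scale / 2,
                                      priors$process_sd_scale / 2),
                       alpha_top = c(0, 0),
                       alpha_sub = rbind(c(0, 0), c(0, 0)),
                       dive_mu = c(10, 150, 25),
                       dive_sd = c(10, 60, 12))
  list(latent = latent, params = params)
}

#' Run the full MCMC sampler
#'
#' Per iteration and chain: a Gibbs pass over both discrete state layers
#' ([sample_states_ffbs()]), a Metropolis sweep over the latent locations
#' ([sample_locations()]), and the parameter block ([sample_parameters()]).
#' Proposal scales adapt toward 20-50% acceptance during burn-in only, so the
#' retained chain is Markovian. Post-burn-in draws are thinned and stored
#' together with the latent states for decoding.
#'
#' @param tracks list of `regular_track` objects (see [preprocess()]).
#' @param config [mcmc_config()].
#' @param priors [default_priors()].
#' @param error_table [argos_error_table()].
#' @param init optional initialization (as returned by the internal
#'   deterministic initializer); mostly for tests.
#' @param threshold dive truncation depth (m).
#' @param verbose log progress to stderr.
#' @return Object of class `crw_draws`: per chain a parameter matrix
#'   (`n_retained x 18`), integer state matrices for both layers, and
#'   acceptance summaries; plus a `data_map` linking state columns to
#'   animals, interval start times, dive timestamps and depths.
#' @export
run_mcmc <- function(tracks, config = mcmc_config(),
                     priors = default_priors(),
                     error_table = argos_error_table(), init = NULL,
                     threshold = 10, verbose = FALSE) {
  if (!length(tracks)) stop("empty track set", call. = FALSE)
  pn <- param_names()
  n_int <- vapply(tracks, function(t) t$n_intervals, integer(1))
  n_dv <- vapply(tracks, function(t) nrow(t$dives), integer(1))
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 10007L * (ch - 1L))
    st <- init %||% init_state(tracks, priors)
    latent <- st$latent
    params <- st$params
    if (!is.finite(log_prior(params, priors)) ||
        !is.finite(complete_data_loglik(tracks, latent, params, error_table,
                                        threshold)))
      stop("non-finite posterior at initialization", call. = FALSE)
    y_scales <- lapply(n_int, function(T) rep(1, T + 1L))
    p_scales <- stats::setNames(rep(0.1, length(pn)), pn)
    p_scales[c("mu_travel", "mu_forage", "mu_rest")] <- 2
    p_scales[c("sd_travel", "sd_forage", "sd_rest")] <- 0.1
    p_scales[grep("alpha", pn)] <- 0.3
    y_acc <- lapply(n_int, function(T) rep(0L, T + 1L))
    p_acc <- stats::setNames(rep(0L, length(pn)), pn)
    p_n <- stats::setNames(rep(0L, length(pn)), pn)
    win <- 0L
    pmat <- matrix(NA_real_, config$n_retained, length(pn),
                   dimnames = list(NULL, pn))
    smat <- matrix(NA_integer_, config$n_retained, sum(n_int))
    dmat <- matrix(NA_integer_, config$n_retained, sum(n_dv))
    kept <- 0L
    acc_total <- list(y = 0, p = stats::setNames(rep(0, length(pn)), pn),
                      n = 0L)
    for (it in seq_len(config$n_iter)) {
      latent <- sample_states_ffbs(tracks, latent, params, threshold)
      loc <- sample_locations(tracks, latent, params, error_table, y_scales)
      latent <- loc$latent
      up <- sample_parameters(tracks, latent, params, priors, p_scales,
                              threshold)
      params <- up$params
      win <- win + 1L
      for (k in seq_along(tracks)) y_acc[[k]] <- y_acc[[k]] + loc$accept[[k]]
      p_acc <- p_acc + up$accept
      p_n <- p_n + up$adapt_count
      if (it > config$n_burnin) {
        acc_total$y <- acc_total$y + mean(unlist(loc$accept))
        acc_total$p <- acc_total$p + up$accept
        acc_total$n <- acc_total$n + 1L
      }
      if (it <= config$n_burnin && win >= config$adapt_window) {
        for (k in seq_along(tracks)) {
          rate <- y_acc[[k]] / win
          y_scales[[k]] <- y_scales[[k]] *
            exp(0.6 * (pmin(pmax(rate, 0.01), 0.9) - 0.3))
          y_acc[[k]][] <- 0L
        }
        rate <- p_acc / pmax(p_n, 1L)
        p_scales <- p_scales * exp(0.6 * (pmin(pmax(rate, 0.01), 0.9) - 0.3))
        p_acc[] <- 0L
        p_n[] <- 0L
        win <- 0L
      }
      if (it > config$n_burnin &&
          (it - config$n_burnin) %% config$thin == 0L &&
          kept < config$n_retained) {
        kept <- kept + 1L
        pmat[kept, ] <- params_to_vector(params)
        smat[kept, ] <- unlist(lapply(latent, `[[`, "s_top"))
        dmat[kept, ] <- unlist(lapply(latent, `[[`, "s_sub"))
      }
      if (verbose && it %% 1000 == 0)
        log_line("mcmc", "progress", chain = ch, iter = it)
    }
    chains[[ch]] <- list(params = pmat[seq_len(kept), , drop = FALSE],
                         s_top = smat[seq_len(kept), , drop = FALSE],
                         s_sub = dmat[seq_len(kept), , drop = FALSE],
                         accept = list(
                           y_rate = acc_total$y / max(acc_total$n, 1L),
                           p_rate = acc_total$p / max(acc_total$n, 1L)),
                         seed = config$seed + 10007L * (ch - 1L))
  }
  interval_map <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    trk <- tracks[[k]]
    data.frame(track = k, animal = trk$animal, t = seq_len(trk$n_intervals),
               start = trk$start + (seq_len(trk$n_intervals) - 1) * 6 * 3600)
  }))
  dive_map <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    trk <- tracks[[k]]
    if (!nrow(trk$dives)) return(NULL)
    data.frame(track = k, animal = trk$animal, t = trk$dives$t,
               timestamp = trk$dives$timestamp, depth = trk$dives$depth)
  }))
  out <- list(chains = chains, param_names = pn,
              data_map = list(intervals = interval_map, dives = dive_map,
                              n_intervals = n_int, n_dives = n_dv),
              config = config, priors = priors, threshold = threshold)
  class(out) <- "crw_draws"
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free PSRF comparing between-chain to within-chain variance:
#' with `m` chains of length `n`, `W` the mean within-chain variance and `B/n`
#' the variance of chain means, the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`. Chains with (numerically) zero
#' within-chain variance are reported as degenerate rather than NaN.
#'
#' @param chains list of equal-length numeric vectors (one per chain) or a
#'   matrix with one column per chain.
#' @return Numeric r-hat with attribute `degenerate` (`TRUE` when the
#'   within-chain variance vanishes, in which case the value is `NA`).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(i) chains[, i])
  m <- length(chains)
  if (m < 2) stop("need >= 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 10) stop("need >= 10 draws per chain",
                                     call. = FALSE)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  means <- vapply(chains, mean, numeric(1))
  B <- n * stats::var(means)
  if (!is.finite(W) || W < 1e-300) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  structure(sqrt(((n - 1) / n * W + B / n) / W), degenerate = FALSE)
}

#' Gelman-Rubin table over all sampled parameters
#'
#' @param draws a `crw_draws` object with at least two chains.
#' @return Data.frame with `parameter`, `rhat`, `degenerate`.
#' @export
rhat_table <- function(draws) {
  stopifnot(inherits(draws, "crw_draws"))
  if (length(draws$chains) < 2) stop("need >= 2 chains", call. = FALSE)
  res <- lapply(draws$param_names, function(nm) {
    r <- gelman_rubin(lapply(draws$chains, function(ch) ch$params[, nm]))
    data.frame(parameter = nm, rhat = as.numeric(r),
               degenerate = isTRUE(attr(r, "degenerate")))
  })
  do.call(rbind, res)
}
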