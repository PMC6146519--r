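# Posterior decoding and the behavioral summaries: time-in-state proportions,
# per-state dive-depth distributions, and seasonal/diel frequency profiles.

#' Decode behavioral states from posterior draws
#'
#' Pools the retained draws of all chains. Per interval, the posterior
#' probability of traveling is its frequency across draws; the modal label is
#' traveling when that probability exceeds 0.5 and area-restricted search
#' otherwise (a tie goes to ARS, since only a strict majority names
#' traveling). Per dive, the three-way behavior (traveling / foraging /
#' resting, combining the interval's top state with the dive's sub-state) is
#' labeled by plurality across draws, ties broken in that fixed order.
#'
#' @param draws a `crw_draws` object with at least one retained draw.
#' @return Object of class `crw_decoded`: `$intervals` (`animal`, `start`,
#'   `p_travel`, `label`) and `$dives` (`animal`, `timestamp`, `depth`,
#'   `p_traveling`, `p_foraging`, `p_resting`, `label`, `p_label`).
#' @export
decode <- function(draws) {
  stopifnot(inherits(draws, "crw_draws"))
  s_top <- do.call(rbind, lapply(draws$chains, `[[`, "s_top"))
  if (nrow(s_top) < 1) stop("no retained draws", call. = FALSE)
  p_travel <- colMeans(s_top == 1L)
  intervals <- draws$data_map$intervals
  intervals$p_travel <- p_travel
  intervals$label <- ifelse(p_travel > 0.5, "traveling", "ars")
  dv <- draws$data_map$dives
  dives <- NULL
  if (!is.null(dv) && nrow(dv)) {
    beh <- dive_behavior_draws(draws)
    pmat <- cbind(colMeans(beh == 1L), colMeans(beh == 2L),
                  colMeans(beh == 3L))
    lab <- .behaviors[max.col(pmat, ties.method = "first")]
    dives <- dv
    dives$p_traveling <- pmat[, 1]
    dives$p_foraging <- pmat[, 2]
    dives$p_resting <- pmat[, 3]
    dives$label <- lab
    dives$p_label <- pmat[cbind(seq_len(nrow(pmat)),
                                match(lab, .behaviors))]
  }
  structure(list(intervals = intervals, dives = dives), class = "crw_decoded")
}

# draws x dives matrix of 3-way behaviors (1 traveling, 2 foraging, 3 resting)
dive_behavior_draws <- function(draws, chain_rows = NULL) {
  s_top <- do.call(rbind, lapply(draws$chains, `[[`, "s_top"))
  s_sub <- do.call(rbind, lapply(draws$chains, `[[`, "s_sub"))
  dv <- draws$data_map$dives
  n_int <- draws$data_map$n_intervals
  offs <- c(0L, cumsum(n_int))
  col_top <- offs[dv$track] + dv$t  # interval column of each dive
  if (!is.null(chain_rows)) {
    s_top <- s_top[chain_rows, , drop = FALSE]
    s_sub <- s_sub[chain_rows, , drop = FALSE]
  }
  top_of_dive <- s_top[, col_top, drop = FALSE]
  ifelse(top_of_dive == 1L, 1L, 1L + s_sub)
}

#' Time-in-state proportions per individual
#'
#' Fraction of dive observations spent in each behavior per individual
#' (decoded modal labels), and across individuals the mean and sample
#' standard deviation of those fractions, reported on both the percentage and
#' the proportion scale. Individuals with zero decoded dives are excluded
#' (with a message). With a single individual the sd is reported as 0 and
#' flagged `n = 1`.
#'
#' @param decoded a `crw_decoded` object.
#' @return List with `per_individual` (one row per animal and behavior) and
#'   `summary` (per behavior: `mean_pct`, `sd_pct`, `mean_prop`, `sd_prop`,
#'   `n_individuals`).
#' @export
state_time_proportions <- function(decoded) {
  stopifnot(inherits(decoded, "crw_decoded"))
  dv <- decoded$dives
  if (is.null(dv) || !nrow(dv)) stop("no decoded dives", call. = FALSE)
  animals <- unique(dv$animal)
  rows <- list()
  for (a in animals) {
    lab <- dv$label[dv$animal == a]
    if (!length(lab)) {
      message("individual ", a, " has zero dives; excluded")
      next
    }
    prop <- vapply(.behaviors, function(b) mean(lab == b), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(animal = a,
                                            behavior = .behaviors,
                                            proportion = as.numeric(prop),
                                            n_dives = length(lab))
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(.behaviors, function(b) {
    p <- per$proportion[per$behavior == b]
    n <- length(p)
    data.frame(behavior = b,
               mean_pct = 100 * mean(p),
               sd_pct = if (n > 1) 100 * stats::sd(p) else 0,
               mean_prop = mean(p),
               sd_prop = if (n > 1) stats::sd(p) else 0,
               n_individuals = n)
  }))
  list(per_individual = per, summary = summ)
}

#' Per-state dive-depth distribution summary
#'
#' Per behavior: the posterior mean and 95% credible interval of the state's
#' mean-depth parameter, and the empirical 25th/75th quantiles (type-7,
#' linear interpolation of order statistics) and maximum of the observed
#' depths carrying that decoded label. A behavior with no assigned dives gets
#' `NA` empirical entries.
#'
#' @param decoded a `crw_decoded` object.
#' @param draws the `crw_draws` the decoding came from.
#' @return Data.frame, one row per behavior.
#' @export
depth_distribution_summary <- function(decoded, draws) {
  stopifnot(inherits(decoded, "crw_decoded"), inherits(draws, "crw_draws"))
  pmat <- do.call(rbind, lapply(draws$chains, `[[`, "params"))
  mu_cols <- c("mu_travel", "mu_forage", "mu_rest")
  dv <- decoded$dives
  do.call(rbind, lapply(seq_along(.behaviors), function(b) {
    mu <- pmat[, mu_cols[b]]
    depths <- if (!is.null(dv)) dv$depth[dv$label == .behaviors[b]]
              else numeric(0)
    data.frame(behavior = .behaviors[b],
               mu_mean = mean(mu),
               mu_lower = as.numeric(stats::quantile(mu, 0.025, type = 7)),
               mu_upper = as.numeric(stats::quantile(mu, 0.975, type = 7)),
               q25 = if (length(depths))
                 as.numeric(stats::quantile(depths, 0.25, type = 7))
                 else NA_real_,
               q75 = if (length(depths))
                 as.numeric(stats::quantile(depths, 0.75, type = 7))
                 else NA_real_,
               max_depth = if (length(depths)) max(depths) else NA_real_,
               n_dives = length(depths))
  }))
}

#' Seasonal or diel behavior frequency profiles
#'
#' Bins dive observations by UTC calendar month or UTC hour of day and
#' reports, per bin and behavior, the fraction of dives in that behavior.
#' Point estimates are posterior mean fractions over `n_uncertainty_draws`
#' evenly spaced retained draws of the latent labels; the uncertainty band is
#' the min-max spread of the per-draw fractions (so the point estimate always
#' lies inside the band, and a single draw gives zero-width bands). Empty
#' bins are reported with `n = 0` and `NA` fractions.
#'
#' @param decoded a `crw_decoded` object.
#' @param draws the `crw_draws` the decoding came from.
#' @param resolution `"month"` or `"hour"`.
#' @param n_uncertainty_draws number of posterior draws for the bands.
#' @return Data.frame with `bin`, `behavior`, `frequency`, `lower`, `upper`,
#'   `n` (dives in bin).
#' @export
temporal_frequency <- function(decoded, draws,
                               resolution = c("month", "hour"),
                               n_uncertainty_draws = 50) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(decoded, "crw_decoded"), inherits(draws, "crw_draws"))
  dv <- decoded$dives
  if (is.null(dv) || !nrow(dv)) stop("no decoded dives", call. = FALSE)
  bin <- if (resolution == "month")
    as.integer(format(dv$timestamp, "%m", tz = "UTC"))
  else as.integer(format(dv$timestamp, "%H", tz = "UTC"))
  bins <- if (resolution == "month") 1:12 else 0:23
  n_total <- nrow(do.call(rbind, lapply(draws$chains, `[[`, "s_top")))
  nd <- min(n_uncertainty_draws, n_total)
  rows <- unique(round(seq(1, n_total, length.out = nd)))
  beh <- dive_behavior_draws(draws, chain_rows = rows)
  out <- list()
  for (bv in bins) {
    sel <- bin == bv
    n <- sum(sel)
    for (b in seq_along(.behaviors)) {
      if (n == 0L) {
        out[[length(out) + 1L]] <- data.frame(bin = bv,
                                              behavior = .behaviors[b],
                                              frequency = NA_real_,
                                              lower = NA_real_,
                                              upper = NA_real_, n = 0L)
      } else {
        fr <- rowMeans(beh[, sel, drop = FALSE] == b)
        out[[length(out) + 1L]] <- data.frame(bin = bv,
                                              behavior = .behaviors[b],
                                              frequency = mean(fr),
                                              lower = min(fr),
                                              upper = max(fr), n = n)
      }
    }
  }
  do.call(rbind, out)
}

#' Count deep dives
#'
#' Number of observed dives strictly deeper than a threshold, overall and per
#' decoded behavior.
#'
#' @param decoded a `crw_decoded` object.
#' @param threshold depth threshold (m), at least the dive-definition depth
#'   (10 m, at which every retained dive counts).
#' @return List with `total` and named `by_behavior` counts.
#' @export
deep_dive_count <- function(decoded, threshold) {
  stopifnot(inherits(decoded, "crw_decoded"))
  if (threshold < 10) stop("threshold must be at least the dive definition depth",
                           call. = FALSE)
  dv <- decoded$dives
  if (is.null(dv)) return(list(total = 0L,
                               by_behavior = stats::setNames(
                                 rep(0L, 3), .behaviors)))
  deep <- dv$depth > threshold
  list(total = sum(deep),
       by_behavior = vapply(.behaviors, function(b)
         sum(deep & dv$label == b), integer(1)))
}
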