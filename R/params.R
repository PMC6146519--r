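#' Parameters of the nested switching correlated random walk
#'
#' Bundles every unknown of the two-layer movement model. The top layer is a
#' two-state (traveling / area-restricted search) switching correlated random
#' walk on a regular six-hour grid; the bottom layer is a two-state
#' (foraging / resting) Markov chain over individual dives that is active
#' inside area-restricted search intervals.
#'
#' @param gamma length-2 numeric in `[0, 1]`: step autocorrelation per top
#'   state, ordered `c(travel, ars)`. Traveling is expected to be the more
#'   persistent state (see [default_priors()] for the ordering constraint).
#' @param theta length-2 numeric in `(-pi, pi]`: mean turning angle (radians)
#'   per top state, `c(travel, ars)`.
#' @param process_sd length-2 positive numeric: process standard deviation in
#'   km per planar coordinate `c(x, y)`, shared across behavioral states.
#' @param alpha_top length-2 numeric: logit of the probability that the next
#'   interval is traveling, indexed by the previous top state
#'   `c(from_travel, from_ars)`. One free logit per conditioning state fully
#'   parameterizes the two-state transition law.
#' @param alpha_sub 2x2 numeric matrix: logit of the probability that the next
#'   dive is foraging; rows index the current top state (travel, ars), columns
#'   the previous sub-state (from_forage, from_rest).
#' @param dive_mu length-3 numeric: mean dive depth (m) for the traveling,
#'   foraging and resting emission components.
#' @param dive_sd length-3 positive numeric: depth standard deviations (m) for
#'   the same components.
#'
#' @return An object of class `crw_params`.
#' @seealso [default_params()], [log_prior()], [dive_loglik()]
#' @export
crw_params <- function(gamma, theta, process_sd, alpha_top, alpha_sub,
                       dive_mu, dive_sd) {
  p <- list(
    gamma = stats::setNames(as.numeric(gamma), .top_states),
    theta = stats::setNames(as.numeric(theta), .top_states),
    process_sd = stats::setNames(as.numeric(process_sd), c("x", "y")),
    alpha_top = stats::setNames(as.numeric(alpha_top),
                                c("from_travel", "from_ars")),
    alpha_sub = matrix(as.numeric(alpha_sub), 2, 2,
                       dimnames = list(.top_states,
                                       c("from_forage", "from_rest"))),
    dive_mu = stats::setNames(as.numeric(dive_mu), .behaviors),
    dive_sd = stats::setNames(as.numeric(dive_sd), .behaviors)
  )
  class(p) <- "crw_params"
  validate_params(p)
  p
}

#' @keywords internal
validate_params <- function(p) {
  num <- unlist(p[c("gamma", "theta", "process_sd", "alpha_top",
                    "alpha_sub", "dive_mu", "dive_sd")])
  if (!all(is.finite(num)))
    stop("non-finite value in model parameters", call. = FALSE)
  if (any(p$gamma < 0 | p$gamma > 1))
    stop("gamma must lie in [0, 1]", call. = FALSE)
  if (any(p$process_sd <= 0)) stop("process_sd must be > 0", call. = FALSE)
  if (any(p$dive_sd <= 0)) stop("dive_sd must be > 0", call. = FALSE)
  invisible(p)
}

#' Default generative parameters
#'
#' A well-separated, biologically plausible parameter set used as the default
#' truth of the synthetic-data generator: persistent, low-turning traveling
#' (`gamma` 0.9, `theta` 0) against diffuse, high-turning area-restricted
#' search (`gamma` 0.25, `theta` 2.5 rad); a 5 km per-coordinate process
#' scale, so traveling covers roughly 20-30 km per six-hour interval (a
#' realistic whale transit speed of 3-5 km/h); strongly self-persistent dive
#' sub-states; and depth components the three behaviors can actually be told
#' apart by - shallow, tight transit dives while traveling (12 +/- 5 m),
#' resting dives at 25.1 +/- 10 m, and deep foraging dives at 194.3 +/- 60 m,
#' the foraging and resting depth scales of humpback dive records off the
#' West Antarctic Peninsula. All location parameters lie inside their prior
#' supports.
#'
#' @return A [crw_params] object.
#' @export
default_params <- function() {
  crw_params(
    gamma = c(0.9, 0.25),
    theta = c(0, 2.5),
    process_sd = c(5, 5),
    alpha_top = c(2.2, -2.2),
    alpha_sub = rbind(travel = c(0, 0), ars = c(3.0, -2.0)),
    dive_mu = c(12.0, 194.3, 25.1),
    dive_sd = c(5, 60, 10)
  )
}

#' Prior specification
#'
#' Priors used by [log_prior()] and the sampler. Mean-depth priors are uniform
#' on bounded supports that separate the shallow components (traveling and
#' resting, 0-30 m) from the deep foraging component (50-250 m); this, with
#' the ordering constraint `gamma[travel] > gamma[ars]`, pins the labels of
#' the latent states. Scale parameters get weakly-informative half-normal
#' priors; transition logits get normal(0, 2) priors; turning angles are
#' uniform on the circle.
#'
#' @param dive_mu_bounds 3x2 matrix of `[lower, upper]` bounds (m) for the
#'   traveling, foraging, resting mean depths.
#' @param dive_sd_scale half-normal scale (m) for depth standard deviations.
#' @param process_sd_scale half-normal scale (km) for the process standard
#'   deviations.
#' @param alpha_sd normal prior standard deviation for all transition logits.
#' @param gamma_ordered enforce `gamma[travel] > gamma[ars]`.
#' @return A list of class `crw_priors`.
#' @export
default_priors <- function(dive_mu_bounds = rbind(traveling = c(0, 30),
                                                  foraging = c(50, 250),
                                                  resting = c(0, 30)),
                           dive_sd_scale = 100,
                           process_sd_scale = 10,
                           alpha_sd = 2,
                           gamma_ordered = TRUE) {
  pr <- list(dive_mu_bounds = dive_mu_bounds,
             dive_sd_scale = dive_sd_scale,
             process_sd_scale = process_sd_scale,
             alpha_sd = alpha_sd,
             gamma_ordered = gamma_ordered)
  class(pr) <- "crw_priors"
  pr
}

half_normal_log <- function(x, scale) {
  ifelse(x > 0, log(2) + stats::dnorm(x, 0, scale, log = TRUE), -Inf)
}

#' Log prior density of the model parameters
#'
#' Sum of the component log prior densities of [default_priors()]: ordered
#' uniform for `gamma` (density 2 on the ordered triangle when the ordering
#' constraint is on), uniform on the circle for `theta`, half-normal for the
#' process and depth standard deviations, normal for the transition logits,
#' and bounded-uniform for the mean depths (bounds inclusive). Returns `-Inf`
#' outside the support.
#'
#' @param params a [crw_params] object.
#' @param priors a [default_priors()] object.
#' @return Scalar log density.
#' @export
log_prior <- function(params, priors = default_priors()) {
  p <- params
  pr <- priors
  if (any(p$gamma < 0 | p$gamma > 1)) return(-Inf)
  if (pr$gamma_ordered && p$gamma["travel"] <= p$gamma["ars"]) return(-Inf)
  lp <- if (pr$gamma_ordered) log(2) else 0
  if (any(p$theta <= -pi | p$theta > pi)) return(-Inf)
  lp <- lp - 2 * log(2 * pi)
  b <- pr$dive_mu_bounds
  for (k in 1:3) {
    if (p$dive_mu[k] < b[k, 1] || p$dive_mu[k] > b[k, 2]) return(-Inf)
    lp <- lp - log(b[k, 2] - b[k, 1])
  }
  lp <- lp + sum(half_normal_log(p$process_sd, pr$process_sd_scale))
  lp <- lp + sum(half_normal_log(p$dive_sd, pr$dive_sd_scale))
  lp <- lp + sum(stats::dnorm(c(p$alpha_top, p$alpha_sub), 0, pr$alpha_sd,
                              log = TRUE))
  as.numeric(lp)
}

#' Argos location-error table
#'
#' Per-class measurement standard deviations (km per planar coordinate) for
#' the six Argos quality classes 3, 2, 1, 0, A, B, ordered from most to least
#' precise. The shipped defaults
#' (`system.file("extdata", "argos_error_classes.csv", package = "nestcrw")`)
#' follow the magnitudes reported for Argos class errors by Jonsen et
#' al. (2005) and the calibration literature; they are configuration, not
#' constants, and any file with columns `error_class, sd_km` can be supplied.
#'
#' @param path CSV file with columns `error_class` and `sd_km`.
#' @return Named numeric vector of class `argos_error_table` (km), one entry
#'   per error class.
#' @export
argos_error_table <- function(path = system.file("extdata",
                                                 "argos_error_classes.csv",
                                                 package = "nestcrw")) {
  tab <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("error_class", "sd_km") %in% names(tab)))
    stop("error table needs columns error_class, sd_km", call. = FALSE)
  sds <- stats::setNames(tab$sd_km, tab$error_class)
  missing <- setdiff(.argos_classes, names(sds))
  if (length(missing))
    stop("error table missing classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sds <- sds[.argos_classes]
  if (any(sds <= 0)) stop("error sds must be > 0", call. = FALSE)
  if (any(diff(sds) < 0))
    stop("error sds must be non-decreasing from class 3 to class B",
         call. = FALSE)
  class(sds) <- "argos_error_table"
  sds
}
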