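# Internal helpers shared across modules.

# Top-layer states are coded 1 = traveling, 2 = area-restricted search (ARS);
# sub-states 1 = foraging, 2 = resting. Dive-level behaviors combine both layers.
.top_states <- c("travel", "ars")
.sub_states <- c("forage", "rest")
.behaviors <- c("traveling", "foraging", "resting")
.argos_classes <- c("3", "2", "1", "0", "A", "B")

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-normal log density on (lower, Inf), renormalized.
dtnorm_log <- function(x, mean, sd, lower) {
  stats::dnorm(x, mean, sd, log = TRUE) -
    stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
}

# Truncated-normal sampler on (lower, Inf) by inverse CDF.
rtnorm <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  # guard against u == 1 rounding
  stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
}

# Mean of a normal truncated below at `lower`.
tnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
}

# Wrap an angle into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# ISO-8601 UTC timestamp formatting/parsing used by all delimited files.
format_utc <- function(t) strftime(t, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_utc <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  fallback <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC",
                                tryFormats = c("%Y-%m-%d %H:%M:%S",
                                               "%Y-%m-%dT%H:%M:%S",
                                               "%Y-%m-%d %H:%M",
                                               "%Y-%m-%d"))
  }
  out
}

# Structured stderr logging used by the pipeline commands.
log_line <- function(stage, event, ...) {
  kv <- list(...)
  extra <- if (length(kv)) {
    paste(vapply(seq_along(kv), function(i) {
      paste0(names(kv)[i], "=", format(kv[[i]]))
    }, character(1)), collapse = " ")
  } else ""
  message(sprintf("%s | %s | %s%s",
                  format_utc(Sys.time()), stage, event,
                  if (nzchar(extra)) paste0(" | ", extra) else ""))
}
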