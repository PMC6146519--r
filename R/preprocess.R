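# Track preprocessing: cleaning, speed filtering, segmentation, dive
# filtering, exclusion windows, and regularization onto the six-hour grid.

#' Clean raw Argos fixes
#'
#' Drops records with missing coordinates, keeps the first of any
#' duplicate-timestamp group within an animal, rejects records with an
#' unparseable timestamp or an unknown error class (logged, not fatal), and
#' optionally drops fixes on land via a user-supplied predicate.
#'
#' @param fixes data.frame with `animal`, `timestamp`, `x`, `y`,
#'   `error_class`, sorted per animal by timestamp (see [read_fixes()]).
#' @param land_mask optional predicate `f(x, y)` returning `TRUE` on land.
#' @return List with `fixes` (survivors) and `report` (removal counts by
#'   reason, overall and per animal).
#' @export
clean_fixes <- function(fixes, land_mask = NULL) {
  n0 <- nrow(fixes)
  reason <- rep(NA_character_, n0)
  bad_time <- is.na(fixes$timestamp)
  bad_class <- !(fixes$error_class %in% .argos_classes)
  reason[bad_time | bad_class] <- "bad_record"
  miss <- is.na(fixes$x) | is.na(fixes$y)
  reason[is.na(reason) & miss] <- "missing_coordinates"
  ok <- is.na(reason)
  dup <- rep(FALSE, n0)
  if (any(ok)) {
    key <- paste(fixes$animal, as.numeric(fixes$timestamp))
    dup[ok] <- duplicated(key[ok])
  }
  reason[ok & dup] <- "duplicate_timestamp"
  ok <- is.na(reason)
  if (!is.null(land_mask) && any(ok)) {
    on_land <- rep(FALSE, n0)
    on_land[ok] <- as.logical(land_mask(fixes$x[ok], fixes$y[ok]))
    reason[ok & on_land] <- "on_land"
    ok <- is.na(reason)
  }
  report <- removal_report(fixes$animal, reason,
                           c("bad_record", "missing_coordinates",
                             "duplicate_timestamp", "on_land"))
  list(fixes = fixes[ok, , drop = FALSE], report = report)
}

removal_report <- function(animal, reason, reasons) {
  counts <- stats::setNames(vapply(reasons, function(r)
    sum(reason == r, na.rm = TRUE), numeric(1)), reasons)
  by_animal <- NULL
  removed <- !is.na(reason)
  if (any(removed)) {
    by_animal <- as.data.frame(table(animal = animal[removed],
                                     reason = reason[removed]),
                               stringsAsFactors = FALSE)
    by_animal <- by_animal[by_animal$Freq > 0, , drop = FALSE]
    names(by_animal)[3] <- "count"
    rownames(by_animal) <- NULL
  }
  list(counts = counts, total_removed = sum(removed), by_animal = by_animal)
}

#' Remove fixes implying implausible travel speed
#'
#' Forward pass per animal: a fix whose planar speed from the last retained
#' fix exceeds `max_speed` is dropped (the later member of the violating pair
#' is removed), and checking resumes from the retained fix, until no
#' violation remains.
#'
#' @param fixes cleaned, time-sorted fixes.
#' @param max_speed speed threshold (km/h), default 20.
#' @return Fixes with violating records removed.
#' @export
speed_filter <- function(fixes, max_speed = 20) {
  if (nrow(fixes) == 0L) return(fixes)
  keep <- rep(TRUE, nrow(fixes))
  for (id in unique(fixes$animal)) {
    idx <- which(fixes$animal == id)
    if (length(idx) < 2L) next
    last <- idx[1]
    for (i in idx[-1]) {
      dt <- as.numeric(difftime(fixes$timestamp[i], fixes$timestamp[last],
                                units = "hours"))
      dist <- sqrt((fixes$x[i] - fixes$x[last])^2 +
                     (fixes$y[i] - fixes$y[last])^2)
      if (dt <= 0 || dist / dt > max_speed) keep[i] <- FALSE else last <- i
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Segment fixes into contiguous tracks
#'
#' Splits each animal's record at inter-fix gaps longer than `max_gap` hours
#' and discards segments spanning less than `min_span` hours, assigning a
#' per-animal track index `g` to the survivors.
#'
#' @param fixes speed-filtered fixes.
#' @param max_gap maximum allowed gap between consecutive fixes (h).
#' @param min_span minimum first-to-last span of a retained segment (h).
#' @return Fixes with an added integer column `g`.
#' @export
segment_tracks <- function(fixes, max_gap = 12, min_span = 24) {
  out <- list()
  for (id in unique(fixes$animal)) {
    sub <- fixes[fixes$animal == id, , drop = FALSE]
    gaps <- diff(as.numeric(sub$timestamp)) / 3600
    seg <- cumsum(c(1, as.integer(gaps > max_gap)))
    g <- 0L
    for (s in unique(seg)) {
      piece <- sub[seg == s, , drop = FALSE]
      span <- as.numeric(difftime(max(piece$timestamp), min(piece$timestamp),
                                  units = "hours"))
      if (span >= min_span) {
        g <- g + 1L
        piece$g <- g
        out[[length(out) + 1L]] <- piece
      }
    }
  }
  if (!length(out)) {
    empty <- fixes[integer(0), , drop = FALSE]
    empty$g <- integer(0)
    return(empty)
  }
  do.call(rbind, out)
}

#' Filter dive records to the dive definition
#'
#' Retains records strictly deeper than `min_depth` and strictly longer than
#' `min_duration` (a dive is a submergence below 10 m for more than 20 s, so
#' records at the boundary are not dives). Records with negative depth or
#' duration are rejected and counted separately.
#'
#' @param dives data.frame with `depth` (m) and `duration` (s).
#' @param min_depth depth threshold (m).
#' @param min_duration duration threshold (s).
#' @return List with `dives` (survivors) and `report`.
#' @export
filter_dives <- function(dives, min_depth = 10, min_duration = 20) {
  reason <- rep(NA_character_, nrow(dives))
  invalid <- is.na(dives$depth) | is.na(dives$duration) |
    dives$depth < 0 | dives$duration < 0
  reason[invalid] <- "invalid_record"
  shallow <- !invalid & dives$depth <= min_depth
  reason[shallow] <- "too_shallow"
  short <- is.na(reason) & dives$duration <= min_duration
  reason[short] <- "too_short"
  report <- removal_report(dives$animal, reason,
                           c("invalid_record", "too_shallow", "too_short"))
  list(dives = dives[is.na(reason), , drop = FALSE], report = report)
}

#' Remove user-flagged time windows
#'
#' Drops fixes and dives falling inside per-animal exclusion windows
#' (inclusive endpoints); overlapping windows are merged silently. Used for
#' manually identified episodes that should not enter the model, such as the
#' onset of directed northward migration.
#'
#' @param fixes,dives data.frames with `animal` and `timestamp`.
#' @param windows data.frame with `animal`, `start`, `end` (POSIXct), or
#'   `NULL`/empty for a no-op.
#' @return List with filtered `fixes` and `dives`.
#' @export
exclude_flagged <- function(fixes, dives, windows = NULL) {
  if (is.null(windows) || nrow(windows) == 0L)
    return(list(fixes = fixes, dives = dives))
  inside <- function(df) {
    bad <- rep(FALSE, nrow(df))
    for (id in unique(windows$animal)) {
      w <- windows[windows$animal == id, , drop = FALSE]
      w <- w[order(w$start), , drop = FALSE]
      sel <- df$animal == id
      for (i in seq_len(nrow(w)))
        bad[sel] <- bad[sel] | (df$timestamp[sel] >= w$start[i] &
                                  df$timestamp[sel] <= w$end[i])
    }
    bad
  }
  list(fixes = fixes[!inside(fixes), , drop = FALSE],
       dives = dives[!inside(dives), , drop = FALSE])
}

#' Regularize one track onto the six-hour grid
#'
#' Anchors a grid of exact six-hour intervals at the track's first fix. Each
#' fix gets an interval index `t` and interval fraction
#' `j = (fix time - interval start) / 6 h`; intervals are half-open
#' `[start, start + 6 h)` except that a fix at the final grid endpoint closes
#' the last interval with `j = 1`. Dives inside the track's span are assigned
#' to the interval containing their timestamp with a within-interval order
#' `u`; dives outside the span are dropped and counted.
#'
#' @param track_fixes fixes of a single animal/track (with column `g`).
#' @param dives dive records of the same animal (time-sorted).
#' @return Object of class `regular_track`: `animal`, `g`, `start`,
#'   `n_intervals`, `fixes` (`t`, `j`, `x`, `y`, `error_class`), `dives`
#'   (`t`, `u`, `timestamp`, `depth`, `duration`), `n_dropped_dives`.
#' @export
regularize <- function(track_fixes, dives) {
  stopifnot(nrow(track_fixes) >= 2L)
  start <- min(track_fixes$timestamp)
  span_h <- as.numeric(difftime(max(track_fixes$timestamp), start,
                                units = "hours"))
  T <- max(1L, as.integer(ceiling(span_h / 6 - 1e-9)))
  elapsed <- as.numeric(difftime(track_fixes$timestamp, start,
                                 units = "hours"))
  t_idx <- pmin(as.integer(floor(elapsed / 6)) + 1L, T)
  # a fix at the final grid endpoint closes the last interval
  at_end <- elapsed >= T * 6 - 1e-9
  t_idx[at_end] <- T
  j <- elapsed / 6 - (t_idx - 1L)
  j <- pmin(pmax(j, 0), 1)
  fixes <- data.frame(t = t_idx, j = j, x = track_fixes$x, y = track_fixes$y,
                      error_class = track_fixes$error_class)
  dsub <- dives[dives$animal == track_fixes$animal[1], , drop = FALSE]
  d_el <- as.numeric(difftime(dsub$timestamp, start, units = "hours"))
  in_span <- d_el >= 0 & d_el <= span_h + 1e-9
  dropped <- sum(!in_span)
  dsub <- dsub[in_span, , drop = FALSE]
  d_el <- d_el[in_span]
  ord <- order(d_el)
  dsub <- dsub[ord, , drop = FALSE]; d_el <- d_el[ord]
  dt <- pmin(as.integer(floor(d_el / 6)) + 1L, T)
  u <- if (length(dt)) as.integer(stats::ave(seq_along(dt), dt,
                                             FUN = seq_along)) else integer(0)
  out <- list(animal = track_fixes$animal[1],
              g = track_fixes$g[1] %||% 1L,
              start = start,
              n_intervals = T,
              fixes = fixes,
              dives = data.frame(t = dt, u = u,
                                 timestamp = dsub$timestamp,
                                 depth = dsub$depth,
                                 duration = dsub$duration),
              n_dropped_dives = dropped)
  class(out) <- "regular_track"
  out
}

#' Run the full preprocessing chain
#'
#' Cleaning, optional exclusion windows, speed filtering, segmentation, dive
#' filtering and regularization, in the order the filters are defined.
#'
#' @param fixes raw fixes (see [read_fixes()]).
#' @param dives raw dive records (see [read_dives()]).
#' @param land_mask optional predicate for [clean_fixes()].
#' @param exclusion_windows optional windows for [exclude_flagged()].
#' @param max_speed,max_gap,min_span,min_depth,min_duration filter settings.
#' @return List with `tracks` (list of `regular_track`) and `report`
#'   (removal reports per stage).
#' @export
preprocess <- function(fixes, dives, land_mask = NULL,
                       exclusion_windows = NULL,
                       max_speed = 20, max_gap = 12, min_span = 24,
                       min_depth = 10, min_duration = 20) {
  cl <- clean_fixes(fixes, land_mask)
  ex <- exclude_flagged(cl$fixes, dives, exclusion_windows)
  sp <- speed_filter(ex$fixes, max_speed)
  seg <- segment_tracks(sp, max_gap, min_span)
  fd <- filter_dives(ex$dives, min_depth, min_duration)
  tracks <- list()
  if (nrow(seg)) {
    for (id in unique(seg$animal)) {
      for (g in unique(seg$g[seg$animal == id])) {
        tf <- seg[seg$animal == id & seg$g == g, , drop = FALSE]
        tracks[[length(tracks) + 1L]] <- regularize(tf, fd$dives)
      }
    }
  }
  list(tracks = tracks,
       report = list(clean = cl$report,
                     dive_filter = fd$report,
                     n_fixes_in = nrow(fixes),
                     n_fixes_out = nrow(seg),
                     n_speed_removed = nrow(ex$fixes) - nrow(sp),
                     n_dives_in = nrow(dives),
                     n_dives_out = nrow(fd$dives),
                     n_tracks = length(tracks)))
}
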