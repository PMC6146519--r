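# Delimited-text readers and writers. All timestamps are ISO-8601 UTC.

#' Write a synthetic dataset to delimited text
#'
#' Writes `fixes.csv` (`animal,timestamp,x_km,y_km,argos_class`), `dives.csv`
#' (`animal,timestamp,depth_m,duration_s,shape`), `truth.csv` (per-interval
#' true states and node coordinates), `truth_dives.csv` (per-dive sub-states)
#' and a `config.json` sidecar recording the full generator configuration.
#'
#' @param dataset a `synthetic_dataset` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fixes = file.path(dir, "fixes.csv"),
             dives = file.path(dir, "dives.csv"),
             truth = file.path(dir, "truth.csv"),
             truth_dives = file.path(dir, "truth_dives.csv"),
             config = file.path(dir, "config.json"))
  fx <- dataset$fixes
  fx$timestamp <- format_utc(fx$timestamp)
  utils::write.csv(fx, paths["fixes"], row.names = FALSE, quote = FALSE)
  dv <- dataset$dives
  dv$timestamp <- format_utc(dv$timestamp)
  utils::write.csv(dv, paths["dives"], row.names = FALSE, quote = FALSE)
  ti <- dataset$truth$intervals
  ti$start <- format_utc(ti$start)
  utils::write.csv(ti, paths["truth"], row.names = FALSE, quote = FALSE)
  td <- dataset$truth$dives
  if (is.null(td)) {
    td <- data.frame(animal = character(0), interval = integer(0),
                     order = integer(0), timestamp = character(0),
                     s_sub = character(0))
  } else {
    td$timestamp <- format_utc(td$timestamp)
  }
  utils::write.csv(td, paths["truth_dives"], row.names = FALSE, quote = FALSE)
  cfg <- dataset$config
  cfg$true_params <- unclass(cfg$true_params)
  cfg$true_params$alpha_sub <- as.numeric(cfg$true_params$alpha_sub)
  cfg$argos_sds <- as.list(unclass(cfg$argos_sds))
  cfg$start_time <- format_utc(cfg$start_time)
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read Argos fixes from delimited text
#'
#' Expects columns `animal`, `timestamp`, `argos_class` and either projected
#' planar coordinates (`x_km`, `y_km`) or geographic ones (`lon`, `lat`);
#' geographic input is projected to planar km with [project_lonlat()]
#' centered on the data centroid.
#'
#' @param path CSV file.
#' @return Data.frame with `animal`, `timestamp` (POSIXct UTC), `x`, `y`
#'   (km), `error_class`, sorted by animal and time.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (all(c("x_km", "y_km") %in% names(raw))) {
    x <- as.numeric(raw$x_km); y <- as.numeric(raw$y_km)
  } else if (all(c("lon", "lat") %in% names(raw))) {
    pr <- project_lonlat(as.numeric(raw$lon), as.numeric(raw$lat))
    x <- pr$x; y <- pr$y
  } else {
    stop("fixes need x_km/y_km or lon/lat columns", call. = FALSE)
  }
  out <- data.frame(animal = raw$animal,
                    timestamp = parse_utc(raw$timestamp),
                    x = x, y = y,
                    error_class = raw$argos_class)
  out[order(out$animal, out$timestamp), , drop = FALSE]
}

#' Read dive records from delimited text
#'
#' @param path CSV with columns `animal`, `timestamp`, `depth_m`,
#'   `duration_s` and optional `shape`.
#' @return Data.frame with `animal`, `timestamp`, `depth`, `duration`,
#'   `shape`, sorted by animal and time.
#' @export
read_dives <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  out <- data.frame(animal = raw$animal,
                    timestamp = parse_utc(raw$timestamp),
                    depth = as.numeric(raw$depth_m),
                    duration = as.numeric(raw$duration_s),
                    shape = if ("shape" %in% names(raw)) raw$shape
                            else NA_character_)
  out[order(out$animal, out$timestamp), , drop = FALSE]
}

#' Project geographic coordinates to a local plane
#'
#' Azimuthal equidistant projection on a spherical Earth (radius 6371 km),
#' centered by default on the data centroid. The movement process is defined
#' on a plane in km, so geographic fixes are projected once before modeling.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param center optional `c(lon, lat)` projection center.
#' @return List with `x`, `y` in km and the `center` used.
#' @export
project_lonlat <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  R <- 6371
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(pmax(cosc, -1), 1)
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- R * k * cos(phi) * sin(lam - lam0)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  list(x = x, y = y, center = center)
}

#' Build a land-mask predicate from a GeoJSON polygon file
#'
#' Reads (Multi)Polygon features and returns a predicate `f(x, y)` that is
#' `TRUE` for points inside any polygon (even-odd ray casting). Coordinates
#' must be in the same planar system as the fixes being cleaned.
#'
#' @param path GeoJSON file.
#' @return Function of two numeric vectors returning a logical vector.
#' @export
land_mask_from_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rings <- list()
  collect <- function(geom) {
    if (is.null(geom)) return()
    if (geom$type == "Polygon") {
      for (r in geom$coordinates)
        rings[[length(rings) + 1L]] <<- do.call(rbind, lapply(r, unlist))
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) for (r in poly)
        rings[[length(rings) + 1L]] <<- do.call(rbind, lapply(r, unlist))
    }
  }
  if (!is.null(gj$features)) {
    for (f in gj$features) collect(f$geometry)
  } else {
    collect(gj)
  }
  function(x, y) {
    inside <- rep(FALSE, length(x))
    for (ring in rings) {
      px <- ring[, 1]; py <- ring[, 2]
      n <- length(px)
      jj <- c(n, seq_len(n - 1L))
      for (i in seq_len(n)) {
        k <- jj[i]
        cross <- ((py[i] > y) != (py[k] > y)) &
          (x < (px[k] - px[i]) * (y - py[i]) / (py[k] - py[i]) + px[i])
        inside <- xor(inside, cross & !is.na(cross))
      }
    }
    inside
  }
}
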