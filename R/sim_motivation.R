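#' Construct a tracking trace
#'
#' A tracking trace holds the time-stamped centre-of-gravity positions of
#' the subject in the sexual incentive motivation (SIM) arena, as exported
#' by a video tracker: strictly increasing times in seconds, positions in
#' cm.
#'
#' @param t numeric vector of sample times (s), strictly increasing.
#' @param x,y numeric vectors of positions (cm).
#' @param arena optional `c(width, height)` of the arena in cm (default
#'   `c(100, 50)`); positions must fall inside.
#' @return An object of class `tracking_trace` (a data.frame `t,x,y` with
#'   an `arena` attribute).
#' @export
tracking_trace <- function(t, x, y, arena = c(100, 50)) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("sample times must be strictly increasing")
  if (any(x < 0 | x > arena[1L] | y < 0 | y > arena[2L]))
    stop("positions outside arena bounds")
  structure(data.frame(t = t, x = x, y = y),
            arena = as.numeric(arena),
            class = c("tracking_trace", "data.frame"))
}

#' Read a tracking trace from CSV
#'
#' Expects header columns `t_s,x_cm,y_cm`.
#'
#' @param path path to the CSV file.
#' @param arena arena dimensions in cm, see [tracking_trace()].
#' @return A [tracking_trace()].
#' @export
read_trace <- function(path, arena = c(100, 50)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns t_s,x_cm,y_cm")
  tracking_trace(df$t_s, df$x_cm, df$y_cm, arena = arena)
}

#' Define the virtual stimulus zones of the SIM arena
#'
#' Zones are axis-aligned rectangles inside the arena, treated as
#' half-open (`[x0, x1) x [y0, y1)`) so that membership is deterministic on
#' shared edges. The standard layout places a 30 x 21 cm zone in front of
#' each stimulus cage on opposite long sides of the 100 x 50 cm arena.
#'
#' @param zones named list of rectangles, each `c(x0, y0, x1, y1)` in cm.
#' @param arena `c(width, height)` in cm.
#' @return An object of class `zone_spec`.
#' @export
zone_spec <- function(zones, arena = c(100, 50)) {
  for (nm in names(zones)) {
    z <- as.numeric(zones[[nm]])
    if (length(z) != 4L || z[3L] <= z[1L] || z[4L] <= z[2L])
      stop("zone '", nm, "' must be c(x0, y0, x1, y1) with x1 > x0, y1 > y0")
    if (z[1L] < 0 || z[2L] < 0 || z[3L] > arena[1L] || z[4L] > arena[2L])
      stop("zone '", nm, "' extends beyond the arena")
    zones[[nm]] <- z
  }
  nms <- names(zones)
  for (i in seq_along(zones)) for (j in seq_len(i - 1L)) {
    a <- zones[[i]]; b <- zones[[j]]
    if (a[1L] < b[3L] && b[1L] < a[3L] && a[2L] < b[4L] && b[2L] < a[4L])
      stop("zones '", nms[i], "' and '", nms[j], "' overlap")
  }
  structure(list(zones = zones, arena = as.numeric(arena)),
            class = "zone_spec")
}

#' Default SIM zone layout
#'
#' Female and male incentive zones of 30 x 21 cm centred on opposite long
#' walls of the 100 x 50 cm arena (in front of the two stimulus cages).
#'
#' @return A [zone_spec()] with zones `female_zone` and `male_zone`.
#' @export
default_zones <- function() {
  zone_spec(list(
    female_zone = c(35, 29, 65, 50),
    male_zone   = c(35,  0, 65, 21)
  ))
}

#' Read a zone layout from YAML
#'
#' The YAML maps each zone name to `x0,y0,x1,y1` (cm) and may carry an
#' `arena: [w, h]` entry.
#'
#' @param path path to the YAML file.
#' @return A [zone_spec()].
#' @export
read_zones <- function(path) {
  y <- yaml::read_yaml(path)
  arena <- if (!is.null(y$arena)) as.numeric(y$arena) else c(100, 50)
  y$arena <- NULL
  zone_spec(lapply(y, as.numeric), arena = arena)
}

# half-open membership test, vectorized over samples
in_zone <- function(x, y, z) {
  x >= z[1L] & x < z[3L] & y >= z[2L] & y < z[4L]
}

#' Zone occupancy times and entry counts
#'
#' Each inter-sample interval is attributed to the zone containing the
#' earlier sample (left-constant interpolation, matching tracker export
#' semantics; no sub-sample interpolation of crossings). An entry is
#' counted at every out-to-in transition of the sample membership sequence;
#' a trace that starts inside a zone counts one initial entry.
#'
#' @param trace a [tracking_trace()].
#' @param zones a [zone_spec()].
#' @return A data.frame with one row per zone: `zone`, `time` (s),
#'   `entries`.
#' @export
zone_occupancy <- function(trace, zones) {
  stopifnot(inherits(trace, "tracking_trace"), inherits(zones, "zone_spec"))
  if (!nrow(trace)) stop("empty trace")
  dt <- if (nrow(trace) > 1L) diff(trace$t) else numeric()
  out <- lapply(names(zones$zones), function(nm) {
    member <- in_zone(trace$x, trace$y, zones$zones[[nm]])
    time <- if (length(dt)) sum(dt[member[-length(member)]]) else 0
    entries <- sum(diff(c(FALSE, member)) == 1L)
    data.frame(zone = nm, time = time, entries = entries)
  })
  do.call(rbind, out)
}

#' Sexual incentive preference score
#'
#' Time spent in the female incentive zone divided by the total time spent
#' in the two incentive zones; 0.5 is the chance level. Undefined (`NA`)
#' when the subject never visited either zone.
#'
#' @param t_female,t_male times in the female and male zones (s), `>= 0`.
#' @return A score in `[0, 1]`, or `NA` when both times are 0.
#' @export
preference_score <- function(t_female, t_male) {
  if (any(c(t_female, t_male) < 0)) stop("zone times must be non-negative")
  tot <- t_female + t_male
  ifelse(tot > 0, t_female / tot, NA_real_)
}

#' Locomotion measures from a tracking trace
#'
#' Distance moved is the sum of Euclidean step lengths between consecutive
#' samples; mean velocity is that distance divided by the elapsed time.
#'
#' @param trace a [tracking_trace()] with at least two samples.
#' @return A list with `distance` (cm) and `mean_velocity` (cm/s).
#' @export
locomotion <- function(trace) {
  stopifnot(inherits(trace, "tracking_trace"))
  if (nrow(trace) < 2L) stop("locomotion needs at least two samples")
  d <- sum(sqrt(diff(trace$x)^2 + diff(trace$y)^2))
  list(distance = d,
       mean_velocity = d / (trace$t[nrow(trace)] - trace$t[1L]))
}

#' All SIM outcome measures for one test
#'
#' Combines [zone_occupancy()], [preference_score()] and [locomotion()]
#' into the standard per-test summary.
#'
#' @param trace a [tracking_trace()].
#' @param zones a [zone_spec()] whose zones include `female_zone` and
#'   `male_zone`.
#' @return A list of class `sim_measures` with `occupancy` (data.frame),
#'   `preference_score`, `distance`, `mean_velocity`.
#' @export
sim_measures <- function(trace, zones = default_zones()) {
  occ <- zone_occupancy(trace, zones)
  tf <- occ$time[occ$zone == "female_zone"]
  tm <- occ$time[occ$zone == "male_zone"]
  loc <- locomotion(trace)
  structure(list(
    occupancy = occ,
    preference_score = if (length(tf) && length(tm))
      preference_score(tf, tm) else NA_real_,
    distance = loc$distance,
    mean_velocity = loc$mean_velocity
  ), class = "sim_measures")
}

#' @export
print.sim_measures <- function(x, ...) {
  cat("<sim_measures>\n")
  print(x$occupancy)
  cat(sprintf("  preference_score: %.3f\n", x$preference_score))
  cat(sprintf("  distance: %.1f cm, mean velocity: %.2f cm/s\n",
              x$distance, x$mean_velocity))
  invisible(x)
}
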