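#' Partition a copulation log into ejaculation series
#'
#' An ejaculation series runs from the first mount or intromission after
#' the previous ejaculation (or after test start, for series 1) up to and
#' including the ejaculation that terminates it. A trailing run of
#' copulatory behavior with no terminating ejaculation forms at most one
#' incomplete series. The post-ejaculatory interval (PEI) of a series is
#' the time from its ejaculation to the first mount or intromission of the
#' next series, and is absent when either endpoint does not exist.
#'
#' @param log a validated [copulation_log()].
#' @return A data.frame of class `ejaculation_series` with one row per
#'   series: `series` (1-based index), `start`, `ejaculation_time` (`NA`
#'   for an incomplete series), `pei`, and `complete`.
#' @export
partition_series <- function(log) {
  stopifnot(inherits(log, "copulation_log"))
  voc <- log$vocabulary
  ev <- log$events
  cop <- ev[ev$behavior %in% voc$copulatory, , drop = FALSE]
  empty <- data.frame(series = integer(), start = numeric(),
                      ejaculation_time = numeric(), pei = numeric(),
                      complete = logical())
  class(empty) <- c("ejaculation_series", "data.frame")
  if (!nrow(cop)) return(empty)

  is_ejac <- cop$behavior == "ejaculation"
  # series boundaries fall immediately after each ejaculation
  series_id <- cumsum(c(0L, utils::head(as.integer(is_ejac), -1L))) + 1L
  ns <- series_id[length(series_id)]
  start <- ejac_t <- first_mi <- rep(NA_real_, ns)
  first_any <- rep(NA_real_, ns)
  for (i in seq_len(nrow(cop))) {
    k <- series_id[i]
    if (is.na(first_any[k])) first_any[k] <- cop$start[i]
    if (is_ejac[i]) {
      if (is.na(ejac_t[k])) ejac_t[k] <- cop$start[i]
    } else if (is.na(first_mi[k])) first_mi[k] <- cop$start[i]
  }
  start <- ifelse(is.na(first_mi), first_any, first_mi)
  pei <- rep(NA_real_, ns)
  if (ns > 1L)
    pei[seq_len(ns - 1L)] <- first_mi[-1L] - ejac_t[seq_len(ns - 1L)]
  out <- data.frame(series = seq_len(ns), start = start,
                    ejaculation_time = ejac_t, pei = pei,
                    complete = !is.na(ejac_t))
  class(out) <- c("ejaculation_series", "data.frame")
  out
}

# copulatory events of one series, in time order
series_events <- function(log, series_row) {
  voc <- log$vocabulary
  ev <- log$events
  cop <- ev[ev$behavior %in% voc$copulatory, , drop = FALSE]
  lo <- series_row$start
  hi <- if (!is.na(series_row$ejaculation_time))
    series_row$ejaculation_time else Inf
  cop[cop$start >= lo & cop$start <= hi, , drop = FALSE]
}

#' Segment one ejaculation series into mount bouts and time-outs
#'
#' A mount bout is a run of one or more copulatory behaviors (mounts,
#' intromissions, the terminating ejaculation) uninterrupted by any
#' behavior, other than genital autogrooming or other female-oriented
#' behavior, that is not oriented towards the female. Concretely, a
#' boundary is placed between two consecutive copulatory events iff some
#' bout-breaking event's interval intersects the open gap between the end
#' of the earlier and the start of the later event. A bout's end is the end
#' of its last copulatory member; the gap to the start of the next bout is
#' recorded as a time-out. Bout-neutral events (genital grooming,
#' anogenital sniffing, chasing, head towards female) never split a bout,
#' and the intervals before the first copulatory behavior and after an
#' ejaculation are never time-outs.
#'
#' @param log a validated [copulation_log()].
#' @param series one row of the output of [partition_series()] (a
#'   data.frame row), or a series index into it.
#' @return A list with two data.frames: `bouts` (`bout`, `start`, `end`,
#'   `n_events`, `n_mounts`, `n_intromissions`, `has_ejaculation`) and
#'   `timeouts` (`start`, `end`, `duration`).
#' @export
segment_mount_bouts <- function(log, series) {
  stopifnot(inherits(log, "copulation_log"))
  if (is.numeric(series) && length(series) == 1L) {
    ser <- partition_series(log)
    stopifnot(series >= 1, series <= nrow(ser))
    series <- ser[series, , drop = FALSE]
  }
  voc <- log$vocabulary
  cop <- series_events(log, series)
  empty_bouts <- data.frame(bout = integer(), start = numeric(),
                            end = numeric(), n_events = integer(),
                            n_mounts = integer(), n_intromissions = integer(),
                            has_ejaculation = logical())
  empty_tos <- data.frame(start = numeric(), end = numeric(),
                          duration = numeric())
  if (!nrow(cop)) return(list(bouts = empty_bouts, timeouts = empty_tos))

  brk <- log$events[log$events$behavior %in% voc$bout_breaking, ,
                    drop = FALSE]
  n <- nrow(cop)
  boundary <- logical(n - 1L)
  if (n > 1L && nrow(brk)) {
    for (k in seq_len(n - 1L)) {
      g1 <- cop$end[k]
      g2 <- cop$start[k + 1L]
      # a breaking event splits iff it intersects the open gap (g1, g2)
      boundary[k] <- any(brk$end > g1 & brk$start < g2)
    }
  }
  bout_id <- cumsum(c(0L, as.integer(boundary))) + 1L
  first <- !duplicated(bout_id)
  last <- !duplicated(bout_id, fromLast = TRUE)
  nb <- bout_id[n]
  bouts <- data.frame(
    bout = seq_len(nb),
    start = cop$start[first],
    end = cop$end[last],
    n_events = tabulate(bout_id, nb),
    n_mounts = as.integer(rowsum(as.numeric(cop$behavior == "mount"),
                                 bout_id)[, 1L]),
    n_intromissions = as.integer(
      rowsum(as.numeric(cop$behavior == "intromission"), bout_id)[, 1L]),
    has_ejaculation = rowsum(as.numeric(cop$behavior == "ejaculation"),
                             bout_id)[, 1L] > 0
  )
  rownames(bouts) <- NULL
  if (nrow(bouts) > 1L) {
    timeouts <- data.frame(
      start = bouts$end[-nrow(bouts)],
      end = bouts$start[-1L]
    )
    timeouts$duration <- timeouts$end - timeouts$start
  } else {
    timeouts <- empty_tos
  }
  list(bouts = bouts, timeouts = timeouts)
}

# clip event intervals to [0, t_cut] and sum durations per behavior label
clipped_time_by_behavior <- function(events, t_cut) {
  if (!nrow(events)) return(numeric())
  s <- pmin(pmax(events$start, 0), t_cut)
  e <- pmin(pmax(events$end, 0), t_cut)
  tapply(pmax(e - s, 0), events$behavior, sum)
}

#' Compute all copulation outcome measures for a test
#'
#' Derives the full set of copulation measures from one 30-min test log.
#' All bout-level measures refer to the first ejaculation series
#' ("Series 1"); the ejaculation count covers the whole test. Censoring
#' follows the standard convention: with no ejaculation the latency to
#' ejaculation is scored as the test duration (1800 s), and with no
#' copulatory behavior at all the latency to first copulatory behavior is
#' scored as 1800 s. Undefined ratios (no mounts and no intromissions) are
#' reported as `NA`, not 0.
#'
#' @param log a validated [copulation_log()].
#' @return A list of class `copulation_measures`:
#'   \describe{
#'     \item{n_ejaculations}{ejaculations in the whole test}
#'     \item{n_mounts, n_intromissions}{counts in series 1 (the
#'       terminating ejaculation excluded)}
#'     \item{n_mount_bouts}{mount bouts in series 1}
#'     \item{intromission_ratio}{intromissions / (mounts + intromissions),
#'       series 1}
#'     \item{mean_mounts_per_bout, mean_intromissions_per_bout}{series-1
#'       bout means}
#'     \item{mean_timeout_duration}{mean series-1 time-out duration (s);
#'       `NA` with fewer than two bouts}
#'     \item{pei_1}{first post-ejaculatory interval (s)}
#'     \item{latency_to_ejaculation}{first mount/intromission to first
#'       ejaculation (s), censored at the test duration}
#'     \item{latency_to_first_copulatory_behavior}{test start to first
#'       mount/intromission (s), censored at the test duration}
#'     \item{percent_time}{named vector, percent of time from test start to
#'       first ejaculation spent on each behavior}
#'     \item{percent_non_copulation_oriented}{percent of that same period
#'       spent on bout-breaking behaviors (non-genital grooming + head not
#'       towards female)}
#'   }
#' @export
compute_measures <- function(log) {
  stopifnot(inherits(log, "copulation_log"))
  voc <- log$vocabulary
  ev <- log$events
  dur <- log$test_duration
  cop <- ev[ev$behavior %in% voc$copulatory, , drop = FALSE]
  mi <- cop[cop$behavior != "ejaculation", , drop = FALSE]
  n_ejac <- sum(cop$behavior == "ejaculation")

  lat_first <- if (nrow(mi)) mi$start[1L] else dur

  ser <- partition_series(log)
  has_s1 <- nrow(ser) > 0L
  s1_complete <- has_s1 && isTRUE(ser$complete[1L])
  ejac1_t <- if (s1_complete) ser$ejaculation_time[1L] else NA_real_

  lat_ejac <- if (s1_complete && nrow(mi)) ejac1_t - ser$start[1L] else dur
  lat_ejac <- min(lat_ejac, dur)

  if (has_s1) {
    seg <- segment_mount_bouts(log, ser[1L, , drop = FALSE])
    bouts <- seg$bouts
    tos <- seg$timeouts
    n_mounts <- sum(bouts$n_mounts)
    n_intro <- sum(bouts$n_intromissions)
    n_bouts <- nrow(bouts)
    mean_to <- if (nrow(tos)) mean(tos$duration) else NA_real_
    mean_m <- mean(bouts$n_mounts)
    mean_i <- mean(bouts$n_intromissions)
  } else {
    n_mounts <- 0L; n_intro <- 0L; n_bouts <- 0L
    mean_to <- NA_real_; mean_m <- NA_real_; mean_i <- NA_real_
  }
  ir <- if (n_mounts + n_intro > 0) n_intro / (n_mounts + n_intro)
        else NA_real_

  # percent-time budget: denominator runs from test start to the first
  # ejaculation, or over the whole test when none occurred
  t_cut <- if (s1_complete) ejac1_t else dur
  by_beh <- clipped_time_by_behavior(ev, t_cut)
  pct <- if (t_cut > 0) 100 * by_beh / t_cut else
    stats::setNames(rep(NA_real_, length(by_beh)), names(by_beh))
  noncop <- sum(by_beh[names(by_beh) %in% voc$bout_breaking])
  pct_noncop <- if (t_cut > 0) 100 * noncop / t_cut else NA_real_

  structure(list(
    subject = log$subject,
    n_ejaculations = n_ejac,
    n_mounts = n_mounts,
    n_intromissions = n_intro,
    n_mount_bouts = n_bouts,
    intromission_ratio = ir,
    mean_mounts_per_bout = mean_m,
    mean_intromissions_per_bout = mean_i,
    mean_timeout_duration = mean_to,
    pei_1 = if (has_s1) ser$pei[1L] else NA_real_,
    latency_to_ejaculation = lat_ejac,
    latency_to_first_copulatory_behavior = lat_first,
    percent_time = pct,
    percent_non_copulation_oriented = pct_noncop
  ), class = "copulation_measures")
}

#' @export
print.copulation_measures <- function(x, ...) {
  cat("<copulation_measures> subject:", x$subject, "\n")
  flat <- x[!(names(x) %in% c("subject", "percent_time"))]
  for (nm in names(flat))
    cat(sprintf("  %-38s %s\n", nm, format(flat[[nm]], digits = 4)))
  invisible(x)
}

#' Flatten copulation measures to a one-row data.frame
#'
#' Convenience for building tidy per-subject result tables; the per-behavior
#' percent-time vector is spread into `pct_<behavior>` columns.
#'
#' @param x a `copulation_measures` object.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return A one-row data.frame.
#' @export
as.data.frame.copulation_measures <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  flat <- x[!(names(x) %in% c("percent_time"))]
  df <- as.data.frame(flat, stringsAsFactors = FALSE)
  if (length(x$percent_time)) {
    p <- as.list(x$percent_time)
    names(p) <- paste0("pct_", names(p))
    df <- cbind(df, as.data.frame(p))
  }
  rownames(df) <- row.names
  df
}
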