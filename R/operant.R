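#' Construct an operant session
#'
#' An operant session is a time-ordered stream of typed events from a
#' sucrose self-administration box: active lever presses, inactive lever
#' presses, reward deliveries and receptacle nosepokes, together with the
#' schedule (FR1 or PR) and the recorded session duration (1800 s for the
#' standard 30-min FR1 session; variable under PR).
#'
#' @param events a data.frame with columns `t` (seconds, non-decreasing)
#'   and `kind` (one of `active_press`, `inactive_press`, `reward`,
#'   `nosepoke`).
#' @param schedule `"FR1"` or `"PR"`.
#' @param subject subject identifier.
#' @param session_duration recorded session duration (s); default 1800 for
#'   FR1, `NA` (derived from the log) for PR.
#' @param design optional named list of design-cell labels.
#' @return An object of class `operant_session`.
#' @export
operant_session <- function(events, schedule = c("FR1", "PR"),
                            subject = NA_character_,
                            session_duration = NULL, design = NULL) {
  schedule <- match.arg(schedule)
  kinds <- c("active_press", "inactive_press", "reward", "nosepoke")
  if (is.null(events) || nrow(as.data.frame(events)) == 0L)
    events <- data.frame(t = numeric(), kind = character())
  events <- as.data.frame(events)[, c("t", "kind")]
  events$t <- as.numeric(events$t)
  events$kind <- as.character(events$kind)
  bad <- setdiff(unique(events$kind), kinds)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  if (any(events$t < 0)) stop("negative event time")
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(session_duration))
    session_duration <- if (schedule == "FR1") 1800 else NA_real_
  structure(list(subject = subject, schedule = schedule, events = events,
                 session_duration = as.numeric(session_duration),
                 design = design),
            class = "operant_session")
}

#' @export
print.operant_session <- function(x, ...) {
  cat("<operant_session> subject:", x$subject, "| schedule:", x$schedule,
      "| events:", nrow(x$events), "\n")
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}

#' Read an operant session log from CSV
#'
#' Expects header columns `t_s,kind`; kinds as in [operant_session()].
#'
#' @param path path to the CSV file.
#' @param schedule `"FR1"` or `"PR"`.
#' @param ... passed to [operant_session()].
#' @return An [operant_session()].
#' @export
read_operant <- function(path, schedule = c("FR1", "PR"), ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_s", "kind") %in% names(df)))
    stop("operant CSV must have columns t_s,kind")
  operant_session(data.frame(t = df$t_s, kind = df$kind),
                  schedule = schedule, ...)
}

#' Generate a progressive-ratio response-requirement schedule
#'
#' Uses the exponential progression of Richardson and Roberts:
#' `r_j = round(5 * exp(0.2 * j)) - 5`, giving the familiar prefix
#' 1, 2, 4, 6, 9, 12, 15, 20, 25, 32, ...
#'
#' @param n number of requirements to generate (`>= 1`).
#' @return Integer vector of `n` response requirements.
#' @export
generate_pr_schedule <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1")
  j <- seq_len(n)
  r <- round(5 * exp(0.2 * j)) - 5
  if (r[length(r)] <= .Machine$integer.max) as.integer(r) else r
}

#' Fixed-ratio-1 session measures
#'
#' Computes the FR1 reward-pacing measures: reward and inactive-press
#' counts, the mean reward interval
#' `(time of last reward - time of first reward) / (number of rewards - 1)`
#' (absent with fewer than two rewards), the cumulative reward curve in
#' 1-s bins, and the time to each successive 10% of total rewards.
#'
#' @param session an [operant_session()] with `schedule == "FR1"`.
#' @return A list with `n_rewards`, `n_inactive`, `mean_reward_interval`,
#'   `cumulative_curve` (data.frame `t`, `rewards`; one row per 1-s bin
#'   edge from 0 to the session duration) and `reward_decile_times`
#'   (length-10 vector; `NA` entries when there are no rewards).
#' @export
fr1_metrics <- function(session) {
  stopifnot(inherits(session, "operant_session"))
  if (session$schedule != "FR1") stop("fr1_metrics requires an FR1 session")
  ev <- session$events
  rw <- ev$t[ev$kind == "reward"]
  n <- length(rw)
  dur <- session$session_duration
  if (is.na(dur)) dur <- if (nrow(ev)) max(ev$t) else 0
  mri <- if (n >= 2L) (rw[n] - rw[1L]) / (n - 1L) else NA_real_
  edges <- seq(0, ceiling(dur), by = 1)
  curve <- data.frame(
    t = edges,
    rewards = vapply(edges, function(b) sum(rw <= b), numeric(1))
  )
  deciles <- if (n >= 1L) rw[ceiling(seq_len(10L) * n / 10 - 1e-9)]
             else rep(NA_real_, 10L)
  list(
    n_rewards = n,
    n_inactive = sum(ev$kind == "inactive_press"),
    mean_reward_interval = mri,
    cumulative_curve = curve,
    reward_decile_times = deciles
  )
}

#' Find the inter-bout-interval threshold from a scree plot of intervals
#'
#' Orders all lever-press interval durations in descending order (the
#' scree plot) and locates the inflection point as the point of maximum
#' perpendicular distance to the chord joining the first and last points;
#' the interval value at that point separates long between-bout intervals
#' from short within-bout intervals. The default mode returns the fixed
#' 10-s threshold adopted for the full data set after the per-animal scree
#' plots clustered around 10 s; `method = "knee"` runs the automatic
#' detector.
#'
#' @param intervals numeric vector of inter-press intervals (s); the knee
#'   detector needs at least 3.
#' @param method `"fixed"` (default) or `"knee"`.
#' @param fixed the fixed threshold (s) returned in `"fixed"` mode and
#'   used as fallback in degenerate cases (default 10).
#' @return Threshold in seconds.
#' @export
find_interval_threshold <- function(intervals, method = c("fixed", "knee"),
                                    fixed = 10) {
  method <- match.arg(method)
  if (method == "fixed") return(fixed)
  intervals <- sort(as.numeric(intervals), decreasing = TRUE)
  n <- length(intervals)
  if (n < 3L) stop("knee detection needs at least 3 intervals")
  if (diff(range(intervals)) == 0) {
    warning("all intervals equal; no knee, returning fixed fallback")
    return(fixed)
  }
  # perpendicular distance from (i, v_i) to the chord (1, v_1)-(n, v_n),
  # with both axes normalized to [0, 1] so the result does not depend on
  # the units of either axis
  u <- (seq_len(n) - 1) / (n - 1)
  v <- (intervals - intervals[n]) / (intervals[1L] - intervals[n])
  # chord runs from (0, 1) to (1, 0); distance = |u + v - 1| / sqrt(2)
  dist <- abs(u + v - 1) / sqrt(2)
  k <- which.max(dist)
  # the knee localizes the elbow; return the midpoint of the steepest
  # drop adjacent to it, so the threshold falls between the long and
  # short interval populations instead of on an observed interval
  # steepness is judged on the log scale: interval durations live on a
  # multiplicative scale, and the within/between cliff is the largest
  # ratio, not necessarily the largest absolute drop
  win <- max(1L, k - 5L):min(n - 1L, k + 5L)
  eps <- 1e-9 * intervals[1L]
  j <- win[which.max(log((intervals[win] + eps) /
                           (intervals[win + 1L] + eps)))]
  (intervals[j] + intervals[j + 1L]) / 2
}

#' Detect lever-press bouts from press timestamps
#'
#' Splits a sorted press-time sequence into bouts: a new bout starts
#' whenever the gap from the previous press is at or above the threshold
#' (ties start a new bout).
#'
#' @param press_times sorted numeric vector of press timestamps (s).
#' @param threshold inter-bout-interval threshold (s).
#' @return A list of class `press_bout_set` with `bouts` (list of
#'   timestamp vectors), `bout_id` (per press), `n_bouts`,
#'   `mean_presses_per_bout`, and `threshold`.
#' @export
detect_press_bouts <- function(press_times, threshold) {
  press_times <- as.numeric(press_times)
  if (is.unsorted(press_times)) stop("press times must be sorted")
  if (!length(press_times)) {
    return(structure(list(bouts = list(), bout_id = integer(),
                          n_bouts = 0L, mean_presses_per_bout = NA_real_,
                          threshold = threshold),
                     class = "press_bout_set"))
  }
  gaps <- diff(press_times)
  bout_id <- cumsum(c(1L, as.integer(gaps >= threshold)))
  bouts <- split(press_times, bout_id)
  names(bouts) <- NULL
  structure(list(bouts = bouts, bout_id = bout_id,
                 n_bouts = length(bouts),
                 mean_presses_per_bout = length(press_times) / length(bouts),
                 threshold = threshold),
            class = "press_bout_set")
}

#' @export
print.press_bout_set <- function(x, ...) {
  cat("<press_bout_set>", x$n_bouts, "bouts,",
      sprintf("%.2f", x$mean_presses_per_bout),
      "presses/bout, threshold", x$threshold, "s\n")
  invisible(x)
}

#' Progressive-ratio session measures
#'
#' Computes PR outcome measures: reward count, breakpoint (the response
#' requirement of the last obtained reward), the mean lever-press interval
#' `(total test duration) / (total number of active lever presses)`, and
#' the test duration under the stop rule that a PR session ends when no
#' further reward is obtained within 30 min of the previous one (recorded
#' as time of last reward + 1800 s, or the recorded session end if the log
#' ends earlier).
#'
#' @param session an [operant_session()] with `schedule == "PR"`.
#' @param schedule integer vector of response requirements, as produced by
#'   [generate_pr_schedule()]; extended automatically if the session earned
#'   more rewards than `length(schedule)`.
#' @param timeout stop-rule window in seconds (default 1800).
#' @return A list with `n_rewards`, `breakpoint`, `mean_press_interval`,
#'   `test_duration`, `n_inactive`, and `cumulative_curve` (1-s bins).
#' @export
pr_metrics <- function(session, schedule = generate_pr_schedule(30),
                       timeout = 1800) {
  stopifnot(inherits(session, "operant_session"))
  if (session$schedule != "PR") stop("pr_metrics requires a PR session")
  ev <- session$events
  rw <- ev$t[ev$kind == "reward"]
  n <- length(rw)
  if (n > length(schedule))
    schedule <- generate_pr_schedule(n)
  breakpoint <- if (n >= 1L) schedule[n] else NA_integer_
  recorded_end <- session$session_duration
  if (is.na(recorded_end)) recorded_end <- if (nrow(ev)) max(ev$t) else 0
  stop_time <- if (n >= 1L) rw[n] + timeout else timeout
  test_duration <- min(stop_time, recorded_end)
  n_active <- sum(ev$kind == "active_press" & ev$t <= test_duration)
  mpi <- if (n_active > 0L) test_duration / n_active else NA_real_
  edges <- seq(0, ceiling(test_duration), by = 1)
  curve <- data.frame(
    t = edges,
    rewards = vapply(edges, function(b) sum(rw <= b), numeric(1))
  )
  list(
    n_rewards = n,
    breakpoint = breakpoint,
    mean_press_interval = mpi,
    test_duration = test_duration,
    n_inactive = sum(ev$kind == "inactive_press" & ev$t <= test_duration),
    cumulative_curve = curve
  )
}

#' Average repeated tests per subject and treatment
#'
#' FR1 outcome measures are variable across sessions, so each rat is
#' tested twice per treatment and the reported value is the mean of the
#' two tests. More than two tests per subject-treatment cell is a design
#' violation and raises an error; a single available test is carried
#' through with a flag rather than imputed.
#'
#' @param measures a data.frame with columns `subject`, `treatment`,
#'   `value` (one row per test).
#' @param max_tests tests expected per cell (default 2).
#' @return A data.frame with one row per subject-treatment cell: `subject`,
#'   `treatment`, `value` (mean), `n_tests`, `incomplete`.
#' @export
average_repeated_tests <- function(measures, max_tests = 2L) {
  need <- c("subject", "treatment", "value")
  if (!all(need %in% names(measures)))
    stop("measures must have columns subject, treatment, value")
  key <- interaction(measures$subject, measures$treatment, drop = TRUE)
  out <- do.call(rbind, lapply(split(measures, key), function(d) {
    if (nrow(d) > max_tests)
      stop("subject ", d$subject[1L], ", treatment ", d$treatment[1L],
           ": ", nrow(d), " tests exceed the designed ", max_tests)
    data.frame(subject = d$subject[1L], treatment = d$treatment[1L],
               value = mean(d$value), n_tests = nrow(d),
               incomplete = nrow(d) < max_tests)
  }))
  rownames(out) <- NULL
  out
}
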