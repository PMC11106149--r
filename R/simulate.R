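#' Parameters for the copulation log generator
#'
#' The generator is an explicit semi-Markov chain over the macro-states of
#' the male rat sexual behavior cycle: mount bout, time-out, and
#' post-ejaculatory interval. Within a bout, copulatory events follow each
#' other at log-normal inter-copulatory intervals; each is an intromission
#' with probability `p_intromission`, and once the cumulative intromission
#' count reaches `intromission_threshold` the next copulatory event is the
#' ejaculation terminating the series. Between bouts, a log-normal
#' time-out elapses and a bout-breaking filler event is placed strictly
#' inside the gap (a gap with no bout-breaking behavior would not be a
#' time-out). After an ejaculation a log-normal PEI elapses before the
#' next series. `timeout_mult` and `pei_mult` are per-design-cell effect
#' multipliers applied to every drawn time-out / PEI duration.
#'
#' @param latency_meanlog,latency_sdlog log-normal parameters for the
#'   latency from test start to the first copulatory behavior (s).
#' @param events_per_bout_lambda bout size is `1 + rpois(lambda)`
#'   copulatory events.
#' @param within_gap_meanlog,within_gap_sdlog log-normal inter-copulatory
#'   interval within a bout (s).
#' @param p_intromission probability that a copulatory event is an
#'   intromission rather than a mount.
#' @param intromission_threshold intromissions required to trigger the
#'   ejaculation; `Inf` yields a log with no ejaculation.
#' @param timeout_meanlog,timeout_sdlog log-normal time-out duration (s).
#' @param pei_meanlog,pei_sdlog log-normal post-ejaculatory interval (s).
#' @param timeout_mult,pei_mult multiplicative effect-injection factors.
#' @param event_duration named durations (s) of mount, intromission and
#'   ejaculation events.
#' @param neutral_fill_prob probability that a within-bout gap receives a
#'   bout-neutral filler event.
#' @param test_duration test length (s), default 1800.
#' @return A list of class `copulation_sim_params`.
#' @export
copulation_sim_params <- function(latency_meanlog = log(60),
                                  latency_sdlog = 0.5,
                                  events_per_bout_lambda = 1.5,
                                  within_gap_meanlog = log(8),
                                  within_gap_sdlog = 0.5,
                                  p_intromission = 0.5,
                                  intromission_threshold = 8,
                                  timeout_meanlog = log(40),
                                  timeout_sdlog = 0.5,
                                  pei_meanlog = log(300),
                                  pei_sdlog = 0.3,
                                  timeout_mult = 1,
                                  pei_mult = 1,
                                  event_duration = c(mount = 1.5,
                                                     intromission = 2,
                                                     ejaculation = 5),
                                  neutral_fill_prob = 0.5,
                                  test_duration = 1800) {
  p <- as.list(environment())
  stopifnot(p$p_intromission >= 0, p$p_intromission <= 1,
            p$events_per_bout_lambda >= 0, p$timeout_mult > 0,
            p$pei_mult > 0, p$test_duration > 0,
            p$intromission_threshold >= 1)
  class(p) <- "copulation_sim_params"
  p
}

#' Simulate a copulation test log with exact ground truth
#'
#' Generates a full 30-min copulation ethogram (alternating mount bouts
#' and time-outs within ejaculation series, separated by post-ejaculatory
#' intervals) together with the generator's own record of every bout,
#' time-out and series, in the same shapes the segmentation stage
#' produces. Events that would extend past the test duration are dropped,
#' and the ground truth reflects the surviving events.
#'
#' @param params a [copulation_sim_params()].
#' @param seed integer seed; the output is a deterministic function of it.
#' @param subject subject id carried into the log.
#' @return A list with `log` (a [copulation_log()]) and `truth`, a list of
#'   data.frames `bouts` (`series`, `bout`, `start`, `end`, `n_events`,
#'   `n_mounts`, `n_intromissions`, `has_ejaculation`), `timeouts`
#'   (`series`, `start`, `end`, `duration`) and `series` (`series`,
#'   `start`, `ejaculation_time`, `pei`, `complete`).
#' @export
simulate_copulation <- function(params = copulation_sim_params(),
                                seed = 1L, subject = "sim") {
  stopifnot(inherits(params, "copulation_sim_params"))
  set.seed(seed)
  p <- params
  dur <- p$test_duration
  cap <- 512L
  beh <- character(cap); st <- numeric(cap); en <- numeric(cap)
  bout_uid <- integer(cap); series_id <- integer(cap)
  n_ev_total <- 0L
  overflow <- FALSE

  add <- function(b, s, e, uid = NA_integer_, ser = NA_integer_) {
    if (e > dur || s < 0) { overflow <<- TRUE; return(FALSE) }
    i <- n_ev_total + 1L
    if (i > cap) {
      cap <<- cap * 2L
      length(beh) <<- cap; length(st) <<- cap; length(en) <<- cap
      length(bout_uid) <<- cap; length(series_id) <<- cap
    }
    beh[i] <<- b; st[i] <<- s; en[i] <<- e
    bout_uid[i] <<- uid; series_id[i] <<- ser
    n_ev_total <<- i
    TRUE
  }

  t <- stats::rlnorm(1, p$latency_meanlog, p$latency_sdlog)
  # pre-copulatory filler (never part of a bout or time-out)
  if (t > 2) add("head_not_towards_female", 0.1 * t, 0.9 * t)
  ser <- 1L
  uid <- 0L
  n_intro <- 0L
  while (!overflow) {
    # ---- one mount bout ----
    uid <- uid + 1L
    n_ev <- 1L + stats::rpois(1, p$events_per_bout_lambda)
    bout_end <- NA_real_
    ejac_this_series <- FALSE
    k <- 0L
    while (k < n_ev && !overflow && !ejac_this_series) {
      k <- k + 1L
      if (k > 1L) {
        gap <- stats::rlnorm(1, p$within_gap_meanlog, p$within_gap_sdlog)
        if (stats::runif(1) < p$neutral_fill_prob && gap > 1) {
          filler <- sample(c("genital_grooming", "head_towards_female",
                             "anogenital_sniffing", "chasing"), 1L)
          if (!add(filler, bout_end + 0.1 * gap, bout_end + 0.9 * gap))
            break
        }
        t <- bout_end + gap
      }
      if (n_intro >= p$intromission_threshold) {
        b <- "ejaculation"
        ejac_this_series <- TRUE
      } else if (stats::runif(1) < p$p_intromission) {
        b <- "intromission"
        n_intro <- n_intro + 1L
      } else {
        b <- "mount"
      }
      d <- unname(p$event_duration[[b]])
      if (!add(b, t, t + d, uid = uid, ser = ser)) break
      bout_end <- t + d
      if (b == "intromission" && n_intro >= p$intromission_threshold &&
          k == n_ev) {
        # extend the bout by one event so the ejaculation lands in it
        n_ev <- n_ev + 1L
      }
    }
    if (overflow) break
    if (ejac_this_series) {
      # ---- post-ejaculatory interval, then a new series ----
      ejac_start <- st[n_ev_total]
      pei <- stats::rlnorm(1, p$pei_meanlog, p$pei_sdlog) * p$pei_mult
      pei <- max(pei, (bout_end - ejac_start) + 5)
      if (bout_end + 0.8 * (ejac_start + pei - bout_end) > dur) break
      add("head_not_towards_female",
          bout_end + 0.2 * (ejac_start + pei - bout_end),
          bout_end + 0.8 * (ejac_start + pei - bout_end))
      t <- ejac_start + pei
      ser <- ser + 1L
      n_intro <- 0L
    } else {
      # ---- time-out before the next bout of the same series ----
      d <- stats::rlnorm(1, p$timeout_meanlog, p$timeout_sdlog) *
        p$timeout_mult
      if (!add("other_grooming", bout_end + 0.2 * d, bout_end + 0.8 * d))
        break
      t <- bout_end + d
    }
  }

  keep <- seq_len(n_ev_total)
  ev <- data.frame(behavior = beh[keep], start = st[keep], end = en[keep])
  bout_uid <- bout_uid[keep]; series_id <- series_id[keep]
  o <- order(ev$start, ev$end)
  ev <- ev[o, , drop = FALSE]
  bout_uid <- bout_uid[o]; series_id <- series_id[o]
  log <- copulation_log(ev, subject = subject, test_duration = dur)

  # ---- ground truth from the generator's own labels ----
  # events are generated in time order, so bout and series ids are
  # non-decreasing along the sorted log and first/last tricks apply
  cop_idx <- which(!is.na(bout_uid))
  bu <- bout_uid[cop_idx]
  sid <- series_id[cop_idx]
  if (length(cop_idx)) {
    bfirst <- !duplicated(bu)
    blast <- !duplicated(bu, fromLast = TRUE)
    bseries <- sid[bfirst]
    truth_bouts <- data.frame(
      series = bseries,
      bout = sequence(rle(bseries)$lengths),
      start = ev$start[cop_idx[bfirst]],
      end = ev$end[cop_idx[blast]],
      n_events = rle(bu)$lengths,
      n_mounts = as.integer(rowsum(
        as.numeric(ev$behavior[cop_idx] == "mount"), bu)[, 1L]),
      n_intromissions = as.integer(rowsum(
        as.numeric(ev$behavior[cop_idx] == "intromission"), bu)[, 1L]),
      has_ejaculation = rowsum(
        as.numeric(ev$behavior[cop_idx] == "ejaculation"), bu)[, 1L] > 0
    )
  } else {
    truth_bouts <- data.frame(series = integer(), bout = integer(),
                              start = numeric(), end = numeric(),
                              n_events = integer(), n_mounts = integer(),
                              n_intromissions = integer(),
                              has_ejaculation = logical())
  }
  rownames(truth_bouts) <- NULL
  nb <- nrow(truth_bouts)
  same <- if (nb > 1L) truth_bouts$series[-nb] == truth_bouts$series[-1L]
          else logical()
  truth_timeouts <- data.frame(
    series = truth_bouts$series[-nb][same],
    start = truth_bouts$end[-nb][same],
    end = truth_bouts$start[-1L][same]
  )
  if (nb <= 1L)
    truth_timeouts <- data.frame(series = integer(), start = numeric(),
                                 end = numeric())
  truth_timeouts$duration <- truth_timeouts$end - truth_timeouts$start

  is_mi <- ev$behavior[cop_idx] != "ejaculation"
  us <- unique(sid)
  s_start <- vapply(us, function(s) {
    i <- cop_idx[sid == s & is_mi]
    if (length(i)) ev$start[i[1L]] else ev$start[cop_idx[sid == s][1L]]
  }, numeric(1))
  s_ejac <- vapply(us, function(s) {
    i <- cop_idx[sid == s & !is_mi]
    if (length(i)) ev$start[i[1L]] else NA_real_
  }, numeric(1))
  truth_series <- data.frame(series = us, start = s_start,
                             ejaculation_time = s_ejac,
                             complete = !is.na(s_ejac))
  truth_series$pei <- NA_real_
  ns <- nrow(truth_series)
  if (ns > 1L)
    truth_series$pei[-ns] <- truth_series$start[-1L] -
      truth_series$ejaculation_time[-ns]

  list(log = log,
       truth = list(bouts = truth_bouts[, c("series", "bout", "start",
                                            "end", "n_events", "n_mounts",
                                            "n_intromissions",
                                            "has_ejaculation")],
                    timeouts = truth_timeouts,
                    series = truth_series[, c("series", "start",
                                              "ejaculation_time", "pei",
                                              "complete")]))
}

#' Parameters for the operant session generator
#'
#' Active lever presses arrive in bouts: presses within a bout are
#' separated by a nosepoke latency plus a short log-normal interval, and
#' bouts are separated by long log-normal pauses, so within-bout intervals
#' are stochastically much smaller than between-bout intervals. Under FR1
#' every press delivers a reward at the press time and a receptacle
#' nosepoke follows after the latency; under PR a reward is delivered at
#' the press completing the current response requirement.
#'
#' @param schedule `"FR1"` or `"PR"`.
#' @param presses_per_bout_lambda bout size is `1 + rpois(lambda)`.
#' @param within_meanlog,within_sdlog log-normal extra within-bout
#'   interval (s), added to the nosepoke latency.
#' @param between_meanlog,between_sdlog log-normal between-bout pause (s).
#' @param nosepoke_meanlog,nosepoke_sdlog log-normal nosepoke latency (s).
#' @param inactive_rate Poisson rate of inactive presses (per s).
#' @param session_duration FR1 session length (s).
#' @param pr_timeout PR stop-rule window (s).
#' @param rate_mult multiplicative effect factor on all pause durations
#'   (within, between, nosepoke); values > 1 slow the animal down.
#' @return A list of class `operant_sim_params`.
#' @export
operant_sim_params <- function(schedule = c("FR1", "PR"),
                               presses_per_bout_lambda = 4,
                               within_meanlog = log(1.5),
                               within_sdlog = 0.4,
                               between_meanlog = log(60),
                               between_sdlog = 0.4,
                               nosepoke_meanlog = log(1),
                               nosepoke_sdlog = 0.3,
                               inactive_rate = 0.005,
                               session_duration = 1800,
                               pr_timeout = 1800,
                               rate_mult = 1) {
  schedule <- match.arg(schedule)
  p <- as.list(environment())
  stopifnot(p$inactive_rate >= 0, p$rate_mult > 0, p$session_duration > 0)
  class(p) <- "operant_sim_params"
  p
}

#' Simulate an operant session with ground-truth bout labels
#'
#' @param params an [operant_sim_params()].
#' @param seed integer seed.
#' @param subject subject id.
#' @return A list with `session` (an [operant_session()]) and `truth`, a
#'   list with `press_times`, `bout_id` (ground-truth bout membership per
#'   active press), `within_intervals` and `between_intervals` (the
#'   realized inter-press intervals by type).
#' @export
simulate_operant <- function(params = operant_sim_params(), seed = 1L,
                             subject = "sim") {
  stopifnot(inherits(params, "operant_sim_params"))
  set.seed(seed)
  p <- params
  horizon <- if (p$schedule == "FR1") p$session_duration else
    10 * p$session_duration
  press <- numeric(); bout_id <- integer()
  nosepokes <- numeric()
  t <- stats::rlnorm(1, p$between_meanlog, p$between_sdlog) * p$rate_mult
  b <- 0L
  while (t <= horizon) {
    b <- b + 1L
    n <- 1L + stats::rpois(1, p$presses_per_bout_lambda)
    for (k in seq_len(n)) {
      if (t > horizon) break
      press <- c(press, t)
      bout_id <- c(bout_id, b)
      np <- t + stats::rlnorm(1, p$nosepoke_meanlog, p$nosepoke_sdlog) *
        p$rate_mult
      nosepokes <- c(nosepokes, np)
      if (k < n)
        t <- np + stats::rlnorm(1, p$within_meanlog, p$within_sdlog) *
          p$rate_mult
    }
    t <- press[length(press)] +
      stats::rlnorm(1, p$between_meanlog, p$between_sdlog) * p$rate_mult
  }

  if (p$schedule == "FR1") {
    rewards <- press
    keep_np <- nosepokes <= p$session_duration
    ev <- data.frame(
      t = c(press, rewards, nosepokes[keep_np]),
      kind = c(rep("active_press", length(press)),
               rep("reward", length(rewards)),
               rep("nosepoke", sum(keep_np)))
    )
    dur <- p$session_duration
  } else {
    n_req <- 1L
    while (sum(generate_pr_schedule(n_req)) < length(press) &&
           n_req < 80L)
      n_req <- n_req + 1L
    req <- generate_pr_schedule(n_req)
    cum_req <- cumsum(as.numeric(req))
    reward_idx <- cum_req[cum_req <= length(press)]
    rewards <- press[reward_idx]
    # stop rule: session ends 'pr_timeout' after the reward not followed
    # by another within the window
    if (length(rewards) > 1L) {
      late <- which(diff(rewards) > p$pr_timeout)
      if (length(late)) rewards <- rewards[seq_len(late[1L])]
    }
    dur <- if (length(rewards)) rewards[length(rewards)] + p$pr_timeout
           else p$pr_timeout
    np_times <- nosepokes[match(rewards, press)] # nosepoke after each reward
    keep <- press <= dur
    press <- press[keep]; bout_id <- bout_id[keep]
    np_times <- np_times[!is.na(np_times) & np_times <= dur]
    ev <- data.frame(
      t = c(press, rewards, np_times),
      kind = c(rep("active_press", length(press)),
               rep("reward", length(rewards)),
               rep("nosepoke", length(np_times)))
    )
  }
  n_inact <- stats::rpois(1, p$inactive_rate * dur)
  if (n_inact > 0)
    ev <- rbind(ev, data.frame(t = sort(stats::runif(n_inact, 0, dur)),
                               kind = "inactive_press"))
  session <- operant_session(ev, schedule = p$schedule, subject = subject,
                             session_duration = dur)
  iv <- diff(press)
  same <- diff(bout_id) == 0L
  list(session = session,
       truth = list(press_times = press, bout_id = bout_id,
                    within_intervals = iv[same],
                    between_intervals = iv[!same]))
}

#' Parameters for the arena tracking-trace generator
#'
#' The subject alternates between three macro-states -- dwelling in the
#' female zone, dwelling in the male zone, and roaming the rest of the
#' arena -- chosen with the given probabilities at each epoch, with
#' exponential dwell times. Within a state the position performs a small
#' reflected random walk confined to the state's region, sampled at the
#' tracker rate.
#'
#' @param duration test length (s), default 600 (10-min SIM test).
#' @param rate sampling rate (Hz), default 10.
#' @param p_female,p_male epoch probabilities of dwelling at the female /
#'   male zone; the remainder is roaming. Must sum to at most 1.
#' @param dwell_mean mean epoch dwell time (s).
#' @param step_sd random-walk step standard deviation (cm per sample).
#' @param zones a [zone_spec()]; default [default_zones()].
#' @return A list of class `arena_sim_params`.
#' @export
arena_sim_params <- function(duration = 600, rate = 10,
                             p_female = 0.45, p_male = 0.2,
                             dwell_mean = 15, step_sd = 0.5,
                             zones = default_zones()) {
  stopifnot(p_female >= 0, p_male >= 0, p_female + p_male <= 1,
            duration > 0, rate > 0, dwell_mean > 0)
  p <- as.list(environment())
  class(p) <- "arena_sim_params"
  p
}

# uniform point strictly inside a rectangle (margin keeps half-open
# membership unambiguous)
runif_rect <- function(z, margin = 0.5) {
  c(stats::runif(1, z[1L] + margin, z[3L] - margin),
    stats::runif(1, z[2L] + margin, z[4L] - margin))
}

#' Simulate an arena tracking trace with a ground-truth occupancy ledger
#'
#' @param params an [arena_sim_params()].
#' @param seed integer seed.
#' @return A list with `trace` (a [tracking_trace()]) and `truth`: the
#'   per-sample `state` (`"female_zone"`, `"male_zone"` or `"arena"`) and
#'   the generator's occupancy ledger `time` and `entries` per zone,
#'   accumulated exactly as the left-constant analysis convention does.
#' @export
simulate_trace <- function(params = arena_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "arena_sim_params"))
  set.seed(seed)
  p <- params
  dt <- 1 / p$rate
  n <- floor(p$duration * p$rate) + 1L
  zf <- p$zones$zones$female_zone
  zm <- p$zones$zones$male_zone
  arena <- p$zones$arena
  states <- c("female_zone", "male_zone", "arena")
  probs <- c(p$p_female, p$p_male, 1 - p$p_female - p$p_male)

  region_of <- function(state) switch(state,
    female_zone = zf, male_zone = zm,
    arena = c(0, 0, arena[1L], arena[2L]))
  outside_zones <- function(pt) {
    !(in_zone(pt[1L], pt[2L], zf) || in_zone(pt[1L], pt[2L], zm))
  }
  draw_point <- function(state) {
    if (state != "arena") return(runif_rect(region_of(state)))
    repeat {
      pt <- runif_rect(c(0, 0, arena[1L], arena[2L]))
      if (outside_zones(pt)) return(pt)
    }
  }

  x <- numeric(n); y <- numeric(n); state <- character(n)
  i <- 1L
  while (i <= n) {
    s <- sample(states, 1L, prob = probs)
    len <- max(1L, round(stats::rexp(1, 1 / p$dwell_mean) * p$rate))
    len <- min(len, n - i + 1L)
    pt <- draw_point(s)
    reg <- region_of(s)
    for (k in seq_len(len)) {
      state[i] <- s
      x[i] <- pt[1L]; y[i] <- pt[2L]
      i <- i + 1L
      if (i > n) break
      repeat {
        cand <- pt + stats::rnorm(2, 0, p$step_sd)
        cand[1L] <- min(max(cand[1L], reg[1L] + 0.5), reg[3L] - 0.5)
        cand[2L] <- min(max(cand[2L], reg[2L] + 0.5), reg[4L] - 0.5)
        if (s != "arena" || outside_zones(cand)) break
      }
      pt <- cand
    }
  }
  t <- seq(0, by = dt, length.out = n)
  trace <- tracking_trace(t, x, y, arena = arena)

  ledger <- do.call(rbind, lapply(c("female_zone", "male_zone"),
    function(zn) {
      member <- state == zn
      data.frame(zone = zn,
                 time = sum(member[-n]) * dt,
                 entries = sum(diff(c(FALSE, member)) == 1L))
    }))
  list(trace = trace, truth = list(state = state, ledger = ledger))
}

#' Parameters for the synthetic brain-section image generator
#'
#' @param width,height image size in pixels.
#' @param n_disks number of bright disks (planted "cells").
#' @param radius_range inclusive integer range of disk radii (px).
#' @param fg,bg foreground and background mean intensities (0-255).
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param min_gap minimum pixel gap between disk boundaries (keeps the
#'   planted particles non-touching).
#' @return A list of class `image_sim_params`.
#' @export
image_sim_params <- function(width = 256, height = 256, n_disks = 25,
                             radius_range = c(5, 15), fg = 200, bg = 30,
                             noise_sd = 5, min_gap = 3) {
  stopifnot(width > 0, height > 0, n_disks >= 0,
            radius_range[1L] >= 1, fg > bg, noise_sd >= 0)
  p <- as.list(environment())
  class(p) <- "image_sim_params"
  p
}

#' Simulate a brain-section image with planted particles
#'
#' Renders non-touching bright disks on a noisy dark background and
#' returns the planted-particle table (center, radius, rendered pixel
#' area) as ground truth for the particle-counting stage.
#'
#' @param params an [image_sim_params()].
#' @param seed integer seed.
#' @return A list with `image` (numeric matrix, 0-255) and `truth`
#'   (data.frame `x`, `y`, `radius`, `area`).
#' @export
simulate_section_image <- function(params = image_sim_params(),
                                   seed = 1L) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(seed)
  p <- params
  img <- matrix(p$bg, p$height, p$width)
  centers <- matrix(numeric(0), 0L, 3L)  # x, y, r
  tries <- 0L
  while (nrow(centers) < p$n_disks) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("could not place ", p$n_disks, " non-touching disks; ",
           "reduce n_disks or radii")
    r <- sample(seq(p$radius_range[1L], p$radius_range[2L]), 1L)
    cx <- stats::runif(1, r + 2, p$width - r - 2)
    cy <- stats::runif(1, r + 2, p$height - r - 2)
    if (nrow(centers)) {
      dd <- sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)
      if (any(dd < centers[, 3L] + r + p$min_gap)) next
    }
    centers <- rbind(centers, c(cx, cy, r))
  }
  area <- integer(nrow(centers))
  if (nrow(centers)) {
    cols <- matrix(rep(seq_len(p$width), each = p$height), p$height)
    rows <- matrix(rep(seq_len(p$height), p$width), p$height)
    for (i in seq_len(nrow(centers))) {
      mask <- (cols - centers[i, 1L])^2 + (rows - centers[i, 2L])^2 <=
        centers[i, 3L]^2
      img[mask] <- p$fg
      area[i] <- sum(mask)
    }
  }
  if (p$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, p$noise_sd),
                        nrow(img))
  img <- round(pmin(pmax(img, 0), 255))
  truth <- data.frame(x = centers[, 1L], y = centers[, 2L],
                      radius = centers[, 3L], area = area)
  list(image = img, truth = truth)
}
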