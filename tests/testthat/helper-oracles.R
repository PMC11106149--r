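# Independent oracles used across the suite. These deliberately use the
# most naive algorithm available (explicit loops, pairwise scans) so they
# stay independent of the package's vectorized implementations.

# brute-force mount-bout segmenter: for every consecutive pair of
# copulatory events, walk over ALL events and declare a boundary iff a
# bout-breaking event intersects the open gap between them
oracle_segment <- function(log, series_row) {
  voc <- log$vocabulary
  ev <- log$events
  cop <- ev[ev$behavior %in% voc$copulatory, , drop = FALSE]
  lo <- series_row$start
  hi <- if (!is.na(series_row$ejaculation_time))
    series_row$ejaculation_time else Inf
  cop <- cop[cop$start >= lo & cop$start <= hi, , drop = FALSE]
  if (!nrow(cop)) return(list(bout_of = integer(), timeouts = numeric()))
  bout_of <- 1L
  for (k in seq_len(nrow(cop) - 1L)) {
    g1 <- cop$end[k]; g2 <- cop$start[k + 1L]
    split_here <- FALSE
    for (i in seq_len(nrow(ev))) {
      if (ev$behavior[i] %in% voc$bout_breaking &&
          ev$end[i] > g1 && ev$start[i] < g2) split_here <- TRUE
    }
    bout_of <- c(bout_of, bout_of[k] + as.integer(split_here))
  }
  timeouts <- numeric()
  for (b in seq_len(max(bout_of) - 1L)) {
    end_b <- max(cop$end[bout_of == b])
    start_next <- min(cop$start[bout_of == b + 1L])
    timeouts <- c(timeouts, start_next - end_b)
  }
  list(bout_of = bout_of, timeouts = timeouts)
}

# randomized small ethogram (<= 12 events) with non-overlapping
# copulatory events; other behaviors may fall anywhere
random_small_log <- function(seed, max_events = 12L) {
  set.seed(seed)
  voc <- default_vocabulary()
  labels <- c(voc$copulatory, voc$bout_breaking, voc$bout_neutral)
  n <- sample(0:max_events, 1L)
  beh <- character(0); st <- numeric(0); en <- numeric(0)
  t_cop <- 0
  for (i in seq_len(n)) {
    b <- sample(labels, 1L)
    if (b %in% voc$copulatory) {
      s <- t_cop + runif(1, 0.1, 30)
      d <- runif(1, 0, 3)
      t_cop <- s + d
    } else {
      s <- runif(1, 0, max(t_cop, 60))
      d <- runif(1, 0, 15)
    }
    e <- min(s + d, 1800)
    beh <- c(beh, b); st <- c(st, s); en <- c(en, e)
  }
  copulation_log(data.frame(behavior = beh, start = st, end = en))
}

# segmentation agreement between implementation and brute-force oracle,
# across every series of the log
segmentation_matches_oracle <- function(log) {
  ser <- partition_series(log)
  for (k in seq_len(nrow(ser))) {
    seg <- segment_mount_bouts(log, ser[k, , drop = FALSE])
    orc <- oracle_segment(log, ser[k, , drop = FALSE])
    if (nrow(seg$bouts) != max(0L, suppressWarnings(max(orc$bout_of, 0L))))
      return(FALSE)
    if (length(seg$timeouts$duration) != length(orc$timeouts))
      return(FALSE)
    if (length(orc$timeouts) &&
        max(abs(seg$timeouts$duration - orc$timeouts)) > 1e-9)
      return(FALSE)
  }
  TRUE
}

# closed-form one-sample t statistic
oracle_t <- function(x, mu) (mean(x) - mu) / (sd(x) / sqrt(length(x)))

# Mann-Whitney U by explicit pair counting
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# max-perpendicular-distance knee index on the descending scree,
# computed with an explicit point-to-line distance formula on
# unit-normalized coordinates
oracle_knee_index <- function(sorted_desc) {
  n <- length(sorted_desc)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (sorted_desc - min(sorted_desc)) / diff(range(sorted_desc))
  p1 <- c(x[1], y[1]); p2 <- c(x[n], y[n])
  d <- vapply(seq_len(n), function(i) {
    v <- c(x[i], y[i])
    abs((p2[1] - p1[1]) * (p1[2] - v[2]) - (p1[1] - v[1]) * (p2[2] - p1[2])) /
      sqrt(sum((p2 - p1)^2))
  }, numeric(1))
  which.max(d)
}

# render one disk in a blank image
render_disk <- function(nrow, ncol, cx, cy, r, fg = 200, bg = 0) {
  cols <- matrix(rep(seq_len(ncol), each = nrow), nrow)
  rows <- matrix(rep(seq_len(nrow), ncol), nrow)
  img <- matrix(bg, nrow, ncol)
  img[(cols - cx)^2 + (rows - cy)^2 <= r^2] <- fg
  img
}
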