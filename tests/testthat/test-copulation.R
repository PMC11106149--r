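make_log <- function(beh, start, end = start) {
  copulation_log(data.frame(behavior = beh, start = start, end = end))
}

test_that("series partition follows the ejaculation-series definitions", {
  # M(5), I(9), E(20), M(60): series 1 = [5, 20], PEI = 40
  log <- make_log(c("mount", "intromission", "ejaculation", "mount"),
                  c(5, 9, 20, 60))
  ser <- partition_series(log)
  expect_equal(nrow(ser), 2)
  expect_equal(ser$start[1], 5)
  expect_equal(ser$ejaculation_time[1], 20)
  expect_equal(ser$pei[1], 40)
  expect_false(ser$complete[2])

  # no ejaculation: one incomplete series
  log2 <- make_log(c("mount", "intromission"), c(5, 9))
  ser2 <- partition_series(log2)
  expect_equal(nrow(ser2), 1)
  expect_true(is.na(ser2$ejaculation_time))

  # no copulatory events at all: zero series
  log3 <- make_log("chasing", 5, 10)
  expect_equal(nrow(partition_series(log3)), 0)

  # two complete series are contiguous and non-overlapping
  log4 <- make_log(rep(c("mount", "intromission", "ejaculation"), 2),
                   c(5, 9, 20, 60, 70, 80))
  ser4 <- partition_series(log4)
  expect_equal(ser4$complete, c(TRUE, TRUE))
  expect_true(ser4$start[2] > ser4$ejaculation_time[1])
})

test_that("bout-breaking events split bouts; neutral events never do", {
  # worked example: two bouts [10-23] and [30-42], one 7-s time-out
  log <- copulation_log(data.frame(
    behavior = c("mount", "head_towards_female", "intromission",
                 "other_grooming", "mount", "chasing", "ejaculation"),
    start = c(10, 12, 20, 23, 30, 32, 40),
    end = c(12, 20, 23, 30, 32, 40, 42)))
  seg <- segment_mount_bouts(log, 1)
  expect_equal(seg$bouts$start, c(10, 30))
  expect_equal(seg$bouts$end, c(23, 42))
  expect_equal(seg$timeouts$duration, 7)
  expect_true(seg$bouts$has_ejaculation[2])

  # genital grooming is exempt: one bout, no time-outs
  log2 <- copulation_log(data.frame(
    behavior = c("mount", "genital_grooming", "mount"),
    start = c(10, 12, 18), end = c(12, 18, 20)))
  seg2 <- segment_mount_bouts(log2, 1)
  expect_equal(nrow(seg2$bouts), 1)
  expect_equal(seg2$bouts$start, 10)
  expect_equal(seg2$bouts$end, 20)
  expect_equal(nrow(seg2$timeouts), 0)

  # no copulatory events: empty segmentation
  log3 <- make_log("other_grooming", 5, 10)
  ser3 <- data.frame(series = 1, start = 0, ejaculation_time = NA_real_,
                     pei = NA_real_, complete = FALSE)
  seg3 <- segment_mount_bouts(log3, ser3)
  expect_equal(nrow(seg3$bouts), 0)
  expect_equal(nrow(seg3$timeouts), 0)
})

test_that("a breaking event wholly overlapping a copulatory event does not split", {
  # breaking event [9, 12] covers the mount [10, 12] but not the open gap
  log <- copulation_log(data.frame(
    behavior = c("mount", "other_grooming", "mount"),
    start = c(10, 8, 14), end = c(12, 12, 16)))
  seg <- segment_mount_bouts(log, 1)
  expect_equal(nrow(seg$bouts), 1)
  # but nudge its end into the open gap and it splits
  log2 <- copulation_log(data.frame(
    behavior = c("mount", "other_grooming", "mount"),
    start = c(10, 8, 14), end = c(12, 12.5, 16)))
  expect_equal(nrow(segment_mount_bouts(log2, 1)$bouts), 2)
})

test_that("segmentation satisfies the partition identity", {
  # bout spans + time-out durations tile the copulatory extent
  for (seed in 1:40) {
    log <- random_small_log(seed)
    ser <- partition_series(log)
    for (k in seq_len(nrow(ser))) {
      seg <- segment_mount_bouts(log, ser[k, , drop = FALSE])
      if (!nrow(seg$bouts)) next
      span <- sum(seg$bouts$end - seg$bouts$start) +
        sum(seg$timeouts$duration)
      expect_equal(span,
                   max(seg$bouts$end) - min(seg$bouts$start),
                   tolerance = 1e-12)
    }
  }
})

test_that("segmentation agrees with the brute-force gap-scan oracle", {
  for (seed in 1:300)
    expect_true(segmentation_matches_oracle(random_small_log(seed)),
                label = paste("seed", seed))
})

test_that("copulation measures reproduce the stated formulas", {
  # 10 mounts + 5 intromissions before the ejaculation
  n <- 15
  beh <- c(rep("mount", 10), rep("intromission", 5), "ejaculation")
  st <- seq(10, by = 10, length.out = 16)
  m <- compute_measures(make_log(beh, st, st + 2))
  expect_equal(m$intromission_ratio, 5 / 15)
  expect_equal(m$n_mounts, 10)
  expect_equal(m$n_intromissions, 5)
  expect_equal(m$n_ejaculations, 1)
  expect_equal(m$latency_to_ejaculation, 160 - 10)

  # worked bout example: 2 bouts, mean time-out 7 s
  log <- copulation_log(data.frame(
    behavior = c("mount", "head_towards_female", "intromission",
                 "other_grooming", "mount", "chasing", "ejaculation"),
    start = c(10, 12, 20, 23, 30, 32, 40),
    end = c(12, 20, 23, 30, 32, 40, 42)))
  m2 <- compute_measures(log)
  expect_equal(m2$n_mount_bouts, 2)
  expect_equal(m2$mean_timeout_duration, 7)
  expect_equal(m2$mean_intromissions_per_bout, 0.5)
})

test_that("latencies are censored at the test duration", {
  # copulatory behavior but no ejaculation
  m <- compute_measures(make_log(c("mount", "intromission"), c(100, 200)))
  expect_equal(m$latency_to_ejaculation, 1800)
  expect_equal(m$latency_to_first_copulatory_behavior, 100)

  # no copulatory behavior at all
  m2 <- compute_measures(make_log("chasing", 5, 50))
  expect_equal(m2$latency_to_first_copulatory_behavior, 1800)
  expect_equal(m2$latency_to_ejaculation, 1800)
  expect_true(is.na(m2$intromission_ratio))
})

test_that("adding an ejaculation can only decrease the censored latency", {
  for (seed in 1:20) {
    log <- random_small_log(seed)
    base <- compute_measures(log)$latency_to_ejaculation
    cop <- log$events[log$events$behavior %in%
                        log$vocabulary$copulatory, , drop = FALSE]
    if (!nrow(cop)) next
    t_new <- max(log$events$end) + 1
    aug <- copulation_log(rbind(log$events,
                                data.frame(behavior = "ejaculation",
                                           start = t_new, end = t_new)))
    expect_lte(compute_measures(aug)$latency_to_ejaculation, base)
  }
})

test_that("percent-time budget uses the span up to the first ejaculation", {
  log <- copulation_log(data.frame(
    behavior = c("mount", "other_grooming", "head_not_towards_female",
                 "intromission", "ejaculation"),
    start = c(10, 20, 60, 90, 100),
    end = c(12, 40, 80, 92, 102)))
  m <- compute_measures(log)
  # (20 + 20) s of bout-breaking behavior in the first 100 s
  expect_equal(m$percent_non_copulation_oriented, 40)
  expect_equal(unname(m$percent_time["mount"]), 2)
  # events past the ejaculation are clipped out of the budget
  log2 <- copulation_log(data.frame(
    behavior = c("mount", "ejaculation", "other_grooming"),
    start = c(10, 100, 150), end = c(12, 102, 200)))
  expect_equal(compute_measures(log2)$percent_non_copulation_oriented, 0)
})
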