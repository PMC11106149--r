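test_that("PR schedule reproduces the exponential progression", {
  expect_identical(generate_pr_schedule(9L),
                   c(1L, 2L, 4L, 6L, 9L, 12L, 15L, 20L, 25L))
  expect_identical(generate_pr_schedule(1L), 1L)
  # 10th element from the progression formula, evaluated independently
  expect_identical(generate_pr_schedule(10L)[10],
                   as.integer(round(5 * exp(0.2 * 10)) - 5))
  # strictly increasing beyond the start
  r <- generate_pr_schedule(30L)
  expect_true(all(diff(r) > 0))
  expect_error(generate_pr_schedule(0), ">= 1")
})

make_session <- function(rewards = numeric(), active = rewards,
                         inactive = numeric(), schedule = "FR1",
                         duration = if (schedule == "FR1") 1800 else NA) {
  ev <- data.frame(
    t = c(active, rewards, inactive),
    kind = c(rep("active_press", length(active)),
             rep("reward", length(rewards)),
             rep("inactive_press", length(inactive))))
  operant_session(ev, schedule = schedule, session_duration = duration)
}

test_that("FR1 mean reward interval follows the printed formula", {
  s <- make_session(rewards = c(10, 100))
  f <- fr1_metrics(s)
  expect_equal(f$mean_reward_interval, 90)
  expect_equal(f$n_rewards, 2)

  # fewer than two rewards: interval absent, curve identically zero
  s0 <- make_session()
  f0 <- fr1_metrics(s0)
  expect_true(is.na(f0$mean_reward_interval))
  expect_true(all(f0$cumulative_curve$rewards == 0))

  # general case equals the formula applied to first/last reward times
  set.seed(2)
  rw <- sort(runif(37, 0, 1800))
  f2 <- fr1_metrics(make_session(rewards = rw))
  expect_equal(f2$mean_reward_interval, (max(rw) - min(rw)) / 36)
})

test_that("cumulative curve is a non-decreasing 1-s binned count", {
  rw <- c(3.2, 3.9, 700, 1799.5)
  f <- fr1_metrics(make_session(rewards = rw))
  cc <- f$cumulative_curve
  expect_true(all(diff(cc$rewards) >= 0))
  expect_equal(cc$rewards[nrow(cc)], 4)
  expect_equal(cc$rewards[cc$t == 3], 0)
  expect_equal(cc$rewards[cc$t == 4], 2)
})

test_that("reward decile times mark each successive 10% of rewards", {
  rw <- seq(90, 900, by = 90)
  f <- fr1_metrics(make_session(rewards = rw))
  expect_equal(f$reward_decile_times, seq(90, 900, by = 90))
  # uneven count: deciles index the ceiling reward
  f2 <- fr1_metrics(make_session(rewards = c(10, 20, 30)))
  expect_equal(f2$reward_decile_times,
               c(10, 10, 10, 20, 20, 20, 30, 30, 30, 30))
})

test_that("fixed mode returns the 10-s threshold; knee mode finds the cliff", {
  expect_equal(find_interval_threshold(c(1, 2, 3)), 10)
  set.seed(1)
  iv <- c(rlnorm(50, 0, 0.2), rlnorm(50, log(60), 0.2))
  th <- find_interval_threshold(iv, method = "knee")
  expect_gt(th, exp(0))       # above the short mode
  expect_lt(th, 60)           # below the long mode
  # knee localization agrees with an independent max-chord-distance oracle
  k <- oracle_knee_index(sort(iv, decreasing = TRUE))
  sorted <- sort(iv, decreasing = TRUE)
  expect_gte(th, sorted[min(length(iv), k + 6)])
  expect_lte(th, sorted[max(1, k - 6)])

  expect_warning(th0 <- find_interval_threshold(rep(5, 10), method = "knee"),
                 "no knee")
  expect_equal(th0, 10)
  expect_error(find_interval_threshold(c(1, 2), method = "knee"),
               "at least 3")
})

test_that("press bouts split at gaps at or above the threshold", {
  bs <- detect_press_bouts(c(0, 1, 2, 100, 101), 10)
  expect_equal(bs$n_bouts, 2)
  expect_equal(lengths(bs$bouts), c(3, 2))
  expect_equal(bs$mean_presses_per_bout, 2.5)

  expect_equal(detect_press_bouts(5, 10)$n_bouts, 1)
  expect_equal(detect_press_bouts(c(0, 1, 2), 10)$n_bouts, 1)
  # tie at exactly the threshold starts a new bout
  expect_equal(detect_press_bouts(c(0, 10), 10)$n_bouts, 2)
  expect_equal(detect_press_bouts(numeric(), 10)$n_bouts, 0)
})

test_that("bouts partition the presses; extreme thresholds collapse or atomize", {
  set.seed(3)
  pt <- sort(runif(60, 0, 1800))
  for (th in c(0.5, 5, 50)) {
    bs <- detect_press_bouts(pt, th)
    expect_equal(sum(lengths(bs$bouts)), length(pt))
    expect_identical(unlist(bs$bouts), pt)
  }
  expect_equal(detect_press_bouts(pt, Inf)$n_bouts, 1)
  expect_equal(detect_press_bouts(pt, 1e-12)$n_bouts, length(pt))
})

test_that("PR metrics follow the printed interval formula and stop rule", {
  # 600-s session with 60 active presses: mean press interval 10 s
  active <- seq(10, 600, by = 10)
  ev <- rbind(data.frame(t = active, kind = "active_press"),
              data.frame(t = active[cumsum(generate_pr_schedule(5))],
                         kind = "reward"))
  s <- operant_session(ev, schedule = "PR", session_duration = 600)
  pm <- pr_metrics(s)
  expect_equal(pm$mean_press_interval, 10)
  expect_equal(pm$test_duration, 600)

  # rewards through requirement 9 and none after: breakpoint 9
  rw <- seq(100, by = 100, length.out = 5)
  ev2 <- data.frame(t = rw, kind = "reward")
  s2 <- operant_session(ev2, schedule = "PR", session_duration = 3000)
  expect_equal(pr_metrics(s2)$breakpoint, 9)

  # stop rule: session ends 1800 s after the last reward
  expect_equal(pr_metrics(s2)$test_duration, 500 + 1800)

  # zero active presses: interval absent
  expect_true(is.na(pr_metrics(s2)$mean_press_interval))
})

test_that("PR stop rule matches an event-replay oracle on synthetic sessions", {
  for (seed in c(2, 7, 13)) {
    sim <- simulate_operant(operant_sim_params(schedule = "PR"), seed = seed)
    pm <- pr_metrics(sim$session)
    rw <- sim$session$events$t[sim$session$events$kind == "reward"]
    # replay: walk rewards until one is more than 30 min after the previous
    end <- NA_real_
    for (i in seq_along(rw)) {
      if (i > 1 && rw[i] - rw[i - 1] > 1800) { end <- rw[i - 1] + 1800; break }
    }
    if (is.na(end)) end <- rw[length(rw)] + 1800
    expect_equal(pm$test_duration, min(end, sim$session$session_duration))
    expect_equal(pm$breakpoint,
                 generate_pr_schedule(pm$n_rewards)[pm$n_rewards])
  }
})

test_that("repeated FR1 tests average per subject and treatment", {
  d <- data.frame(subject = c("a", "a", "a", "a", "b", "b"),
                  treatment = c("VEH", "VEH", "CNO", "CNO", "VEH", "CNO"),
                  value = c(20, 30, 10, 14, 8, 9))
  avg <- average_repeated_tests(d)
  expect_equal(avg$value[avg$subject == "a" & avg$treatment == "VEH"], 25)
  expect_equal(avg$value[avg$subject == "a" & avg$treatment == "CNO"], 12)
  # single test flagged, not imputed
  b_row <- avg[avg$subject == "b" & avg$treatment == "VEH", ]
  expect_true(b_row$incomplete)
  expect_equal(b_row$value, 8)
  # three tests violate the design
  d3 <- rbind(d, data.frame(subject = "a", treatment = "VEH", value = 1))
  expect_error(average_repeated_tests(d3), "exceed")
})

test_that("operant CSV round-trips", {
  sim <- simulate_operant(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t_s = sim$session$events$t,
                              kind = sim$session$events$kind),
                   path, row.names = FALSE)
  s <- read_operant(path, schedule = "FR1")
  expect_equal(s$events$t, sim$session$events$t)
  expect_equal(fr1_metrics(s)$n_rewards, fr1_metrics(sim$session)$n_rewards)
})
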