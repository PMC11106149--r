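test_that("generators are deterministic given the seed", {
  a <- simulate_copulation(seed = 7); b <- simulate_copulation(seed = 7)
  expect_identical(a$log$events, b$log$events)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$log$events, simulate_copulation(seed = 8)$log$events))

  o1 <- simulate_operant(seed = 7); o2 <- simulate_operant(seed = 7)
  expect_identical(o1$session$events, o2$session$events)

  t1 <- simulate_trace(seed = 7); t2 <- simulate_trace(seed = 7)
  expect_identical(t1$trace, t2$trace)

  i1 <- simulate_section_image(seed = 7); i2 <- simulate_section_image(seed = 7)
  expect_identical(i1$image, i2$image)
})

test_that("simulated copulation logs validate and carry exact ground truth", {
  for (seed in 1:60) {
    sim <- simulate_copulation(seed = seed)
    expect_length(validate_log(sim$log), 0)
    ser <- partition_series(sim$log)
    expect_equal(nrow(ser), nrow(sim$truth$series))
    expect_equal(ser$ejaculation_time, sim$truth$series$ejaculation_time)
    expect_equal(ser$pei, sim$truth$series$pei)
    n_bouts <- 0L; timeouts <- numeric()
    for (k in seq_len(nrow(ser))) {
      seg <- segment_mount_bouts(sim$log, ser[k, , drop = FALSE])
      n_bouts <- n_bouts + nrow(seg$bouts)
      timeouts <- c(timeouts, seg$timeouts$duration)
    }
    expect_equal(n_bouts, nrow(sim$truth$bouts))
    expect_equal(sort(timeouts), sort(sim$truth$timeouts$duration),
                 tolerance = 1e-9)
  }
})

test_that("an infinite intromission threshold forces the censored latency", {
  sim <- simulate_copulation(
    copulation_sim_params(intromission_threshold = Inf), seed = 3)
  expect_equal(sum(sim$log$events$behavior == "ejaculation"), 0)
  expect_equal(compute_measures(sim$log)$latency_to_ejaculation, 1800)
})

test_that("time-out and PEI multipliers scale the generated pauses", {
  base <- simulate_copulation(seed = 5)
  slow <- simulate_copulation(
    copulation_sim_params(timeout_mult = 3), seed = 5)
  expect_gt(mean(slow$truth$timeouts$duration),
            mean(base$truth$timeouts$duration))
})

test_that("simulated operant sessions honor the FR1 trial structure", {
  for (seed in 1:10) {
    sim <- simulate_operant(seed = seed)
    ev <- sim$session$events
    expect_equal(sum(ev$kind == "reward"), sum(ev$kind == "active_press"))
    f <- fr1_metrics(sim$session)
    expect_equal(f$n_rewards, length(sim$truth$press_times))
    # ground-truth interval populations are ordered
    if (length(sim$truth$between_intervals))
      expect_gt(min(sim$truth$between_intervals),
                max(sim$truth$within_intervals))
  }
})

test_that("a session too short for a second bout yields a single bout", {
  sim <- simulate_operant(
    operant_sim_params(between_meanlog = log(20),
                       presses_per_bout_lambda = 60,
                       session_duration = 60), seed = 4)
  expect_gt(length(sim$truth$bout_id), 0)
  expect_equal(max(sim$truth$bout_id), 1)
})

test_that("trace generator emits an exact occupancy ledger", {
  for (seed in 1:8) {
    st <- simulate_trace(arena_sim_params(duration = 120), seed = seed)
    occ <- zone_occupancy(st$trace, default_zones())
    led <- st$truth$ledger
    dt <- diff(st$trace$t[1:2])
    for (zn in c("female_zone", "male_zone")) {
      expect_lte(abs(occ$time[occ$zone == zn] - led$time[led$zone == zn]),
                 dt + 1e-9)
      expect_equal(occ$entries[occ$zone == zn],
                   led$entries[led$zone == zn])
    }
  }
})

test_that("extreme dwell settings pin the preference score", {
  st <- simulate_trace(arena_sim_params(p_female = 1, p_male = 0), seed = 2)
  occ <- zone_occupancy(st$trace, default_zones())
  expect_equal(preference_score(occ$time[occ$zone == "female_zone"],
                                occ$time[occ$zone == "male_zone"]), 1)
  # symmetric dwell approaches chance over a long run
  st2 <- simulate_trace(
    arena_sim_params(p_female = 0.35, p_male = 0.35, duration = 3600,
                     dwell_mean = 5), seed = 3)
  occ2 <- zone_occupancy(st2$trace, default_zones())
  p <- preference_score(occ2$time[occ2$zone == "female_zone"],
                        occ2$time[occ2$zone == "male_zone"])
  expect_lt(abs(p - 0.5), 0.05)
})

test_that("planted image truth matches the rendered rasters", {
  sim0 <- simulate_section_image(image_sim_params(n_disks = 0), seed = 1)
  expect_equal(count_particles(binarize(sim0$image, 120))$count, 0)

  sim <- simulate_section_image(seed = 6)
  expect_equal(nrow(sim$truth), 25)
  expect_true(all(sim$truth$radius >= 5 & sim$truth$radius <= 15))
  expect_equal(count_particles(binarize(sim$image, 120))$count, 25)

  # a radius-1 disk renders below the 5-px minimum and is excluded
  tiny <- simulate_section_image(
    image_sim_params(n_disks = 1, radius_range = c(1, 1), noise_sd = 0),
    seed = 2)
  expect_lt(tiny$truth$area, 5)
  expect_equal(count_particles(binarize(tiny$image, 120))$count, 0)
  expect_equal(count_particles(binarize(tiny$image, 120),
                               size = c(1, 2000), circ = c(0, 1))$count, 1)
})
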