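test_that("classify_states applies the 5-minute rule exactly", {
  expect_equal(classify_states(c(1, 0, 0, 0, 0, 1)),
               c("wake", rep("pause", 4), "wake"))
  expect_equal(classify_states(c(1, 0, 0, 0, 0, 0, 1)),
               c("wake", rep("sleep", 5), "wake"))
  allz <- classify_states(rep(0, 1440))
  expect_true(all(allz == "sleep"))
  expect_error(classify_states(c(1, -1)), "negative")
  expect_error(classify_states(numeric(0)), "empty")
})

test_that("score_traits matches constructed single-bout examples", {
  # immobile from minute 30 to 59 after lights-off (30 awake minutes first)
  counts <- rep(1, 1440)
  counts[721 + 30:59] <- 0
  tr <- activity_trace(counts)
  s <- score_traits(tr)
  expect_equal(s$night_sleep, 30)
  expect_equal(s$night_bout_number, 1)
  expect_equal(s$night_avg_bout_length, 30)
  expect_equal(s$sleep_latency, 30)
  expect_equal(s$day_sleep, 0)

  # fully active fly, 1 count per minute
  s2 <- score_traits(activity_trace(rep(1, 1440)))
  expect_equal(s2$night_sleep + s2$day_sleep, 0)
  expect_equal(s2$night_bout_number + s2$day_bout_number, 0)
  expect_equal(s2$sleep_latency, 720)
  expect_equal(s2$waking_activity, 1.0)

  # all-zero trace: one bout spanning both phases, attributed to day onset
  s3 <- score_traits(activity_trace(rep(0, 1440)))
  expect_equal(s3$night_sleep, 720)
  expect_equal(s3$day_sleep, 720)
  expect_equal(s3$day_bout_number, 1)
  expect_equal(s3$night_bout_number, 0)
  expect_equal(s3$sleep_latency, 0)
  expect_true(is.na(s3$waking_activity))
})

test_that("scoring invariants hold on generated traces", {
  for (seed in 1:8) {
    tr <- simulate_activity(mean_night_sleep = 300, mean_day_sleep = 150,
                            n_night_bouts = 3, n_day_bouts = 2,
                            n_pauses = 3, seed = seed)
    st <- classify_states(tr)
    s <- score_traits(tr)
    expect_equal(s$night_sleep + s$day_sleep, sum(st == "sleep"))
    # bout accounting: avg length x number = onset-attributed minutes
    ph <- ifelse(((seq_along(tr$counts) - 1) %% 1440) < 720, "day", "night")
    r <- rle(st == "sleep")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    onsets <- starts[r$values]; lens <- r$lengths[r$values]
    night_attr <- sum(lens[ph[onsets] == "night"])
    expect_equal(s$night_avg_bout_length * s$night_bout_number, night_attr)
    # appending waking minutes does not change sleep traits
    tr2 <- activity_trace(c(tr$counts, rep(2, 60)), lights_on_minute = 1)
    s2 <- score_days(tr2)[1, ]
    expect_equal(s2$night_sleep, s$night_sleep)
    expect_equal(s2$night_bout_number, s$night_bout_number)
  }
})

test_that("simulate_activity hits its targets on average and at the edges", {
  # one full 720-minute night block
  tr <- simulate_activity(mean_night_sleep = 720, mean_day_sleep = 0,
                          sd_sleep = 0, n_night_bouts = 1, n_pauses = 0,
                          seed = 1)
  s <- score_traits(tr)
  expect_equal(s$night_sleep, 720)
  expect_equal(s$night_bout_number, 1)
  # zero sleep with sub-threshold pauses only
  tr0 <- simulate_activity(mean_night_sleep = 0, mean_day_sleep = 0,
                           n_pauses = 3, seed = 2)
  s0 <- score_traits(tr0)
  expect_equal(s0$night_sleep + s0$day_sleep, 0)
  expect_gt(sum(classify_states(tr0) == "pause"), 0)
  # population mean recovery: 200 flies, target night sleep 400
  scored <- vapply(1:200, function(k)
    score_traits(simulate_activity(mean_night_sleep = 400, sd_sleep = 30,
                                   seed = 100 + k))$night_sleep, 0)
  se <- sd(scored) / sqrt(length(scored))
  expect_lt(abs(mean(scored) - 400), 3 * se + 1)  # +1 for rounding drift
  # infeasible request errors
  expect_error(simulate_activity(mean_night_sleep = 900), "outside")
})

test_that("population_state_fractions partitions and averages correctly", {
  traces <- lapply(1:20, function(k)
    classify_states(simulate_activity(mean_night_sleep = 50,
                                      mean_day_sleep = 50, seed = k)))
  fr <- population_state_fractions(traces)
  expect_true(all(abs(fr$sleep + fr$wake + fr$pause - 1) < 1e-12))
  # flat short-sleeper population: time-averaged sleep fraction ~ target
  target <- (50 + 50) / 1440
  expect_lt(abs(mean(fr$sleep) - target), 0.03)
  # all flies asleep at a minute -> fraction 1
  allsleep <- lapply(1:3, function(k) rep("sleep", 10))
  expect_equal(population_state_fractions(allsleep)$sleep, rep(1, 10))
  expect_error(population_state_fractions(list()), "empty")
})

test_that("deprivation_deltas reproduces the printed 48% night-sleep drop", {
  days <- data.frame(day = 1:4,
                     night_sleep = c(412.8, 412.8, 215.01, 412.8),
                     day_sleep = c(100, 100, 100, 100))
  d <- deprivation_deltas(days, baseline_days = 1:2, event_day = 3,
                          recovery_day = 4)
  expect_equal(round(-d["event", "night_pct"]), 48)
  expect_equal(d["recovery", "night_delta"], 0)
  # event equals baseline -> all deltas zero
  flat <- data.frame(day = 1:4, night_sleep = 100, day_sleep = 50)
  d0 <- deprivation_deltas(flat, 1:2, 3, 4)
  expect_true(all(abs(as.matrix(d0)) < 1e-12))
  # total loss
  gone <- data.frame(day = 1:4, night_sleep = c(100, 100, 0, 100),
                     day_sleep = 0)
  expect_equal(deprivation_deltas(gone, 1:2, 3, 4)["event", "night_pct"], -100)
  expect_error(deprivation_deltas(flat, 1:2, 9, 4), "missing day")
})

test_that("dead flies are flagged and DAM files round-trip", {
  dead <- activity_trace(c(rep(1, 720), rep(0, 1500)))
  live <- activity_trace(rep(c(1, 0), 1110))
  expect_true(flag_dead(dead))
  expect_false(flag_dead(live))
  tmp <- tempfile(fileext = ".txt")
  traces <- lapply(1:3, function(k)
    simulate_activity(mean_night_sleep = 200, seed = k))
  write_dam(traces, tmp)
  back <- read_dam(tmp)
  expect_length(back, 3)
  expect_equal(back$ch2$counts, traces[[2]]$counts)
})
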