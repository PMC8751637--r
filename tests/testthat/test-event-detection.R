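silent_tracking <- function(dur) {
  data.frame(t_s = seq(0, dur, by = 0.02), pos_cm = 2, speed_cms = 0,
             direction = 0L)
}

test_that("an injected population burst yields exactly one MUA event", {
  set.seed(31)
  cells <- data.frame(cell_id = 1:20, pyramidal = TRUE)
  tracking <- silent_tracking(600)
  burst <- data.frame(cell_id = rep(1:10, each = 3),
                      t_s = 100 + runif(30, 0, 0.1))
  ev <- detect_candidate_events_mua(burst, cells, tracking, c(0, 600))
  expect_equal(nrow(ev), 1)
  expect_lte(ev$start_s, min(burst$t_s))
  expect_gte(ev$end_s, max(burst$t_s))
  expect_equal(ev$n_active, 10)
  expect_gte(ev$peak_s, ev$start_s)
  expect_lte(ev$peak_s, ev$end_s)
})

test_that("bursts 30 ms apart are merged; fast-running events are excluded", {
  set.seed(32)
  cells <- data.frame(cell_id = 1:20, pyramidal = TRUE)
  tracking <- silent_tracking(600)
  b1 <- data.frame(cell_id = rep(1:10, 2), t_s = 200 + runif(20, 0, 0.05))
  b2 <- data.frame(cell_id = rep(1:10, 2), t_s = 200.08 + runif(20, 0, 0.05))
  ev <- detect_candidate_events_mua(rbind(b1, b2), cells, tracking, c(0, 600))
  expect_equal(nrow(ev), 1)
  expect_gte(ev$end_s - ev$start_s, 0.1)
  # same burst during running: excluded by the median-speed filter
  tr_fast <- tracking
  tr_fast$speed_cms <- 15
  ev2 <- detect_candidate_events_mua(rbind(b1, b2), cells, tr_fast, c(0, 600))
  expect_equal(nrow(ev2), 0)
  # participation filter: 4 active cells < max(5, 15% of 20)
  b3 <- data.frame(cell_id = rep(1:4, each = 8), t_s = 300 + runif(32, 0, 0.1))
  ev3 <- detect_candidate_events_mua(b3, cells, tracking, c(0, 600))
  expect_equal(nrow(ev3), 0)
})

test_that("background false alarms are consistent with the Monte-Carlo null", {
  null_count <- function(seed) {
    s <- generate_session(session_config(n_cells = 40, n_runs = 1,
                                         rest_duration = 150,
                                         n_replay_events = 0), seed = seed)
    rest <- unlist(s$epochs[2, c("start_s", "end_s")])
    nrow(detect_candidate_events_mua(s$spikes, s$cells, s$tracking, rest))
  }
  null <- vapply(101:105, null_count, integer(1))
  observed <- null_count(106)
  m <- mean(null)
  expect_lte(observed, m + 5 * sqrt(m + 1))
  expect_gte(observed, max(0, m - 5 * sqrt(m + 1)))
})

test_that("ripple-power detection finds an injected transient and honours filters", {
  set.seed(33)
  fs <- 1000
  dur <- 120
  x <- rnorm(dur * fs, 0, 0.2)
  i <- (60 * fs):(60 * fs + 80)
  x[i] <- x[i] + 1.5 * sin(2 * pi * 200 * seq_along(i) / fs)
  cells <- data.frame(cell_id = 1:20, pyramidal = TRUE)
  spikes <- data.frame(cell_id = rep(1:8, 3), t_s = 60 + runif(24, 0, 0.08))
  tracking <- silent_tracking(dur)
  ev <- detect_candidate_events_ripple(x, fs, 0, spikes, cells, tracking,
                                       c(0, dur))
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, 60.02)
  expect_gt(ev$end_s, 60.05)
  expect_equal(ev$method, "ripple")
  # the same transient while the animal runs is excluded
  tr_run <- tracking
  tr_run$speed_cms <- 15
  expect_equal(nrow(detect_candidate_events_ripple(x, fs, 0, spikes, cells,
                                                   tr_run, c(0, dur))), 0)
  expect_error(detect_candidate_events_ripple(x, 400, 0, spikes, cells,
                                              tracking, c(0, dur)),
               "sample rate")
})

test_that("event classification flags n-spike events and context", {
  s <- small_session()
  rest <- unlist(s$epochs[2, c("start_s", "end_s")])
  ev <- detect_candidate_events_mua(s$spikes, s$cells, s$tracking, rest)
  ev <- classify_events(ev, s$spikes, s$epochs)
  expect_true(all(ev$context == "offline"))
  for (i in seq_len(nrow(ev))) {
    sel <- s$spikes$t_s >= ev$start_s[i] & s$spikes$t_s <= ev$end_s[i]
    tab <- table(s$spikes$cell_id[sel])
    expect_equal(ev$is_nspike[i], any(tab >= 3))
    expect_setequal(ev$n_spike_cells[[i]], as.integer(names(tab)[tab >= 3]))
  }
})

test_that("every emitted event satisfies every stated filter", {
  s <- small_session()
  rest <- unlist(s$epochs[2, c("start_s", "end_s")])
  for (ev in list(
    detect_candidate_events_mua(s$spikes, s$cells, s$tracking, rest),
    detect_candidate_events_ripple(s$lfp[, 1], s$lfp_fs, s$lfp_t0, s$spikes,
                                   s$cells, s$tracking, rest))) {
    dur <- ev$end_s - ev$start_s
    expect_true(all(dur > 0.04 & dur <= 0.5))
    expect_true(all(ev$n_active >= max(5, 0.15 * nrow(s$cells))))
    expect_true(all(ev$median_speed_cms <= 10))
    # non-overlapping after merging, and merging is idempotent
    o <- order(ev$start_s)
    expect_true(all(diff(ev$start_s[o]) > 0))
    expect_true(all(ev$start_s[o][-1] - ev$end_s[o][-nrow(ev)] > 0.04))
  }
})

test_that("interval merging is idempotent", {
  set.seed(34)
  st <- sort(runif(30, 0, 10))
  en <- st + runif(30, 0.01, 0.3)
  m1 <- ripplephase:::merge_intervals(st, en, 0.04)
  m2 <- ripplephase:::merge_intervals(m1$start, m1$end, 0.04)
  expect_equal(m1, m2)
})

test_that("theta spike trains follow the rate, merge and cycle rules", {
  fs <- 1000
  theta <- fixture("theta_noise_ps", function()
    noise_phase_series(c(6, 12), fs, 40, seed = 6))
  tracking <- data.frame(t_s = seq(0, 40, by = 0.02), pos_cm = 0,
                         speed_cms = 40, direction = 1L)
  # silent cell
  expect_equal(nrow(detect_theta_spike_trains(numeric(0), tracking, theta,
                                              c(0, 40))), 0)
  # 1 s tonic 10 Hz burst: exactly one train
  st <- seq(10, 11, by = 0.1)
  tt <- detect_theta_spike_trains(st, tracking, theta, c(0, 40))
  expect_equal(nrow(tt), 1)
  expect_equal(tt$n_spikes, 11)
  expect_gte(tt$n_cycles, 3)
  # spikes at < 10 cm/s are discarded
  slow <- tracking
  slow$speed_cms <- 5
  expect_equal(nrow(detect_theta_spike_trains(st, slow, theta, c(0, 40))), 0)
  # 3 spikes inside one cycle: dropped under the first-per-cycle restriction
  b <- which(diff(theta$phase) < -pi)
  one_cycle <- b[50] / fs + c(0.005, 0.01, 0.015)
  tt3 <- detect_theta_spike_trains(one_cycle, tracking, theta, c(0, 40),
                                   restrict_first_per_cycle = TRUE)
  expect_equal(nrow(tt3), 0)
})

test_that("movement events are maximal speed-qualified intervals", {
  tr <- data.frame(t_s = seq(0, 9.98, by = 0.02), pos_cm = 0,
                   speed_cms = rep(c(40, 0), each = 250, length.out = 500),
                   direction = 0L)
  me <- detect_movement_events(tr)
  expect_equal(nrow(me), 1)
  expect_equal(me$end_s - me$start_s, 4.98, tolerance = 1e-9)
  # alternating 0.5 s above/below threshold: no qualifying interval
  tr2 <- data.frame(t_s = seq(0, 9.98, by = 0.02), pos_cm = 0,
                    speed_cms = rep(c(40, 0), each = 25, length.out = 500),
                    direction = 0L)
  expect_equal(nrow(detect_movement_events(tr2)), 0)
  # generator schedule is recovered to within one tracking sample
  s <- small_session()
  me2 <- detect_movement_events(s$tracking)
  runs <- s$ground_truth$runs
  expect_equal(nrow(me2), nrow(runs))
  expect_true(all(abs(me2$start_s - runs$t_start) <= 0.02 + 1e-9))
  expect_true(all(abs(me2$end_s - runs$t_end) <= 0.02 + 1e-9))
})
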