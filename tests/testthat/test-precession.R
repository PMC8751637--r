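test_that("first spike per cycle retains the right subset", {
  ps <- tone_phase_series(8, 250, 10)
  # 3 spikes in one cycle -> 1 retained
  expect_length(first_spike_per_cycle(c(2.01, 2.03, 2.05), ps), 1)
  # 1 spike per cycle over 5 cycles -> all retained
  st <- 2 + (0:4) / 8
  expect_length(first_spike_per_cycle(st, ps), 5)
})

test_that("within-event fits recover exact linear precession", {
  fs <- 1000
  t <- (0:999) / fs
  ps <- instantaneous_phase_amplitude(cos(2 * pi * 200 * t), fs)
  st <- c(time_at_phase(pi, 0.1, 200), time_at_phase(pi - 0.5, 0.5, 200),
          time_at_phase(pi - 1, 0.9, 200))
  # with 3 spikes at x = 0, 0.5, 1 slopes alias at multiples of 4*pi, so the
  # fit is checked within one alias band
  w <- within_event_fit(st, ps, 0, 1, slope_bounds = c(-2 * pi, 2 * pi))
  expect_lt(abs(w$fit$slope - (-1)), 0.08)
  expect_lt(abs(wrap_pi(w$fit$intercept - pi)), 0.08)
  expect_lt(max(abs(w$shifts - c(-0.5, -0.5))), 0.08)
  # constant phase: zero slope
  st2 <- time_at_phase(rep(2, 4), c(0.1, 0.3, 0.6, 0.9), 200)
  w2 <- within_event_fit(st2, ps, 0, 1)
  expect_equal(w2$fit$slope, 0)
  # fewer than 3 spikes: excluded, not an error
  expect_null(within_event_fit(st[1:2], ps, 0, 1))
  # normalized time depends only on the spikes, not on the event window
  w3 <- within_event_fit(st, ps, -0.4, 1.6,
                         slope_bounds = c(-2 * pi, 2 * pi))
  expect_equal(w3$fit$slope, w$fit$slope)
  expect_equal(w3$fit$intercept, w$fit$intercept)
})

test_that("per-cell aggregation pools events correctly", {
  fs <- 1000
  t <- (0:4999) / fs
  ps <- instantaneous_phase_amplitude(cos(2 * pi * 200 * t), fs)
  mk_event <- function(t0) {
    st <- c(time_at_phase(pi, t0 + 0.1, 200),
            time_at_phase(pi - 0.4, t0 + 0.5, 200),
            time_at_phase(pi - 0.8, t0 + 0.9, 200))
    within_event_fit(st, ps, t0, t0 + 1)
  }
  fits <- lapply(c(0, 1, 2, 3), mk_event)
  summ <- cell_precession_summary(fits, cell_id = 7L)
  expect_equal(summ$n_events, 4)
  expect_equal(summ$mean_slope, -0.8, tolerance = 0.1)
  expect_equal(summ$mean_shift, -0.4, tolerance = 0.05)
  expect_length(summ$shifts_by_pair[[1]], 2)   # first and second spike pairs
  expect_length(summ$shifts_by_pair[[1]][[1]], 4)
})

test_that("burst index follows its definition and flags degenerate cells", {
  expect_equal(burst_index(cumsum(c(0, 0.005, 0.008, 0.05, 0.15, 0.3))), 0.5)
  expect_true(is.na(burst_index(c(0, 0.3, 0.7))))
  expect_equal(burst_index(cumsum(c(0, rep(0.005, 9)))), 1)
  expect_true(is.na(burst_index(0.5)))
})

test_that("within-field fits enforce spike-count and coverage rules", {
  set.seed(51)
  d <- runif(40, 0, 1)
  ph <- wrap_2pi(pi + 0.25 - 0.5 * d + rnorm(40, 0, 0.1))
  wf <- within_field_fit(d, ph)
  expect_true(wf$included)
  expect_lt(abs(wf$slope - (-0.5)), 0.15)
  # 4 spikes: excluded
  expect_false(within_field_fit(d[1:4], ph[1:4])$included)
  # 40% coverage: excluded
  d2 <- runif(20, 0.3, 0.7)
  expect_false(within_field_fit(d2, ph[1:20])$included)
  # single-spike-per-event data still enters a pooled fit (n counts spikes,
  # not events)
  expect_true(within_field_fit(d[1:6], ph[1:6])$included)
})

test_that("first-per-cycle restriction never flips a noiseless precession slope", {
  fs <- 1000
  t <- (0:1999) / fs
  ps <- instantaneous_phase_amplitude(cos(2 * pi * 200 * t), fs)
  # bursty train: doublets in each of 6 cycles, phases precessing
  base <- 0.5 + (0:5) * 0.005 * 4
  st <- c()
  for (k in seq_along(base)) {
    ph <- pi - 0.3 * (k - 1)
    t1 <- time_at_phase(ph, base[k], 200)
    st <- c(st, t1, t1 + 0.001)
  }
  all_fit <- within_event_fit(st, ps, 0, 2)
  first_fit <- within_event_fit(st, ps, 0, 2, restrict_first_per_cycle = TRUE)
  expect_lt(all_fit$fit$slope, 0)
  expect_lt(first_fit$fit$slope, 0)
  expect_equal(first_fit$n, 6)
})

test_that("generator-injected per-spike ripple shift is recovered at scale", {
  # three spikes per crossing at d = 1/6, 1/2, 5/6: shift = slope / 3 per
  # spike; slope -2.76 rad/field gives -0.92 rad/spike
  s <- fixture("shift_session", function()
    generate_session(session_config(n_cells = 12, n_runs = 1,
                                    rest_duration = 800,
                                    n_replay_events = 200,
                                    ripple_slope = -2.76,
                                    background_rate = 0,
                                    phase_noise_sd = 0.2,
                                    replay_speed_range = c(600, 1000)),
                     seed = 77))
  ripple <- instantaneous_phase_amplitude(
    bandpass_filter(s$lfp[, 1], c(150, 250), s$lfp_fs), s$lfp_fs, s$lfp_t0)
  gts <- s$ground_truth$spikes
  ev <- s$ground_truth$events
  all_shifts <- c()
  for (i in seq_len(nrow(ev))) {
    sel <- gts$origin == "event" & gts$origin_id == i
    for (cid in unique(gts$cell_id[sel])) {
      rows <- which(sel & gts$cell_id == cid)
      rows <- rows[order(gts$t_s[rows])]
      if (length(rows) < 3) next
      # keep complete field crossings, where successive spikes are 1/3 of the
      # field apart by construction
      if (any(abs(abs(diff(gts$d[rows])) - 1 / 3) > 0.02)) next
      ph <- phase_at(ripple, gts$t_s[rows])
      all_shifts <- c(all_shifts, successive_phase_shifts(ph)$shifts)
    }
  }
  expect_gte(length(all_shifts), 500)
  grand <- wrap_pi(ripplephase:::circ_mean_angle(all_shifts))
  expect_lt(abs(grand - (-0.92)), 0.05)
})

test_that("single-spike events contribute to within-field pooling", {
  # pooled positions include spikes from cells firing once per event
  ps <- tone_phase_series(200, 1000, 1)
  traj <- structure(list(origin_cm = 100, speed_cms = 1000, score = 1,
                         significant = TRUE),
                    class = "fitted_trajectory")
  events <- data.frame(start_s = 0.2, end_s = 0.4)
  events$active_cells <- list(c(1L, 2L))
  spikes <- data.frame(cell_id = c(1L, 2L, 2L, 2L),
                       t_s = c(0.25, 0.26, 0.3, 0.34))
  fields <- data.frame(cell_id = c(1L, 2L), direction = 1L,
                       left_cm = c(130, 180), right_cm = c(170, 260),
                       peak_cm = c(150, 220))
  pooled <- pool_within_field_ripple(events, list(traj), spikes, fields,
                                     ps, 600)
  expect_true(1L %in% pooled$cell_id)   # the single-spike cell
  expect_true(all(pooled$d >= 0 & pooled$d <= 1))
})
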