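test_that("identical (config, seed) pairs yield identical bundles", {
  cfg <- session_config(n_cells = 6, n_runs = 2, rest_duration = 60,
                        n_replay_events = 5)
  a <- generate_session(cfg, seed = 9)
  b <- generate_session(cfg, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$tracking, b$tracking)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_session(cfg, seed = 10)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("generator rejects infeasible configurations", {
  expect_error(generate_session(
    session_config(rest_duration = 40, n_replay_events = 30), seed = 1),
    "overlap")
  expect_error(generate_session(
    session_config(field_width = 700), seed = 1), "wider")
  expect_error(generate_replay_event(
    list(start_cm = 100, direction = 1, speed_cms = 50),
    data.frame(cell_id = 1, centre_cm = 120, width_cm = 40,
               ripple_slope = -0.5),
    session_config()), "100-5000")
})

test_that("zero injected events leaves only background REST spiking", {
  s <- generate_session(session_config(n_cells = 20, n_runs = 2,
                                       rest_duration = 200,
                                       n_replay_events = 0), seed = 13)
  expect_equal(nrow(s$ground_truth$events), 0)
  rest <- s$epochs[s$epochs$name == "rest", ]
  origins <- s$ground_truth$spikes$origin[
    s$ground_truth$spikes$t_s >= rest$start_s]
  expect_true(all(origins == "background"))
})

test_that("replay trajectories crossing zero fields carry no event spikes", {
  cells <- data.frame(cell_id = 1:3, centre_cm = c(300, 350, 400),
                      width_cm = 40, ripple_slope = -0.5)
  ev <- generate_replay_event(list(start_cm = 10, direction = 1,
                                   speed_cms = 300),
                              cells, session_config())
  expect_equal(nrow(ev$spikes), 0)
  expect_false(ev$clipped)
  # trajectory leaving the track is clipped and flagged
  ev2 <- generate_replay_event(list(start_cm = 550, direction = 1,
                                    speed_cms = 1000),
                               cells, session_config())
  expect_true(ev2$clipped)
})

test_that("rate calibration: empirical in-field peak rate tracks the config", {
  s <- fixture("calib_session", function()
    generate_session(session_config(n_cells = 4, n_runs = 25, peak_rate = 8,
                                    rest_duration = 30, n_replay_events = 0,
                                    run_speed_mean = 40), seed = 17))
  gt <- s$ground_truth$cells
  tr <- s$tracking
  dt <- median(diff(tr$t_s))
  for (j in c(1, 3)) {
    near <- abs(tr$pos_cm - gt$centre_cm[j]) <= 2 & tr$speed_cms > 0
    dwell <- sum(near) * dt
    spk <- s$ground_truth$spikes
    spk <- spk[spk$cell_id == j & spk$origin == "run", ]
    pos <- approx(tr$t_s, tr$pos_cm, spk$t_s, rule = 2)$y
    n_in <- sum(abs(pos - gt$centre_cm[j]) <= 2)
    expect_equal(n_in / dwell, gt$peak_rate_hz[j], tolerance = 0.1)
  }
})

test_that("phase calibration: spikes at the field centre fire at the intercept", {
  s <- small_session()
  theta <- session_theta_phase(s)
  gts <- s$ground_truth$spikes
  ctr <- gts[gts$origin == "run" & !is.na(gts$d) & abs(gts$d - 0.5) < 0.05, ]
  ph <- phase_at(theta, ctr$t_s)
  mu <- circ_descriptives(ph[!is.na(ph)])$mean
  expect_lt(abs(wrap_pi(mu - s$config$phase_intercept)), 0.1)
})

test_that("REST ripple-band power is concentrated inside injected events", {
  s <- small_session()
  ripple <- session_ripple_phase(s)
  env2 <- ripple$amplitude^2
  tl <- s$lfp_t0 + (seq_along(env2) - 1) / s$lfp_fs
  ev <- s$ground_truth$events
  inev <- rep(FALSE, length(env2))
  for (i in seq_len(nrow(ev)))
    inev <- inev | (tl >= ev$start_s[i] & tl <= ev$end_s[i])
  rest <- tl >= s$epochs$start_s[2]
  ratio <- mean(env2[inev & rest]) / mean(env2[!inev & rest])
  # configured amplitude 1 vs in-band noise power of the 0.2-SD background
  expect_gt(ratio, 10)
})

test_that("noiseless decode-refit recovers an on-grid replay speed exactly", {
  # dense tiling (~10 fields crossed) so the decoded staircase resolves the
  # slope to within the search grid
  cfg <- session_config(n_cells = 40, spikes_per_crossing = 4,
                        phase_noise_sd = 0)
  geom <- cfg$geometry
  gt <- data.frame(cell_id = 1:40,
                   centre_cm = seq(30, geom$total - 30, length.out = 40),
                   width_cm = 40, peak_rate_hz = 8, ripple_slope = -0.5)
  maps <- analytic_maps(list(config = cfg,
                             ground_truth = list(cells = gt)))
  set.seed(1)
  ev <- generate_replay_event(list(start_cm = 80, direction = 1,
                                   speed_cms = 500), gt, cfg, duration = 0.4)
  expect_gte(length(unique(ev$spikes$cell_id)), 8)
  counts <- event_counts(ev$spikes, nrow(maps), 0, 0.4, 0.01)
  post <- bayes_decode(counts, maps, 0.01, bin_centres = geom$bin_centres)
  fit <- fit_linear_trajectory(post)
  expect_lte(abs(fit$speed_cms - 500), 50)   # within one grid step
  expect_lt(abs(fit$origin_cm - 80), 20)
  # reverse event: negative fitted slope along the outbound axis
  ev2 <- generate_replay_event(list(start_cm = 500, direction = -1,
                                    speed_cms = 500), gt, cfg, duration = 0.4)
  counts2 <- event_counts(ev2$spikes, nrow(maps), 0, 0.4, 0.01)
  fit2 <- fit_linear_trajectory(
    bayes_decode(counts2, maps, 0.01, bin_centres = geom$bin_centres))
  expect_lt(fit2$speed_cms, 0)
  expect_lte(abs(abs(fit2$speed_cms) - 500), 50)
})

test_that("session bundles round-trip through disk losslessly", {
  s <- generate_session(session_config(n_cells = 5, n_runs = 2,
                                       rest_duration = 40,
                                       n_replay_events = 3), seed = 23)
  path <- tempfile("bundle")
  write_session(s, path)
  s2 <- read_session(path)
  expect_lt(max(abs(s2$tracking$t_s - s$tracking$t_s)), 1e-9)
  expect_lt(max(abs(s2$tracking$pos_cm - s$tracking$pos_cm)), 0.01)
  expect_lt(max(abs(s2$spikes$t_s - s$spikes$t_s)), 1e-9)
  expect_equal(s2$spikes$cell_id, s$spikes$cell_id)
  expect_lt(max(abs(s2$lfp - s$lfp)), 1e-6)
  expect_equal(s2$lfp_fs, s$lfp_fs)
  expect_equal(as.data.frame(s2$ground_truth$events), s$ground_truth$events,
               tolerance = 1e-8)
  expect_equal(s2$config$n_cells, s$config$n_cells)

  file.remove(file.path(path, "lfp.bin"))
  expect_error(read_session(path), "lfp")

  # non-monotone tracking timestamps are rejected on read
  path2 <- tempfile("bundle")
  write_session(s, path2)
  tr <- read.csv(file.path(path2, "tracking.csv"))
  tr$t_s[2] <- tr$t_s[1]
  write.csv(tr, file.path(path2, "tracking.csv"), row.names = FALSE)
  expect_error(read_session(path2), "increasing")
  unlink(c(path, path2), recursive = TRUE)
})
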