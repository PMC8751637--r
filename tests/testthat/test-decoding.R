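naive_posterior <- function(counts, maps, tbin, eps = 0.01) {
  # independent literal evaluation of the Poisson decoding rule
  n_bins <- ncol(maps)
  out <- matrix(NA_real_, n_bins, ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (sum(counts[, j]) == 0) next
    p <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      v <- 1
      for (i in seq_len(nrow(maps))) {
        lam <- tbin * (maps[i, b] + eps)
        k <- counts[i, j]
        v <- v * lam^k / factorial(k) * exp(-lam)
      }
      p[b] <- v
    }
    out[, j] <- p / sum(p)
  }
  out
}

test_that("decoder matches a naive evaluation of the Poisson rule", {
  set.seed(14)
  maps <- matrix(runif(15, 0, 10), nrow = 3)      # 3 cells x 5 bins
  counts <- matrix(rpois(9, 2), nrow = 3)         # 3 time bins
  post <- bayes_decode(counts, maps, tbin = 0.02,
                       bin_centres = seq(1, 9, by = 2))
  ref <- naive_posterior(counts, maps, 0.02)
  expect_lt(max(abs(post$prob - ref) / pmax(ref, 1e-300)), 1e-12)
  expect_equal(colSums(post$prob), rep(1, 3), tolerance = 1e-9)
})

test_that("decoder degenerate cases: delta map, flat maps, zero-spike bins", {
  maps <- rbind(c(0, 0, 0, 100, 0))
  post <- bayes_decode(matrix(1, 1, 1), maps, 0.01, bin_centres = 1:5)
  expect_equal(which.max(post$prob[, 1]), 4L)
  expect_gt(post$prob[4, 1], 0.99)
  # identical flat maps for all cells: uniform posterior
  maps2 <- matrix(3, nrow = 4, ncol = 6)
  post2 <- bayes_decode(matrix(1L, 4, 1), maps2, 0.01, bin_centres = 1:6)
  expect_equal(post2$prob[, 1], rep(1 / 6, 6))
  # zero-spike column is flagged undecoded
  post3 <- bayes_decode(matrix(0L, 4, 2), maps2, 0.01, bin_centres = 1:6)
  expect_equal(post3$decoded, c(FALSE, FALSE))
})

test_that("duplicating a cell leaves the posterior argmax unchanged", {
  set.seed(15)
  maps <- matrix(runif(40, 0, 8), nrow = 4)
  counts <- matrix(rpois(4, 1.5), nrow = 4, ncol = 1)
  p1 <- bayes_decode(counts, maps, 0.02, bin_centres = 1:10)
  p2 <- bayes_decode(rbind(counts, counts[4, ]), rbind(maps, maps[4, ]),
                     0.02, bin_centres = 1:10)
  expect_equal(which.max(p1$prob[, 1]), which.max(p2$prob[, 1]))
})

test_that("trajectory fit: alignment, tie-breaks and brute-force agreement", {
  geom <- track_geometry()
  n <- geom$n_bins
  nt <- 20
  prob <- matrix(0, n, nt)
  for (j in seq_len(nt)) {
    pos <- 80 + 300 * ((j - 0.5) * 0.01)
    prob[round((pos - 1) / 2) + 1, j] <- 1
  }
  post <- structure(list(prob = prob, decoded = rep(TRUE, nt), tbin = 0.01,
                         bin_centres = geom$bin_centres),
                    class = "posterior_matrix")
  # restricted to the true speed the line captures all mass at the true origin
  f_true <- fit_linear_trajectory(post, speeds = 300)
  expect_equal(f_true$speed_cms, 300)
  expect_equal(f_true$score, 1)
  # origins tie over half a window width; the earliest wins
  expect_gte(f_true$origin_cm, 80 - 15)
  expect_lte(f_true$origin_cm, 82)
  # full grid: a band of speeds ties at score 1 and the lower |speed| wins
  f_full <- fit_linear_trajectory(post)
  expect_equal(f_full$score, 1)
  expect_lte(abs(f_full$speed_cms), 300)
  # stationary mass: grid excludes 0, so the minimum speed is returned
  prob2 <- matrix(0, n, nt)
  prob2[100, ] <- 1
  post2 <- structure(list(prob = prob2, decoded = rep(TRUE, nt), tbin = 0.01,
                          bin_centres = geom$bin_centres),
                     class = "posterior_matrix")
  f2 <- fit_linear_trajectory(post2)
  expect_equal(abs(f2$speed_cms), 100)
  expect_equal(f2$score, 1)
})

test_that("fit search equals a brute-force reimplementation on small posteriors", {
  set.seed(16)
  n_bins <- 40
  nt <- 6
  centres <- seq(1, by = 2, length.out = n_bins)
  speeds <- seq(100, 1000, by = 50)
  for (rep in 1:5) {
    prob <- matrix(rexp(n_bins * nt), n_bins, nt)
    prob <- sweep(prob, 2, colSums(prob), "/")
    post <- structure(list(prob = prob, decoded = rep(TRUE, nt), tbin = 0.02,
                           bin_centres = centres),
                      class = "posterior_matrix")
    fit <- fit_linear_trajectory(post, speeds = speeds)
    # brute force with identical tie-break order
    best <- list(score = -1)
    for (sp in as.vector(rbind(speeds, -speeds))) {
      for (o in seq_len(n_bins)) {
        sc <- 0
        for (j in seq_len(nt)) {
          b <- o + round(sp * (j - 0.5) * 0.02 / 2)
          b <- min(max(b, 1), n_bins)
          lo <- max(b - 7, 1); hi <- min(b + 7, n_bins)
          sc <- sc + sum(prob[lo:hi, j])
        }
        sc <- sc / nt
        if (sc > best$score) best <- list(score = sc, speed = sp, origin = o)
      }
    }
    expect_equal(fit$speed_cms, best$speed)
    expect_equal(fit$origin_bin, best$origin)
    expect_equal(fit$score, best$score, tolerance = 1e-12)
  }
})

test_that("decoding validation recovers position and degrades with permuted maps", {
  s <- small_session()
  geom <- s$config$geometry
  runs <- segment_runs(s$tracking, geom)
  maps <- analytic_maps(s)
  rownames(maps) <- s$ground_truth$cells$cell_id
  both <- list(outbound = maps, inbound = maps)
  val <- run_decoding_validation(s$spikes, s$cells$cell_id, s$tracking, runs,
                                 both, geom)
  expect_lt(val$outbound, 10)
  expect_lt(val$inbound, 10)
  # permuted cell identities: error comparable to uniform guessing (~L/4)
  set.seed(3)
  perm <- sample(nrow(maps))
  both_perm <- list(outbound = maps[perm, ], inbound = maps[perm, ])
  val_perm <- run_decoding_validation(s$spikes, s$cells$cell_id, s$tracking,
                                      runs, both_perm, geom)
  expect_gt(mean(c(val_perm$outbound, val_perm$inbound)), 60)
})

test_that("five active cells admit exactly 120 orderings; shuffles exclude identity", {
  perms <- enumerate_cell_permutations(11:15)
  expect_equal(nrow(perms), 120)
  expect_equal(nrow(unique(perms)), 120)
  expect_true(all(apply(perms, 1, function(r) setequal(r, 11:15))))
})

test_that("clean replay events are significant; exchangeable events are not", {
  cfg <- session_config(n_cells = 30, spikes_per_crossing = 4,
                        phase_noise_sd = 0)
  geom <- cfg$geometry
  gt <- data.frame(cell_id = 1:30,
                   centre_cm = seq(25, geom$total - 25, length.out = 30),
                   width_cm = 40, peak_rate_hz = 8, ripple_slope = -0.5)
  maps <- analytic_maps(list(config = cfg, ground_truth = list(cells = gt)))
  set.seed(18)
  ev <- generate_replay_event(list(start_cm = 100, direction = 1,
                                   speed_cms = 1000), gt, cfg,
                              duration = 0.3)
  counts <- event_counts(ev$spikes, 30, 0, 0.3, 0.01)
  act <- sort(unique(ev$spikes$cell_id))
  sig <- trajectory_significance(counts, 1:30, act, list(outbound = maps),
                                 0.01, geom$bin_centres, n_shuffles = 100)
  expect_true(sig$fit$significant)
  expect_lt(sig$fit$p, 0.05)
  # all maps identical: cell identity is exchangeable, shuffling changes nothing
  flat <- matrix(2, 30, geom$n_bins)
  sig2 <- trajectory_significance(counts, 1:30, act, list(outbound = flat),
                                  0.01, geom$bin_centres, n_shuffles = 50)
  expect_false(sig2$fit$significant)
})

test_that("cycle-decoded locations advance at the fitted speed and clip", {
  ps <- tone_phase_series(200, 1000, 2)
  traj <- structure(list(origin_cm = 100, speed_cms = 500, score = 1,
                         significant = TRUE),
                    class = "fitted_trajectory")
  locs <- cycle_decoded_locations(traj, ps, 0.5, 0.7, 600)
  # 200 Hz cycles: midpoints 5 ms apart -> 2.5 cm steps
  expect_equal(median(diff(locs$loc_cm)), 2.5, tolerance = 0.1)
  expect_true(all(diff(locs$loc_cm) >= 0))
  traj2 <- structure(list(origin_cm = 20, speed_cms = -500, score = 1),
                     class = "fitted_trajectory")
  locs2 <- cycle_decoded_locations(traj2, ps, 0.5, 0.7, 600)
  expect_true(all(diff(locs2$loc_cm) <= 0))
  expect_true(all(locs2$loc_cm >= 0))
})
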