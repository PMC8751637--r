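#' Z-track geometry
#'
#' Linearized geometry of a three-section shuttle track. Positions run from 0
#' at one end to the summed section length at the other; the two corners sit
#' at the cumulative section boundaries.
#'
#' @param section_lengths lengths of the three sections (cm).
#' @param bin_width spatial bin width (cm).
#' @param end_margin excluded margin at each track end (cm).
#' @param corner_margin excluded margin around each corner (cm).
#' @return object of class `track_geometry`.
#' @export
track_geometry <- function(section_lengths = c(190, 220, 190), bin_width = 2,
                           end_margin = 10, corner_margin = 5) {
  stopifnot(length(section_lengths) == 3, all(section_lengths > 0),
            bin_width > 0)
  if (max(end_margin, corner_margin) >= min(section_lengths))
    stop("margins must be smaller than the shortest section")
  total <- sum(section_lengths)
  n_bins <- as.integer(ceiling(total / bin_width))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  structure(list(section_lengths = section_lengths, bin_width = bin_width,
                 end_margin = end_margin, corner_margin = corner_margin,
                 total = total, corners = cumsum(section_lengths)[1:2],
                 n_bins = n_bins, bin_edges = edges,
                 bin_centres = edges[-1] - bin_width / 2),
            class = "track_geometry")
}

#' @export
print.track_geometry <- function(x, ...) {
  cat(sprintf("track: %s cm sections, %g cm total, %d bins of %g cm\n",
              paste(x$section_lengths, collapse = "+"), x$total, x$n_bins,
              x$bin_width))
  invisible(x)
}

# logical mask of bins outside the end/corner exclusion zones
valid_track_bins <- function(geometry) {
  ctr <- geometry$bin_centres
  ok <- ctr >= geometry$end_margin & ctr <= geometry$total - geometry$end_margin
  for (corner in geometry$corners)
    ok <- ok & abs(ctr - corner) > geometry$corner_margin
  ok
}

# TRUE for positions inside an exclusion zone
in_exclusion_zone <- function(pos, geometry) {
  out <- pos < geometry$end_margin | pos > geometry$total - geometry$end_margin
  for (corner in geometry$corners)
    out <- out | abs(pos - corner) <= geometry$corner_margin
  out
}

#' Generator settings for a synthetic session
#'
#' All parameters of the synthetic-session generator, surfaced explicitly so
#' that none is hard-coded. Defaults describe a linear Z-track session with
#' theta-precessing place cells during RUN and ripple-band-precessing replay
#' events during REST.
#'
#' @param geometry a [track_geometry()].
#' @param tracking_hz tracking sample rate (Hz).
#' @param lfp_hz LFP sample rate (Hz). 1 kHz keeps simulations light; all
#'   downstream filters scale with sample rate.
#' @param n_lfp_channels number of LFP channels; channel 1 carries the
#'   oscillatory content, additional channels are noise-only.
#' @param n_cells number of simulated putative pyramidal place cells.
#' @param field_width full place-field extent (cm).
#' @param peak_rate in-field peak firing rate (Hz).
#' @param theta_hz theta carrier frequency (Hz).
#' @param theta_band,ripple_band analysis bands (Hz pairs).
#' @param ripple_hz ripple carrier frequency (Hz).
#' @param theta_amp,ripple_amp oscillation amplitudes (arbitrary units).
#' @param lfp_noise_sd white-noise SD added to every LFP sample.
#' @param theta_slope,ripple_slope injected phase-precession slopes, rad per
#'   full field traversal.
#' @param phase_intercept spike phase at the field centre (rad).
#' @param phase_noise_sd wrapped-normal SD of spike-phase noise (rad).
#' @param n_runs shuttle runs per direction.
#' @param run_speed_mean,run_speed_sd running speed distribution (cm/s).
#' @param pause_s immobile pause at each track end (s).
#' @param n_unsuccessful number of half-track excursions (unsuccessful runs).
#' @param rest_duration REST epoch duration (s).
#' @param n_replay_events injected replay events in REST.
#' @param event_duration replay event duration (s, <= 0.5).
#' @param replay_speed_range trajectory speed range (cm/s, within 100-5000).
#' @param spikes_per_crossing spikes emitted per field crossing.
#' @param background_rate REST background Poisson rate per cell (Hz).
#' @param include_distractor add one high-rate (>10 Hz) distractor cell to
#'   exercise the putative-interneuron exclusion filter.
#' @param distractor_rate distractor firing rate (Hz).
#' @param min_event_gap minimum gap between injected replay events (s).
#' @return list of class `session_config`.
#' @export
session_config <- function(geometry = track_geometry(),
                           tracking_hz = 50,
                           lfp_hz = 1000,
                           n_lfp_channels = 1,
                           n_cells = 30,
                           field_width = 40,
                           peak_rate = 8,
                           theta_hz = 8,
                           theta_band = c(6, 12),
                           ripple_hz = 200,
                           ripple_band = c(150, 250),
                           theta_amp = 1,
                           ripple_amp = 1,
                           lfp_noise_sd = 0.2,
                           theta_slope = -2.77,
                           ripple_slope = -0.5,
                           phase_intercept = pi,
                           phase_noise_sd = 0.4,
                           n_runs = 10,
                           run_speed_mean = 50,
                           run_speed_sd = 5,
                           pause_s = 2,
                           n_unsuccessful = 0,
                           rest_duration = 300,
                           n_replay_events = 30,
                           event_duration = 0.2,
                           replay_speed_range = c(300, 2000),
                           spikes_per_crossing = 3,
                           background_rate = 0.5,
                           include_distractor = FALSE,
                           distractor_rate = 20,
                           min_event_gap = 3) {
  cfg <- as.list(environment())
  class(cfg) <- "session_config"
  cfg
}

# Tukey (tapered cosine) amplitude envelope, length n, taper fraction alpha
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

#' Generate a synthetic replay event
#'
#' Inverse model of the trajectory-fitting analysis: a constant-speed
#' trajectory sweeps along the linearized track, each place cell whose field
#' it crosses emits spikes ordered along the trajectory, and each in-field
#' spike's ripple-band phase equals the within-field precession model value
#' (`phase_intercept + ripple_slope * (d - 1/2)`, `d` the relative distance
#' through the field along the movement direction) plus wrapped-normal noise.
#' The accompanying LFP segment is a ripple-frequency oscillation under a
#' smooth tapered envelope.
#'
#' @param trajectory list with `start_cm`, `direction` (+1/-1 along the
#'   outbound axis) and `speed_cms` (within 100-5000).
#' @param cells data.frame with `cell_id`, `centre_cm`, `width_cm`,
#'   `ripple_slope` per cell (a `ground_truth$cells` subset).
#' @param config a [session_config()].
#' @param duration event duration (s, <= 0.5; default `config$event_duration`).
#' @return list with `spikes` (cell_id, t_rel, d, phase), `lfp` (segment at
#'   `config$lfp_hz`), `clipped` flag, and `duration`.
#' @export
generate_replay_event <- function(trajectory, cells, config,
                                  duration = config$event_duration) {
  v <- trajectory$speed_cms
  dir <- trajectory$direction
  x0 <- trajectory$start_cm
  if (v < 100 || v > 5000)
    stop("trajectory speed must lie in the detectable 100-5000 cm/s range")
  if (duration > 0.5) stop("event duration must be <= 0.5 s")
  L <- config$geometry$total
  # time until the trajectory would leave the track (clipped thereafter)
  t_edge <- if (dir > 0) (L - x0) / v else x0 / v
  clipped <- t_edge < duration
  t_move <- min(duration, t_edge)
  fr <- config$ripple_hz
  # spikes are emitted only while the ripple transient is strong, i.e. inside
  # the flat part of the tapered amplitude envelope
  taper <- 0.25 / 2 * duration
  t_lo <- taper
  t_hi <- t_move - taper

  spk <- list()
  for (j in seq_len(nrow(cells))) {
    c_cm <- cells$centre_cm[j]
    W <- cells$width_cm[j]
    slope <- cells$ripple_slope[j]
    entry <- c_cm - dir * W / 2
    exit <- c_cm + dir * W / 2
    t_in <- (entry - x0) / (dir * v)
    t_out <- (exit - x0) / (dir * v)
    a <- max(t_lo, t_in)
    b <- min(t_hi, t_out)
    if (b - a < 1e-9) next
    k <- config$spikes_per_crossing
    t_raw <- a + (b - a) * seq(0.5 / k, 1 - 0.5 / k, length.out = k)
    x_t <- x0 + dir * v * t_raw
    d <- (dir * (x_t - c_cm) + W / 2) / W
    target <- wrap_2pi(config$phase_intercept + slope * (d - 0.5) +
                         stats::rnorm(k, 0, config$phase_noise_sd))
    # place each spike at the time within its ripple cycle where the LFP
    # phase equals the target phase
    t_snap <- (round(fr * t_raw - target / (2 * pi)) + target / (2 * pi)) / fr
    period <- 1 / fr
    t_snap[t_snap < t_lo] <- t_snap[t_snap < t_lo] + period
    t_snap[t_snap > t_hi] <- t_snap[t_snap > t_hi] - period
    keep <- t_snap >= t_lo & t_snap <= t_hi
    if (!any(keep)) next
    spk[[length(spk) + 1L]] <- data.frame(
      cell_id = cells$cell_id[j], t_rel = t_snap[keep], d = d[keep],
      phase = target[keep])
  }
  spikes <- if (length(spk)) do.call(rbind, spk) else
    data.frame(cell_id = integer(0), t_rel = numeric(0), d = numeric(0),
               phase = numeric(0))
  spikes <- spikes[order(spikes$t_rel), , drop = FALSE]

  n <- as.integer(round(duration * config$lfp_hz))
  trel <- (seq_len(n) - 1L) / config$lfp_hz
  lfp <- config$ripple_amp * tukey_window(n, 0.25) * cos(2 * pi * fr * trel)
  list(spikes = spikes, lfp = lfp, clipped = clipped, duration = duration)
}

#' Generate a synthetic session bundle
#'
#' Produces a RUN epoch (shuttle runs on the linearized Z-track with
#' theta-modulated, theta-phase-precessing place cells and a theta-band LFP)
#' followed by a REST epoch (immobile tracking, low-rate background Poisson
#' spiking, and injected replay events with ripple-band LFP transients and
#' ripple-phase-precessing spikes), together with a ground-truth record of
#' every generated quantity. Identical `(config, seed)` pairs yield identical
#' sessions.
#'
#' @param config a [session_config()].
#' @param seed integer RNG seed.
#' @return object of class `replay_session`: list with `tracking` (t_s,
#'   pos_cm, speed_cms, direction), `spikes` (cell_id, t_s), `cells`
#'   (cell_id, pyramidal), `lfp` (samples x channels matrix), `lfp_fs`,
#'   `lfp_t0`, `epochs`, `ground_truth`, `config`, `seed`.
#' @export
generate_session <- function(config = session_config(), seed = 1) {
  set.seed(seed)
  geom <- config$geometry
  L <- geom$total
  if (config$field_width >= L) stop("field wider than the track")
  fs_tr <- config$tracking_hz
  fs <- config$lfp_hz

  ## ---- RUN epoch: schedule of pauses and constant-speed runs ----
  segs <- list()  # each: t0, t1, x0, x1, speed, direction, run_id, successful
  t_cur <- 0
  x_cur <- 0
  run_id <- 0L
  add_pause <- function(dur) {
    segs[[length(segs) + 1L]] <<- list(t0 = t_cur, t1 = t_cur + dur,
                                       x0 = x_cur, x1 = x_cur, speed = 0,
                                       direction = 0L, run_id = NA_integer_,
                                       successful = NA)
    t_cur <<- t_cur + dur
  }
  add_run <- function(target, successful) {
    run_id <<- run_id + 1L
    speed <- max(15, stats::rnorm(1, config$run_speed_mean, config$run_speed_sd))
    dur <- abs(target - x_cur) / speed
    segs[[length(segs) + 1L]] <<- list(t0 = t_cur, t1 = t_cur + dur,
                                       x0 = x_cur, x1 = target, speed = speed,
                                       direction = if (target > x_cur) 1L else -1L,
                                       run_id = run_id, successful = successful)
    t_cur <<- t_cur + dur
    x_cur <<- target
  }
  add_pause(config$pause_s)
  for (r in seq_len(config$n_runs)) {
    add_run(L, TRUE); add_pause(config$pause_s)   # outbound
    add_run(0, TRUE); add_pause(config$pause_s)   # inbound
  }
  for (r in seq_len(config$n_unsuccessful)) {
    add_run(L / 2, FALSE)
    add_run(0, FALSE)
    add_pause(config$pause_s)
  }
  t_run_end <- t_cur

  run_rows <- Filter(function(s) !is.na(s$run_id), segs)
  runs_gt <- data.frame(
    run_id = vapply(run_rows, `[[`, integer(1), "run_id"),
    t_start = vapply(run_rows, `[[`, numeric(1), "t0"),
    t_end = vapply(run_rows, `[[`, numeric(1), "t1"),
    direction = vapply(run_rows, `[[`, integer(1), "direction"),
    speed_cms = vapply(run_rows, `[[`, numeric(1), "speed"),
    successful = vapply(run_rows, `[[`, logical(1), "successful"))

  ## RUN tracking
  t_tr <- seq(0, t_run_end, by = 1 / fs_tr)
  pos <- numeric(length(t_tr))
  spd <- numeric(length(t_tr))
  dirv <- integer(length(t_tr))
  for (s in segs) {
    ii <- t_tr >= s$t0 & t_tr < s$t1 + 1e-12
    frac <- if (s$t1 > s$t0) (t_tr[ii] - s$t0) / (s$t1 - s$t0) else 0
    pos[ii] <- s$x0 + frac * (s$x1 - s$x0)
    spd[ii] <- s$speed
    dirv[ii] <- s$direction
  }
  run_tracking <- data.frame(t_s = t_tr, pos_cm = pos, speed_cms = spd,
                             direction = dirv)

  ## ---- Cells and their ground-truth fields ----
  n_cells <- config$n_cells
  margin <- geom$end_margin + config$field_width / 2
  centres <- seq(margin, L - margin, length.out = n_cells)
  cells_gt <- data.frame(
    cell_id = seq_len(n_cells),
    centre_cm = centres,
    width_cm = config$field_width,
    peak_rate_hz = config$peak_rate,
    theta_slope = config$theta_slope,
    ripple_slope = config$ripple_slope)

  ## ---- RUN spikes: inhomogeneous Poisson with theta phase coding ----
  f_th <- config$theta_hz
  dt <- 1 / fs_tr
  moving <- spd > 0
  spike_list <- list()
  for (j in seq_len(n_cells)) {
    c_cm <- cells_gt$centre_cm[j]
    W <- cells_gt$width_cm[j]
    sigma <- W / 4
    rate <- cells_gt$peak_rate_hz[j] *
      exp(-(pos[moving] - c_cm)^2 / (2 * sigma^2))
    counts <- stats::rpois(length(rate), rate * dt)
    if (sum(counts) == 0) next
    src <- rep(which(moving)[counts > 0], counts[counts > 0])
    t_raw <- t_tr[src] + stats::runif(length(src), 0, dt)
    x_s <- pos[src] + spd[src] * dirv[src] * (t_raw - t_tr[src])
    d <- (dirv[src] * (x_s - c_cm) + W / 2) / W
    infield <- d >= 0 & d <= 1
    if (!any(infield)) next
    t_raw <- t_raw[infield]; d <- d[infield]; src <- src[infield]
    target <- wrap_2pi(config$phase_intercept +
                         cells_gt$theta_slope[j] * (d - 0.5) +
                         stats::rnorm(length(d), 0, config$phase_noise_sd))
    t_snap <- (round(f_th * t_raw - target / (2 * pi)) +
                 target / (2 * pi)) / f_th
    run_of <- vapply(t_raw, function(tt) {
      hit <- runs_gt$t_start <= tt & runs_gt$t_end > tt
      if (any(hit)) runs_gt$run_id[which(hit)[1]] else NA_integer_
    }, integer(1))
    keep <- t_snap >= 0 & t_snap <= t_run_end & !is.na(run_of)
    if (!any(keep)) next
    spike_list[[length(spike_list) + 1L]] <- data.frame(
      cell_id = j, t_s = t_snap[keep], origin = "run",
      origin_id = run_of[keep], d = d[keep], phase = target[keep])
  }

  ## ---- REST epoch ----
  rest_start <- t_run_end
  rest_end <- t_run_end + config$rest_duration
  rest_tracking <- data.frame(
    t_s = seq(rest_start + 1 / fs_tr, rest_end, by = 1 / fs_tr),
    pos_cm = 2, speed_cms = 0, direction = 0L)

  n_ev <- config$n_replay_events
  events_gt <- data.frame(event_id = integer(0), start_s = numeric(0),
                          end_s = numeric(0), start_cm = numeric(0),
                          direction = integer(0), speed_cms = numeric(0),
                          clipped = logical(0))
  n_rest <- as.integer(round(config$rest_duration * fs))
  n_run_lfp <- as.integer(round(t_run_end * fs))
  rest_lfp <- stats::rnorm(n_rest, 0, config$lfp_noise_sd)
  ev_spikes <- list()
  if (n_ev > 0) {
    usable <- c(rest_start + 5, rest_end - 5)
    spacing <- diff(usable) / n_ev
    if (spacing < config$event_duration + config$min_event_gap)
      stop("replay event density implies overlapping events; reduce ",
           "n_replay_events or extend rest_duration")
    jit <- max(0, min(0.5, (spacing - config$event_duration -
                              config$min_event_gap) / 2))
    starts <- usable[1] + spacing * (seq_len(n_ev) - 0.5) +
      stats::runif(n_ev, -jit, jit)
    for (e in seq_len(n_ev)) {
      dir <- sample(c(1L, -1L), 1)
      v <- stats::runif(1, config$replay_speed_range[1],
                        config$replay_speed_range[2])
      path <- v * config$event_duration
      x0 <- if (dir > 0) stats::runif(1, 0, max(1e-6, L - path)) else
        stats::runif(1, min(L, path), L)
      ev <- generate_replay_event(
        list(start_cm = x0, direction = dir, speed_cms = v),
        cells_gt, config)
      # align the event start to the LFP sample grid so that the injected
      # ripple phase convention holds exactly at spike times
      i0 <- as.integer(round((starts[e] - rest_start) * fs))
      t0 <- (n_run_lfp + i0) / fs
      idx <- i0 + seq_along(ev$lfp)
      rest_lfp[idx] <- rest_lfp[idx] + ev$lfp
      if (nrow(ev$spikes)) {
        ev_spikes[[length(ev_spikes) + 1L]] <- data.frame(
          cell_id = ev$spikes$cell_id, t_s = t0 + ev$spikes$t_rel,
          origin = "event", origin_id = e, d = ev$spikes$d,
          phase = ev$spikes$phase)
      }
      events_gt[e, ] <- list(e, t0, t0 + ev$duration, x0, dir, v, ev$clipped)
    }
  }

  ## background REST spiking (homogeneous Poisson per cell)
  for (j in seq_len(n_cells)) {
    n_bg <- stats::rpois(1, config$background_rate * config$rest_duration)
    if (n_bg == 0) next
    spike_list[[length(spike_list) + 1L]] <- data.frame(
      cell_id = j, t_s = sort(stats::runif(n_bg, rest_start, rest_end)),
      origin = "background", origin_id = NA_integer_, d = NA_real_,
      phase = NA_real_)
  }

  cells <- data.frame(cell_id = seq_len(n_cells), pyramidal = TRUE)
  if (config$include_distractor) {
    did <- n_cells + 1L
    n_d <- stats::rpois(1, config$distractor_rate * rest_end)
    spike_list[[length(spike_list) + 1L]] <- data.frame(
      cell_id = did, t_s = sort(stats::runif(n_d, 0, rest_end)),
      origin = "distractor", origin_id = NA_integer_, d = NA_real_,
      phase = NA_real_)
    cells <- rbind(cells, data.frame(cell_id = did, pyramidal = TRUE))
  }

  all_spikes <- do.call(rbind, c(spike_list, ev_spikes))
  all_spikes <- all_spikes[order(all_spikes$t_s), , drop = FALSE]
  rownames(all_spikes) <- NULL

  ## ---- LFP assembly ----
  t_lfp_run <- (seq_len(n_run_lfp) - 1L) / fs
  run_lfp <- config$theta_amp * cos(2 * pi * f_th * t_lfp_run) +
    stats::rnorm(n_run_lfp, 0, config$lfp_noise_sd)
  ch1 <- c(run_lfp, rest_lfp)
  lfp <- matrix(ch1, ncol = 1)
  if (config$n_lfp_channels > 1) {
    extra <- vapply(seq_len(config$n_lfp_channels - 1L), function(k)
      stats::rnorm(length(ch1), 0, config$lfp_noise_sd), numeric(length(ch1)))
    lfp <- cbind(lfp, extra)
  }

  tracking <- rbind(run_tracking, rest_tracking)
  epochs <- data.frame(name = c("run", "rest"),
                       start_s = c(0, rest_start),
                       end_s = c(rest_start, rest_end))

  structure(list(
    tracking = tracking,
    spikes = all_spikes[, c("cell_id", "t_s")],
    cells = cells,
    lfp = lfp,
    lfp_fs = fs,
    lfp_t0 = 0,
    epochs = epochs,
    ground_truth = list(cells = cells_gt, events = events_gt, runs = runs_gt,
                        spikes = all_spikes),
    config = config,
    seed = seed), class = "replay_session")
}

#' @export
print.replay_session <- function(x, ...) {
  cat(sprintf(paste0("synthetic session: %d cells, %d spikes, RUN %.0f s / ",
                     "REST %.0f s, %d replay events (seed %d)\n"),
              nrow(x$cells), nrow(x$spikes),
              x$epochs$end_s[1], diff(unlist(x$epochs[2, 2:3])),
              nrow(x$ground_truth$events), x$seed))
  invisible(x)
}

#' Write a session bundle to disk
#'
#' Writes the plain-text/binary bundle layout: `tracking.csv`, `spikes.csv`,
#' `cells.csv`, `lfp.bin` (little-endian float32, channel blocks) +
#' `lfp.json`, `ground_truth.json` and `config.yaml`. Times are stored to ns
#' precision and positions to 0.01 cm.
#'
#' @param session a `replay_session`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- session$tracking
  tr$t_s <- sprintf("%.9f", tr$t_s)
  tr$pos_cm <- sprintf("%.4f", tr$pos_cm)
  tr$speed_cms <- sprintf("%.6f", tr$speed_cms)
  utils::write.csv(tr, file.path(path, "tracking.csv"), row.names = FALSE,
                   quote = FALSE)
  sp <- session$spikes
  sp$t_s <- sprintf("%.9f", sp$t_s)
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(session$cells, file.path(path, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  con <- file(file.path(path, "lfp.bin"), "wb")
  writeBin(as.numeric(session$lfp), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(sample_rate_hz = session$lfp_fs, t0_s = session$lfp_t0,
         n_samples = nrow(session$lfp), n_channels = ncol(session$lfp),
         channel_ids = seq_len(ncol(session$lfp)), layout = "channel_blocks"),
    file.path(path, "lfp.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(session$ground_truth,
                       file.path(path, "ground_truth.json"),
                       digits = NA, na = "null")
  cfg <- session$config
  cfg$geometry <- unclass(cfg$geometry)[c("section_lengths", "bin_width",
                                          "end_margin", "corner_margin")]
  yaml::write_yaml(c(unclass(cfg), list(seed = session$seed),
                     list(epochs = as.list(session$epochs))),
                   file.path(path, "config.yaml"))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path bundle directory written by [write_session()].
#' @return a `replay_session`.
#' @export
read_session <- function(path) {
  need <- c(tracking = "tracking.csv", spikes = "spikes.csv",
            cells = "cells.csv", lfp = "lfp.bin", lfp_meta = "lfp.json",
            ground_truth = "ground_truth.json", config = "config.yaml")
  for (comp in names(need)) {
    if (!file.exists(file.path(path, need[[comp]])))
      stop("malformed session bundle: missing component '", comp, "' (",
           need[[comp]], ")")
  }
  tracking <- utils::read.csv(file.path(path, "tracking.csv"))
  if (any(diff(tracking$t_s) <= 0))
    stop("tracking timestamps are not strictly increasing")
  spikes <- utils::read.csv(file.path(path, "spikes.csv"))
  cells <- utils::read.csv(file.path(path, "cells.csv"))
  meta <- jsonlite::read_json(file.path(path, "lfp.json"), simplifyVector = TRUE)
  con <- file(file.path(path, "lfp.bin"), "rb")
  raw <- readBin(con, numeric(), n = meta$n_samples * meta$n_channels,
                 size = 4L, endian = "little")
  close(con)
  lfp <- matrix(raw, nrow = meta$n_samples, ncol = meta$n_channels)
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)
  cfgl <- yaml::read_yaml(file.path(path, "config.yaml"))
  epochs <- as.data.frame(cfgl$epochs)
  seed <- cfgl$seed
  cfgl$seed <- NULL
  cfgl$epochs <- NULL
  cfgl$geometry <- do.call(track_geometry, cfgl$geometry)
  cfg <- do.call(session_config, cfgl)
  structure(list(tracking = tracking, spikes = spikes, cells = cells,
                 lfp = lfp, lfp_fs = meta$sample_rate_hz, lfp_t0 = meta$t0_s,
                 epochs = epochs, ground_truth = gt, config = cfg,
                 seed = seed), class = "replay_session")
}
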