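# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# phase series of a pure tone (cos convention: phase = 2*pi*f*t mod 2*pi)
tone_phase_series <- function(f, fs, dur) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  instantaneous_phase_amplitude(cos(2 * pi * f * t), fs, band = c(f / 2, 2 * f))
}

# phase series of band-limited noise (phase drifts, so time-shift surrogates
# genuinely decorrelate)
noise_phase_series <- function(band, fs, dur, seed = 1) {
  set.seed(seed)
  x <- bandpass_filter(stats::rnorm(round(dur * fs)), band, fs)
  instantaneous_phase_amplitude(x, fs, band = band)
}

# spike time at which a tone of frequency f has the requested phase,
# in the cycle nearest `near`
time_at_phase <- function(phase, near, f) {
  (round(f * near - phase / (2 * pi)) + phase / (2 * pi)) / f
}

# a small generated session reused across test files
small_session <- function() {
  fixture("small_session", function()
    generate_session(session_config(n_cells = 12, n_runs = 6,
                                    rest_duration = 150,
                                    n_replay_events = 12,
                                    replay_speed_range = c(600, 1500),
                                    spikes_per_crossing = 4),
                     seed = 42))
}

session_ripple_phase <- function(s) {
  fixture("small_session_ripple", function()
    instantaneous_phase_amplitude(
      bandpass_filter(s$lfp[, 1], c(150, 250), s$lfp_fs), s$lfp_fs,
      s$lfp_t0, c(150, 250)))
}

session_theta_phase <- function(s) {
  fixture("small_session_theta", function()
    instantaneous_phase_amplitude(
      bandpass_filter(s$lfp[, 1], c(6, 12), s$lfp_fs), s$lfp_fs,
      s$lfp_t0, c(6, 12)))
}

# analytic (generative) rate maps from a session's ground truth
analytic_maps <- function(s) {
  geom <- s$config$geometry
  gt <- s$ground_truth$cells
  t(vapply(seq_len(nrow(gt)), function(j)
    gt$peak_rate_hz[j] *
      exp(-(geom$bin_centres - gt$centre_cm[j])^2 /
            (2 * (gt$width_cm[j] / 4)^2)),
    numeric(geom$n_bins)))
}

# ground-truth place-field table (both directions) for pooling helpers
truth_fields <- function(s) {
  gt <- s$ground_truth$cells
  do.call(rbind, lapply(c(1L, -1L), function(dirn)
    data.frame(cell_id = gt$cell_id, direction = dirn,
               left_cm = gt$centre_cm - gt$width_cm / 2,
               right_cm = gt$centre_cm + gt$width_cm / 2,
               peak_cm = gt$centre_cm)))
}

# event spike counts binned for decoding
event_counts <- function(ev_spikes, n_cells, t0, duration, tbin) {
  n_t <- max(1L, as.integer(round(duration / tbin)))
  counts <- matrix(0L, n_cells, n_t)
  if (nrow(ev_spikes)) {
    ti <- pmin(pmax(floor((ev_spikes$t_rel - t0) / tbin) + 1L, 1L), n_t)
    for (k in seq_len(nrow(ev_spikes)))
      counts[ev_spikes$cell_id[k], ti[k]] <- counts[ev_spikes$cell_id[k], ti[k]] + 1L
  }
  counts
}
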