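# Candidate replay event detection (MUA and ripple-power methods), theta
# spike trains, and movement events.

# Shared morphology/exclusion chain: a z-scored activation trace is cut into
# contiguous z >= 0 spans containing a z >= 3 peak, nearby spans are merged,
# and events are dropped by duration, participation and running speed.
detect_events_from_trace <- function(trace, fs, t0, spikes, cells, tracking,
                                     method,
                                     peak_z = 3,
                                     merge_gap = 0.04,
                                     min_duration = 0.04,
                                     max_duration = 0.5,
                                     min_cells = 5,
                                     min_cell_frac = 0.15,
                                     max_median_speed = 10) {
  mu <- mean(trace)
  sdv <- stats::sd(trace)
  if (!is.finite(sdv) || sdv == 0) return(empty_events(method))
  z <- (trace - mu) / sdv
  spans <- logical_spans(z >= 0)
  if (nrow(spans) == 0) return(empty_events(method))
  peak_ok <- vapply(seq_len(nrow(spans)), function(i)
    max(z[spans$start[i]:spans$end[i]]) >= peak_z, logical(1))
  spans <- spans[peak_ok, , drop = FALSE]
  if (nrow(spans) == 0) return(empty_events(method))
  start_s <- t0 + (spans$start - 1L) / fs
  end_s <- t0 + spans$end / fs
  m <- merge_intervals(start_s, end_s, merge_gap)
  dur <- m$end - m$start
  m <- m[dur > min_duration, , drop = FALSE]
  if (nrow(m) == 0) return(empty_events(method))

  pyr_ids <- cells$cell_id[cells$pyramidal]
  n_pyr <- length(pyr_ids)
  need <- max(min_cells, min_cell_frac * n_pyr)
  keep <- logical(nrow(m))
  active <- vector("list", nrow(m))
  n_active <- integer(nrow(m))
  peak_s <- numeric(nrow(m))
  med_speed <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    sel <- spikes$t_s >= m$start[i] & spikes$t_s <= m$end[i] &
      spikes$cell_id %in% pyr_ids
    ids <- sort(unique(spikes$cell_id[sel]))
    active[[i]] <- ids
    n_active[i] <- length(ids)
    i0 <- sample_index(m$start[i], t0, fs, length(z))
    i1 <- sample_index(m$end[i], t0, fs, length(z))
    peak_s[i] <- t0 + (i0 + which.max(z[i0:i1]) - 2L) / fs + 0.5 / fs
    tsel <- tracking$t_s >= m$start[i] & tracking$t_s <= m$end[i]
    med_speed[i] <- if (any(tsel)) stats::median(tracking$speed_cms[tsel]) else
      track_interp(tracking, "speed_cms", (m$start[i] + m$end[i]) / 2)
    keep[i] <- n_active[i] >= need && med_speed[i] <= max_median_speed &&
      (m$end[i] - m$start[i]) <= max_duration
  }
  out <- data.frame(start_s = m$start[keep], end_s = m$end[keep],
                    peak_s = peak_s[keep], n_active = n_active[keep],
                    median_speed_cms = med_speed[keep],
                    method = rep(method, sum(keep)), stringsAsFactors = FALSE)
  out$active_cells <- active[keep]
  out[order(out$start_s), , drop = FALSE]
}

empty_events <- function(method) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    peak_s = numeric(0), n_active = integer(0),
                    median_speed_cms = numeric(0),
                    method = character(0), stringsAsFactors = FALSE)
  out$active_cells <- list()
  out
}

# merge intervals separated by <= max_gap; idempotent
merge_intervals <- function(start, end, max_gap) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) == 0) return(data.frame(start = start, end = end))
  ms <- start[1]; me <- end[1]
  outs <- c(); oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] - me <= max_gap) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

#' Detect candidate replay events from multi-unit activity
#'
#' Pools spikes of all putative pyramidal cells into a 1 ms histogram,
#' smooths it with a 5 ms SD Gaussian kernel, z-scores it over the epoch, and
#' extracts contiguous periods of Z >= 0 containing a peak Z >= 3. Events
#' separated by <= 40 ms are merged; events with duration <= 40 ms, fewer
#' active cells than `max(5, 15%)` of pyramidal cells, median running speed
#' > 10 cm/s, or duration > 0.5 s are excluded.
#'
#' @param spikes data.frame with `cell_id`, `t_s`.
#' @param cells data.frame with `cell_id`, `pyramidal`.
#' @param tracking data.frame with `t_s`, `speed_cms`.
#' @param epoch c(start, end) seconds delimiting the analyzed epoch.
#' @param bin_s MUA histogram bin (s).
#' @param smooth_sd_s Gaussian smoothing SD (s).
#' @param ... thresholds passed to the shared detection chain.
#' @return data.frame of events: `start_s`, `end_s`, `peak_s`, `n_active`,
#'   `median_speed_cms`, `method`, and list-column `active_cells`.
#' @export
detect_candidate_events_mua <- function(spikes, cells, tracking, epoch,
                                        bin_s = 0.001, smooth_sd_s = 0.005,
                                        ...) {
  pyr <- cells$cell_id[cells$pyramidal]
  sel <- spikes$cell_id %in% pyr & spikes$t_s >= epoch[1] &
    spikes$t_s < epoch[2]
  n_bins <- as.integer(ceiling(diff(epoch) / bin_s))
  counts <- tabulate(
    pmin(pmax(floor((spikes$t_s[sel] - epoch[1]) / bin_s) + 1L, 1L), n_bins),
    nbins = n_bins)
  trace <- smooth_gaussian(counts, smooth_sd_s / bin_s)
  detect_events_from_trace(trace, fs = 1 / bin_s, t0 = epoch[1],
                           spikes = spikes, cells = cells,
                           tracking = tracking, method = "mua", ...)
}

#' Detect candidate replay events from ripple-band power
#'
#' Filters one LFP channel in the ripple band, extracts the Hilbert envelope,
#' smooths it with a 5 ms SD Gaussian kernel, and applies the same
#' z-score/morphology/exclusion chain as [detect_candidate_events_mua()].
#'
#' @param lfp numeric vector, one LFP channel covering `epoch`.
#' @param fs LFP sample rate (Hz; must exceed 500 Hz).
#' @param t0 time of first LFP sample (s).
#' @param spikes,cells,tracking,epoch as in [detect_candidate_events_mua()].
#' @param band ripple band (Hz pair).
#' @param smooth_sd_s envelope smoothing SD (s).
#' @param ... thresholds passed to the shared detection chain.
#' @return data.frame of events (see [detect_candidate_events_mua()]).
#' @export
detect_candidate_events_ripple <- function(lfp, fs, t0, spikes, cells,
                                           tracking, epoch,
                                           band = c(150, 250),
                                           smooth_sd_s = 0.005, ...) {
  if (fs <= 500) stop("LFP sample rate must exceed 500 Hz for ripple detection")
  i0 <- sample_index(epoch[1], t0, fs, length(lfp))
  i1 <- sample_index(epoch[2], t0, fs, length(lfp))
  seg <- lfp[i0:i1]
  filt <- bandpass_filter(seg, band, fs)
  env <- instantaneous_phase_amplitude(filt, fs)$amplitude
  trace <- smooth_gaussian(env, smooth_sd_s * fs)
  detect_events_from_trace(trace, fs = fs, t0 = t0 + (i0 - 1L) / fs,
                           spikes = spikes, cells = cells,
                           tracking = tracking, method = "ripple", ...)
}

#' Classify events: n-spike flag and online/offline context
#'
#' An event is an "n-spike" event when at least one active cell fires >= 3
#' spikes within it; its context is "offline" when it falls inside the REST
#' epoch and "online" otherwise (online events have already passed the
#' immobility filter at detection time).
#'
#' @param events event data.frame from a detector.
#' @param spikes data.frame with `cell_id`, `t_s`.
#' @param epochs data.frame with `name`, `start_s`, `end_s`.
#' @return `events` with added `is_nspike`, `n_spike_cells` (list-column) and
#'   `context` columns.
#' @export
classify_events <- function(events, spikes, epochs) {
  rest <- epochs[epochs$name == "rest", , drop = FALSE]
  is_n <- logical(nrow(events))
  nsc <- vector("list", nrow(events))
  ctx <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    sel <- spikes$t_s >= events$start_s[i] & spikes$t_s <= events$end_s[i] &
      spikes$cell_id %in% events$active_cells[[i]]
    tab <- table(spikes$cell_id[sel])
    ids <- as.integer(names(tab)[tab >= 3])
    nsc[[i]] <- ids
    is_n[i] <- length(ids) > 0
    mid <- (events$start_s[i] + events$end_s[i]) / 2
    off <- nrow(rest) > 0 && any(mid >= rest$start_s & mid <= rest$end_s)
    ctx[i] <- if (off) "offline" else "online"
  }
  events$is_nspike <- is_n
  events$n_spike_cells <- nsc
  events$context <- ctx
  events
}

#' Detect movement-related theta spike trains for one cell
#'
#' Speed-qualified spikes are binned at 5 ms, smoothed with an 80 ms SD
#' Gaussian kernel and converted to a rate; contiguous periods with rate
#' >= 1 Hz are merged across gaps <= 500 ms, and trains shorter than 500 ms
#' or with fewer than 3 spikes are discarded. With
#' `restrict_first_per_cycle`, trains whose spikes span fewer than 3 theta
#' cycles are also discarded and the per-cycle first spikes are reported.
#'
#' @param spike_times spike times of one cell (s).
#' @param tracking data.frame with `t_s`, `speed_cms`.
#' @param theta a theta-band [phase_series()] used to assign cycles.
#' @param epoch c(start, end) seconds.
#' @param min_speed running-speed threshold (cm/s).
#' @param restrict_first_per_cycle apply the first-spike-per-cycle rule.
#' @return data.frame with `start_s`, `end_s`, `n_spikes`, `n_cycles` and
#'   list-columns `spike_times`, `cycle_first_spikes`.
#' @export
detect_theta_spike_trains <- function(spike_times, tracking, theta, epoch,
                                      min_speed = 10, bin_s = 0.005,
                                      smooth_sd_s = 0.08, min_rate = 1,
                                      merge_gap = 0.5, min_duration = 0.5,
                                      restrict_first_per_cycle = FALSE) {
  st <- spike_times[spike_times >= epoch[1] & spike_times < epoch[2]]
  st <- st[track_interp(tracking, "speed_cms", st) >= min_speed]
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), n_cycles = integer(0))
  empty$spike_times <- list(); empty$cycle_first_spikes <- list()
  if (length(st) < 3) return(empty)
  n_bins <- as.integer(ceiling(diff(epoch) / bin_s))
  counts <- tabulate(pmin(floor((st - epoch[1]) / bin_s) + 1L, n_bins),
                     nbins = n_bins)
  rate <- smooth_gaussian(counts, smooth_sd_s / bin_s) / bin_s
  spans <- logical_spans(rate >= min_rate)
  if (nrow(spans) == 0) return(empty)
  iv <- merge_intervals(epoch[1] + (spans$start - 1L) * bin_s,
                        epoch[1] + spans$end * bin_s, merge_gap)
  iv <- iv[iv$end - iv$start >= min_duration, , drop = FALSE]
  if (nrow(iv) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    s <- st[st >= iv$start[i] & st <= iv$end[i]]
    if (length(s) < 3) next
    cyc <- cycle_index(theta, s)
    firsts <- s[!duplicated(cyc)]
    n_cyc <- length(unique(cyc))
    if (restrict_first_per_cycle && n_cyc < 3) next
    row <- data.frame(start_s = iv$start[i], end_s = iv$end[i],
                      n_spikes = length(s), n_cycles = n_cyc)
    row$spike_times <- list(s)
    row$cycle_first_spikes <- list(firsts)
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Detect movement events
#'
#' Maximal intervals of continuous running at or above `min_speed` lasting at
#' least `min_duration` seconds.
#'
#' @param tracking data.frame with `t_s`, `speed_cms`.
#' @param min_speed threshold (cm/s, default 10).
#' @param min_duration minimum duration (s, default 1).
#' @return data.frame with `start_s`, `end_s`.
#' @export
detect_movement_events <- function(tracking, min_speed = 10,
                                   min_duration = 1) {
  spans <- logical_spans(tracking$speed_cms >= min_speed)
  if (nrow(spans) == 0) return(data.frame(start_s = numeric(0),
                                          end_s = numeric(0)))
  out <- data.frame(start_s = tracking$t_s[spans$start],
                    end_s = tracking$t_s[spans$end])
  out[out$end_s - out$start_s >= min_duration, , drop = FALSE]
}

# cycle index of each time relative to a phase series: number of descending
# phase wraps (jumps > pi downward) before that time
cycle_index <- function(ps, t) {
  wraps <- which(diff(ps$phase) < -pi)
  wrap_t <- ps$t0 + wraps / ps$fs
  findInterval(t, wrap_t)
}

# times of cycle boundaries (descending phase wraps) within an interval
cycle_boundaries <- function(ps, start_s, end_s) {
  i0 <- sample_index(start_s, ps$t0, ps$fs, length(ps$phase))
  i1 <- sample_index(end_s, ps$t0, ps$fs, length(ps$phase))
  seg <- ps$phase[i0:i1]
  w <- which(diff(seg) < -pi)
  ps$t0 + (i0 - 1L + w) / ps$fs
}
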