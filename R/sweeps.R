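# Theta sweeps during movement and ripple-band sweeps during replay.

# shared core: given per-spike (phase, relative distance) pairs and cycle
# durations, bin by phase, regress median distance on phase-bin centre over
# the configured range, and convert to range and speed
sweep_from_pairs <- function(phase, dist, cycle_durations, n_bins,
                             phase_range, context, min_fields = 1,
                             n_fields = NA_integer_) {
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  centres <- edges[-1] - diff(edges)[1] / 2
  bin <- pmin(pmax(findInterval(phase, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  med <- vapply(seq_len(n_bins), function(b)
    if (any(bin == b)) stats::median(dist[bin == b]) else NA_real_,
    numeric(1))
  in_range <- centres >= phase_range[1] & centres <= phase_range[2]
  use <- in_range & !is.na(med)
  if (sum(use) < 2 || (!is.na(n_fields) && n_fields < min_fields))
    return(structure(list(included = FALSE, context = context,
                          n_bins_used = sum(use), n_fields = n_fields,
                          bin_centres = centres, bin_medians = med),
                     class = "sweep_estimate"))
  co <- stats::coef(stats::lm(med[use] ~ centres[use]))
  slope <- unname(co[2])
  range_cm <- slope * diff(phase_range)
  mean_cycle <- mean(cycle_durations)
  structure(list(included = TRUE, context = context,
                 slope_cm_per_rad = slope, range_cm = range_cm,
                 speed_cms = range_cm / mean_cycle,
                 direction_consistent = slope > 0,
                 bin_centres = centres, bin_medians = med,
                 n_bins_used = sum(use), n_fields = n_fields,
                 mean_cycle_s = mean_cycle),
            class = "sweep_estimate")
}

#' @export
print.sweep_estimate <- function(x, ...) {
  if (!x$included) {
    cat(sprintf("%s sweep: excluded (%d usable phase bins)\n", x$context,
                x$n_bins_used))
  } else {
    cat(sprintf("%s sweep: %.1f cm per cycle (%.0f cm/s), slope %.2f cm/rad%s\n",
                x$context, x$range_cm, x$speed_cms, x$slope_cm_per_rad,
                if (x$direction_consistent) ", direction-consistent" else ""))
  }
  invisible(x)
}

# nearest field peak of a cell (one direction); NA when the cell has no field
nearest_field_peak <- function(fields, cell, ref_pos) {
  ff <- fields[fields$cell_id == cell, , drop = FALSE]
  if (nrow(ff) == 0) return(NA_real_)
  ff$peak_cm[which.min(abs(ff$peak_cm - ref_pos))]
}

#' Theta sweep for one movement event
#'
#' For every theta cycle in the event, the first spike of each active cell is
#' assigned the signed distance (along the movement direction) from the
#' animal's mean position in that cycle to the peak of the cell's nearest
#' same-direction place field. Distances are binned into `n_bins` equal theta
#' phase bins; the per-bin medians are regressed on phase-bin centre over
#' `phase_range`, giving the sweep slope (cm/rad), the per-cycle range
#' (slope x range width) and the equivalent speed (range / mean cycle
#' duration).
#'
#' @param start_s,end_s movement-event interval (s).
#' @param spikes data.frame with `cell_id`, `t_s`.
#' @param fields place fields (with `cell_id`) for the movement direction.
#' @param theta normalized theta [phase_series()].
#' @param tracking data.frame with `t_s`, `pos_cm`.
#' @param direction movement direction (+1/-1 along the track axis).
#' @param n_bins number of phase bins (default 10).
#' @param phase_range regression range (rad, default c(0, 7*pi/5)).
#' @return object of class `sweep_estimate`.
#' @export
theta_sweep <- function(start_s, end_s, spikes, fields, theta, tracking,
                        direction, n_bins = 10,
                        phase_range = c(0, 7 * pi / 5)) {
  b <- cycle_boundaries(theta, start_s, end_s)
  edges <- sort(unique(c(start_s, b, end_s)))
  ph <- c(); dist <- c(); used_fields <- character(0)
  for (k in seq_len(length(edges) - 1L)) {
    c0 <- edges[k]; c1 <- edges[k + 1L]
    tsel <- tracking$t_s >= c0 & tracking$t_s < c1
    if (!any(tsel)) next
    mean_pos <- mean(tracking$pos_cm[tsel])
    sel <- spikes$t_s >= c0 & spikes$t_s < c1
    sp <- spikes[sel, , drop = FALSE]
    if (nrow(sp) == 0) next
    sp <- sp[order(sp$t_s), , drop = FALSE]
    sp <- sp[!duplicated(sp$cell_id), , drop = FALSE]  # first spike per cell
    for (r in seq_len(nrow(sp))) {
      peak <- nearest_field_peak(fields, sp$cell_id[r], mean_pos)
      if (is.na(peak)) next
      ph <- c(ph, phase_at(theta, sp$t_s[r]))
      dist <- c(dist, (peak - mean_pos) * direction)
      used_fields <- c(used_fields, paste(sp$cell_id[r], round(peak)))
    }
  }
  if (length(ph) == 0)
    return(sweep_from_pairs(numeric(0), numeric(0), NA_real_, n_bins,
                            phase_range, "theta"))
  sweep_from_pairs(ph, dist, diff(edges), n_bins, phase_range, "theta",
                   n_fields = length(unique(used_fields)))
}

#' Ripple sweep for one significant replay event
#'
#' As [theta_sweep()], but the reference position in each ripple cycle is the
#' decoded location from the fitted trajectory, distances are signed along
#' the decoded movement direction, all spikes contribute by default, and the
#' regression runs over 5 phase bins in `phase_range`. Events whose spikes
#' come from fewer than two distinct fields are excluded as degenerate.
#'
#' @param start_s,end_s event interval (s).
#' @param trajectory significant `fitted_trajectory` for the event.
#' @param spikes data.frame with `cell_id`, `t_s`.
#' @param fields place fields (with `cell_id`) for the decoded map direction.
#' @param ripple normalized ripple [phase_series()].
#' @param track_length track length (cm).
#' @param n_bins number of phase bins (default 5).
#' @param phase_range regression range (rad, default c(2*pi/5, 2*pi)).
#' @param first_per_cycle restrict to each cell's first spike per ripple
#'   cycle (default FALSE: all spikes).
#' @param direction decoded movement direction; defaults to the sign of the
#'   trajectory speed.
#' @return object of class `sweep_estimate`.
#' @export
ripple_sweep <- function(start_s, end_s, trajectory, spikes, fields, ripple,
                         track_length, n_bins = 5,
                         phase_range = c(2 * pi / 5, 2 * pi),
                         first_per_cycle = FALSE,
                         direction = sign(trajectory$speed_cms)) {
  locs <- cycle_decoded_locations(trajectory, ripple, start_s, end_s,
                                  track_length)
  if (nrow(locs) == 0)
    return(sweep_from_pairs(numeric(0), numeric(0), NA_real_, n_bins,
                            phase_range, "ripple", min_fields = 2,
                            n_fields = 0L))
  bounds <- c(start_s, (locs$t_mid[-1] + locs$t_mid[-nrow(locs)]) / 2, end_s)
  sel <- spikes$t_s >= start_s & spikes$t_s <= end_s
  sp <- spikes[sel, , drop = FALSE]
  ph <- c(); dist <- c(); used_fields <- character(0)
  if (nrow(sp) > 0) {
    sp <- sp[order(sp$t_s), , drop = FALSE]
    cyc <- pmin(pmax(findInterval(sp$t_s, bounds), 1L), nrow(locs))
    if (first_per_cycle)
      sp <- sp[!duplicated(data.frame(sp$cell_id, cyc)), , drop = FALSE]
    cyc <- pmin(pmax(findInterval(sp$t_s, bounds), 1L), nrow(locs))
    for (r in seq_len(nrow(sp))) {
      ref <- locs$loc_cm[cyc[r]]
      peak <- nearest_field_peak(fields, sp$cell_id[r], ref)
      if (is.na(peak)) next
      ph <- c(ph, phase_at(ripple, sp$t_s[r]))
      dist <- c(dist, (peak - ref) * direction)
      used_fields <- c(used_fields, paste(sp$cell_id[r], round(peak)))
    }
  }
  cyc_durs <- diff(bounds)
  sweep_from_pairs(ph, dist, cyc_durs, n_bins, phase_range, "ripple",
                   min_fields = 2, n_fields = length(unique(used_fields)))
}
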