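# Within-event and within-field phase precession analyses, first-spike-per-
# cycle restriction, burst index, per-cell aggregation.

#' Restrict spikes to the first spike of each oscillatory cycle
#'
#' @param spike_times ordered spike times of one cell (s).
#' @param ps a [phase_series()] defining cycle boundaries (descending phase
#'   wraps).
#' @return the retained spike times.
#' @export
first_spike_per_cycle <- function(spike_times, ps) {
  if (length(spike_times) == 0) return(spike_times)
  st <- sort(spike_times)
  st[!duplicated(cycle_index(ps, st))]
}

#' Within-event time versus phase fit for one cell
#'
#' Normalizes spike times so the cell's first spike in the event is at t = 0
#' and its last at t = 1, and returns the circular-linear regression of phase
#' on normalized time together with the successive-spike phase shifts.
#'
#' @param spike_times spike times of one cell (s).
#' @param ps band-limited [phase_series()] (normalized ripple or theta).
#' @param start_s,end_s event interval (s).
#' @param restrict_first_per_cycle keep only the first spike of each cycle
#'   (in which case >= 3 distinct cycles are required).
#' @param min_spikes minimum qualifying spikes (default 3).
#' @param ... passed to [circ_lin_regression()] (e.g. `slope_bounds`).
#' @return list with `fit` (a `circlin_fit`), `shifts`, `mean_shift`,
#'   `phases`, `n`; or NULL when the cell does not qualify.
#' @export
within_event_fit <- function(spike_times, ps, start_s, end_s,
                             restrict_first_per_cycle = FALSE,
                             min_spikes = 3, ...) {
  st <- sort(spike_times[spike_times >= start_s & spike_times <= end_s])
  if (restrict_first_per_cycle) {
    st <- first_spike_per_cycle(st, ps)
    if (length(st) < 3) return(NULL)
  }
  if (length(st) < min_spikes) return(NULL)
  if (st[length(st)] - st[1] < 1e-9) return(NULL)
  x <- (st - st[1]) / (st[length(st)] - st[1])
  phases <- phase_at(ps, st)
  if (any(is.na(phases))) return(NULL)
  fit <- circ_lin_regression(x, phases, ...)
  sh <- successive_phase_shifts(phases)
  list(fit = fit, shifts = sh$shifts, mean_shift = sh$mean_shift,
       phases = phases, times = st, n = length(st))
}

#' Aggregate within-event fits for one cell
#'
#' Averages slopes linearly and intercepts/shifts circularly across the
#' events in which the cell qualified, and pools per-pair shifts by spike-pair
#' index.
#'
#' @param fits list of non-NULL [within_event_fit()] results for one cell.
#' @param cell_id the cell's id.
#' @return one-row data.frame with `cell_id`, `n_events`, `mean_slope`,
#'   `intercept` (circular mean), `mean_shift` (circular mean of per-event
#'   mean shifts), plus list-columns `shifts_by_pair` and `all_shifts`.
#' @export
cell_precession_summary <- function(fits, cell_id) {
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(NULL)
  slopes <- vapply(fits, function(f) f$fit$slope, numeric(1))
  intercepts <- vapply(fits, function(f) f$fit$intercept, numeric(1))
  mshifts <- vapply(fits, function(f) f$mean_shift, numeric(1))
  by_pair <- list()
  for (f in fits) {
    for (k in seq_along(f$shifts)) {
      if (k > length(by_pair)) by_pair[[k]] <- numeric(0)
      by_pair[[k]] <- c(by_pair[[k]], f$shifts[k])
    }
  }
  out <- data.frame(cell_id = cell_id, n_events = length(fits),
                    mean_slope = mean(slopes),
                    intercept = circ_mean_angle(intercepts),
                    mean_shift = wrap_pi(circ_mean_angle(mshifts)))
  out$shifts_by_pair <- list(by_pair)
  out$all_shifts <- list(unlist(lapply(fits, `[[`, "shifts")))
  out
}

#' Burst index
#'
#' The proportion of inter-spike intervals of at most 200 ms that are at most
#' 10 ms.
#'
#' @param spike_times spike times of one cell (s).
#' @return burst index in \[0, 1\], or NA when the cell has fewer than two
#'   spikes or no ISI <= 200 ms.
#' @export
burst_index <- function(spike_times) {
  if (length(spike_times) < 2) return(NA_real_)
  isi <- diff(sort(spike_times))
  denom <- sum(isi <= 0.2)
  if (denom == 0) return(NA_real_)
  sum(isi <= 0.01) / denom
}

#' Within-field location versus phase fit
#'
#' Circular-linear regression of firing phase on relative distance through a
#' place field. Fields with fewer than `min_spikes` spikes or whose spikes
#' cover less than `min_coverage` of the field extent are excluded.
#'
#' @param d relative spike positions through the field, in \[0, 1\] along the
#'   (actual or decoded) movement direction.
#' @param phases spike phases (rad), same length as `d`.
#' @param min_spikes minimum spikes (default 5).
#' @param min_coverage minimum covered fraction `max(d) - min(d)` (default
#'   0.5).
#' @param ... passed to [circ_lin_regression()].
#' @return list with `fit` (a `circlin_fit`), `slope` (rad per field),
#'   `intercept`, `n`, `coverage`, `included`; when excluded, `included =
#'   FALSE` and a `reason` string.
#' @export
within_field_fit <- function(d, phases, min_spikes = 5, min_coverage = 0.5,
                             ...) {
  stopifnot(length(d) == length(phases))
  ok <- !is.na(d) & !is.na(phases)
  d <- d[ok]; phases <- phases[ok]
  if (length(d) < min_spikes)
    return(list(included = FALSE, n = length(d),
                reason = sprintf("fewer than %d spikes", min_spikes)))
  coverage <- max(d) - min(d)
  if (coverage < min_coverage)
    return(list(included = FALSE, n = length(d), coverage = coverage,
                reason = sprintf("spikes cover %.0f%% of the field",
                                 100 * coverage)))
  fit <- circ_lin_regression(d, phases, ...)
  list(fit = fit, slope = fit$slope, intercept = fit$intercept,
       n = length(d), coverage = coverage, included = TRUE)
}

# relative distance through a field along a movement direction:
# 0 at the entry edge, 1 at the exit edge
relative_field_position <- function(pos, left_cm, right_cm, direction) {
  w <- right_cm - left_cm
  if (direction > 0) (pos - left_cm) / w else (right_cm - pos) / w
}

#' Pool decoded within-field spike positions across replay events
#'
#' For each significant replay event, every spike is assigned the decoded
#' location of its ripple cycle; spikes whose decoded location falls inside a
#' field of the spiking cell (for the map direction matching the decoded
#' movement direction) contribute a (relative position, phase) pair to that
#' field, with forward and reverse passes kept as separate strata via the
#' event's movement direction.
#'
#' @param events data.frame with `start_s`, `end_s` and list-column
#'   `active_cells`.
#' @param trajectories list of `fitted_trajectory` (parallel to `events`);
#'   non-significant entries may be NULL.
#' @param spikes data.frame with `cell_id`, `t_s`.
#' @param fields data.frame from [detect_place_fields()] with an added
#'   `cell_id` column.
#' @param ripple normalized ripple [phase_series()].
#' @param track_length track length (cm).
#' @return data.frame with one row per (field, spike): `cell_id`,
#'   `direction`, `left_cm`, `right_cm`, `d`, `phase`, `event`.
#' @export
pool_within_field_ripple <- function(events, trajectories, spikes, fields,
                                     ripple, track_length) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    traj <- trajectories[[i]]
    if (is.null(traj) || !isTRUE(traj$significant)) next
    mv_dir <- if (traj$speed_cms > 0) 1L else -1L
    locs <- cycle_decoded_locations(traj, ripple, events$start_s[i],
                                    events$end_s[i], track_length)
    if (nrow(locs) == 0) next
    bounds <- c(events$start_s[i],
                (locs$t_mid[-1] + locs$t_mid[-nrow(locs)]) / 2,
                events$end_s[i])
    sel <- spikes$t_s >= events$start_s[i] & spikes$t_s <= events$end_s[i]
    sp <- spikes[sel, , drop = FALSE]
    if (nrow(sp) == 0) next
    cyc <- pmin(pmax(findInterval(sp$t_s, bounds), 1L), nrow(locs))
    sp$loc <- locs$loc_cm[cyc]
    sp$phase <- phase_at(ripple, sp$t_s)
    ff <- fields[fields$direction == mv_dir, , drop = FALSE]
    for (j in seq_len(nrow(ff))) {
      ss <- sp[sp$cell_id == ff$cell_id[j] & sp$loc >= ff$left_cm[j] &
                 sp$loc <= ff$right_cm[j], , drop = FALSE]
      if (nrow(ss) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = ff$cell_id[j], direction = mv_dir,
        left_cm = ff$left_cm[j], right_cm = ff$right_cm[j],
        d = relative_field_position(ss$loc, ff$left_cm[j], ff$right_cm[j],
                                    mv_dir),
        phase = ss$phase, event = i)
    }
  }
  if (length(rows) == 0)
    return(data.frame(cell_id = integer(0), direction = integer(0),
                      left_cm = numeric(0), right_cm = numeric(0),
                      d = numeric(0), phase = numeric(0), event = integer(0)))
  do.call(rbind, rows)
}
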