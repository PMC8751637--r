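# Run segmentation, directional firing-rate maps, place-field detection.

#' Segment shuttle runs
#'
#' Splits linearized tracking into runs between the two track end zones. A
#' successful run leaves one end zone and next enters the opposite one;
#' excursions that return to the starting end are labeled unsuccessful.
#' Direction is the sign of net displacement (+1 outbound, -1 inbound).
#'
#' @param tracking data.frame with `t_s`, `pos_cm`.
#' @param geometry a [track_geometry()]; the end zones are its `end_margin`.
#' @return data.frame with `run_id`, `t_start`, `t_end`, `direction`,
#'   `successful`.
#' @export
segment_runs <- function(tracking, geometry) {
  pos <- tracking$pos_cm
  L <- geometry$total
  m <- geometry$end_margin
  zone <- ifelse(pos <= m, 1L, ifelse(pos >= L - m, 2L, 0L))
  out <- list()
  cur_origin <- NA_integer_
  start_i <- NA_integer_
  last_zone <- zone[1]
  for (i in seq_along(zone)[-1]) {
    if (zone[i] == 0L && last_zone != 0L) {      # left a zone
      cur_origin <- last_zone
      start_i <- i - 1L
    } else if (zone[i] != 0L && last_zone == 0L && !is.na(cur_origin)) {
      success <- zone[i] != cur_origin
      dirn <- if (pos[i] > pos[start_i]) 1L else -1L
      out[[length(out) + 1L]] <- data.frame(
        t_start = tracking$t_s[start_i], t_end = tracking$t_s[i],
        direction = dirn, successful = success)
      cur_origin <- NA_integer_
    }
    if (zone[i] != 0L) last_zone <- zone[i] else last_zone <- 0L
  }
  if (length(out) == 0)
    return(data.frame(run_id = integer(0), t_start = numeric(0),
                      t_end = numeric(0), direction = integer(0),
                      successful = logical(0)))
  res <- do.call(rbind, out)
  cbind(run_id = seq_len(nrow(res)), res)
}

# Gaussian smoothing over valid bins only: the kernel is renormalized over
# the valid support, and excluded bins come back as NA.
smooth_over_valid <- function(x, valid, sd) {
  xx <- ifelse(valid, x, 0)
  num <- smooth_gaussian(xx, sd, renorm = FALSE)
  den <- smooth_gaussian(as.numeric(valid), sd, renorm = FALSE)
  out <- ifelse(den > 1e-9, num / den, NA_real_)
  out[!valid] <- NA_real_
  out
}

#' Directional firing-rate map
#'
#' Dwell time and spike counts at running speeds >= `min_speed` during
#' successful runs in one direction, binned at the geometry's bin width with
#' end/corner exclusion zones removed, each smoothed with a Gaussian kernel
#' (SD 5 bins, renormalized at edges and around exclusion gaps), and divided
#' to give rate.
#'
#' @param spike_times spike times of one cell (s).
#' @param tracking data.frame with `t_s`, `pos_cm`, `speed_cms`.
#' @param runs output of [segment_runs()] (or the generator's run table).
#' @param direction +1 (outbound) or -1 (inbound).
#' @param geometry a [track_geometry()].
#' @param min_speed speed threshold (cm/s).
#' @param smooth_sd_bins Gaussian SD in bins.
#' @return object of class `rate_map`: list with `direction`, `centres`,
#'   `rate`, `dwell`, `counts`, `valid`, `geometry`.
#' @export
compute_directional_rate_map <- function(spike_times, tracking, runs,
                                         direction, geometry,
                                         min_speed = 10,
                                         smooth_sd_bins = 5) {
  use <- runs[runs$successful & runs$direction == direction, , drop = FALSE]
  if (nrow(use) == 0) stop("no successful run in this direction")
  in_run <- function(t) {
    ok <- rep(FALSE, length(t))
    for (i in seq_len(nrow(use)))
      ok <- ok | (t >= use$t_start[i] & t <= use$t_end[i])
    ok
  }
  dt <- stats::median(diff(tracking$t_s))
  tsel <- in_run(tracking$t_s) & tracking$speed_cms >= min_speed &
    !in_exclusion_zone(tracking$pos_cm, geometry)
  bw <- geometry$bin_width
  n <- geometry$n_bins
  bin_of <- function(pos) pmin(pmax(floor(pos / bw) + 1L, 1L), n)
  dwell <- tabulate(bin_of(tracking$pos_cm[tsel]), nbins = n) * dt
  st <- spike_times[in_run(spike_times)]
  if (length(st)) {
    sp_speed <- track_interp(tracking, "speed_cms", st)
    sp_pos <- track_interp(tracking, "pos_cm", st)
    ok <- sp_speed >= min_speed & !in_exclusion_zone(sp_pos, geometry)
    st <- st[ok]; sp_pos <- sp_pos[ok]
  } else sp_pos <- numeric(0)
  counts <- tabulate(bin_of(sp_pos), nbins = n)
  if (sum(dwell) == 0) stop("zero dwell everywhere; cannot form a rate map")
  valid <- valid_track_bins(geometry)
  sm_dwell <- smooth_over_valid(dwell, valid, smooth_sd_bins)
  sm_counts <- smooth_over_valid(counts, valid, smooth_sd_bins)
  rate <- ifelse(!is.na(sm_dwell) & sm_dwell > 1e-9, sm_counts / sm_dwell,
                 NA_real_)
  structure(list(direction = direction, centres = geometry$bin_centres,
                 rate = rate, dwell = sm_dwell, counts = counts,
                 raw_dwell = dwell, valid = valid, geometry = geometry),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate map (%s): peak %.2f Hz at %.0f cm, %d bins\n",
              if (x$direction > 0) "outbound" else "inbound",
              max(x$rate, na.rm = TRUE),
              x$centres[which.max(x$rate)], length(x$rate)))
  invisible(x)
}

#' Detect place fields in a rate map
#'
#' Place fields are contiguous regions of at least `min_bins` bins whose
#' smoothed rate exceeds the across-bin mean, with a peak in-field rate of at
#' least `min_peak_rate` Hz. Exclusion-zone bins break contiguity.
#'
#' @param map a `rate_map`.
#' @param min_bins minimum field extent in bins (default 10).
#' @param min_peak_rate minimum in-field peak rate (Hz, default 1).
#' @return data.frame with `start_bin`, `end_bin`, `left_cm`, `right_cm`,
#'   `peak_cm`, `peak_hz`, `width_cm`, `direction`.
#' @export
detect_place_fields <- function(map, min_bins = 10, min_peak_rate = 1) {
  rate <- map$rate
  mu <- mean(rate, na.rm = TRUE)
  above <- !is.na(rate) & rate > mu
  spans <- logical_spans(above)
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      left_cm = numeric(0), right_cm = numeric(0),
                      peak_cm = numeric(0), peak_hz = numeric(0),
                      width_cm = numeric(0), direction = integer(0))
  if (nrow(spans) == 0) return(empty)
  rows <- list()
  bw <- map$geometry$bin_width
  for (i in seq_len(nrow(spans))) {
    ii <- spans$start[i]:spans$end[i]
    if (length(ii) < min_bins) next
    pk <- which.max(rate[ii])
    if (rate[ii][pk] < min_peak_rate) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_bin = spans$start[i], end_bin = spans$end[i],
      left_cm = map$centres[spans$start[i]] - bw / 2,
      right_cm = map$centres[spans$end[i]] + bw / 2,
      peak_cm = map$centres[ii][pk], peak_hz = rate[ii][pk],
      width_cm = length(ii) * bw, direction = map$direction)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}
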