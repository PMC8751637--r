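# Poisson Bayesian position decoding, decoding validation, replay trajectory
# fitting, and cell-identity shuffle significance.

#' Bayesian position decoding from population spike counts
#'
#' For each time bin of width `T` the posterior over spatial bins is the
#' normalized product over cells of Poisson terms with mean `T * a_i(x)`,
#' where `a_i(x)` is cell i's firing-rate map. Computation is in log space; a
#' small rate floor `eps` is added to every map to avoid zero-probability
#' lockout. Time bins with no spikes from any cell are marked undecoded.
#'
#' @param counts integer matrix, cells x time bins.
#' @param maps numeric matrix, cells x spatial bins (Hz); NA columns are
#'   excluded bins and receive zero posterior mass.
#' @param tbin time-bin duration T (s).
#' @param eps rate floor (Hz, default 0.01).
#' @param bin_centres optional spatial bin centres (cm).
#' @return object of class `posterior_matrix`: list with `prob` (spatial bins
#'   x time bins; decoded columns sum to 1), `decoded` (logical per time
#'   bin), `tbin`, `bin_centres`.
#' @export
bayes_decode <- function(counts, maps, tbin, eps = 0.01,
                         bin_centres = NULL) {
  stopifnot(nrow(counts) == nrow(maps), tbin > 0)
  valid <- !apply(maps, 2, function(col) any(is.na(col)))
  a <- maps[, valid, drop = FALSE] + eps
  la <- log(a)
  suma <- colSums(a)
  ll <- t(la) %*% counts - tbin * suma          # valid bins x time
  ll <- ll + log(tbin) * matrix(colSums(counts), nrow(ll), ncol(counts),
                                byrow = TRUE)   # constant per column
  decoded <- colSums(counts) > 0
  prob <- matrix(0, ncol(maps), ncol(counts))
  for (j in seq_len(ncol(counts))) {
    w <- ll[, j]
    w <- exp(w - max(w))
    prob[valid, j] <- w / sum(w)
  }
  prob[, !decoded] <- NA_real_
  structure(list(prob = prob, decoded = decoded, tbin = tbin,
                 bin_centres = bin_centres),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("posterior: %d spatial bins x %d time bins (%d decoded), T = %g s\n",
              nrow(x$prob), ncol(x$prob), sum(x$decoded), x$tbin))
  invisible(x)
}

#' Spike counts per cell in consecutive time bins
#'
#' @param spikes data.frame with `cell_id`, `t_s`.
#' @param cell_ids cells defining the row order.
#' @param start_s,end_s interval to bin (s).
#' @param tbin bin width (s).
#' @return integer matrix, cells x time bins.
#' @export
bin_spike_counts <- function(spikes, cell_ids, start_s, end_s, tbin) {
  n_t <- max(1L, as.integer(floor((end_s - start_s) / tbin + 1e-9)))
  counts <- matrix(0L, length(cell_ids), n_t)
  sel <- spikes$t_s >= start_s & spikes$t_s < start_s + n_t * tbin &
    spikes$cell_id %in% cell_ids
  if (any(sel)) {
    ci <- match(spikes$cell_id[sel], cell_ids)
    ti <- pmin(floor((spikes$t_s[sel] - start_s) / tbin) + 1L, n_t)
    for (k in seq_along(ci)) counts[ci[k], ti[k]] <- counts[ci[k], ti[k]] + 1L
  }
  counts
}

#' Decoding validation on the track
#'
#' Decodes position in consecutive `tbin` (default 500 ms) windows during
#' speed-qualified travel on successful runs, separately per direction, and
#' returns the median absolute error between the posterior-maximum bin centre
#' and the mean tracked position in each window.
#'
#' @param spikes data.frame with `cell_id`, `t_s` (pyramidal cells).
#' @param cell_ids cells used for decoding (rows of the map matrices).
#' @param tracking data.frame with `t_s`, `pos_cm`, `speed_cms`.
#' @param runs run table from [segment_runs()].
#' @param maps_by_direction list with `outbound` and `inbound` cells x bins
#'   matrices.
#' @param geometry a [track_geometry()].
#' @param tbin decoding window (s).
#' @param min_speed speed threshold (cm/s).
#' @return list with `outbound`, `inbound` (median errors, cm) and `detail`
#'   data.frame per time bin.
#' @export
run_decoding_validation <- function(spikes, cell_ids, tracking, runs,
                                    maps_by_direction, geometry, tbin = 0.5,
                                    min_speed = 10) {
  detail <- list()
  for (dname in c("outbound", "inbound")) {
    dirn <- if (dname == "outbound") 1L else -1L
    use <- runs[runs$successful & runs$direction == dirn, , drop = FALSE]
    maps <- maps_by_direction[[dname]]
    for (i in seq_len(nrow(use))) {
      n_t <- floor((use$t_end[i] - use$t_start[i]) / tbin)
      if (n_t < 1) next
      counts <- bin_spike_counts(spikes, cell_ids, use$t_start[i],
                                 use$t_end[i], tbin)
      post <- bayes_decode(counts, maps, tbin,
                           bin_centres = geometry$bin_centres)
      for (j in seq_len(n_t)) {
        if (!post$decoded[j]) next
        w0 <- use$t_start[i] + (j - 1) * tbin
        tsel <- tracking$t_s >= w0 & tracking$t_s < w0 + tbin
        if (!any(tsel)) next
        if (stats::median(tracking$speed_cms[tsel]) < min_speed) next
        true_pos <- mean(tracking$pos_cm[tsel])
        dec_pos <- geometry$bin_centres[which.max(post$prob[, j])]
        detail[[length(detail) + 1L]] <- data.frame(
          direction = dname, t_s = w0, true_cm = true_pos,
          decoded_cm = dec_pos, error_cm = abs(dec_pos - true_pos))
      }
    }
  }
  if (length(detail) == 0) stop("no decodable time bins")
  detail <- do.call(rbind, detail)
  med <- function(d) if (any(detail$direction == d))
    stats::median(detail$error_cm[detail$direction == d]) else NA_real_
  list(outbound = med("outbound"), inbound = med("inbound"), detail = detail)
}

# Precomputed search grid for the trajectory fit: per-candidate-speed bin
# shifts of the line at each time-bin centre, with candidate speeds ordered
# by |speed| (positive first) for deterministic tie-breaking.
make_fit_grid <- function(n_bins, n_time, tbin, bin_width,
                          speeds = seq(100, 5000, by = 50)) {
  signed <- as.vector(rbind(speeds, -speeds))   # +100, -100, +150, ...
  t_rel <- (seq_len(n_time) - 0.5) * tbin
  shift <- round(outer(signed, t_rel) / bin_width)  # n_speed x n_time
  storage.mode(shift) <- "integer"
  list(shift = shift, signed = signed, n_bins = n_bins, n_time = n_time)
}

#' Fit a constant-speed linear trajectory through a posterior matrix
#'
#' Exhaustively searches all origin bins, speeds 100-5000 cm/s in 50 cm/s
#' steps, and both directions; each candidate line is scored by the posterior
#' mass inside a 15-spatial-bin (30 cm) window centred on the line's position
#' at each decoded time-bin centre (clipped at track ends), averaged over
#' decoded bins. Ties prefer lower |speed| (positive direction first), then
#' the earlier origin.
#'
#' @param posterior a `posterior_matrix` with `bin_centres` set.
#' @param window_bins window width in bins (odd, default 15).
#' @param speeds candidate speed magnitudes (cm/s).
#' @param grid optional precomputed [make_fit_grid()] result (reused across
#'   shuffles for speed).
#' @return object of class `fitted_trajectory`: list with `origin_cm` (line
#'   position at the first time-bin centre), `speed_cms` (signed), `score`,
#'   `n_decoded`, `tbin`.
#' @export
fit_linear_trajectory <- function(posterior, window_bins = 15,
                                  speeds = seq(100, 5000, by = 50),
                                  grid = NULL) {
  prob <- posterior$prob
  dec <- posterior$decoded
  if (!any(dec)) stop("no decoded time bins")
  if (sum(dec) < 2) stop("need at least 2 decoded time bins")
  n_bins <- nrow(prob)
  n_time <- ncol(prob)
  half <- (window_bins - 1L) %/% 2L
  if (is.null(grid))
    grid <- make_fit_grid(n_bins, n_time, posterior$tbin,
                          diff(posterior$bin_centres[1:2]), speeds)
  # windowed column sums, zero for undecoded columns
  P <- prob
  P[, !dec] <- 0
  cs <- apply(P, 2, cumsum)
  hi <- pmin(seq_len(n_bins) + half, n_bins)
  lo <- pmax(seq_len(n_bins) - half, 1L)
  W <- cs[hi, , drop = FALSE] -
    rbind(0, cs)[lo, , drop = FALSE]
  res <- .fit_search_cpp(W, grid$shift)
  o <- res$origin
  s <- grid$signed[res$speed_idx]
  # origin is the line's position at the event start (t = 0)
  structure(list(origin_cm = posterior$bin_centres[o], speed_cms = s,
                 score = res$sum / sum(dec), n_decoded = sum(dec),
                 tbin = posterior$tbin, origin_bin = o),
            class = "fitted_trajectory")
}

#' @export
print.fitted_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: origin %.0f cm, speed %+d cm/s, fit score %.3f (%d decoded bins)",
              x$origin_cm, as.integer(x$speed_cms), x$score, x$n_decoded))
  if (!is.null(x$p)) cat(sprintf(", p = %.3f%s", x$p,
                                 if (isTRUE(x$significant)) " *" else ""))
  cat("\n")
  invisible(x)
}

#' Enumerate cell-identity orderings
#'
#' All distinct orderings of a set of active cells, used as the shuffle null
#' for trajectory significance. For `n` cells there are `n!` orderings (120
#' for the minimum of 5 active cells); the identity ordering is the observed
#' assignment.
#'
#' @param ids vector of cell ids (length <= 8 to enumerate).
#' @return matrix with one ordering per row.
#' @export
enumerate_cell_permutations <- function(ids) {
  p <- all_permutations(length(ids))
  matrix(ids[p], nrow(p), ncol(p))
}

#' Cell-identity shuffle significance of a fitted trajectory
#'
#' Permutes which rate map belongs to which active cell, re-decodes and
#' re-fits `n_shuffles` times, and declares the event significant when the
#' true fit score exceeds the 95th percentile of the shuffle distribution.
#' When the active cells admit no more than `n_shuffles` distinct non-identity
#' orderings, shuffles are drawn from the full enumeration without
#' replacement.
#'
#' @param counts cells x time-bins spike-count matrix for the event (rows
#'   ordered as `cell_ids`).
#' @param cell_ids cell ids for the rows of `counts`.
#' @param active_ids ids of the active cells whose map identities are
#'   shuffled.
#' @param map_sets list of cells x bins map matrices (e.g. outbound and
#'   inbound); the fit searches all sets and keeps the best score.
#' @param tbin event time-bin duration (s).
#' @param bin_centres spatial bin centres (cm).
#' @param n_shuffles number of shuffles (default 100).
#' @param prob significance percentile (default 0.95).
#' @param speeds candidate speed magnitudes (cm/s).
#' @return list with `fit` (best true fit, a `fitted_trajectory` with added
#'   `p`, `significant`, `map_set`), `null_scores`.
#' @export
trajectory_significance <- function(counts, cell_ids, active_ids, map_sets,
                                    tbin, bin_centres, n_shuffles = 100,
                                    prob = 0.95,
                                    speeds = seq(100, 5000, by = 50)) {
  if (!is.list(map_sets)) map_sets <- list(map_sets)
  n_bins <- ncol(map_sets[[1]])
  grid <- make_fit_grid(n_bins, ncol(counts), tbin,
                        diff(bin_centres[1:2]), speeds)
  act <- match(active_ids, cell_ids)
  stopifnot(!any(is.na(act)))

  decode_fit <- function(perm) {
    best <- NULL
    for (k in seq_along(map_sets)) {
      maps <- map_sets[[k]]
      maps[act, ] <- maps[act[perm], , drop = FALSE]
      post <- bayes_decode(counts, maps, tbin, bin_centres = bin_centres)
      fit <- fit_linear_trajectory(post, grid = grid, speeds = speeds)
      if (is.null(best) || fit$score > best$score) {
        best <- fit
        best$map_set <- names(map_sets)[k] %||% as.character(k)
      }
    }
    best
  }

  true_fit <- decode_fit(seq_along(act))
  m <- length(act)
  if (factorial(m) <= max(5040, n_shuffles + 1)) {
    perms <- all_permutations(m)
    ident <- apply(perms, 1, function(p) all(p == seq_len(m)))
    perms <- perms[!ident, , drop = FALSE]
    take <- sample(nrow(perms), min(n_shuffles, nrow(perms)))
    perms <- perms[take, , drop = FALSE]
  } else {
    perms <- t(replicate(n_shuffles, {
      p <- sample(m)
      while (all(p == seq_len(m))) p <- sample(m)
      p
    }))
  }
  null_scores <- vapply(seq_len(nrow(perms)),
                        function(i) decode_fit(perms[i, ])$score, numeric(1))
  # percentile as MATLAB's prctile computes it
  thr <- stats::quantile(null_scores, prob, names = FALSE, type = 5)
  true_fit$p <- (1 + sum(null_scores >= true_fit$score)) /
    (1 + length(null_scores))
  true_fit$significant <- true_fit$score > thr
  list(fit = true_fit, null_scores = null_scores)
}

#' Decoded location in each ripple cycle of a replay event
#'
#' Places the fitted trajectory at the midpoint of every ripple-band cycle
#' within the event: `location = origin + speed * (midpoint - event_start)`,
#' clipped to the track.
#'
#' @param trajectory a `fitted_trajectory`.
#' @param ripple a ripple-band [phase_series()].
#' @param start_s,end_s event interval (s); `start_s` is the trajectory
#'   origin time.
#' @param track_length track length (cm) used for clipping.
#' @return data.frame with `cycle`, `t_mid`, `loc_cm`.
#' @export
cycle_decoded_locations <- function(trajectory, ripple, start_s, end_s,
                                    track_length) {
  b <- cycle_boundaries(ripple, start_s, end_s)
  edges <- sort(unique(c(start_s, b, end_s)))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mids <- mids[mids >= start_s & mids <= end_s]
  loc <- trajectory$origin_cm + trajectory$speed_cms * (mids - start_s)
  data.frame(cycle = seq_along(mids), t_mid = mids,
             loc_cm = pmin(pmax(loc, 0), track_length))
}
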