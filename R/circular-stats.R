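#' Circular descriptive statistics
#'
#' Computes the circular mean, circular median, resultant vector length and
#' circular standard deviation of a sample of angles.
#'
#' The circular median is the sample angle that minimizes the mean absolute
#' circular deviation; ties are broken in favour of the candidate closest to
#' the circular mean. The circular SD is `sqrt(-2 log R)` and is infinite
#' (flagged via `sd_defined = FALSE`) when the resultant length is zero.
#'
#' @param angles numeric vector of angles in radians (any range).
#' @return list with `mean`, `median`, `R` (resultant length in \[0,1\]),
#'   `sd` (circular SD, radians), `sd_defined`, `n`.
#' @export
circ_descriptives <- function(angles) {
  if (length(angles) < 1) stop("need at least one angle")
  a <- wrap_2pi(angles)
  n <- length(a)
  z <- mean(exp(1i * a))
  R <- Mod(z)
  if (R < 1e-12) R <- 0
  mu <- if (R == 0) NA_real_ else wrap_2pi(Arg(z))
  sd <- if (R == 0) Inf else sqrt(-2 * log(R))
  # candidate medians are the data points themselves
  dev <- vapply(a, function(m) mean(abs(wrap_pi(a - m))), numeric(1))
  best <- which(dev <= min(dev) + 1e-12)
  med <- if (length(best) > 1 && !is.na(mu)) {
    a[best][which.min(abs(wrap_pi(a[best] - mu)))]
  } else {
    a[best[1]]
  }
  list(mean = mu, median = med, R = R, sd = sd,
       sd_defined = is.finite(sd), n = n)
}

#' Rayleigh test of circular uniformity
#'
#' @param angles numeric vector of angles in radians, `n >= 2`.
#' @return list with the test statistic `Z = n R^2`, approximate `p` value,
#'   resultant length `R` and `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least two angles")
  R <- circ_resultant(angles)
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(Z = Z, p = min(p, 1), R = R, n = n)
}

#' Sign test for a hypothesized circular median
#'
#' Tests whether angles fall symmetrically clockwise versus counter-clockwise
#' of `m0` with an exact two-sided binomial sign test. Angles exactly equal to
#' `m0` or its antipode are dropped.
#'
#' @param angles numeric vector of angles in radians.
#' @param m0 hypothesized median (radians).
#' @return list with `p`, counts `n_pos`/`n_neg` and `n_used`.
#' @export
circular_median_test <- function(angles, m0) {
  d <- wrap_pi(angles - m0)
  keep <- abs(d) > 1e-12 & abs(abs(d) - pi) > 1e-12
  d <- d[keep]
  if (length(d) == 0) stop("all angles equal to m0 or its antipode")
  n_pos <- sum(d > 0)
  p <- stats::binom.test(n_pos, length(d), 0.5)$p.value
  list(p = p, n_pos = n_pos, n_neg = length(d) - n_pos, n_used = length(d))
}

#' Circular-linear regression
#'
#' Fits `theta ~ intercept + slope * x` by maximizing the resultant vector
#' length of the residual angles `theta - slope * x` over a dense grid of
#' candidate slopes, the standard approach for phase-precession fits.
#'
#' @param x linear covariate (e.g. normalized time or position).
#' @param angles angles in radians, same length as `x`.
#' @param slope_bounds search bounds for the slope, radians per unit of `x`
#'   (default +/- 3 cycles per unit).
#' @param slope_step grid step, radians per unit (default 0.01).
#' @return object of class `circlin_fit`: list with `slope` (rad/unit),
#'   `intercept` (rad in \[0,2pi)), `rho` (circular-linear correlation),
#'   `R` (resultant at the optimum), `n`.
#' @export
circ_lin_regression <- function(x, angles, slope_bounds = c(-6 * pi, 6 * pi),
                                slope_step = 0.01) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(angles) != n) stop("x and angles must have equal length")
  if (max(x) - min(x) < 1e-12) stop("degenerate covariate: all x equal")
  # grid in integer multiples of the step so that a zero slope is on it
  grid <- seq(ceiling(slope_bounds[1] / slope_step),
              floor(slope_bounds[2] / slope_step)) * slope_step
  E <- exp(1i * angles)
  # R(s) = |sum exp(i(theta - s x))| / n, evaluated in chunks to bound memory
  Rv <- numeric(length(grid))
  chunk <- max(1L, floor(4e6 / n))
  for (i0 in seq(1L, length(grid), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(grid))
    Rv[ii] <- Mod(exp(-1i * outer(grid[ii], x)) %*% E) / n
  }
  # ties: prefer smaller |slope|
  best <- which(Rv >= max(Rv) - 1e-12)
  s <- grid[best[which.min(abs(grid[best]))]]
  resid <- angles - s * x
  intercept <- wrap_2pi(circ_mean_angle(resid))
  rho <- circ_circ_correlation(wrap_2pi(s * x), wrap_2pi(angles))
  structure(list(slope = s, intercept = intercept, rho = rho,
                 R = max(Rv), n = n),
            class = "circlin_fit")
}

# Jammalamadaka-SarmaRao circular-circular correlation
circ_circ_correlation <- function(a, b) {
  ma <- circ_mean_angle(a)
  mb <- circ_mean_angle(b)
  if (is.na(ma) || is.na(mb)) return(NA_real_)
  sa <- sin(a - ma)
  sb <- sin(b - mb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) return(NA_real_)
  sum(sa * sb) / den
}

#' @export
print.circlin_fit <- function(x, ...) {
  cat(sprintf("circular-linear fit: slope %.3f rad/unit, intercept %.3f rad, rho %.3f (n = %d)\n",
              x$slope, x$intercept, x$rho, x$n))
  invisible(x)
}

#' Phase shifts between successive spikes
#'
#' @param angles ordered spike phases in radians.
#' @return list with `shifts` (wrapped to (-pi, pi\]) and `mean_shift`
#'   (circular mean of the shifts).
#' @export
successive_phase_shifts <- function(angles) {
  if (length(angles) < 2) stop("need at least two ordered angles")
  shifts <- wrap_pi(diff(angles))
  list(shifts = shifts, mean_shift = wrap_pi(circ_mean_angle(shifts)))
}

#' Phase autocorrelogram of unwrapped spike phases
#'
#' For every ordered spike pair within an event the difference of unwrapped
#' phases is accumulated into lag bins; histograms are averaged per cell
#' across events and then across cells.
#'
#' @param unwrapped_by_cell list (per cell) of lists (per event) of numeric
#'   vectors of unwrapped phases (radians, monotone within event).
#' @param lag_max maximum phase lag (default `6*pi`).
#' @param bin_width lag bin width (default `pi/8`).
#' @return data.frame with `lag` (bin centres) and `density` (grand average
#'   pair count per bin).
#' @export
phase_autocorrelogram <- function(unwrapped_by_cell, lag_max = 6 * pi,
                                  bin_width = pi / 8) {
  edges <- seq(0, lag_max, by = bin_width)
  centres <- edges[-1] - bin_width / 2
  per_cell <- list()
  for (cell in unwrapped_by_cell) {
    hists <- list()
    for (ph in cell) {
      if (length(ph) < 2) next
      d <- unlist(lapply(seq_along(ph)[-length(ph)], function(j) ph[-seq_len(j)] - ph[j]))
      d <- d[d > 0 & d <= lag_max]
      hists[[length(hists) + 1L]] <-
        tabulate(pmin(ceiling(d / bin_width), length(centres)),
                 nbins = length(centres))
    }
    if (length(hists)) {
      per_cell[[length(per_cell) + 1L]] <- Reduce(`+`, hists) / length(hists)
    }
  }
  density <- if (length(per_cell)) Reduce(`+`, per_cell) / length(per_cell) else
    rep(0, length(centres))
  data.frame(lag = centres, density = density)
}

#' Phase-locking value with time-shift permutation test
#'
#' The observed resultant length of spike phases is compared with a null
#' distribution obtained by circularly shifting the spike train relative to
#' the phase series by random offsets of at least `min_shift` seconds.
#'
#' @param spike_times spike times (s).
#' @param phase_series a `phase_series` object (see
#'   [instantaneous_phase_amplitude()]).
#' @param n_perm number of permutations (default 1000); `0` returns the
#'   descriptive PLV only.
#' @param min_shift minimum temporal shift (s, default 30).
#' @param prob percentile defining significance (default 0.99).
#' @return object of class `phase_locking`: list with `plv`, `preferred`
#'   (rad), `threshold` (null percentile), `significant`, `null` (vector),
#'   `n_spikes`.
#' @export
plv_permutation_test <- function(spike_times, phase_series, n_perm = 1000,
                                 min_shift = 30, prob = 0.99) {
  fs <- phase_series$fs
  n <- length(phase_series$phase)
  t0 <- phase_series$t0
  epoch <- n / fs
  if (n_perm > 0 && epoch <= 2 * min_shift)
    stop("recording too short for a ", min_shift, " s minimum shift")
  ph <- phase_at(phase_series, spike_times)
  plv <- circ_resultant(ph)
  preferred <- circ_mean_angle(ph)
  if (n_perm == 0) {
    return(structure(list(plv = plv, preferred = preferred, threshold = NA_real_,
                          significant = NA, null = numeric(0),
                          n_spikes = length(spike_times)),
                     class = "phase_locking"))
  }
  shifts <- stats::runif(n_perm, min_shift, epoch - min_shift)
  rel <- spike_times - t0
  shifted <- t0 + outer(rel, shifts, `+`) %% epoch
  phm <- matrix(phase_at(phase_series, as.vector(shifted)),
                nrow = length(rel))
  null <- Mod(colSums(exp(1i * phm))) / length(rel)
  # percentile as MATLAB's prctile computes it
  threshold <- stats::quantile(null, prob, names = FALSE, type = 5)
  structure(list(plv = plv, preferred = preferred, threshold = threshold,
                 significant = plv > threshold, null = null,
                 n_spikes = length(spike_times)),
            class = "phase_locking")
}

#' @export
print.phase_locking <- function(x, ...) {
  cat(sprintf("PLV %.3f (preferred phase %.2f rad, n = %d spikes)",
              x$plv, x$preferred, x$n_spikes))
  if (!is.na(x$significant))
    cat(sprintf("; 99th pct null %.3f -> %s", x$threshold,
                if (x$significant) "significant" else "not significant"))
  cat("\n")
  invisible(x)
}
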