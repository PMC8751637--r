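#' Construct a phase series
#'
#' Container for per-sample band-limited phase and amplitude of an LFP
#' channel.
#'
#' @param phase phase in \[0, 2*pi) per sample (NA where undefined).
#' @param amplitude analytic envelope per sample (same units as input).
#' @param fs sample rate (Hz).
#' @param t0 time of the first sample (s).
#' @param band frequency band (Hz pair).
#' @param offset reference offset (rad) already applied to `phase`.
#' @return object of class `phase_series`.
#' @export
phase_series <- function(phase, amplitude, fs, t0 = 0, band = NULL,
                         offset = 0) {
  stopifnot(length(phase) == length(amplitude), fs > 0)
  if (!is.null(band) && band[1] >= band[2]) stop("band low must be < band high")
  structure(list(phase = phase, amplitude = amplitude, fs = fs, t0 = t0,
                 band = band, offset = offset),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("phase series: %d samples at %g Hz", length(x$phase), x$fs))
  if (!is.null(x$band)) cat(sprintf(", band %g-%g Hz", x$band[1], x$band[2]))
  if (x$offset != 0) cat(sprintf(", reference offset %.3f rad", x$offset))
  cat("\n")
  invisible(x)
}

#' Phase of a phase series at arbitrary times
#'
#' Looks up the instantaneous phase at (spike) times with phasor
#' interpolation: the unit vectors at the two neighbouring samples are
#' linearly interpolated and the angle of the result is returned. This is
#' accurate whenever the per-sample phase advance is below pi, i.e. for any
#' in-band oscillation sampled above twice the band.
#'
#' @param ps a [phase_series()].
#' @param t times (s).
#' @return phases in \[0, 2*pi); NA where the phase is undefined.
#' @export
phase_at <- function(ps, t) {
  if (length(t) == 0) return(numeric(0))
  pos <- (t - ps$t0) * ps$fs + 1
  n <- length(ps$phase)
  i0 <- pmin(pmax(floor(pos), 1L), n)
  i1 <- pmin(i0 + 1L, n)
  w <- pmin(pmax(pos - i0, 0), 1)
  z <- (1 - w) * exp(1i * ps$phase[i0]) + w * exp(1i * ps$phase[i1])
  out <- wrap_2pi(Arg(z))
  out[is.na(ps$phase[i0]) | is.na(ps$phase[i1]) | Mod(z) < 1e-9] <- NA_real_
  out
}

amplitude_at <- function(ps, t) {
  ps$amplitude[sample_index(t, ps$t0, ps$fs, length(ps$amplitude))]
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a Hamming-windowed linear-phase FIR band-pass filter and applies it
#' with exact group-delay compensation, so that filtered features are not
#' shifted in time. The default order scales with sample rate (400 taps at
#' 4.8 kHz) but is raised for narrow bands so that a pure tone one octave
#' below the band is attenuated by at least 20 dB while in-band tones pass
#' with gain >= 0.9.
#'
#' @param x sampled signal.
#' @param band c(low, high) in Hz; `high` must be below Nyquist.
#' @param fs sample rate (Hz).
#' @param order filter order (number of taps - 1); even. Default
#'   `max(round(400 * fs / 4800), ceiling(6.6 * fs / band[1]))`, made even.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, band, fs, order = NULL) {
  if (band[2] >= fs / 2) stop("band high must be below Nyquist (", fs / 2, " Hz)")
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  if (is.null(order)) {
    order <- max(round(400 * fs / 4800), ceiling(6.6 * fs / band[1]))
  }
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  if (order + 1L >= length(x)) stop("signal shorter than the filter")
  h <- signal::fir1(order, band / (fs / 2), type = "pass")
  h <- as.numeric(h)
  n <- length(x)
  full <- Re(conv_full(x, h))
  delay <- order / 2L
  full[(delay + 1L):(delay + n)]
}

#' Instantaneous phase and amplitude via the analytic signal
#'
#' Computes the analytic signal of an already band-limited trace with the
#' Hilbert transform (frequency-domain construction) and returns per-sample
#' phase and envelope. Samples whose envelope is numerically zero carry an
#' undefined phase and are returned as NA.
#'
#' @param x band-limited signal.
#' @param fs sample rate (Hz).
#' @param t0 time of first sample (s).
#' @param band the band of `x` (Hz pair), stored for reference.
#' @return a [phase_series()].
#' @export
instantaneous_phase_amplitude <- function(x, fs, t0 = 0, band = NULL) {
  n_orig <- length(x)
  # zero-pad to a highly composite length: FFT cost is otherwise governed by
  # the largest prime factor of an arbitrary recording length
  n <- stats::nextn(n_orig, 2)
  X <- stats::fft(c(x, rep(0, n - n_orig)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n_orig)]
  amplitude <- Mod(z)
  phase <- wrap_2pi(Arg(z))
  scale <- max(amplitude, 1)
  phase[amplitude < 1e-12 * scale] <- NA_real_
  phase_series(phase, amplitude, fs = fs, t0 = t0, band = band)
}

#' Reference phase normalization
#'
#' Computes the offset that makes the across-cell circular mean of per-cell
#' preferred firing phases equal to pi, and optionally applies it to a phase
#' series. Adding the same offset to all spike phases keeps spike-LFP
#' relations intact while standardizing the phase convention across sessions.
#'
#' @param phases_by_cell list of numeric vectors: spike phases (rad) per cell.
#' @param series optional [phase_series()] to which the offset is applied.
#' @return list with `offset` (rad), `preferred_by_cell`, and `series`
#'   (shifted copy, or NULL).
#' @export
reference_phase_normalization <- function(phases_by_cell, series = NULL) {
  phases_by_cell <- Filter(length, phases_by_cell)
  if (length(phases_by_cell) == 0) stop("no spike phases supplied")
  pref <- vapply(phases_by_cell, circ_mean_angle, numeric(1))
  pref <- pref[!is.na(pref)]
  if (length(pref) == 0) stop("no cell has a defined preferred phase")
  z <- mean(exp(1i * pref))
  if (Mod(z) < 1e-9)
    stop("degenerate across-cell preferred phase (resultant ~ 0)")
  offset <- wrap_pi(pi - Arg(z))
  if (!is.null(series)) {
    series$phase <- wrap_2pi(series$phase + offset)
    series$offset <- series$offset + offset
  }
  list(offset = offset, preferred_by_cell = pref, series = series)
}

#' Select the channel with the highest theta signal-to-noise ratio
#'
#' SNR is the mean periodogram power inside the theta band divided by the
#' mean power in 1-50 Hz excluding the theta band, computed over the supplied
#' (RUN-epoch) samples. Ties go to the lowest index.
#'
#' @param channels list of numeric vectors (one per channel), equal length.
#' @param fs sample rate (Hz).
#' @param theta_band theta band (Hz pair, default 6-12).
#' @return integer channel index.
#' @export
select_theta_channel <- function(channels, fs, theta_band = c(6, 12)) {
  if (length(channels) == 0) stop("need at least one channel")
  if (length(channels) == 1) return(1L)
  snr <- vapply(channels, function(x) {
    n <- stats::nextn(length(x), 2)
    P <- Mod(stats::fft(c(x - mean(x), rep(0, n - length(x)))))^2
    f <- (seq_len(n) - 1) * fs / n
    half <- f <= fs / 2
    f <- f[half]; P <- P[half]
    in_theta <- f >= theta_band[1] & f <= theta_band[2]
    noise <- f >= 1 & f <= 50 & !in_theta
    mean(P[in_theta]) / mean(P[noise])
  }, numeric(1))
  which.max(snr)
}

#' Event-locked Morlet wavelet spectrogram
#'
#' Computes 5-cycle Morlet log-power in a window centred on each event's peak
#' time, averages across events, and subtracts a per-frequency baseline taken
#' from the central sections of inter-event gaps of at least `min_gap`
#' seconds.
#'
#' @param x LFP signal.
#' @param fs sample rate (Hz).
#' @param t0 time of first sample (s).
#' @param events data.frame with `start_s`, `end_s`, `peak_s` columns.
#' @param freqs frequency grid (Hz, default 100-300 in 2 Hz steps).
#' @param window half-window around the peak (s, default 0.2).
#' @param n_cycles wavelet cycles (default 5).
#' @param min_gap minimum event separation qualifying a baseline gap (s,
#'   default 2.4); the central `2*window` seconds of each gap are used.
#' @return object of class `spectrogram`: list with `freq`, `time`,
#'   `power` (freq x time, log10 units), `corrected` flag.
#' @export
event_spectrogram <- function(x, fs, t0, events, freqs = seq(100, 300, by = 2),
                              window = 0.2, n_cycles = 5, min_gap = 2.4) {
  if (nrow(events) == 0) stop("need at least one event")
  half <- as.integer(round(window * fs))
  times <- (-half:half) / fs
  # wavelet support: 4 SD at the lowest frequency
  pad <- as.integer(ceiling(4 * n_cycles / (2 * pi * min(freqs)) * fs))
  n <- length(x)

  segment_power <- function(centre_s) {
    c_idx <- sample_index(centre_s, t0, fs, n)
    lo <- c_idx - half - pad
    hi <- c_idx + half + pad
    if (lo < 1 || hi > n) return(NULL)
    seg <- x[lo:hi]
    P <- matrix(NA_real_, length(freqs), 2 * half + 1)
    for (k in seq_along(freqs)) {
      f <- freqs[k]
      sd_t <- n_cycles / (2 * pi * f)
      r <- as.integer(ceiling(4 * sd_t * fs))
      tt <- (-r:r) / fs
      env <- exp(-tt^2 / (2 * sd_t^2))
      # unit gain at the wavelet's centre frequency, so a tone of amplitude A
      # yields |coefficient| = A there irrespective of frequency
      w <- exp(2i * pi * f * tt) * env / sum(env)
      mid <- conv_full(seg, w)[(r + 1L):(r + length(seg))]
      P[k, ] <- Mod(mid[(pad + 1L):(pad + 2L * half + 1L)])^2
    }
    log10(pmax(P, .Machine$double.xmin))
  }

  ev_pow <- Filter(Negate(is.null), lapply(events$peak_s, segment_power))
  if (length(ev_pow) == 0) stop("no event window fits inside the recording")
  avg <- Reduce(`+`, ev_pow) / length(ev_pow)

  ord <- order(events$start_s)
  gaps_start <- events$end_s[ord][-length(ord)]
  gaps_end <- events$start_s[ord][-1]
  ok <- (gaps_end - gaps_start) >= min_gap
  base_centres <- (gaps_start[ok] + gaps_end[ok]) / 2
  corrected <- FALSE
  if (length(base_centres) > 0) {
    base_pow <- Filter(Negate(is.null), lapply(base_centres, segment_power))
    if (length(base_pow) > 0) {
      base <- Reduce(`+`, base_pow) / length(base_pow)
      avg <- avg - rowMeans(base)
      corrected <- TRUE
    }
  }
  if (!corrected)
    warning("no qualifying inter-event gap; returning uncorrected spectrogram")
  structure(list(freq = freqs, time = times, power = avg,
                 corrected = corrected),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d frequencies (%g-%g Hz) x %d time points%s\n",
              length(x$freq), min(x$freq), max(x$freq), length(x$time),
              if (x$corrected) ", baseline-corrected" else ""))
  invisible(x)
}
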