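# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 2*pi)
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to [0, 2*pi).
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Wrap angular differences into (-pi, pi]
#' @param x numeric vector of angular differences in radians.
#' @return differences wrapped to (-pi, pi].
#' @export
wrap_pi <- function(x) -(((-x + pi) %% (2 * pi)) - pi)

# circular mean direction (radians, in [0, 2pi)); NA if resultant ~ 0
circ_mean_angle <- function(a) {
  z <- sum(exp(1i * a))
  if (Mod(z) / length(a) < 1e-12) return(NA_real_)
  wrap_2pi(Arg(z))
}

circ_resultant <- function(a) Mod(mean(exp(1i * a)))

# Gaussian kernel with given SD in samples, truncated at 4 SD, sums to 1
gaussian_kernel <- function(sd) {
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(4 * sd))
  k <- exp(-0.5 * ((-r:r) / sd)^2)
  k / sum(k)
}

# Zero-phase Gaussian smoothing; edges renormalized over the valid support so
# that a constant input is returned unchanged.
smooth_gaussian <- function(x, sd, renorm = TRUE) {
  if (sd <= 0 || length(x) < 2) return(x)
  k <- gaussian_kernel(sd)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  out <- Re(conv_full(x, k))[(r + 1L):(r + n)]
  if (renorm) {
    wfull <- Re(conv_full(rep(1, n), k))
    out <- out / wfull[(r + 1L):(r + n)]
  }
  out
}

# full linear convolution via FFT; supports complex input
conv_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  N <- stats::nextn(n, 2)
  fx <- stats::fft(c(x, rep(0, N - length(x))))
  fy <- stats::fft(c(y, rep(0, N - length(y))))
  stats::fft(fx * fy, inverse = TRUE)[seq_len(n)] / N
}

# start/end indices (inclusive) of runs of TRUE
logical_spans <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# nearest-sample lookup into a regularly sampled series
sample_index <- function(t, t0, fs, n) {
  pmin(pmax(as.integer(round((t - t0) * fs)) + 1L, 1L), n)
}

# linear interpolation of tracking column at arbitrary times
track_interp <- function(tracking, column, t) {
  stats::approx(tracking$t_s, tracking[[column]], xout = t, rule = 2)$y
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- sub[j, ]
      rest[rest >= k] <- rest[rest >= k] + 1L
      out[row, ] <- c(k, rest)
      row <- row + 1L
    }
  }
  out
}
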