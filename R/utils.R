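#' @importFrom stats quantile cor cor.test mad median rnorm runif rlnorm rpois
#' @importFrom stats fft kmeans wilcox.test lm coef complete.cases sd var
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

#' Convert a time in milliseconds to the 1-based index of the sample
#' containing it (sample i covers \code{[(i-1)/fs, i/fs)} seconds).
#' @param t_ms time in milliseconds (0-based)
#' @param fs sampling rate in Hz
#' @return integer sample index
#' @keywords internal
ms_to_sample <- function(t_ms, fs) as.integer(floor(t_ms * fs / 1000)) + 1L

#' Samples covered by the half-open interval [onset_ms, offset_ms)
#' @keywords internal
interval_samples <- function(onset_ms, offset_ms, fs, n = Inf) {
  i0 <- ms_to_sample(onset_ms, fs)
  ## last sample whose start time is strictly before offset
  i1 <- as.integer(ceiling(offset_ms * fs / 1000))
  i0 <- max(1L, i0)
  i1 <- min(n, i1)
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

## Merge possibly overlapping [onset, offset) intervals given as a two-column
## matrix/data.frame; returns a data.frame with columns onset, offset.
merge_intervals <- function(onset, offset) {
  if (length(onset) == 0L) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  o <- order(onset, offset)
  onset <- onset[o]; offset <- offset[o]
  out_on <- onset[1]; out_off <- offset[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= out_off) {
      out_off <- max(out_off, offset[i])
    } else {
      res_on <- c(res_on, out_on); res_off <- c(res_off, out_off)
      out_on <- onset[i]; out_off <- offset[i]
    }
  }
  data.frame(onset = c(res_on, out_on), offset = c(res_off, out_off))
}

## Ornstein-Uhlenbeck sample path with stationary sd `sigma` and correlation
## time `tau_s` (seconds), sampled at fs Hz. `smooth_ms > 0` applies a
## Gaussian moving average and rescales back to `sigma`: raw OU innovations
## are white, so an unsmoothed path used as oscillator phase noise would
## smear the oscillator far outside its nominal band (instantaneous
## frequency excursions of sigma*sqrt(1-a^2)*fs/(2*pi) Hz).
ou_path <- function(n, fs, sigma, tau_s, smooth_ms = 0) {
  if (sigma <= 0) return(numeric(n))
  a <- exp(-1 / (fs * tau_s))
  innov <- rnorm(n, sd = sigma * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sigma)
  x <- as.numeric(stats::filter(innov, a, method = "recursive"))
  if (smooth_ms > 0) {
    sig <- smooth_ms / 1000 * fs
    r <- ceiling(3 * sig)
    kern <- exp(-(-r:r)^2 / (2 * sig^2)); kern <- kern / sum(kern)
    xs <- stats::filter(c(rep(x[1], r), x, rep(x[n], r)), kern, sides = 2)
    x <- as.numeric(xs[(r + 1):(r + n)])
    s <- sd(x)
    if (s > 0) x <- x * sigma / s
  }
  x
}

## 1/f^beta ("pink" for beta = 1) Gaussian noise, standardized to sd `sigma`.
pink_noise <- function(n, sigma = 1, beta = 1) {
  if (sigma <= 0) return(numeric(n))
  nfft <- stats::nextn(n, 2)
  w <- fft(rnorm(nfft))
  f <- c(1, seq_len(nfft - 1))             # avoid division by zero at DC
  f <- pmin(f, nfft - f + 1)               # symmetric frequency magnitude
  w <- w * f^(-beta / 2)
  w[1] <- 0
  x <- Re(fft(w, inverse = TRUE))[seq_len(n)]
  sigma * (x - mean(x)) / sd(x)
}

## Zero-phase band-pass of a real signal via FFT masking.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  fr <- (seq_len(nfft) - 1) * fs / nfft
  fr <- pmin(fr, fs - fr)
  X[fr < lo | fr > hi] <- 0
  Re(fft(X, inverse = TRUE) / nfft)[seq_len(n)]
}
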