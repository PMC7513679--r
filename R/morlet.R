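## Complex Morlet kernel at frequency f, truncated at 4 temporal standard
## deviations; sigma_t = n_cycles / (2 pi f). Normalized to unit energy in
## the continuous sense (sum |g|^2 / fs = 1), which makes the power response
## to a sinusoid invariant under the sampling rate.
morlet_kernel <- function(f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  g / sqrt(sum(Mod(g)^2) * fs)
}

#' Complex Morlet wavelet transform of one channel
#'
#' Convolves the signal with unit-energy complex Morlet kernels at each grid
#' frequency (FFT-based, zero-padded, "same" alignment). The transform is
#' linear in the input. Samples within one kernel half-support of either edge
#' are boundary-invalid per frequency and must not contribute to segment
#' averages.
#'
#' @param x numeric time series (microvolts)
#' @param fs sampling rate, Hz; must exceed twice the highest frequency
#' @param freqs analysis frequencies in Hz (e.g. `analysis_grid()$freqs`)
#' @param n_cycles Morlet width in cycles (constant across frequencies;
#'   default 7, a standard compromise giving ~175-467 ms time resolution over
#'   the 15-40 Hz grid)
#' @return object of class `morlet_stack`: list with `coeffs` (complex matrix,
#'   frequency x time), `freqs`, `fs`, `n_cycles` and `margin` (integer vector
#'   per frequency: number of boundary-invalid samples at each edge)
#' @export
morlet_transform <- function(x, fs, freqs, n_cycles = 7) {
  morlet_apply(x, morlet_bank(length(x), fs, freqs, n_cycles))
}

## Precomputed kernel spectra for repeated transforms of signals up to n
## samples (all channels / excerpts of a session share one bank).
morlet_bank <- function(n, fs, freqs, n_cycles = 7) {
  stopifnot(n >= 2, n_cycles >= 3)
  if (fs <= 2 * max(freqs)) {
    stop("sampling rate ", fs, " Hz violates the Nyquist requirement for ",
         max(freqs), " Hz")
  }
  kernels <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles)
  margins <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))
  nfft <- stats::nextn(n + max(lengths(kernels)), 2)
  K <- vapply(kernels, function(k) fft(c(k, numeric(nfft - length(k)))),
              complex(nfft))
  list(n = n, nfft = nfft, fs = fs, freqs = freqs, n_cycles = n_cycles,
       margin = margins, K = K)
}

## Apply a kernel bank to one channel (length(x) <= bank$n). All frequencies
## are convolved in one batched inverse FFT (mvfft over kernel columns).
morlet_apply <- function(x, bank) {
  stopifnot(is.numeric(x), length(x) <= bank$n)
  n <- length(x)
  X <- fft(c(x, numeric(bank$nfft - n)))
  conv <- stats::mvfft(bank$K * X, inverse = TRUE) / bank$nfft
  out <- matrix(0i, length(bank$freqs), n)
  for (i in seq_along(bank$freqs)) {
    half <- bank$margin[i]
    out[i, ] <- conv[(half + 1L):(half + n), i]
  }
  structure(list(coeffs = out, freqs = bank$freqs, fs = bank$fs,
                 n_cycles = bank$n_cycles, margin = bank$margin),
            class = "morlet_stack")
}

## Wavelet coefficients at selected sample indices only, by direct kernel
## dot products (two real BLAS matmuls). Identical to the convolution values
## of morlet_transform at interior samples, but orders of magnitude cheaper
## when only window centers are needed. All centers must clear the largest
## kernel half-support from both signal edges.
morlet_kernel_matrix <- function(fs, freqs, n_cycles = 7) {
  kernels <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles)
  H <- max(vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1)))
  L <- 2L * H + 1L
  Kr <- matrix(0, L, length(freqs)); Ki <- matrix(0, L, length(freqs))
  for (i in seq_along(kernels)) {
    h <- (length(kernels[[i]]) - 1L) %/% 2L
    rows <- (H - h + 1L):(H + h + 1L)
    Kr[rows, i] <- Re(kernels[[i]])
    Ki[rows, i] <- Im(kernels[[i]])
  }
  list(Kr = Kr, Ki = Ki, H = H, freqs = freqs)
}

morlet_at <- function(x, fs, freqs, centers, n_cycles = 7,
                      km = morlet_kernel_matrix(fs, freqs, n_cycles)) {
  H <- km$H
  stopifnot(all(centers > H & centers <= length(x) - H))
  W <- matrix(x[outer(seq(-H, H), as.integer(centers), `+`)],
              nrow = 2L * H + 1L)
  ## coef[t] = sum_v Conj(g(v)) x(t+v)
  matrix(complex(real = crossprod(km$Kr, W), imaginary = -crossprod(km$Ki, W)),
         nrow = length(freqs))
}

#' Wavelet power
#'
#' Squared magnitude of the wavelet coefficients; non-negative.
#' @param stack a [morlet_transform()] result
#' @return real matrix, frequency x time
#' @export
wavelet_power <- function(stack) Mod(stack$coeffs)^2

#' Wavelet phase
#'
#' Argument of the complex coefficients in `(-pi, pi]`. Zero-magnitude
#' coefficients have no defined phase and are returned as `NA` rather than an
#' arbitrary angle.
#' @param stack a [morlet_transform()] result
#' @return real matrix, frequency x time, `NA` where undefined
#' @export
wavelet_phase <- function(stack) {
  ph <- Arg(stack$coeffs)
  ph[Mod(stack$coeffs) == 0] <- NA_real_
  ph
}

#' Boundary validity of wavelet coefficients
#' @param stack a [morlet_transform()] result
#' @return logical matrix, frequency x time; FALSE within one kernel
#'   half-support of either edge
#' @export
wavelet_valid <- function(stack) {
  n <- ncol(stack$coeffs)
  t(vapply(stack$margin, function(m) {
    v <- rep(TRUE, n); if (m > 0) v[c(seq_len(min(m, n)),
                                      seq.int(max(1L, n - m + 1L), n))] <- FALSE
    v
  }, logical(n)))
}
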