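#' Time-frequency analysis grid
#'
#' The fixed coordinate system of the analysis: a wavelet frequency grid from
#' 15 to 40 Hz in steps of 0.5 Hz (51 bins, covering the low/high beta and
#' low/medium gamma range), reporting bands, and the sliding-window geometry
#' used for phase coherence (80 ms windows stepped by 40 ms, so that the
#' shortest window still represents oscillations down to 12.5 Hz).
#'
#' Reporting bands overlap at 30 Hz in their nominal edges; each frequency bin
#' is assigned to the first band (in the order given) that contains it, so the
#' 30 Hz bin belongs to the 25-30 Hz band only.
#'
#' @param f_min,f_max,f_step frequency grid limits and step, Hz
#' @param bands named list of two-element numeric ranges (Hz) used for band
#'   averaging in reports
#' @param win_ms sliding-window length in milliseconds
#' @param step_ms sliding-window step in milliseconds
#' @return an object of class `analysis_grid`
#' @examples
#' g <- analysis_grid()
#' length(g$freqs)           # 51
#' lowest_window_freq(g)     # 12.5 Hz
#' @export
analysis_grid <- function(f_min = 15, f_max = 40, f_step = 0.5,
                          bands = list("20-24" = c(20, 24),
                                       "25-30" = c(25, 30),
                                       "30-34" = c(30, 34),
                                       "35-39" = c(35, 39)),
                          win_ms = 80, step_ms = 40) {
  stopifnot(f_min > 0, f_max > f_min, f_step > 0, win_ms >= 1, step_ms >= 1)
  freqs <- seq(f_min, f_max, by = f_step)
  for (b in bands) {
    if (b[1] < f_min || b[2] > f_max) {
      stop("band [", b[1], ", ", b[2], "] outside frequency grid")
    }
  }
  structure(list(freqs = freqs, bands = bands,
                 win_ms = win_ms, step_ms = step_ms),
            class = "analysis_grid")
}

#' Lowest frequency fully representable by one analysis window
#'
#' One cycle must fit in the window, i.e. `1000 / win_ms` Hz (12.5 Hz for the
#' default 80 ms window).
#' @param grid an [analysis_grid()]
#' @return frequency in Hz
#' @export
lowest_window_freq <- function(grid) 1000 / grid$win_ms

#' Membership of each grid frequency in the reporting bands
#'
#' @param grid an [analysis_grid()]
#' @return character vector along `grid$freqs`: band name or `NA` for bins
#'   outside all bands. Each bin belongs to at most one band (first match).
#' @export
band_membership <- function(grid) {
  out <- rep(NA_character_, length(grid$freqs))
  for (nm in names(grid$bands)) {
    b <- grid$bands[[nm]]
    hit <- is.na(out) & grid$freqs >= b[1] & grid$freqs <= b[2]
    out[hit] <- nm
  }
  out
}

#' Dimensionality of the dyadic state spaces
#'
#' For a dyad with `k` electrodes per subject and `f` analysis frequencies,
#' the wavelet power state space has `2*k*f` dimensions (one per subject,
#' electrode and frequency) and the phase-coherence state space has
#' `k*(2k - 1)*f` dimensions (one per unordered electrode pair among the
#' `2k` electrodes of the dyad, per frequency).
#'
#' @param k electrodes per subject
#' @param f number of frequencies (defaults to the grid's 51)
#' @param grid optional [analysis_grid()] supplying `f`
#' @return named numeric vector `c(power_dim =, coherence_dim =)`
#' @examples
#' state_space_dims(k = 60, f = 51)  # 6120, 364140
#' @export
state_space_dims <- function(k, f = NULL, grid = NULL) {
  if (is.null(f)) f <- length((grid %||% analysis_grid())$freqs)
  stopifnot(k >= 1, f >= 1)
  c(power_dim = 2 * k * f, coherence_dim = k * (2 * k - 1) * f)
}
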