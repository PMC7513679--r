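## Residual of a rolling least-squares line fit evaluated at each sample.
## Windows are centered, truncated at the edges; the fit is exact for a pure
## line everywhere (including the edges), so linear signals yield zero
## residual by construction.
rolling_linfit_residual <- function(x, win) {
  n <- length(x)
  h <- max(1L, floor(win / 2))
  s <- as.numeric(seq_len(n))
  cs <- function(v) cumsum(v)
  C0 <- cs(rep(1, n)); C1 <- cs(s); C2 <- cs(s^2); Cy <- cs(x); Csy <- cs(s * x)
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  at <- function(C, i) ifelse(i >= 1, C[pmax(i, 1)], 0)
  S0 <- at(C0, hi) - at(C0, lo - 1L)
  S1 <- at(C1, hi) - at(C1, lo - 1L)
  S2 <- at(C2, hi) - at(C2, lo - 1L)
  Sy <- at(Cy, hi) - at(Cy, lo - 1L)
  Ssy <- at(Csy, hi) - at(Csy, lo - 1L)
  det <- S0 * S2 - S1^2
  b <- ifelse(det > 0, (S0 * Ssy - S1 * Sy) / det, 0)
  a <- (Sy - b * S1) / S0
  x - (a + b * s)
}

#' Detect ocular blink epochs on an EOG channel
#'
#' Windowed linear approximation: a least-squares line is fit in a sliding
#' window around every sample and the residual from the local fit is
#' thresholded at `residual_thresh` robust scales (median absolute deviation).
#' Samples exceeding the threshold seed peak regions; overlapping regions are
#' merged and each region is expanded outward to the surrounding
#' zero-crossings of the residual. Purely linear signals (any slope) produce
#' no detections, as does a flat signal.
#'
#' @param eog numeric EOG time series (microvolts)
#' @param fs sampling rate, Hz
#' @param win_ms linear-fit window length (default 200 ms; blink transients
#'   last roughly 100-400 ms)
#' @param residual_thresh threshold in robust scales of the residual
#' @return data.frame with columns `onset_ms`, `offset_ms` (half-open
#'   intervals)
#' @export
detect_blinks <- function(eog, fs, win_ms = 200, residual_thresh = 6) {
  win <- max(2L, round(win_ms * fs / 1000))
  r <- rolling_linfit_residual(eog, win)
  scale <- mad(r)
  if (scale <= 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  seed <- abs(r) > residual_thresh * scale
  if (!any(seed)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  runs <- rle(seed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  n <- length(eog)
  on <- integer(0); off <- integer(0)
  for (i in keep) {
    a <- starts[i]; b <- ends[i]
    sgn <- sign(r[a])
    while (a > 1L && sign(r[a - 1L]) == sgn && r[a - 1L] != 0) a <- a - 1L
    while (b < n && sign(r[b + 1L]) == sgn && r[b + 1L] != 0) b <- b + 1L
    on <- c(on, a); off <- c(off, b)
  }
  iv <- merge_intervals((on - 1L) * 1000 / fs, off * 1000 / fs)
  data.frame(onset_ms = iv$onset, offset_ms = iv$offset)
}

#' Detect muscle artifacts by thresholding 40-60 Hz wavelet power
#'
#' Wavelet power on a coarse grid spanning `band` is averaged per sliding
#' window and per scalp channel; windows whose band power exceeds
#' `power_thresh` times the channel's median window power are flagged, and
#' contiguous flagged windows are merged into intervals. The median is stable
#' under sparse bursts, so clean oscillatory activity below the band produces
#' no detections.
#'
#' @param rec a [dual_recording()] (`fs` must exceed twice the band top)
#' @param band two-element frequency range, Hz
#' @param power_thresh multiple of the per-channel median window band power
#' @param win_ms,step_ms sliding-window geometry (defaults match the
#'   coherence windows)
#' @param freq_step spacing of the coarse wavelet grid inside `band`, Hz
#' @param n_cycles Morlet width
#' @param power_floor absolute guard: a window is only flagged when its band
#'   power also exceeds this fraction of the channel variance, so that
#'   fluctuations of numerically negligible out-of-band leakage (a clean
#'   oscillator below the band leaks ~1e-6 of its variance) can never fire
#'   the median-relative threshold; genuine muscle bursts carry band power
#'   orders of magnitude above this floor
#' @return data.frame with columns `subject`, `channel`, `onset_ms`,
#'   `offset_ms`
#' @export
detect_muscle <- function(rec, band = c(40, 60), power_thresh = 5,
                          win_ms = 80, step_ms = 40, freq_step = 5,
                          n_cycles = 7, power_floor = 0.005) {
  validate_recording(rec)
  fs <- rec$fs
  if (fs <= 2 * band[2]) stop("sampling rate too low for the ", band[1], "-",
                              band[2], " Hz artifact band")
  freqs <- seq(band[1], band[2], by = freq_step)
  n <- ncol(rec$samples[[1]])
  win <- round(win_ms * fs / 1000)
  step <- round(step_ms * fs / 1000)
  out <- list()
  bank <- morlet_bank(n, fs, freqs, n_cycles)
  ## windows inside the kernel half-support of either recording edge carry
  ## boundary-contaminated power and are not assessed
  marg <- max(bank$margin)
  starts <- seq(marg + 1L, n - win + 1L - marg, by = step)
  for (s in 1:2) {
    scalp <- which(rec$channel_types[[s]] == "scalp")
    for (ch in scalp) {
      x <- rec$samples[[s]][ch, ]
      st <- morlet_apply(x, bank)
      p <- colMeans(Mod(st$coeffs)^2)
      wp <- vapply(starts, function(a) mean(p[a:(a + win - 1L)]), numeric(1))
      m <- median(wp)
      flag <- m > 0 & wp > power_thresh * m & wp > power_floor * var(x)
      if (!any(flag)) next
      runs <- rle(flag)
      ends <- cumsum(runs$lengths)
      for (i in which(runs$values)) {
        a <- starts[ends[i] - runs$lengths[i] + 1L]
        b <- starts[ends[i]] + win
        out[[length(out) + 1]] <- data.frame(
          subject = s, channel = rownames(rec$samples[[s]])[ch],
          onset_ms = (a - 1L) * 1000 / fs, offset_ms = (b - 1L) * 1000 / fs)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject = integer(0), channel = character(0),
                      onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  do.call(rbind, out)
}

#' Remove the least-squares linear trend from a time series
#'
#' Subtracts the ordinary least-squares line, leaving a signal with zero mean
#' and zero least-squares slope. Idempotent, and commutes with amplitude
#' scaling.
#' @param x numeric vector, length >= 2
#' @return detrended vector
#' @export
detrend <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  s <- seq_len(n) - (n + 1) / 2          # centered regressor
  x - mean(x) - s * (sum(s * x) / sum(s^2))
}

#' Detrend every channel of a recording
#' @param rec a [dual_recording()]
#' @return recording with each channel linearly detrended
#' @export
detrend_recording <- function(rec) {
  for (s in 1:2) {
    rec$samples[[s]] <- t(apply(rec$samples[[s]], 1, detrend))
  }
  rec
}

#' Build a per-sample validity mask from detected artifacts
#'
#' The union of all blink and muscle intervals of a subject is marked invalid
#' for that subject; downstream windowing drops any analysis window that
#' overlaps invalid samples of either subject (exclusion rather than
#' interpolation, because all derived quantities are averages over windows).
#'
#' @param blinks list of two data.frames from [detect_blinks()] (one per
#'   subject), or NULL
#' @param muscle data.frame from [detect_muscle()], or NULL
#' @param rec the [dual_recording()] the intervals refer to
#' @return object of class `artifact_mask`: list with `valid` (list of two
#'   logical vectors, TRUE = usable) and `provenance` (data.frame `kind`,
#'   `subject`, `channel`, `onset_ms`, `offset_ms`)
#' @export
build_mask <- function(blinks = NULL, muscle = NULL, rec) {
  n <- ncol(rec$samples[[1]])
  span <- n * 1000 / rec$fs
  valid <- list(rep(TRUE, n), rep(TRUE, n))
  prov <- list()
  mark <- function(kind, subject, channel, onset, offset) {
    if (onset < 0 || offset > span + 1e-9) {
      stop(kind, " interval [", onset, ", ", offset, ") outside recording span")
    }
    idx <- interval_samples(onset, offset, rec$fs, n)
    valid[[subject]][idx] <<- FALSE
    prov[[length(prov) + 1]] <<- data.frame(kind = kind, subject = subject,
                                            channel = channel, onset_ms = onset,
                                            offset_ms = offset)
  }
  for (s in 1:2) {
    b <- if (is.null(blinks)) NULL else blinks[[s]]
    if (!is.null(b) && nrow(b)) {
      for (i in seq_len(nrow(b))) mark("blink", s, "EOG", b$onset_ms[i], b$offset_ms[i])
    }
  }
  if (!is.null(muscle) && nrow(muscle)) {
    for (i in seq_len(nrow(muscle))) {
      mark("muscle", muscle$subject[i], muscle$channel[i],
           muscle$onset_ms[i], muscle$offset_ms[i])
    }
  }
  structure(list(valid = valid,
                 provenance = if (length(prov)) do.call(rbind, prov) else
                   data.frame(kind = character(0), subject = integer(0),
                              channel = character(0), onset_ms = numeric(0),
                              offset_ms = numeric(0))),
            class = "artifact_mask")
}

#' Full artifact-correction pass over a recording
#'
#' Detrends every channel, detects blinks on each subject's EOG channel(s) and
#' muscle bursts on scalp channels, and assembles the validity mask consumed
#' by all downstream windowing.
#'
#' @param rec a [dual_recording()]
#' @param blink_win_ms,blink_thresh blink detector parameters
#' @param muscle_band,muscle_thresh muscle detector parameters
#' @return list with `recording` (detrended) and `mask` ([build_mask()])
#' @export
preprocess_recording <- function(rec, blink_win_ms = 200, blink_thresh = 6,
                                 muscle_band = c(40, 60), muscle_thresh = 5) {
  rec <- detrend_recording(rec)
  blinks <- lapply(1:2, function(s) {
    eog <- which(rec$channel_types[[s]] == "eog")
    if (!length(eog)) {
      return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
    }
    res <- lapply(eog, function(ch) {
      detect_blinks(rec$samples[[s]][ch, ], rec$fs,
                    win_ms = blink_win_ms, residual_thresh = blink_thresh)
    })
    res <- do.call(rbind, res)
    iv <- merge_intervals(res$onset_ms, res$offset_ms)
    data.frame(onset_ms = iv$onset, offset_ms = iv$offset)
  })
  muscle <- detect_muscle(rec, band = muscle_band, power_thresh = muscle_thresh)
  list(recording = rec, mask = build_mask(blinks, muscle, rec))
}
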