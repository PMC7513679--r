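#' Inject artifacts into a clean recording
#'
#' Adds the three artifact types the preprocessing stage must handle, with a
#' ledger of ground-truth onsets/slopes for recovery tests:
#' \itemize{
#'   \item ocular blinks: stereotyped Gaussian-shaped positive transients on
#'     each subject's EOG channel(s), Poisson onsets at
#'     `cfg$blink_rate_per_min`;
#'   \item muscle bursts: 40-60 Hz band-limited noise bursts on randomly
#'     chosen scalp channels at `cfg$muscle_rate_per_min`;
#'   \item linear drift: per-scalp-channel slope drawn uniformly from
#'     `cfg$drift_range` (microvolts per second).
#' }
#' With all rates zero and a degenerate drift range `{0}` the output equals
#' the input exactly.
#'
#' @param rec a clean [dual_recording()]
#' @param cfg a [scenario_config()] supplying rates and amplitudes
#' @return list with `recording` (artifact-laden copy) and `ledger`, a
#'   data.frame with columns `kind` (`"blink"`, `"muscle"`, `"drift"`),
#'   `subject`, `channel`, `onset_ms`, `offset_ms`, `peak_ms` (blinks; NA
#'   otherwise) and `value` (blink amplitude, burst sd, or drift slope in
#'   microvolts/second)
#' @export
inject_artifacts <- function(rec, cfg) {
  validate_recording(rec)
  fs <- rec$fs
  n <- ncol(rec$samples[[1]])
  dur_min <- n / fs / 60
  led <- list()
  add <- function(kind, subject, channel, onset, offset, peak, value) {
    led[[length(led) + 1]] <<- data.frame(kind = kind, subject = subject,
                                          channel = channel, onset_ms = onset,
                                          offset_ms = offset, peak_ms = peak,
                                          value = value)
  }
  tt <- (seq_len(n) - 1) / fs

  for (s in 1:2) {
    X <- rec$samples[[s]]
    scalp <- which(rec$channel_types[[s]] == "scalp")
    eog <- which(rec$channel_types[[s]] == "eog")

    ## blinks on EOG channels
    if (cfg$blink_rate_per_min > 0 && length(eog)) {
      n_blink <- rpois(1, cfg$blink_rate_per_min * dur_min)
      sig_ms <- cfg$blink_dur_ms / 6          # +-3 sd spans the blink
      half_ms <- 3 * sig_ms
      if (n_blink > 0) {
        peaks <- sort(runif(n_blink, half_ms, n / fs * 1000 - half_ms))
        for (p in peaks) {
          idx <- interval_samples(p - half_ms, p + half_ms, fs, n)
          t_ms <- (idx - 1) / fs * 1000
          wave <- cfg$blink_amp * exp(-(t_ms - p)^2 / (2 * sig_ms^2))
          for (ch in eog) X[ch, idx] <- X[ch, idx] + wave
          add("blink", s, rownames(X)[eog[1]], p - half_ms, p + half_ms, p,
              cfg$blink_amp)
        }
      }
    }

    ## muscle bursts on scalp channels
    if (cfg$muscle_rate_per_min > 0 && length(scalp)) {
      n_burst <- rpois(1, cfg$muscle_rate_per_min * dur_min)
      if (n_burst > 0) {
        onsets <- sort(runif(n_burst, 0, n / fs * 1000 - cfg$muscle_dur_ms))
        for (o in onsets) {
          ch <- sample(scalp, 1)
          idx <- interval_samples(o, o + cfg$muscle_dur_ms, fs, n)
          burst <- fft_bandpass(rnorm(length(idx)), fs,
                                cfg$muscle_band[1], cfg$muscle_band[2])
          burst <- burst / max(sd(burst), 1e-12) * cfg$muscle_amp
          burst <- burst * envelope_ramp(length(idx), fs, ramp_ms = 30)
          X[ch, idx] <- X[ch, idx] + burst
          add("muscle", s, rownames(X)[ch], o, o + cfg$muscle_dur_ms, NA,
              cfg$muscle_amp)
        }
      }
    }

    ## linear drift on every scalp channel
    if (any(cfg$drift_range != 0)) {
      for (ch in scalp) {
        slope <- runif(1, cfg$drift_range[1], cfg$drift_range[2])
        X[ch, ] <- X[ch, ] + slope * tt
        add("drift", s, rownames(X)[ch], 0, n / fs * 1000, NA, slope)
      }
    }
    rec$samples[[s]] <- X
  }

  ledger <- if (length(led)) do.call(rbind, led) else
    data.frame(kind = character(0), subject = integer(0), channel = character(0),
               onset_ms = numeric(0), offset_ms = numeric(0),
               peak_ms = numeric(0), value = numeric(0))
  list(recording = rec, ledger = ledger)
}
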