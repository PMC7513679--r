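## Shared builders for desk-scale synthetic scenarios. Simulation sizes in the
## module tests are scaled down from the full defaults (60 electrodes, 32
## trials) so the whole suite stays within its time budget; the statistical
## structure under test is unchanged.

## Shortened non-s1 segments: cuts session length ~3x while keeping every
## segment long enough for at least two 80 ms analysis windows.
short_segments <- function() {
  list(s9 = c(400, 80, 250, 700), s0 = c(350, 70, 250, 600),
       s2 = c(350, 70, 250, 600), s3 = c(400, 80, 250, 700),
       s4 = c(350, 70, 250, 600), s5 = c(400, 80, 250, 700),
       s6 = c(300, 60, 200, 500), s7a = c(250, 50, 200, 400),
       s7b = c(250, 50, 200, 400), s8 = c(300, 60, 200, 500))
}

## Minimal clean dyad: no artifacts, no planted power patterns, single
## coupled oscillator; used for phase-coupling ground-truth checks.
clean_cfg <- function(n_scalp = 1, n_trials = 2, fixed_coupling = NULL,
                      noise_sd = 0, coupling_freqs = 27.5,
                      seg_durations = short_segments(), ...) {
  scenario_config(n_trials = n_trials, n_scalp = n_scalp,
                  seg_durations = seg_durations,
                  coupling_freqs = coupling_freqs,
                  fixed_coupling = fixed_coupling,
                  noise_sd = noise_sd, eog_noise_sd = max(noise_sd / 2, 0),
                  pattern_amp = 0,
                  blink_rate_per_min = 0, muscle_rate_per_min = 0,
                  drift_range = c(0, 0), gap_ms = 400, ...)
}

## Inter-brain PLV of subject-1 vs subject-2 scalp channel 1 at one frequency
## for all instances of one segment id; returns one PLV per instance.
## Independent, direct route (morlet on a padded excerpt + plv()), used as a
## light oracle against the full dyad_coherence driver.
measure_inter_plv <- function(ses, segment, freq, grid = analysis_grid(),
                              n_cycles = 7) {
  rec <- ses$recording
  fs <- rec$fs
  n <- ncol(rec$samples[[1]])
  margin <- ceiling(4 * n_cycles / (2 * pi * freq) * fs)
  margin_ms <- margin * 1000 / fs
  rows <- ses$segments[ses$segments$segment == segment, ]
  ch <- lapply(1:2, function(s) {
    which(rec$channel_types[[s]] == "scalp")[1]
  })
  out <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    w <- segment_windows(rows$onset_ms[i], rows$offset_ms[i], grid)
    if (nrow(w) < 2) next
    ex0 <- max(0, rows$onset_ms[i] - margin_ms)
    ex1 <- min(n * 1000 / fs, rows$offset_ms[i] + margin_ms)
    idx <- interval_samples(ex0, ex1, fs, n)
    centers <- ms_to_sample(w$center_ms, fs) - idx[1] + 1L
    keep <- centers > margin & centers <= length(idx) - margin
    if (sum(keep) < 2) next
    ph <- lapply(1:2, function(s) {
      st <- morlet_transform(rec$samples[[s]][ch[[s]], idx], fs, freq, n_cycles)
      Arg(st$coeffs[1, centers[keep]])
    })
    out <- c(out, plv(ph[[1]], ph[[2]]))
  }
  out
}

## ms_to_sample / interval_samples are internal; expose for helpers above.
ms_to_sample <- dyadsync:::ms_to_sample
interval_samples <- dyadsync:::interval_samples
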