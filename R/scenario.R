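#' Scenario configuration for the synthetic dual-EEG generator
#'
#' Describes the statistical world the generator emulates: segment-structured
#' trials whose s1 duration ("leader readiness", follower tap to leader
#' movement onset) varies across trials; inter-brain phase coupling in the
#' beta/gamma range that strengthens with readiness during the
#' information-exchange segments only; centro-parietal wavelet-power patterns
#' with symmetric same-frequency leader/follower co-modulation in low-readiness
#' trials and asymmetric cross-frequency co-modulation (follower 25 Hz with
#' leader 18 Hz, follower 20 Hz with leader 30 Hz) in high-readiness trials;
#' 1/f background noise; and ocular blink, muscle-burst and linear-drift
#' artifacts.
#'
#' The s1 duration distribution is lognormal with parameters chosen so that
#' its 35th/65th percentiles sit at the published class cutoffs (338 ms and
#' 523 ms). The readiness-to-coupling map is affine and decreasing in s1
#' duration, clipped to `[0, 1]`: full coupling at `coupling_d_full` ms and
#' zero at `coupling_d_zero` ms.
#'
#' @param n_trials trials per session (default 32, one per building)
#' @param fs sampling rate in Hz; 250 by default for desk-scale work (the
#'   laboratory rate of 1000 Hz is available by configuration)
#' @param n_scalp scalp electrodes per subject (default 60; reduced montages
#'   keep the centro-parietal set, see [default_montage()])
#' @param seg_durations named list of `c(mean, sd, min, max)` in ms for every
#'   segment except s1 (truncated-normal draws)
#' @param s1_meanlog,s1_sdlog,s1_min,s1_max lognormal parameters and bounds
#'   (ms) of the s1 duration distribution
#' @param split_percentiles percentile cutoffs of the high/low readiness split
#' @param coupling_freqs oscillator frequencies (Hz) carrying inter-brain
#'   phase coupling, one per reporting band by default
#' @param coupling_amp oscillator amplitude, microvolts
#' @param coupled_segments segments in which the programmed coupling applies;
#'   elsewhere coupling is `baseline_coupling`
#' @param baseline_coupling coupling strength outside `coupled_segments`
#' @param coupling_d_full,coupling_d_zero s1 durations (ms) mapping to
#'   coupling 1 and 0
#' @param fixed_coupling if non-NULL, overrides the readiness map with a
#'   constant coupling strength in `[0, 1]` (used for calibration experiments)
#' @param phase_noise_sd,phase_noise_tau_ms stationary sd (radians) and
#'   correlation time of the Ornstein-Uhlenbeck phase noise of each oscillator
#' @param topo_range range of the per-channel projection weights of the
#'   coupling oscillators
#' @param pattern_electrodes scalp labels carrying the planted power patterns
#' @param sym_freqs frequencies (Hz) of the symmetric same-frequency power
#'   co-modulation planted in low-readiness trials
#' @param asym_follower_freqs,asym_leader_freqs paired frequencies (Hz) of the
#'   asymmetric cross-frequency co-modulation planted in high-readiness trials
#' @param pattern_amp planted oscillator amplitude, microvolts
#' @param pattern_amp_sdlog lognormal sd of the per-trial amplitude factor
#'   shared within a co-modulated pair (this sharing is what creates the
#'   across-trial power correlation)
#' @param pattern_env_sdlog,pattern_env_tau_ms within-segment slow lognormal
#'   envelope parameters
#' @param noise_sd,noise_exponent amplitude (microvolts) and spectral exponent
#'   of the 1/f^a background noise per scalp channel
#' @param eog_noise_sd baseline EOG channel noise, microvolts
#' @param blink_rate_per_min,blink_amp,blink_dur_ms ocular blink artifact
#'   model (stereotyped Gaussian transients on the EOG channels)
#' @param muscle_rate_per_min,muscle_amp,muscle_dur_ms,muscle_band muscle
#'   artifact model (40-60 Hz band-limited noise bursts on scalp channels)
#' @param drift_range linear drift slope range, microvolts per second
#' @param gap_ms inter-trial gap (also applied before the first and after the
#'   last trial so wavelet edge effects do not eat into segments)
#' @param seed default RNG seed used by [generate_session()]
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(n_trials = 32,
                            fs = 250,
                            n_scalp = 60,
                            seg_durations = list(
                              s9  = c(1500, 300, 800, 2500),
                              s0  = c(800, 200, 300, 1500),
                              s2  = c(600, 150, 250, 1200),
                              s3  = c(1200, 300, 500, 2000),
                              s4  = c(800, 200, 300, 1500),
                              s5  = c(1500, 300, 700, 2500),
                              s6  = c(800, 200, 300, 1500),
                              s7a = c(600, 150, 250, 1200),
                              s7b = c(500, 150, 200, 1000),
                              s8  = c(1500, 300, 700, 2500)),
                            s1_meanlog = 6.041, s1_sdlog = 0.567,
                            s1_min = 150, s1_max = 2000,
                            split_percentiles = c(35, 65),
                            coupling_freqs = c(22, 27.5, 32, 37),
                            coupling_amp = 4,
                            coupled_segments = c("s9", "s0", "s1", "s2", "s3", "s4"),
                            baseline_coupling = 0,
                            coupling_d_full = 100, coupling_d_zero = 1000,
                            fixed_coupling = NULL,
                            phase_noise_sd = 1.2, phase_noise_tau_ms = 150,
                            topo_range = c(0.4, 1),
                            pattern_electrodes = centro_parietal_set(),
                            sym_freqs = c(18, 20, 25, 30),
                            asym_follower_freqs = c(25, 20),
                            asym_leader_freqs = c(18, 30),
                            pattern_amp = 8,
                            pattern_amp_sdlog = 0.25,
                            pattern_env_sdlog = 0.3, pattern_env_tau_ms = 400,
                            noise_sd = 10, noise_exponent = 1,
                            eog_noise_sd = 5,
                            blink_rate_per_min = 10, blink_amp = 120,
                            blink_dur_ms = 300,
                            muscle_rate_per_min = 4, muscle_amp = 20,
                            muscle_dur_ms = 300, muscle_band = c(40, 60),
                            drift_range = c(-2, 2),
                            gap_ms = 500,
                            seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#' @param cfg a [scenario_config()]
#' @return `cfg`, invisibly
#' @export
validate_scenario <- function(cfg) {
  stopifnot(cfg$n_trials >= 1, cfg$fs > 120, cfg$n_scalp >= 1, cfg$n_scalp <= 60)
  for (nm in setdiff(segment_ids(), "s1")) {
    d <- cfg$seg_durations[[nm]]
    if (is.null(d) || length(d) != 4 || any(d[c(1, 3, 4)] <= 0)) {
      stop("seg_durations must give c(mean, sd, min, max) > 0 for ", nm)
    }
  }
  stopifnot(cfg$s1_min > 0, cfg$s1_max > cfg$s1_min)
  rates <- c(cfg$blink_rate_per_min, cfg$muscle_rate_per_min)
  if (any(rates < 0)) stop("artifact rates must be >= 0")
  if (!is.null(cfg$fixed_coupling)) {
    stopifnot(cfg$fixed_coupling >= 0, cfg$fixed_coupling <= 1)
  }
  stopifnot(cfg$baseline_coupling >= 0, cfg$baseline_coupling <= 1)
  if (length(cfg$asym_follower_freqs) != length(cfg$asym_leader_freqs)) {
    stop("asymmetric frequency maps must pair follower and leader frequencies")
  }
  stopifnot(all(cfg$split_percentiles > 0), all(cfg$split_percentiles < 100))
  invisible(cfg)
}

#' Readiness-to-coupling map
#'
#' Affine decreasing function of s1 duration, clipped to `[0, 1]`: trials with
#' a prompt leader (short s1) get strong inter-brain phase coupling.
#' @param s1_ms s1 duration(s) in milliseconds
#' @param cfg a [scenario_config()]
#' @return coupling strength(s) in `[0, 1]`
#' @export
readiness_coupling <- function(s1_ms, cfg) {
  if (!is.null(cfg$fixed_coupling)) {
    return(rep(cfg$fixed_coupling, length(s1_ms)))
  }
  clip01((cfg$coupling_d_zero - s1_ms) / (cfg$coupling_d_zero - cfg$coupling_d_full))
}
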