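## Round a duration in ms to a whole number of samples at fs.
round_to_samples <- function(ms, fs) round(ms * fs / 1000) * 1000 / fs

## Truncated-normal draw by clamping (documented simplification: clamping
## slightly inflates density at the bounds, which are several sd away).
rtnorm_clamp <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, rnorm(n, mean, sd)))

#' Generate a synthetic dual-EEG session
#'
#' Produces a synchronized two-subject recording, its behavioral segment
#' table, and a ground-truth ledger. The source model is a small set of
#' band-limited oscillators per subject whose phase is a mixture of a common
#' drive and private phase noise, with mixing weight equal to the programmed
#' coupling strength; that gives direct, provable control over the
#' phase-locking value. During the information-exchange segments
#' (`cfg$coupled_segments`, by default s9 and s0-s4) the coupling strength is
#' `g(readiness)` of that trial; elsewhere it is the configured baseline.
#' Planted centro-parietal power patterns follow the symmetric (low-readiness)
#' or asymmetric (high-readiness) co-modulation specification. Each planted
#' oscillator has an independent random phase per electrode so the power
#' structure leaves the phase-coherence analysis untouched.
#'
#' @param cfg a [scenario_config()]
#' @param seed RNG seed (overrides `cfg$seed`); identical seeds give
#'   bit-identical sessions
#' @param artifacts add blink/muscle/drift artifacts (via
#'   [inject_artifacts()]) at the configured rates
#' @return list with elements `recording` ([dual_recording()]), `segments`
#'   ([segment_table()]), `truth` (per-trial data.frame: `trial`, `s1_ms`,
#'   `coupling`, `class`, `pattern_id`), `artifacts` (ledger from
#'   [inject_artifacts()] or NULL), and `config`
#' @export
generate_session <- function(cfg, seed = cfg$seed, artifacts = TRUE) {
  validate_scenario(cfg)
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$fs

  ## --- segment layout ------------------------------------------------------
  seg_order <- segment_ids()
  gap <- round_to_samples(cfg$gap_ms, fs)
  rows <- list()
  t_cur <- gap
  s1_ms <- numeric(cfg$n_trials)
  for (tr in seq_len(cfg$n_trials)) {
    for (sg in seg_order) {
      if (sg == "s1") {
        d <- min(cfg$s1_max, max(cfg$s1_min, rlnorm(1, cfg$s1_meanlog, cfg$s1_sdlog)))
        d <- round_to_samples(d, fs)
        s1_ms[tr] <- d
      } else {
        p <- cfg$seg_durations[[sg]]
        d <- round_to_samples(rtnorm_clamp(1, p[1], p[2], p[3], p[4]), fs)
      }
      rows[[length(rows) + 1]] <- data.frame(trial = tr, segment = sg,
                                             onset_ms = t_cur, offset_ms = t_cur + d)
      t_cur <- t_cur + d
    }
    t_cur <- t_cur + gap
  }
  segs <- segment_table(do.call(rbind, rows))
  total_ms <- t_cur
  n <- as.integer(round(total_ms * fs / 1000))
  if (n < 2) stop("degenerate configuration: zero-length session")

  ## --- readiness, classes, planted structure -------------------------------
  g_trial <- readiness_coupling(s1_ms, cfg)
  cuts <- quantile(s1_ms, cfg$split_percentiles / 100, type = 7, names = FALSE)
  cls <- rep("middle", cfg$n_trials)
  cls[s1_ms < cuts[1]] <- "high"
  cls[s1_ms > cuts[2]] <- "low"
  pattern_id <- ifelse(cls == "high", "asym", ifelse(cls == "low", "sym", "none"))

  ## per-sample coupling strength from the segment layout
  g_t <- rep(cfg$baseline_coupling, n)
  for (i in seq_len(nrow(segs))) {
    if (segs$segment[i] %in% cfg$coupled_segments) {
      idx <- interval_samples(segs$onset_ms[i], segs$offset_ms[i], fs, n)
      g_t[idx] <- g_trial[segs$trial[i]]
    }
  }

  labels <- default_montage(cfg$n_scalp)
  k <- cfg$n_scalp
  tt <- (seq_len(n) - 1) / fs
  X <- list(matrix(0, k, n), matrix(0, k, n))
  tau_s <- cfg$phase_noise_tau_ms / 1000

  ## --- coupled band-limited oscillators ------------------------------------
  ## One projection weight per oscillator, uniform across a subject's
  ## electrodes: with channel-varying weights the within-subject mixture
  ## phase at a frequency bin would depend on the coupling mixing weight
  ## (relative oscillator phase variance scales with g^2 + (1-g)^2), leaking
  ## the programmed inter-brain coupling into intra-brain coherence.
  for (f in cfg$coupling_freqs) {
    psi <- ou_path(n, fs, cfg$phase_noise_sd, tau_s, smooth_ms = 20)
    w <- rep(runif(1, cfg$topo_range[1], cfg$topo_range[2]), k)
    base <- 2 * pi * f * tt
    for (s in 1:2) {
      eta <- ou_path(n, fs, cfg$phase_noise_sd, tau_s, smooth_ms = 20)
      phi <- base + g_t * psi + (1 - g_t) * eta
      X[[s]] <- X[[s]] + cfg$coupling_amp * (w %o% cos(phi))
    }
  }

  ## --- planted centro-parietal power patterns ------------------------------
  cp_idx <- match(intersect(cfg$pattern_electrodes, labels), labels)
  leader <- 1L   # subject 1 leads by construction
  follower <- 2L
  s1_rows <- segs[segs$segment == "s1", ]
  for (tr in seq_len(cfg$n_trials)) {
    spec <- pattern_id[tr]
    if (spec == "none" || length(cp_idx) == 0) next
    row <- s1_rows[s1_rows$trial == tr, ]
    idx <- interval_samples(row$onset_ms, row$offset_ms, fs, n)
    if (length(idx) < 4) next
    ramp <- envelope_ramp(length(idx), fs, ramp_ms = 20)
    plant <- function(subject, f, amp_factor, env) {
      ph <- runif(length(cp_idx), 0, 2 * pi)       # independent phase/electrode
      carrier <- outer(ph, 2 * pi * f * tt[idx], `+`)
      a <- cfg$pattern_amp * amp_factor * env * ramp
      X[[subject]][cp_idx, idx] <<-
        X[[subject]][cp_idx, idx] + cos(carrier) * rep(a, each = length(cp_idx))
    }
    if (spec == "sym") {
      for (f in cfg$sym_freqs) {
        m <- rlnorm(1, 0, cfg$pattern_amp_sdlog)
        env <- exp(ou_path(length(idx), fs, cfg$pattern_env_sdlog,
                           cfg$pattern_env_tau_ms / 1000))
        plant(leader, f, m, env)
        plant(follower, f, m, env)
      }
    } else {
      for (p in seq_along(cfg$asym_follower_freqs)) {
        m <- rlnorm(1, 0, cfg$pattern_amp_sdlog)
        env <- exp(ou_path(length(idx), fs, cfg$pattern_env_sdlog,
                           cfg$pattern_env_tau_ms / 1000))
        plant(follower, cfg$asym_follower_freqs[p], m, env)
        plant(leader, cfg$asym_leader_freqs[p], m, env)
      }
    }
  }

  ## --- background noise and assembly ---------------------------------------
  samples <- vector("list", 2)
  types <- vector("list", 2)
  for (s in 1:2) {
    for (ch in seq_len(k)) {
      X[[s]][ch, ] <- X[[s]][ch, ] + pink_noise(n, cfg$noise_sd, cfg$noise_exponent)
    }
    eog <- matrix(pink_noise(n, cfg$eog_noise_sd, cfg$noise_exponent), 1, n)
    M <- rbind(X[[s]], eog)
    rownames(M) <- c(labels, "EOG")
    samples[[s]] <- M
    types[[s]] <- c(rep("scalp", k), "eog")
  }
  rec <- dual_recording(samples, fs = fs, channel_types = types,
                        roles = c("leader", "follower"), t0 = 0)

  truth <- data.frame(trial = seq_len(cfg$n_trials), s1_ms = s1_ms,
                      coupling = g_trial, class = cls, pattern_id = pattern_id)
  attr(truth, "cutoffs_ms") <- cuts
  attr(truth, "coupled_segments") <- cfg$coupled_segments
  attr(truth, "coupling_freqs") <- cfg$coupling_freqs

  ledger <- NULL
  if (artifacts &&
      (cfg$blink_rate_per_min > 0 || cfg$muscle_rate_per_min > 0 ||
       any(cfg$drift_range != 0))) {
    art <- inject_artifacts(rec, cfg)
    rec <- art$recording
    ledger <- art$ledger
  }

  list(recording = rec, segments = segs, truth = truth,
       artifacts = ledger, config = cfg)
}

## Raised-cosine on/off ramp of ramp_ms at each end of a segment of len samples.
envelope_ramp <- function(len, fs, ramp_ms = 20) {
  r <- min(floor(len / 4), max(1, round(ramp_ms * fs / 1000)))
  env <- rep(1, len)
  up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  env[seq_len(r)] <- up
  env[len + 1 - seq_len(r)] <- up
  env
}
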