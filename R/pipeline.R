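#' Multi-team coherence-readiness study
#'
#' Simulates `n_dyads` sessions, preprocesses each, computes segment-wise
#' intra-/inter-brain coherence, pools trials over all teams (readiness
#' cutoffs computed on the pooled s1 durations), and runs the trimmed
#' correlation scan.
#'
#' @param cfg a [scenario_config()]
#' @param n_dyads number of teams to simulate
#' @param seed base RNG seed; team d uses `seed + d`
#' @param grid an [analysis_grid()]
#' @param preprocess run artifact correction before the analysis
#' @param segments segments to analyze
#' @return list: `scan` (correlation grid), `coherence` (pooled per-trial
#'   table with team-qualified trial ids), `readiness` (pooled table)
#' @export
run_coherence_study <- function(cfg, n_dyads = 8, seed = 1,
                                grid = analysis_grid(), preprocess = TRUE,
                                segments = c("s9", "s0", "s1", "s2", "s3",
                                             "s4", "s5")) {
  coh_all <- list(); seg_all <- list()
  for (d in seq_len(n_dyads)) {
    ses <- generate_session(cfg, seed = seed + d)
    rec <- ses$recording; mask <- NULL
    if (preprocess) {
      pp <- preprocess_recording(rec)
      rec <- pp$recording; mask <- pp$mask
    }
    coh <- dyad_coherence(rec, ses$segments, grid, mask, segments = segments)
    ## qualify trial ids so pooling across teams keeps pairs distinct
    coh$trial <- sprintf("d%02d_t%03d", d, coh$trial)
    segs <- as.data.frame(ses$segments)
    segs$trial <- sprintf("d%02d_t%03d", d, segs$trial)
    coh_all[[d]] <- coh
    seg_all[[d]] <- segs
  }
  coh <- do.call(rbind, coh_all)
  segs <- segment_table(do.call(rbind, seg_all))
  readiness <- leader_readiness(segs)   # pooled cutoffs over all trials/teams
  scan <- coherence_readiness_scan(coh, readiness)
  list(scan = scan, coherence = coh, readiness = readiness)
}

#' Pattern-specificity and asymmetry study
#'
#' Simulates `n_dyads` sessions, preprocesses each, builds the s1 dyadic
#' wavelet-power patterns, splits trials into readiness classes at percentile
#' cutoffs pooled over all trials and teams, mines class-specific patterns
#' within each dyad with the percentile distance criterion, pools the
#' specific patterns of all dyads per class, and computes the inter-subject
#' frequency correlation matrices, asymmetry coefficients, the Wilcoxon
#' comparison and the strongest asymmetric frequency pairs.
#'
#' The wavelet width for this pathway defaults to `n_cycles = 20` (spectral
#' sd about 0.8-2 Hz over the grid): power patterns are resolved on a 0.5 Hz
#' frequency grid and distinguishing cross-frequency associations a few Hz
#' apart requires a spectral bandwidth well below their separation. The
#' phase-coherence pathway keeps the faster 7-cycle wavelet, where temporal
#' resolution against 80 ms windows matters instead.
#'
#' @param cfg a [scenario_config()]
#' @param n_dyads number of teams to simulate and pool
#' @param seed base RNG seed; team d uses `seed + d`
#' @param grid an [analysis_grid()]
#' @param preprocess run artifact correction first
#' @param percentile class-distance percentile
#' @param electrode_set set for the frequency correlation
#' @param n_cycles Morlet width for the power patterns
#' @return list: `patterns` (pooled matrix), `classes`, `dyad` (per pattern),
#'   `readiness`, `n_specific` (named high/low, pooled), `M_high`, `M_low`
#'   (frequency correlation matrices, follower rows x leader columns),
#'   `asym_high`, `asym_low` (coefficient tables), `test`
#'   ([asymmetry_test()]), `top_pairs`
#' @export
run_pattern_study <- function(cfg, n_dyads = 1, seed = 1,
                              grid = analysis_grid(), preprocess = TRUE,
                              percentile = 10,
                              electrode_set = centro_parietal_set(),
                              n_cycles = 20) {
  pats <- list(); s1 <- list(); meta <- NULL
  for (d in seq_len(n_dyads)) {
    ses <- generate_session(cfg, seed = seed + d)
    rec <- ses$recording; mask <- NULL
    if (preprocess) {
      pp <- preprocess_recording(rec)
      rec <- pp$recording; mask <- pp$mask
    }
    pat <- build_patterns(rec, ses$segments, grid, mask, n_cycles = n_cycles)
    pats[[d]] <- pat
    seg <- as.data.frame(ses$segments)
    seg$trial <- sprintf("d%02d_t%03d", d, seg$trial)
    s1[[d]] <- seg
    if (is.null(meta)) meta <- pat[c("k", "f", "freqs", "labels", "roles")]
  }
  readiness <- leader_readiness(segment_table(do.call(rbind, s1)))

  spec_high <- list(); spec_low <- list()
  all_pat <- list(); all_cls <- list(); all_dyad <- list()
  for (d in seq_len(n_dyads)) {
    trial_ids <- sprintf("d%02d_t%03d", d, pats[[d]]$trial)
    cls <- readiness$class[match(trial_ids, readiness$trial)]
    all_pat[[d]] <- pats[[d]]$patterns
    all_cls[[d]] <- cls
    all_dyad[[d]] <- rep(d, length(cls))
    if (sum(cls == "high") < 2 || sum(cls == "low") < 2) {
      message("dyad ", d, ": a readiness class has fewer than 2 patterns; ",
              "skipped in mining")
      next
    }
    mining <- mine_specific_patterns(pats[[d]]$patterns, cls, percentile)
    spec_high[[d]] <- pats[[d]]$patterns[mining$specific_high, , drop = FALSE]
    spec_low[[d]] <- pats[[d]]$patterns[mining$specific_low, , drop = FALSE]
  }
  H <- do.call(rbind, spec_high)
  L <- do.call(rbind, spec_low)
  n_spec <- c(high = if (is.null(H)) 0L else nrow(H),
              low = if (is.null(L)) 0L else nrow(L))
  out <- list(patterns = do.call(rbind, all_pat),
              classes = unlist(all_cls), dyad = unlist(all_dyad),
              readiness = readiness, n_specific = n_spec,
              M_high = NULL, M_low = NULL, asym_high = NULL, asym_low = NULL,
              test = NULL, top_pairs = NULL)
  if (n_spec["high"] < 3 || n_spec["low"] < 3) {
    message("fewer than 3 specific patterns in a class; ",
            "asymmetry analysis skipped")
    return(out)
  }
  out$M_high <- frequency_corr(H, electrode_set, meta$labels, meta$roles,
                               meta$k, meta$f)
  out$M_low <- frequency_corr(L, electrode_set, meta$labels, meta$roles,
                              meta$k, meta$f)
  out$asym_high <- asymmetry_coefficient(out$M_high)
  out$asym_low <- asymmetry_coefficient(out$M_low)
  out$test <- asymmetry_test(out$asym_high$a, out$asym_low$a)
  out$top_pairs <- top_asymmetry_pairs(out$M_high, meta$freqs, n = 2)
  out
}
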