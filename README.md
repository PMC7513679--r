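# dyadsync

Analysis of dual-EEG (hyperscanning) recordings from two-person teams
performing a segmented coordination task, for researchers studying the
neural correlates of team coordination. A *follower* cues a *leader* to
initiate a joint maneuver; the interval from cue to movement onset (segment
s1) measures **leader readiness**, the behavioral index of team
coordination. The package asks two questions of such data:

1. Does **inter-brain phase coherence** track team coordination?
   Phase-locking values over 80 ms windows stepped by 40 ms,

       c_jk(φ) = (1/N) |Σ_n exp(i(φ_n(j) − φ_n(k)))|,

   for all electrode pairs j, k ∈ {1, …, 120} of the dyad at frequencies
   φ ∈ {15, 15.5, …, 40} Hz, averaged into intra-brain (1,770 pairs per
   subject) and inter-brain (3,600 pairs) band coherence per trial segment,
   then correlated with readiness after excluding the 5% tails of both
   variables.

2. Are there **dyadic wavelet-power patterns specific to high vs. low
   coordination**? Each trial's s1 power over both subjects' electrodes and
   all frequencies is one vector in a 2·60·51 = 6,120-dimensional space;
   with the distance d(x, y) = ‖x − y‖² / (‖x‖‖y‖), a pattern is *specific*
   to its readiness class when its 10th-percentile inter-class distance
   exceeds its 10th-percentile intra-class distance. Inter-subject
   correlation of the specific patterns' centro-parietal power across
   frequencies, and a Wilcoxon signed-rank test on the asymmetry
   coefficients |M(i,j) − M(j,i)|, then quantify role-dependent
   cross-frequency structure.

Because such recordings are typically available only on request, the package
ships a coupled-oscillator synthetic dual-EEG generator
(`generate_session()`) with a ground-truth ledger: programmed inter-brain
coupling that strengthens with readiness during information-exchange
segments, planted symmetric/asymmetric centro-parietal power co-modulation,
1/f background, and blink/muscle/drift artifacts. Every pipeline stage has a
recovery test against this world.

## Worked example

```r
library(dyadsync)

grid <- analysis_grid()              # 15-40 Hz / 0.5 Hz, 80/40 ms windows
cfg  <- scenario_config(n_trials = 12, n_scalp = 12)  # desk-scale montage
ses  <- generate_session(cfg, seed = 7)

pp   <- preprocess_recording(ses$recording)   # detrend, blink + muscle mask
coh  <- dyad_coherence(pp$recording, ses$segments, grid, pp$mask)
rdy  <- leader_readiness(ses$segments)
scan <- coherence_readiness_scan(coh, rdy)
head(subset(scan, scope == "inter" & segment == "s3"))
```

```
   segment  band scope     r       p tier n_used
37      s3 20-24 inter 0.797 0.01011    *      9
40      s3 25-30 inter 0.755 0.03050    *      8
43      s3 30-34 inter 0.880 0.00398   **      8
46      s3 35-39 inter 0.778 0.02297    *      8
```

During the approach-to-door segment (s3, an information-exchange segment)
inter-brain coherence in every beta/gamma band correlates positively with
leader readiness — the generator programmed exactly that coupling, and the
pipeline recovers it. The same scan shows no significant association in s5
(movement to corners, no information exchange), and only chance-level hits
(2 of 48 cells at the nominal 5% level) among the intra-brain scopes.

The pattern pathway on the same world:

```r
pat <- run_pattern_study(scenario_config(n_trials = 48, n_scalp = 12),
                         n_dyads = 3, seed = 7)
pat$n_specific
#> high  low
#>   38   48
pat$test$p            # Wilcoxon on asymmetry coefficients, high vs low
#> 4.1e-128
pat$top_pairs[, 1:2]  # strongest asymmetric frequency pairs (Hz)
#>   f_lo f_hi
#> 1   20   30
#> 2   18   25
```

The recovered pairs are the planted follower-25↔leader-18 and
follower-20↔leader-30 associations to within the analysis' spectral
resolution.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs both pathways end to end on freshly simulated sessions — the
coherence-readiness scan over four teams and the pattern-specificity /
asymmetry study — printing the scan grid, the specific-pattern counts, the
Wilcoxon result and the top asymmetric frequency pairs, and writes the
results JSON to `--out`.

A thin command-line wrapper for the individual stages
(`simulate`, `preprocess`, `coherence`, `correlate`, `patterns`,
`asymmetry`) is installed at `inst/cli/dyadsync.R`.

See the methods vignette (`vignettes/dyadsync-methods.Rmd`) for the model
assumptions, parameter defaults and their rationale, the synthetic world's
scope, and known limitations.
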