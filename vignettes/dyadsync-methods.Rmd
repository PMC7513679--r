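---
title: "Methods: inter-brain coherence and dyadic power patterns in dual EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-brain coherence and dyadic power patterns in dual EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dyadsync` analyzes dual-EEG recordings of two-person teams performing a
segmented coordination task in which a *follower* cues a *leader* to initiate
a joint maneuver. Each trial decomposes into behavioral segments s0--s9 (plus
s7a/s7b): restacking and alignment (s9), preparation to tap (s0), the
follower-to-leader tap interval (s1), movement onset and approach (s2, s3),
entry (s4), movement to the corners (s5), and visual scanning and re-forming
(s6--s8). The package implements two complementary analyses:

1. **Inter-brain phase coherence vs. team coordination.** Sliding-window
   phase-locking values (PLV) per electrode pair and frequency, averaged into
   intra-brain and inter-brain band coherence per trial segment, correlated
   with a behavioral *leader readiness* score using 5% tail exclusion.
2. **Class-specific dyadic wavelet-power patterns.** Per trial, the joint
   power of both subjects' electrodes across the frequency grid forms one
   high-dimensional pattern vector; a percentile-based distance criterion
   mines patterns specific to high vs. low team coordination, and an
   inter-subject frequency correlation analysis quantifies the cross-frequency
   asymmetry of the specific patterns.

A coupled-oscillator synthetic generator reproduces the statistical structure
both analyses assume, with a ground-truth ledger, so that every stage has a
recovery test without access to laboratory recordings (which, for the
original study, exist only on request).

# Coordinate conventions

Time is in milliseconds, 0-based, with half-open segment intervals
`[onset, offset)`; this makes the 80 ms / 40 ms window tiling unambiguous.
Electrodes of a dyad are numbered 1..2k (subject 1 first); unordered pairs
exclude self-pairs, giving `k(2k-1)` pairs per frequency — for the full
`k = 60` montage, 1,770 intra-brain pairs per subject, 3,600 inter-brain
pairs, 7,140 in total. The wavelet grid is fixed at 15--40 Hz in 0.5 Hz
steps (`f = 51` bins), so the power state space has `2kf = 6,120` dimensions
and the coherence state space `k(2k-1)f = 364,140`. Reporting bands are
20--24, 25--30, 30--34 and 35--39 Hz; the band edges as printed overlap at
30 Hz, and each bin is assigned to the first band containing it, so 30 Hz
counts toward 25--30 only.

# Time-frequency decomposition

All spectral quantities come from convolution with complex Morlet wavelets,
truncated at four temporal standard deviations and normalized to unit energy
in the continuous sense, which makes the power response to a sinusoid
invariant under the sampling rate (verified to < 2% between 1000 Hz and
250 Hz). Samples within one kernel half-support of a boundary are flagged
invalid and never enter segment averages; the synthetic generator pads
sessions with inter-trial gaps so that no behavioral segment loses windows to
boundaries.

The wavelet width is the one genuinely free parameter:

* **Coherence pathway: `n_cycles = 7`.** Phase is sampled at the center of
  80 ms windows stepped by 40 ms (one representative phase per window; a
  circular-mean alternative is available by configuration). Temporal
  resolution (6 standard deviations: 175--467 ms over the grid) is matched to
  the window geometry; an 80 ms window fully represents frequencies down to
  12.5 Hz.
* **Power-pattern pathway: `n_cycles = 20`.** The spectral standard deviation
  of a Morlet atom is `f / n_cycles`. At 7 cycles this is 2.6--4.3 Hz —
  5--8 times the 0.5 Hz grid spacing, and larger than the separations of the
  cross-frequency associations of interest (18 vs. 20 Hz, 25 vs. 30 Hz). Under
  that much smearing the transposed entries of the inter-subject frequency
  correlation matrix become as large as the direct entries and the asymmetry
  structure is unrecoverable *by any statistic*; resolving structure on a
  0.5 Hz grid presupposes a spectral bandwidth around 1 Hz. At 20 cycles the
  spectral sd is 0.75--2 Hz, which resolves the planted associations while
  the temporal support (at most ~850 ms at 15 Hz) still fits around an s1
  segment. The package default for `morlet_transform()` remains 7; the
  pattern drivers pass 20 explicitly and the choice is logged here.

# Phase-locking value and its aggregation

For a trial segment with `N` valid windows, the coherence of electrodes
`j, k` at frequency `phi` is

    c_jk(phi) = (1/N) | sum_n exp( i (phi_n(j) - phi_n(k)) ) |

(the printed form of this equation omits the imaginary unit; without it the
value cannot lie on the unit circle, so the standard phase-locking value is
implemented). Windows restart at each segment onset because `N` counts
windows *in the trial segment*; windows overlapping artifact-masked samples
of either subject are dropped, and a segment with fewer than two surviving
windows is excluded with a logged reason. For independent uniform phases the
expected PLV decays as `sqrt(pi/4N)`; the acceptance suite checks the −1/2
log-log slope and the exact equivalence of the windowed implementation with a
brute-force complex sum.

Intra-brain coherence averages `c_jk` over all pairs within a subject,
inter-brain coherence over all pairs spanning the two subjects — all pairs,
not only homologous ones — and band coherence averages over the band's grid
frequencies.

# Leader readiness and the trimmed correlation

Leader readiness is the promptness of the leader's movement onset upon the
follower's cue: inversely related to the duration of segment s1. The package
scores readiness as the negated s1 duration so that "more coordination"
is a larger score and the reported correlations carry the intuitive sign.
Trials are split at the 35th/65th percentiles of s1 duration (linear
interpolation between order statistics, `quantile` type 7) pooled over all
trials and teams; in the original study these cutoffs landed at 338 ms and
523 ms, and the generator's default s1 distribution is a lognormal whose
35th/65th percentiles sit at exactly those values
(`meanlog 6.041, sdlog 0.567`).

Correlations between per-trial coherence and readiness exclude, per cell,
trials in the lowest/highest 5% of either variable (union), then compute
Pearson's r with its two-sided p (Spearman by configuration). Cells are
reported with conventional tiers (+ p<0.10, * p<0.05, ** p<0.01,
*** p<0.001) and no multiple-testing correction by default, matching
per-cell reporting practice; a Benjamini--Hochberg option exists. Trials are
pooled over teams (with team-qualified trial identifiers), consistent with
percentile cutoffs "over all trials and teams".

# Pattern mining

For segment s1 of each trial, mean wavelet power over the segment's valid
windows per (subject, electrode, frequency) — power read at window centers,
`mean` reduction by default, `median` by option, no log transform by default
— is flattened subject-major, electrode-major, frequency-minor into one
`2kf`-dimensional vector. The distance between patterns is

    d(x, y) = ||x - y||^2 / (||x|| ||y||)

with the Euclidean norm (the norm is not stated in the source analysis;
Euclidean is assumed). This distance is deliberately *not* invariant under
rescaling one argument — overall power magnitude is part of the pattern —
but is invariant under joint rescaling, so specificity decisions do not
depend on global calibration.

With `N` high- and `n` low-readiness patterns, the `(N+n) x (N+n)` distance
matrix has intra-class diagonal blocks and inter-class off-diagonal blocks.
Per pattern, the intra-class distance is the 10th-percentile of its sorted
intra-block column (self-distance removed first — keeping the zero would
collapse the criterion at small `N`), the inter-class distance the
10th-percentile of its inter-block column; the percentile rank is the
smallest order statistic reaching the percentile (`ceiling(p/100 * m)`),
which is deterministic across platforms. A pattern is *specific* iff its
inter-class distance strictly exceeds its intra-class distance; ties are not
specific. Patterns are mined within each dyad (class labels from the pooled
cutoffs) and the specific patterns pooled across dyads afterwards.

# Electrode clustering and cross-frequency asymmetry

For each team role, electrode profiles (power across frequencies and
specific patterns) yield a `k x k` correlation matrix, reordered by
normalized spectral clustering (affinity `(corr+1)/2`, symmetric graph
Laplacian, k-means on row-normalized leading eigenvectors, Lloyd
iterations) so correlated clusters form diagonal blocks; the cluster count
defaults to the eigengap heuristic. The medial centro-parietal set
(C1, Cz, C2, CP1, CPz, CP2, P3, P1, Pz, P2, POz) is a configuration default
taken from the reported result, with data-driven derivation available
through the clustering.

Averaging specific patterns over that set per subject and frequency and
correlating follower frequency i against leader frequency j across the
class's specific patterns yields an `f x f` matrix per readiness class
(rows = follower, columns = leader; the orientation is a fixed convention).
The asymmetry coefficient per unordered pair is `|M(i,j) - M(j,i)|` — no
formula is given in the source, and this is the simplest per-element
definition; a normalized variant is available. The high- and low-class
coefficient vectors are compared pairwise by a two-sided Wilcoxon
signed-rank test (zeros dropped — classic Wilcoxon rather than Pratt, for
determinism and oracle availability), reporting the direction of the median
difference.

**Locating the asymmetric pairs.** `top_asymmetry_pairs()` separates
*selection* from *localization*: pairs qualify as asymmetric when the
smoothed asymmetry map reaches half its maximum, and qualifying pairs are
ranked by smoothed co-occurrence strength `max(M(i,j), M(j,i))` with 4 Hz
non-maximum suppression. Ranking by raw asymmetry would be biased: where two
associations coexist, leakage from one raises the transposed entries of the
other, eroding its asymmetry ridge on the near side and displacing the peak
outward by 1--3 Hz, while the co-occurrence peak sits on the association
itself. Smoothing at 1 Hz (the analysis' spectral resolution) suppresses
single-bin estimation-noise peaks. At high signal-to-noise a correlation
ridge plateaus out to roughly `sigma_f * sqrt(2 ln R)` (R the
planted-to-background power ratio), about 2--3 Hz here, so recovery within
2 Hz of a planted association is the appropriate notion of "found".

# The synthetic world

`scenario_config()` states the world; `generate_session()` realizes it
deterministically per seed. Defaults are fixed once:

* **Sessions**: 32 trials (one per building of the original task), 60 scalp
  electrodes per subject plus one EOG each, 250 Hz sampling (desk-scale;
  1000 Hz by configuration), 500 ms inter-trial gaps. Segment durations are
  truncated normals with means from several hundred ms (tap, movement
  onsets) to 1.5 s (alignment, corner movement); s1 is the lognormal above.
* **Coupling**: one oscillator per reporting band (22, 27.5, 32, 37 Hz,
  4 uV). Each oscillator's phase is a mixture of a common drive and private
  noise, `phi_s = base + g*psi_common + (1-g)*eta_s`, both
  Ornstein--Uhlenbeck with 1.2 rad stationary sd and 150 ms correlation
  time, smoothed over 20 ms (raw OU innovations are spectrally white and
  would smear the oscillator far outside its band). The mixing weight *is*
  the programmed coupling `g`, so PLV control is provable: `g = 1` gives
  PLV = 1 to machine precision, `g = 0` the independent-phase baseline.
  During the information-exchange segments (s9, s0--s4) `g` follows the
  readiness map `g = clip((1000 - s1_ms)/900)` — affine and decreasing in s1
  duration; elsewhere (s5--s8 and gaps) coupling is baseline 0. Oscillators
  project with one scalar weight per oscillator, uniform across electrodes:
  channel-varying weights would make within-subject mixture phases depend on
  `g` (relative phase variance scales with `g^2 + (1-g)^2`), leaking
  programmed inter-brain coupling into intra-brain coherence, which the
  world must not do.
* **Power patterns**: planted on the 11 centro-parietal electrodes during s1
  only, as amplitude-modulated oscillators (8 uV nominal) with a per-trial
  lognormal amplitude factor (sdlog 0.25) shared within a co-modulated pair
  — this sharing *is* the across-trial power correlation — times a slow
  within-segment lognormal envelope (sdlog 0.3, 400 ms correlation time).
  Low-readiness trials receive the symmetric specification (both subjects at
  18, 20, 25, 30 Hz, envelope shared per frequency); high-readiness trials
  the asymmetric one (follower 25 Hz paired with leader 18 Hz, follower
  20 Hz with leader 30 Hz); middle trials none. Each planted oscillator has
  an independent random phase per electrode, so plants shape power, not
  phase coherence.
* **Noise and artifacts**: per-channel 1/f noise (10 uV), EOG noise (5 uV);
  blinks as 300 ms Gaussian transients on EOG (120 uV, 10/min), muscle
  bursts as 40--60 Hz band-limited noise on random scalp channels (20 uV,
  4/min), and a linear drift of ±2 uV/s per scalp channel — with every
  onset, peak and slope in a ground-truth ledger.

**What the generator does not emulate** — and hence what a green test does
not establish: volume conduction and realistic topographies, saccades,
non-stationary background spectra, genuine behavioral dynamics, and the
temporal causality between preparatory-segment coherence and subsequent
readiness. One interaction deserves emphasis: planted s1 power at
desk-scale amplitudes changes measured s1 PLV through the signal-to-noise
ratio of the phase estimate, and since plant power is class-dependent by
construction, intra-brain s1 coherence acquires a spurious association with
readiness in the full default world. This is a generator-scale artifact
(real s1 power effects are far smaller relative to background), so the
coherence-recovery acceptance study runs with `pattern_amp = 0` and the
power-pattern world is exercised by its own acceptance study.

# Desk-scale acceptance studies

The original study (16 dyads x 32 trials x 60 electrodes at 1000 Hz) is far
beyond a test budget; the suite scales down without changing the statistical
structure and each scaling is stated in the test:

* Coherence recovery: 8 dyads x 16 trials at 24 electrodes/subject, trials
  pooled. Inter-brain band coherence must correlate positively and
  significantly with readiness in the coupled segments (at least 3 of 4
  bands per segment, at least 22 of 24 cells), not in s5 (at most 1 of 4
  cells at the nominal 5% level), with intra-brain cells significant at most
  at a chance-compatible 15%.
* Asymmetry recovery: 50 seeds, each 3 dyads x 48 trials at 12
  electrodes/subject with shortened non-s1 segments (only s1 enters this
  analysis); per-dyad mining at pooled cutoffs, specific patterns pooled per
  class. The Wilcoxon comparison must reject with direction high > low, and
  the two recovered pairs must match the planted (25,18) and (20,30)
  associations within 2 Hz, each in at least 90% of seeds.
* Null calibrations run at the statistic level (independent phase tables,
  independent normal scans), where they are cheap and exact.

# Numerical and degenerate-input policy

Zero-magnitude wavelet coefficients have no phase and are flagged rather
than given an arbitrary angle; flat EOG yields no blink detections rather
than an error; muscle windows require band power above both five times the
channel's median window power and an absolute floor of 0.5% of channel
variance (without the floor, fluctuations of numerically negligible
out-of-band leakage could fire the median-relative threshold on artifact-free
channels); masked windows are excluded, never interpolated, because every
downstream quantity is an average over windows; degenerate readiness splits
(all durations equal) and classes with fewer than the minimum patterns are
reported as such, not silently computed. Percentile rules (type-7 quantiles
for readiness cutoffs and trimming; ceiling ranks for class distances) are
fixed for reproducibility; any consistent rule would do, but one must be
chosen.

# Known limitations

Blink detection masks rather than corrects (no ICA/regression ocular
correction); no re-referencing or channel interpolation; coherence is PLV
only (no imaginary coherency or wPLI debiasing, so volume-conduction-driven
zero-lag coherence in real data lands in the intra-brain averages); the
per-window representative phase is a point estimate; and the cross-frequency
analysis assumes the centro-parietal set unless the clustering-based
derivation is enabled. The readiness-coupling map of the generator is a
design choice (affine, clipped), not an empirical claim.
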