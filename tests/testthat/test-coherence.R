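grid <- analysis_grid()

test_that("window tiling matches hand enumeration, with and without masks", {
  ## 400 ms segment: starts 0,40,...,320 -> 9 windows of 80 ms
  w <- segment_windows(0, 400, grid)
  expect_equal(nrow(w), 9)
  expect_equal(w$start_ms, seq(0, 320, by = 40))
  expect_equal(w$center_ms, w$start_ms + 40)

  ## 100 ms segment: a single window -> too short for a PLV
  expect_equal(nrow(segment_windows(0, 100, grid)), 1)
  expect_equal(nrow(segment_windows(0, 79, grid)), 0)

  ## mask covering [0, 120) ms removes every window overlapping it
  cfg <- clean_cfg(n_scalp = 1, n_trials = 1)
  ses <- generate_session(cfg, seed = 51)
  rec <- ses$recording
  msk <- build_mask(list(data.frame(onset_ms = 0, offset_ms = 120),
                         data.frame(onset_ms = numeric(0),
                                    offset_ms = numeric(0))),
                    NULL, rec)
  wm <- segment_windows(0, 400, grid, fs = rec$fs, mask = msk)
  expect_equal(wm$start_ms, seq(120, 320, by = 40))
})

test_that("the phase-locking value matches its closed forms and brute force", {
  ## constant phase difference -> 1
  set.seed(7)
  ph <- runif(20, -pi, pi)
  expect_equal(plv(ph, ph), 1)
  expect_equal(plv(ph + 0.7, ph), 1)

  ## N-th roots of unity phase differences -> geometric sum 0
  for (N in c(2, 3, 7, 16)) {
    expect_lt(plv(2 * pi * seq_len(N) / N, rep(0, N)), 1e-12)
  }

  ## hand-computed two-window cases
  expect_lt(plv(c(0, pi), c(0, 0)), 1e-12)
  expect_equal(plv(c(0, pi / 2), c(0, 0)), sqrt(2) / 2)

  expect_error(plv(c(0, 1), c(0, 1, 2)), "length")

  ## brute-force complex-sum oracle, symmetry, offset invariance, bounds
  plv_brute <- function(a, b) {
    acc <- 0i
    for (i in seq_along(a)) acc <- acc + exp(1i * (a[i] - b[i]))
    Mod(acc) / length(a)
  }
  for (r in 1:100) {
    N <- sample(2:40, 1)
    a <- runif(N, -pi, pi); b <- runif(N, -pi, pi)
    v <- plv(a, b)
    expect_equal(v, plv_brute(a, b), tolerance = 1e-12)
    expect_equal(v, plv(b, a), tolerance = 1e-12)
    expect_equal(v, plv(a + 1.234, b), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v + 1e-15, 1)
  }
})

test_that("window phases equal the analytic phase and are stable to grid shifts", {
  fs <- 250
  tt <- seq(0, 6 - 1/fs, by = 1/fs)
  f0 <- 25; phi0 <- 0.9
  x <- cos(2 * pi * f0 * tt + phi0)
  st <- morlet_transform(x, fs, grid$freqs)
  fi <- which(grid$freqs == f0)
  for (start in c(2000, 3000)) {
    ph <- window_phase(st, start, fi, grid)
    t_center <- (ms_to_sample(start + 40, fs) - 1) / fs
    expect_equal(Arg(exp(1i * (ph - (2 * pi * f0 * t_center + phi0)))), 0,
                 tolerance = 0.02)
  }
  ## identical signals -> identical window phases
  st2 <- morlet_transform(x, fs, grid$freqs)
  expect_identical(window_phase(st2, 2000, fi, grid),
                   window_phase(st, 2000, fi, grid))
  ## boundary windows are refused
  expect_true(is.na(window_phase(st, 0, 1, grid)))

  ## shifting the window grid by one step barely moves the PLV of a
  ## stationary pair (4 s segments)
  set.seed(8)
  deltas <- replicate(20, {
    n <- 10 * fs
    y1 <- dyadsync:::fft_bandpass(rnorm(n), fs, 22, 28)
    y2 <- dyadsync:::fft_bandpass(rnorm(n), fs, 22, 28)
    sa <- morlet_transform(y1, fs, 25)
    sb <- morlet_transform(y2, fs, 25)
    pl <- function(offset) {
      w <- segment_windows(2000 + offset, 6000 + offset, grid)
      cs <- ms_to_sample(w$center_ms, fs)
      plv(Arg(sa$coeffs[1, cs]), Arg(sb$coeffs[1, cs]))
    }
    abs(pl(0) - pl(40))
  })
  expect_lt(mean(deltas), 0.05)
})

test_that("scope aggregation averages the right electrode pairs", {
  k <- 60
  msks <- dyadsync:::scope_masks(k)
  expect_equal(sum(msks$intra_1), 1770)
  expect_equal(sum(msks$intra_2), 1770)
  expect_equal(sum(msks$inter), 3600)
  expect_equal(sum(msks$intra_1) + sum(msks$intra_2) + sum(msks$inter),
               k * (2 * k - 1))
  ## consistency with the state-space dimensionality for small k
  for (kk in 1:8) {
    mm <- dyadsync:::scope_masks(kk)
    expect_equal(sum(mm$intra_1) + sum(mm$intra_2) + sum(mm$inter),
                 unname(state_space_dims(kk, 1)["coherence_dim"]))
  }

  ## constant PLV array -> the constant, for every scope
  arr <- array(0.3, c(6, 6, 2))
  for (sc in c("inter", "intra_1", "intra_2")) {
    expect_equal(aggregate_coherence(arr, c(20, 21), c(20, 21), sc), 0.3)
  }
  expect_error(aggregate_coherence(arr, c(20, 21), c(50, 60)), "band")
})

test_that("pairwise PLV equals the scalar implementation on random phase tables", {
  set.seed(9)
  ph <- array(runif(8 * 3 * 12, -pi, pi), c(8, 3, 12))
  pl <- pairwise_plv(ph)
  for (f in 1:3) for (j in 1:7) for (k in (j + 1):8) {
    expect_equal(pl[j, k, f], plv(ph[j, f, ], ph[k, f, ]), tolerance = 1e-12)
  }
  expect_equal(pl[2, 5, 2], pl[5, 2, 2])
})

test_that("a fully phase-locked dyad yields unit inter-brain coherence", {
  cfg <- clean_cfg(n_scalp = 2, n_trials = 2, fixed_coupling = 1)
  ses <- generate_session(cfg, seed = 52)
  coh <- dyad_coherence(ses$recording, ses$segments, grid, segments = "s3")
  expect_true(all(coh$mean_plv > 1 - 1e-6))
  expect_true(all(c("inter", "intra_1", "intra_2") %in% coh$scope))
})

test_that("segments too short for two windows are dropped with a reason", {
  cfg <- clean_cfg(n_scalp = 1, n_trials = 1)
  ses <- generate_session(cfg, seed = 53)
  segs <- ses$segments
  segs$offset_ms[segs$segment == "s2"] <- segs$onset_ms[segs$segment == "s2"] + 100
  segs <- segment_table(as.data.frame(segs))
  coh <- dyad_coherence(ses$recording, segs, grid, segments = c("s2", "s3"))
  expect_false("s2" %in% coh$segment)
  expect_true("s2" %in% attr(coh, "dropped")$segment)
})

test_that("coupled segments raise inter-brain PLV; intra-brain stays put", {
  ## paired comparison over seeds: coupling confined to the information
  ## exchange segments lifts inter PLV there but not in s5
  n_seeds <- 15
  d_inter <- numeric(n_seeds); d_s5 <- numeric(n_seeds)
  intra_hi <- numeric(n_seeds); intra_lo <- numeric(n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg_hi <- clean_cfg(n_scalp = 2, n_trials = 2, fixed_coupling = 0.95,
                        noise_sd = 2)
    cfg_lo <- clean_cfg(n_scalp = 2, n_trials = 2, fixed_coupling = 0,
                        noise_sd = 2)
    ses_hi <- generate_session(cfg_hi, seed = 700 + r)
    ses_lo <- generate_session(cfg_lo, seed = 900 + r)
    d_inter[r] <- mean(measure_inter_plv(ses_hi, "s3", 27.5)) -
                  mean(measure_inter_plv(ses_lo, "s3", 27.5))
    d_s5[r] <- mean(measure_inter_plv(ses_hi, "s5", 27.5)) -
               mean(measure_inter_plv(ses_lo, "s5", 27.5))
    ## intra-brain PLV from the two scalp channels of subject 1
    intra_plv <- function(ses) {
      coh <- dyad_coherence(ses$recording, ses$segments, grid, segments = "s3")
      mean(coh$mean_plv[coh$scope == "intra_1" & coh$band == "25-30"])
    }
    intra_hi[r] <- intra_plv(ses_hi); intra_lo[r] <- intra_plv(ses_lo)
  }
  expect_lt(t.test(d_inter, alternative = "greater")$p.value, 0.01)
  expect_gt(t.test(d_s5)$p.value, 0.01)          # s5 unaffected by coupling
  expect_gt(t.test(intra_hi, intra_lo, paired = TRUE)$p.value, 0.01)
})
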