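## Direct construction of pattern matrices with known correlation structure:
## power at chosen (subject, centro-parietal electrode, frequency) entries is
## driven by shared or independent lognormal amplitudes across patterns.
fake_patterns <- function(n_pat, k, f, freqs, links, sd_noise = 0.05,
                          labels = default_montage(k)) {
  cp <- match(intersect(centro_parietal_set(), labels), labels)
  P <- matrix(abs(rnorm(n_pat * 2 * k * f, mean = 1, sd = sd_noise)),
              n_pat)
  for (ln in links) {
    a <- rlnorm(n_pat, 0, 0.5)
    for (side in ln) {
      s <- side$subject; fi <- which(freqs == side$freq)
      cols <- (s - 1) * k * f + (cp - 1) * f + fi
      P[, cols] <- P[, cols] + a
    }
  }
  P
}

test_that("electrode profiles correlate exactly as a naive Pearson oracle", {
  set.seed(17)
  k <- 5; f <- 4
  P <- matrix(abs(rnorm(8 * 2 * k * f)) + 1, 8)
  C <- electrode_corr(P, "leader", k = k, f = f)
  ## brute force: correlate concatenated (pattern, frequency) profiles
  prof <- sapply(seq_len(k), function(e) {
    as.vector(t(P[, (e - 1) * f + seq_len(f)]))
  })
  for (i in 1:k) for (j in 1:k) {
    expect_equal(C[i, j], cor(prof[, i], prof[, j]), tolerance = 1e-12)
  }
  ## identical profiles -> correlation 1
  P2 <- P; P2[, f + seq_len(f)] <- P2[, seq_len(f)]
  C2 <- electrode_corr(P2, "leader", k = k, f = f)
  expect_equal(C2[1, 2], 1)

  ## zero-variance profile -> NA entries
  P3 <- P; P3[, seq_len(f)] <- 1
  C3 <- electrode_corr(P3, "leader", k = k, f = f)
  expect_true(all(is.na(C3[1, -1])))
})

test_that("a planted co-modulated electrode set coheres above its surround", {
  grid <- analysis_grid()
  cfg <- scenario_config(n_trials = 16, n_scalp = 14,
                         seg_durations = short_segments(),
                         noise_sd = 6, eog_noise_sd = 3,
                         blink_rate_per_min = 0, muscle_rate_per_min = 0,
                         drift_range = c(0, 0), gap_ms = 300)
  ses <- generate_session(cfg, seed = 93)
  pat <- suppressMessages(
    build_patterns(ses$recording, ses$segments, grid, n_cycles = 20))
  use <- ses$truth$pattern_id[match(pat$trial, ses$truth$trial)] != "none"
  C <- electrode_corr(pat$patterns[use, , drop = FALSE], "follower",
                      pat$roles, pat$k, pat$f)
  cp <- match(intersect(centro_parietal_set(), pat$labels), pat$labels)
  within <- mean(C[cp, cp][upper.tri(diag(length(cp)))])
  crossed <- mean(C[cp, setdiff(seq_len(pat$k), cp)])
  expect_gt(within, crossed + 0.2)
})

test_that("spectral reordering recovers planted blocks for any permutation", {
  set.seed(18)
  blocks <- rep(1:3, times = c(5, 4, 3))
  C0 <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0)) +
    diag(0.1, 12)
  for (r in 1:20) {
    perm <- sample(12)
    C <- C0[perm, perm]
    res <- spectral_reorder(C, n_clusters = 3)
    ## recovered clusters equal the planted partition up to label names
    planted <- blocks[perm][res$permutation]
    expect_equal(length(unique(paste(planted, res$clusters))), 3)
    ## permutation is a bijection and the reordered matrix is consistent
    expect_setequal(res$permutation, 1:12)
    expect_equal(res$reordered, C[res$permutation, res$permutation])
    ## reordered matrix is block diagonal: within-block mean >> off-block
    rb <- res$reordered
    in1 <- res$clusters == res$clusters[1]
    expect_gt(mean(rb[in1, in1]), mean(rb[in1, !in1]) + 0.5)
  }

  ## structureless matrix: any clustering, near-zero contrast
  C1 <- diag(12)
  res1 <- spectral_reorder(C1, n_clusters = 2)
  g1 <- res1$clusters == res1$clusters[1]
  contrast <- mean(res1$reordered[g1, g1][upper.tri(diag(sum(g1)))]) -
    mean(res1$reordered[g1, !g1])
  expect_lt(abs(contrast), 0.2)

  ## eigengap heuristic lands on the planted count
  res2 <- spectral_reorder(C0)
  expect_equal(res2$n_clusters, 3)
})

test_that("inter-subject frequency correlations expose planted signatures", {
  freqs <- analysis_grid()$freqs
  k <- 12; f <- length(freqs)
  labels <- default_montage(k)
  lead <- function(fr) list(subject = 1, freq = fr)
  fol <- function(fr) list(subject = 2, freq = fr)

  ## symmetric same-frequency co-modulation: strong diagonal entries
  set.seed(19)
  P <- fake_patterns(40, k, f, freqs,
                     links = list(list(fol(20), lead(20)),
                                  list(fol(30), lead(30))))
  M <- frequency_corr(P, labels = labels, k = k, f = f)
  expect_gt(M[freqs == 20, freqs == 20], 0.8)
  expect_gt(M[freqs == 30, freqs == 30], 0.8)
  expect_lt(abs(M[freqs == 20, freqs == 35]), 0.4)
  expect_lt(abs(M[freqs == 20, freqs == 30] - M[freqs == 30, freqs == 20]), 0.3)
  expect_lt(median(asymmetry_coefficient(M)$a), 0.2)

  ## asymmetric cross-frequency map: entries exceed their transposes
  Pa <- fake_patterns(40, k, f, freqs,
                      links = list(list(fol(25), lead(18)),
                                   list(fol(20), lead(30))))
  Ma <- frequency_corr(Pa, labels = labels, k = k, f = f)
  expect_gt(Ma[freqs == 25, freqs == 18], Ma[freqs == 18, freqs == 25] + 0.4)
  expect_gt(Ma[freqs == 20, freqs == 30], Ma[freqs == 30, freqs == 20] + 0.4)
  ## directly constructed matrices have single-bin structure: pick peaks
  ## without the resolution smoothing used for wavelet-smeared maps
  tp <- top_asymmetry_pairs(Ma, freqs, n = 2, smooth_sigma_hz = 0)
  expect_setequal(paste(tp$f_lo, tp$f_hi), c("18 25", "20 30"))

  ## independent patterns: entries scatter around zero
  set.seed(20)
  means <- replicate(50, {
    Pn <- fake_patterns(12, 4, 6, freqs[1:6], links = list(), sd_noise = 1,
                        labels = default_montage(4))
    mean(frequency_corr(Pn, labels = default_montage(4), k = 4, f = 6))
  })
  expect_lt(abs(mean(means)), 0.05)

  expect_error(frequency_corr(P[1:2, ], labels = labels, k = k, f = f),
               "at least 3")
})

test_that("asymmetry coefficients measure departure from matrix symmetry", {
  S <- matrix(0.5, 4, 4); diag(S) <- 1
  expect_true(all(asymmetry_coefficient(S)$a == 0))

  M <- S; M[1, 2] <- 0.8; M[2, 1] <- 0.2
  ac <- asymmetry_coefficient(M)
  expect_equal(ac$a[ac$i == 1 & ac$j == 2], 0.6)
  ## invariant under transposition
  expect_equal(asymmetry_coefficient(t(M))$a, ac$a)
  ## normalized variant is bounded by 1
  acn <- asymmetry_coefficient(M, normalized = TRUE)
  expect_true(all(acn$a <= 1 + 1e-9))
})

test_that("the signed-rank comparison matches an independent implementation", {
  ## hand-rolled signed-rank statistic (zeros dropped, average ranks)
  vstat <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    sum(r[d > 0])
  }
  set.seed(21)
  for (r in 1:20) {
    ah <- abs(rnorm(60)); al <- abs(rnorm(60))
    res <- asymmetry_test(ah, al)
    expect_equal(res$statistic, vstat(ah - al))
    expect_equal(res$direction, sign(median((ah - al)[(ah - al) != 0])))
  }
  ## identical coefficient sets: undefined test, zero direction
  same <- abs(rnorm(20))
  res0 <- asymmetry_test(same, same)
  expect_true(is.na(res0$p))
  expect_equal(res0$direction, 0)
})

test_that("the asymmetry test keeps its size under the symmetric null", {
  set.seed(22)
  rej <- logical(500)
  for (r in seq_len(500)) {
    a1 <- abs(rnorm(100)); a2 <- abs(rnorm(100))
    rej[r] <- asymmetry_test(a1, a2)$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
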