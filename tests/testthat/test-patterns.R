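test_that("pattern flattening is a documented, invertible ordering", {
  set.seed(12)
  k <- 4; f <- 3
  arr <- array(rnorm(2 * k * f), c(2, k, f))
  v <- pattern_flatten(arr)
  expect_length(v, 2 * k * f)
  ## subject-major, electrode-major, frequency-minor
  expect_equal(v[(2 - 1) * k * f + (3 - 1) * f + 2], arr[2, 3, 2])
  expect_equal(pattern_unflatten(v, k, f), arr)
  for (r in 1:5) {
    a2 <- array(rnorm(2 * 5 * 7), c(2, 5, 7))
    expect_identical(pattern_unflatten(pattern_flatten(a2), 5, 7), a2)
  }
})

test_that("the normalized squared distance obeys its algebraic identities", {
  expect_equal(pattern_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  e1 <- c(1, 0); e2 <- c(0, 1)
  expect_equal(pattern_distance(e1, e2), 2)        # orthogonal unit vectors
  expect_equal(pattern_distance(e1, -e1), 4)       # antipodal unit vectors
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30)
  d0 <- pattern_distance(x, y)
  expect_equal(pattern_distance(3 * x, 3 * y), d0, tolerance = 1e-12)
  expect_equal(pattern_distance(y, x), d0)
  ## NOT invariant under scaling one argument only
  expect_gt(abs(pattern_distance(3 * x, y) - d0), 1e-3)
  expect_error(pattern_distance(numeric(3), y), "zero norm")
})

test_that("the block distance matrix matches elementwise hand computation", {
  set.seed(14)
  H <- matrix(abs(rnorm(2 * 6)) + 0.1, 2)
  L <- matrix(abs(rnorm(2 * 6)) + 0.1, 2)
  D <- block_distance_matrix(H, L)
  X <- rbind(H, L)
  for (i in 1:4) for (j in 1:4) {
    want <- if (i == j) 0 else pattern_distance(X[i, ], X[j, ])
    expect_equal(D[i, j], want, tolerance = 1e-12)
  }
  expect_equal(D, t(D))
  expect_equal(attr(D, "N"), 2); expect_equal(attr(D, "n"), 2)
  expect_error(block_distance_matrix(H[1, , drop = FALSE], L), "at least 2")

  ## permuting patterns within a class permutes rows/cols within blocks only
  H2 <- matrix(abs(rnorm(3 * 6)) + 0.1, 3)
  D1 <- block_distance_matrix(H2, L)
  D2 <- block_distance_matrix(H2[c(2, 3, 1), ], L)
  expect_equal(D2[1:3, 1:3], D1[c(2, 3, 1), c(2, 3, 1)], ignore_attr = TRUE)
  expect_equal(D2[4:5, 4:5], D1[4:5, 4:5], ignore_attr = TRUE)
})

test_that("percentile class distances follow the ceiling rank rule", {
  ## column distances {0 (self), 1..10}: 10th percentile of {1..10} -> rank 1
  H <- matrix(0, 11, 2)
  ## place patterns on a line so distances from pattern 1 are ordered
  H[, 1] <- c(5, 5 + cumsum(rep(0.3, 10)))
  L <- matrix(c(20, 20.3, 20.6), 3, 2)[, c(1, 1)]
  D <- block_distance_matrix(H, L)
  led <- class_distances(D, percentile = 10)
  col1 <- sort(D[2:11, 1])
  expect_equal(led$intra_d[1], col1[1])      # ceiling(0.1 * 10) = 1
  led50 <- class_distances(D, percentile = 50)
  expect_equal(led50$intra_d[1], col1[5])    # ceiling(0.5 * 10) = 5

  ## all distances equal (orthonormal patterns): intra = inter, ties are
  ## not specific
  E <- diag(4)
  ledc <- class_distances(block_distance_matrix(E[1:2, ], E[3:4, ]))
  expect_true(all(ledc$intra_d == 2 & ledc$inter_d == 2))
  expect_length(specific_patterns(ledc), 0)

  ## an extreme outlier in a column leaves the 10th percentile unchanged
  H3 <- matrix(rnorm(12 * 4, mean = 10), 12)
  L3 <- matrix(rnorm(12 * 4, mean = 10), 12)
  D3 <- block_distance_matrix(H3, L3)
  led3 <- class_distances(D3)
  H3o <- rbind(H3, 1e3 * abs(rnorm(4)))
  D3o <- block_distance_matrix(H3o, L3)
  led3o <- class_distances(D3o)
  expect_equal(led3o$intra_d[1:12], led3$intra_d[1:12], tolerance = 1e-9)
})

test_that("specificity flags separate planted clusters and respect ties", {
  set.seed(15)
  ## two tight, well-separated clusters (between/within ratio ~ 10)
  H <- matrix(rnorm(20 * 8, mean = 10, sd = 0.2), 20)
  L <- matrix(rnorm(20 * 8, mean = 10, sd = 0.2), 20)
  L[, 1] <- L[, 1] + 20
  led <- class_distances(block_distance_matrix(H, L))
  expect_equal(length(specific_patterns(led)), 40)   # 100% specific

  ## identical duplicated pattern in both classes is never specific
  base <- abs(rnorm(8)) + 1
  Hd <- rbind(base, base + rnorm(8, sd = 3), base + rnorm(8, sd = 3))
  Ld <- rbind(base, base + rnorm(8, sd = 3), base + rnorm(8, sd = 3))
  ledd <- class_distances(block_distance_matrix(Hd, Ld))
  expect_false(1 %in% specific_patterns(ledd))       # its twin sits at d = 0
  expect_false(4 %in% specific_patterns(ledd))

  ## joint rescaling of all patterns leaves the decisions unchanged
  led_scaled <- class_distances(block_distance_matrix(7.7 * H, 7.7 * L))
  expect_equal(specific_patterns(led_scaled), specific_patterns(led))
})

test_that("mining splits by class and reports original row indices", {
  set.seed(16)
  P <- matrix(abs(rnorm(10 * 6)) + 0.5, 10)
  P[6:10, ] <- P[6:10, ] + 5
  cls <- rep(c("high", "low"), each = 5)
  res <- mine_specific_patterns(P, cls)
  expect_equal(nrow(res$ledger), 10)
  expect_setequal(res$ledger$row, 1:10)
  expect_true(all(res$specific_high %in% 1:5))
  expect_true(all(res$specific_low %in% 6:10))
})

test_that("pattern vectors carry the planted spectral structure in order", {
  ## one asymmetric high-readiness trial: the follower's centro-parietal
  ## electrodes must show a 25 Hz power peak, the leader an 18 Hz peak,
  ## in exactly the documented vector ordering
  grid <- analysis_grid()
  cfg <- scenario_config(n_trials = 6, n_scalp = 12,
                         seg_durations = short_segments(),
                         noise_sd = 4, eog_noise_sd = 2,
                         blink_rate_per_min = 0, muscle_rate_per_min = 0,
                         drift_range = c(0, 0), gap_ms = 300)
  ses <- generate_session(cfg, seed = 91)
  pat <- suppressMessages(
    build_patterns(ses$recording, ses$segments, grid, n_cycles = 20))
  k <- pat$k; f <- pat$f
  asym_trials <- ses$truth$trial[ses$truth$pattern_id == "asym"]
  expect_gt(length(asym_trials), 0)
  v <- pat$patterns[match(asym_trials[1], pat$trial), ]
  arr <- pattern_unflatten(v, k, f)
  cp <- match(intersect(centro_parietal_set(), pat$labels), pat$labels)
  fol <- which(pat$roles == "follower"); led <- which(pat$roles == "leader")
  band <- function(subj, freq) mean(arr[subj, cp, which(grid$freqs == freq)])
  ## planted peaks beat frequencies 3 Hz away on the same electrodes
  expect_gt(band(fol, 25), 2 * band(fol, 28))
  expect_gt(band(led, 18), 2 * band(led, 15))
  ## and beat the same frequency on non-planted electrodes
  other <- setdiff(seq_len(k), cp)
  expect_gt(band(fol, 25), 2 * mean(arr[fol, other, which(grid$freqs == 25)]))
})
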