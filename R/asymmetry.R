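#' Electrode correlation matrix of one team role
#'
#' For each scalp electrode of the given role, the profile is its wavelet
#' power across all (frequency, pattern) combinations of the supplied
#' patterns; the matrix entry is the Pearson correlation between two
#' electrodes' profiles. Zero-variance profiles yield `NA` entries (excluded
#' from clustering).
#'
#' @param patterns pattern matrix (rows = patterns) in [pattern_flatten()]
#'   order
#' @param role `"leader"` or `"follower"`
#' @param roles role of subject 1 and 2 (as in [dual_recording()])
#' @param k,f electrodes per subject and frequency count
#' @return `k x k` symmetric correlation matrix of class
#'   `electrode_corr_matrix`
#' @export
electrode_corr <- function(patterns, role, roles = c("leader", "follower"),
                           k, f) {
  stopifnot(nrow(patterns) >= 2, ncol(patterns) == 2 * k * f)
  s <- which(roles == role)
  stopifnot(length(s) == 1)
  ## profile matrix: (pattern x frequency) rows, electrode columns
  prof <- matrix(NA_real_, nrow(patterns) * f, k)
  for (e in seq_len(k)) {
    cols <- (s - 1) * k * f + (e - 1) * f + seq_len(f)
    prof[, e] <- as.vector(t(patterns[, cols, drop = FALSE]))
  }
  C <- suppressWarnings(cor(prof))
  structure(C, class = c("electrode_corr_matrix", class(C)))
}

#' Spectral reordering of a correlation matrix
#'
#' Normalized spectral clustering (symmetric graph Laplacian of the affinity
#' `(corr + 1)/2`, k-means on the row-normalized leading eigenvectors),
#' followed by a reordering that places highly correlated clusters as square
#' blocks along the diagonal. Clusters are ordered by descending mean
#' within-cluster correlation; within a cluster, electrodes are ordered by
#' their mean correlation to the cluster. The number of clusters defaults to
#' the eigengap heuristic.
#'
#' @param C correlation matrix (entries in `[-1, 1]`; `NA` rows are excluded
#'   from clustering and appended last as singletons)
#' @param n_clusters number of clusters, or NULL for the eigengap heuristic
#' @param max_clusters upper bound scanned by the eigengap heuristic
#' @return list: `permutation` (bijection on rows), `clusters` (integer
#'   labels in permuted-cluster order), `n_clusters`, `reordered` (the
#'   permuted matrix)
#' @export
spectral_reorder <- function(C, n_clusters = NULL, max_clusters = 10) {
  k <- nrow(C)
  ok <- apply(C, 1, function(r) all(is.finite(r)))
  A <- (C[ok, ok, drop = FALSE] + 1) / 2
  diag(A) <- 0
  m <- nrow(A)
  if (m < 2) stop("fewer than 2 usable rows for clustering")
  d <- rowSums(A)
  d[d == 0] <- 1e-12                     # isolated node: degenerate component
  Dhalf <- 1 / sqrt(d)
  L <- diag(m) - (Dhalf %o% Dhalf) * A   # symmetric normalized Laplacian
  ev <- eigen(L, symmetric = TRUE)
  lambda <- rev(ev$values)               # ascending
  if (is.null(n_clusters)) {
    upper <- min(max_clusters, m - 1)
    gaps <- diff(lambda[seq_len(upper + 1)])
    n_clusters <- max(2L, which.max(gaps[-1]) + 1L)
  }
  stopifnot(n_clusters >= 2, n_clusters <= m)
  V <- ev$vectors[, rev(seq_len(ncol(ev$vectors)))[seq_len(n_clusters)],
                  drop = FALSE]
  rn <- sqrt(rowSums(V^2)); rn[rn == 0] <- 1
  V <- V / rn
  ## Lloyd iterations; duplicated embedding rows (identical profiles) make
  ## some random starts degenerate, which kmeans retries internally
  km <- suppressWarnings(kmeans(V, centers = n_clusters, nstart = 25,
                                iter.max = 100, algorithm = "Lloyd"))
  cl_ok <- km$cluster

  ## order clusters by descending mean within-cluster correlation
  Cok <- C[ok, ok, drop = FALSE]
  within <- vapply(seq_len(n_clusters), function(g) {
    idx <- which(cl_ok == g)
    if (length(idx) < 2) return(1)       # singleton: trivially tight
    mean(Cok[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
  }, numeric(1))
  cl_rank <- rank(-within, ties.method = "first")
  perm_ok <- order(cl_rank[cl_ok],
                   -vapply(seq_len(m), function(i) {
                     idx <- which(cl_ok == cl_ok[i])
                     mean(Cok[i, idx])
                   }, numeric(1)))
  perm <- c(which(ok)[perm_ok], which(!ok))
  clusters <- integer(k)
  clusters[which(ok)] <- cl_rank[cl_ok]
  if (any(!ok)) clusters[which(!ok)] <- n_clusters + seq_len(sum(!ok))
  list(permutation = perm, clusters = clusters[perm],
       n_clusters = n_clusters, reordered = C[perm, perm])
}

#' Inter-subject frequency correlation matrix over an electrode set
#'
#' Averages the pattern power over the given electrode set per subject and
#' frequency, then correlates -- across the class's specific patterns -- the
#' follower's set-mean power at frequency i with the leader's at frequency j.
#' Rows index follower frequencies, columns leader frequencies (this axis
#' convention is fixed and documented here; transpose for the other
#' orientation).
#'
#' @param patterns pattern matrix (rows = specific patterns of one class)
#' @param electrode_set labels of the set (default: the medial
#'   centro-parietal set)
#' @param labels scalp labels per subject in pattern order
#' @param roles role of subject 1 and 2
#' @param k,f electrodes per subject and frequency count
#' @return `f x f` correlation matrix of class `frequency_corr_matrix`
#' @export
frequency_corr <- function(patterns, electrode_set = centro_parietal_set(),
                           labels, roles = c("leader", "follower"), k, f) {
  if (nrow(patterns) < 3) {
    stop("need at least 3 specific patterns in the class (got ",
         nrow(patterns), ")")
  }
  eidx <- match(intersect(electrode_set, labels), labels)
  if (!length(eidx)) stop("electrode set not present in montage")
  set_mean <- function(s) {
    out <- matrix(NA_real_, nrow(patterns), f)
    for (fi in seq_len(f)) {
      cols <- (s - 1) * k * f + (eidx - 1) * f + fi
      out[, fi] <- rowMeans(patterns[, cols, drop = FALSE])
    }
    out
  }
  fol <- set_mean(which(roles == "follower"))
  led <- set_mean(which(roles == "leader"))
  M <- suppressWarnings(cor(fol, led))
  structure(M, class = c("frequency_corr_matrix", class(M)))
}

#' Asymmetry coefficients of a frequency correlation matrix
#'
#' Per unordered frequency pair `i < j`, the absolute difference from the
#' transpose: `a(i, j) = |M(i, j) - M(j, i)|` (`f*(f-1)/2` values; zero for a
#' symmetric matrix). A normalized variant divides by
#' `|M(i,j)| + |M(j,i)| + eps`.
#'
#' @param M square matrix
#' @param normalized use the normalized variant
#' @param eps stabilizer of the normalized variant
#' @return data.frame: `i`, `j` (row/col indices, `i < j`), `a`
#' @export
asymmetry_coefficient <- function(M, normalized = FALSE, eps = 1e-8) {
  stopifnot(nrow(M) == ncol(M))
  ut <- which(upper.tri(M), arr.ind = TRUE)
  a <- abs(M[ut] - t(M)[ut])
  if (normalized) a <- a / (abs(M[ut]) + abs(t(M)[ut]) + eps)
  data.frame(i = ut[, 1], j = ut[, 2], a = a)
}

#' Wilcoxon signed-rank comparison of paired asymmetry coefficients
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences
#' `a_high - a_low` over the same frequency pairs, zeros dropped (classic
#' Wilcoxon, not Pratt). Direction is the sign of the median nonzero
#' difference. All-zero differences make the test undefined and are reported
#' as such.
#'
#' @param a_high,a_low paired numeric vectors (same frequency pairs, same
#'   order)
#' @return list: `statistic` (V), `p`, `direction` (+1 high more asymmetric,
#'   -1 low, 0 undefined), `n_used`
#' @export
asymmetry_test <- function(a_high, a_low) {
  stopifnot(length(a_high) == length(a_low))
  d <- a_high - a_low
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) {
    return(list(statistic = NA_real_, p = NA_real_, direction = 0, n_used = 0))
  }
  wt <- suppressWarnings(wilcox.test(nz, alternative = "two.sided",
                                     mu = 0, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = sign(median(nz)), n_used = length(nz))
}

## Separable Gaussian smoothing of a matrix with edge renormalization.
gauss_smooth2d <- function(A, sigma_bins) {
  if (sigma_bins <= 0) return(A)
  r <- ceiling(3 * sigma_bins)
  kern <- exp(-(-r:r)^2 / (2 * sigma_bins^2))
  sm1 <- function(M) {
    n <- nrow(M)
    out <- matrix(0, n, ncol(M)); W <- matrix(0, n, ncol(M))
    for (d in -r:r) {
      i <- max(1, 1 - d):min(n, n - d)
      out[i, ] <- out[i, ] + kern[d + r + 1] * M[i + d, ]
      W[i, ] <- W[i, ] + kern[d + r + 1]
    }
    out / W
  }
  t(sm1(t(sm1(A))))
}

#' Strongest asymmetric frequency pairs
#'
#' Identifies the cross-frequency associations that are strong in one
#' orientation and absent in the other. Selection and localization are
#' separated, both at the analysis' spectral resolution: pairs qualify as
#' asymmetric when the smoothed asymmetry map `|M - t(M)|` reaches at least
#' `a_frac` of its maximum, and qualifying pairs are then ranked by their
#' smoothed co-occurrence strength `max(M(i,j), M(j,i))`. Ranking by
#' correlation strength rather than by raw asymmetry matters because the
#' asymmetry ridge of one association is eroded on the side facing another
#' association (whose leakage raises the transposed entries), which biases a
#' raw-asymmetry peak outward by 1-3 Hz; the co-occurrence peak sits on the
#' association itself. Smoothing (`smooth_sigma_hz`) suppresses single-bin
#' estimation-noise peaks, which are narrow, whereas a genuine association is
#' smeared over neighboring bins by the wavelet's spectral bandwidth.
#' Non-maximum suppression drops a pair closer than `min_sep_hz` in both
#' coordinates to an already selected, stronger pair.
#'
#' @param M a [frequency_corr()] matrix
#' @param freqs frequency axis (Hz) of the matrix
#' @param n number of pairs to return
#' @param min_sep_hz suppression radius in Hz (default 4: larger than the
#'   smeared ridge of one association, smaller than the separation of
#'   distinct planted associations)
#' @param smooth_sigma_hz Gaussian smoothing bandwidth in Hz (0 disables)
#' @param a_frac asymmetry qualification threshold as a fraction of the
#'   asymmetry map's maximum
#' @return data.frame: `f_lo`, `f_hi` (Hz, unordered pair sorted ascending),
#'   `a` (smoothed asymmetry), `strength` (smoothed co-occurrence)
#' @export
top_asymmetry_pairs <- function(M, freqs, n = 2, min_sep_hz = 4,
                                smooth_sigma_hz = 1, a_frac = 0.5) {
  step <- if (length(freqs) > 1) freqs[2] - freqs[1] else 1
  sig <- smooth_sigma_hz / step
  A <- gauss_smooth2d(abs(M - t(M)), sig)
  S <- gauss_smooth2d(pmax(M, t(M)), sig)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  ac <- data.frame(f_lo = pmin(freqs[ut[, 1]], freqs[ut[, 2]]),
                   f_hi = pmax(freqs[ut[, 1]], freqs[ut[, 2]]),
                   a = A[ut], strength = S[ut])
  ac <- ac[ac$a >= a_frac * max(ac$a), ]
  ac <- ac[order(-ac$strength), ]
  picked <- ac[0, ]
  for (r in seq_len(nrow(ac))) {
    if (nrow(picked) >= n) break
    cand <- ac[r, ]
    close <- nrow(picked) > 0 &&
      any(abs(picked$f_lo - cand$f_lo) <= min_sep_hz &
          abs(picked$f_hi - cand$f_hi) <= min_sep_hz)
    if (!close) picked <- rbind(picked, cand)
  }
  rownames(picked) <- NULL
  picked
}
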