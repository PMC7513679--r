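#' Flatten a dyadic power tensor to a pattern vector
#'
#' Ordering contract for the `2*k*f`-dimensional pattern vectors:
#' subject-major, electrode-major, frequency-minor, i.e. index
#' `(s-1)*k*f + (e-1)*f + phi`.
#' @param arr numeric array `2 x k x f`
#' @return numeric vector of length `2*k*f`
#' @export
pattern_flatten <- function(arr) {
  stopifnot(length(dim(arr)) == 3, dim(arr)[1] == 2)
  as.vector(aperm(arr, c(3, 2, 1)))
}

#' Inverse of [pattern_flatten()]
#' @param v pattern vector of length `2*k*f`
#' @param k electrodes per subject
#' @param f frequencies
#' @return numeric array `2 x k x f`
#' @export
pattern_unflatten <- function(v, k, f) {
  stopifnot(length(v) == 2 * k * f)
  aperm(array(v, c(f, k, 2)), c(3, 2, 1))
}

#' Dyadic wavelet-power pattern vectors for a trial segment
#'
#' For every trial, the mean wavelet power over the segment's valid analysis
#' windows (power taken at each window's center sample) per subject,
#' electrode and frequency, flattened to one `2*k*f`-dimensional vector per
#' trial in the [pattern_flatten()] order. The wavelet transform runs on a
#' padded excerpt around each segment so boundary-invalid coefficients never
#' enter the averages. Trials whose segment has no valid window are excluded
#' with a logged reason.
#'
#' @param rec a (preprocessed) [dual_recording()]
#' @param segs a [segment_table()]
#' @param grid an [analysis_grid()]
#' @param mask optional [build_mask()] result
#' @param segment segment id to build patterns from (default `"s1"`, where
#'   leader readiness is expressed)
#' @param n_cycles Morlet width
#' @param reduce `"mean"` (default) or `"median"` across windows
#' @param log10_power take log10 of power before averaging (off by default)
#' @return list: `patterns` (matrix, trials x `2*k*f`), `trial` (ids),
#'   `k`, `f`, `freqs`, `labels` (scalp labels), `roles`
#' @export
build_patterns <- function(rec, segs, grid, mask = NULL, segment = "s1",
                           n_cycles = 7, reduce = c("mean", "median"),
                           log10_power = FALSE) {
  reduce <- match.arg(reduce)
  validate_recording(rec)
  fs <- rec$fs
  k <- n_scalp(rec)
  freqs <- grid$freqs
  nf <- length(freqs)
  n <- ncol(rec$samples[[1]])
  margin <- ceiling(4 * n_cycles / (2 * pi * min(freqs)) * fs)

  seg_rows <- segs[segs$segment == segment, ]
  km <- morlet_kernel_matrix(fs, freqs, n_cycles)
  pats <- list(); trials <- c()
  for (i in seq_len(nrow(seg_rows))) {
    on <- seg_rows$onset_ms[i]; off <- seg_rows$offset_ms[i]
    w <- segment_windows(on, off, grid, fs, mask)
    centers <- ms_to_sample(w$center_ms, fs)
    ## windows whose center sits within one kernel half-support of the
    ## recording edges are boundary-invalid
    centers <- centers[centers > margin & centers <= n - margin]
    if (!length(centers)) {
      message("trial ", seg_rows$trial[i], ": no valid ", segment,
              " window, excluded")
      next
    }
    P <- array(NA_real_, c(2, k, nf))
    for (s in 1:2) {
      scalp <- which(rec$channel_types[[s]] == "scalp")
      for (ci in seq_along(scalp)) {
        C <- morlet_at(rec$samples[[s]][scalp[ci], ], fs, freqs, centers,
                       n_cycles, km)
        pw <- Mod(C)^2
        if (log10_power) pw <- log10(pw + .Machine$double.eps)
        P[s, ci, ] <- if (reduce == "mean") rowMeans(pw) else
          apply(pw, 1, median)
      }
    }
    pats[[length(pats) + 1]] <- pattern_flatten(P)
    trials <- c(trials, seg_rows$trial[i])
  }
  if (!length(pats)) stop("no computable ", segment, " patterns")
  M <- do.call(rbind, pats)
  rownames(M) <- trials
  list(patterns = M, trial = trials, k = k, f = nf, freqs = freqs,
       labels = scalp_labels(rec, 1), roles = rec$roles)
}

#' Normalized squared-distance between two pattern vectors
#'
#' `d(x, y) = ||x - y||^2 / (||x|| * ||y||)` with the Euclidean norm.
#' Symmetric, zero iff `x == y`, invariant under joint positive rescaling of
#' both arguments (but, deliberately, not under rescaling one argument only).
#'
#' @param x,y numeric vectors with positive norm
#' @return non-negative scalar
#' @export
pattern_distance <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("pattern with zero norm")
  sum((x - y)^2) / (nx * ny)
}

#' Block distance matrix between two pattern classes
#'
#' The `(N+n) x (N+n)` matrix of pairwise pattern distances with the high
#' class first: square `N x N` and `n x n` diagonal blocks hold intra-class
#' distances, rectangular off-diagonal blocks hold inter-class distances.
#'
#' @param high,low numeric matrices of patterns (rows), `N >= 2`, `n >= 2`
#' @return symmetric matrix with zero diagonal and attributes `N`, `n`
#' @export
block_distance_matrix <- function(high, low) {
  N <- nrow(high); n <- nrow(low)
  if (is.null(N) || N < 2 || is.null(n) || n < 2) {
    stop("each class needs at least 2 patterns (got N = ", N %||% 0,
         ", n = ", n %||% 0, ")")
  }
  X <- rbind(high, low)
  G <- X %*% t(X)
  sq <- diag(G)
  if (any(sq == 0)) stop("pattern with zero norm")
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0
  D <- D2 / outer(sqrt(sq), sqrt(sq))
  diag(D) <- 0
  D <- (D + t(D)) / 2
  attr(D, "N") <- N; attr(D, "n") <- n
  D
}

#' Per-pattern intra- and inter-class distances at a percentile
#'
#' For every pattern (column of the block matrix) the distances to its own
#' class are sorted ascending after removing the zero self-distance, and the
#' intra-class distance is the value at the percentile rank; likewise for the
#' distances to the other class (no self-distance to remove). Rank rule: the
#' smallest order statistic whose cumulative fraction reaches the percentile
#' (`ceiling(p/100 * m)`, at least 1) -- deterministic across platforms. The
#' low percentile keeps class distances small while stopping outliers from
#' dominating.
#'
#' @param D a [block_distance_matrix()]
#' @param percentile percentile in (0, 100], default 10
#' @return data.frame of class `specificity_ledger`: `pattern` (index into
#'   the block matrix), `class` (`"high"`/`"low"`), `intra_d`, `inter_d`,
#'   `specific` (strict `inter_d > intra_d`; ties are not specific)
#' @export
class_distances <- function(D, percentile = 10) {
  N <- attr(D, "N"); n <- attr(D, "n")
  stopifnot(!is.null(N), !is.null(n))
  pick <- function(v) sort(v)[max(1L, ceiling(percentile / 100 * length(v)))]
  res <- lapply(seq_len(N + n), function(j) {
    own <- if (j <= N) seq_len(N) else N + seq_len(n)
    other <- setdiff(seq_len(N + n), own)
    intra <- D[setdiff(own, j), j]
    if (length(intra) < 1) {
      return(data.frame(pattern = j, class = if (j <= N) "high" else "low",
                        intra_d = NA_real_, inter_d = NA_real_,
                        specific = NA))
    }
    i_d <- pick(intra)
    e_d <- pick(D[other, j])
    data.frame(pattern = j, class = if (j <= N) "high" else "low",
               intra_d = i_d, inter_d = e_d, specific = e_d > i_d)
  })
  out <- do.call(rbind, res)
  class(out) <- c("specificity_ledger", "data.frame")
  out
}

#' Class-specific patterns
#'
#' A pattern is specific to its readiness class when its inter-class distance
#' strictly exceeds its intra-class distance.
#' @param ledger a [class_distances()] result
#' @return integer vector of pattern indices (into the block matrix)
#' @export
specific_patterns <- function(ledger) {
  ledger$pattern[!is.na(ledger$specific) & ledger$specific]
}

#' Mine class-specific dyadic power patterns
#'
#' Convenience wrapper: splits a pattern matrix by readiness class, builds
#' the block distance matrix, computes percentile class distances and flags
#' specific patterns.
#'
#' @param patterns matrix of pattern vectors (rows) as from
#'   [build_patterns()]
#' @param classes character vector along rows, `"high"`/`"low"`/other (other
#'   classes are ignored)
#' @param percentile see [class_distances()]
#' @return list: `ledger` (with original row indices in `row`), `specific_high`,
#'   `specific_low` (row indices into `patterns`), `D`
#' @export
mine_specific_patterns <- function(patterns, classes, percentile = 10) {
  hi <- which(classes == "high"); lo <- which(classes == "low")
  D <- block_distance_matrix(patterns[hi, , drop = FALSE],
                             patterns[lo, , drop = FALSE])
  led <- class_distances(D, percentile)
  led$row <- c(hi, lo)[led$pattern]
  sp <- specific_patterns(led)
  list(ledger = led,
       specific_high = led$row[led$pattern %in% sp & led$class == "high"],
       specific_low = led$row[led$pattern %in% sp & led$class == "low"],
       D = D)
}
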