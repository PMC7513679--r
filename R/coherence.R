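#' Sliding analysis windows of a trial segment
#'
#' Maximal set of `[t, t + win_ms)` windows starting at
#' `onset + m * step_ms` that lie fully inside the half-open segment
#' `[onset, offset)`. Windows overlapping invalid samples (for either subject,
#' if a mask is supplied) are dropped. Fewer than two surviving windows make a
#' segment uncomputable for the phase-locking value.
#'
#' @param onset_ms,offset_ms segment interval, ms
#' @param grid an [analysis_grid()] (supplies `win_ms`, `step_ms`)
#' @param fs sampling rate, Hz (needed when a mask is supplied)
#' @param mask optional [build_mask()] result
#' @return data.frame with `start_ms`, `center_ms` for each retained window
#' @export
segment_windows <- function(onset_ms, offset_ms, grid, fs = NULL, mask = NULL) {
  win <- grid$win_ms; step <- grid$step_ms
  dur <- offset_ms - onset_ms
  if (dur < win) {
    return(data.frame(start_ms = numeric(0), center_ms = numeric(0)))
  }
  m <- floor((dur - win) / step)
  starts <- onset_ms + (0:m) * step
  if (!is.null(mask)) {
    stopifnot(!is.null(fs))
    n <- length(mask$valid[[1]])
    ok <- vapply(starts, function(a) {
      idx <- interval_samples(a, a + win, fs, n)
      all(mask$valid[[1]][idx]) && all(mask$valid[[2]][idx])
    }, logical(1))
    starts <- starts[ok]
  }
  data.frame(start_ms = starts, center_ms = starts + win / 2)
}

#' Phase-locking value
#'
#' Magnitude of the mean unit phasor of the phase difference:
#' `(1/N) |sum_n exp(i (phi_n(j) - phi_n(k)))|`. Equals 1 for a constant
#' phase difference and tends to 0 for independent phases as N grows. The
#' value is symmetric in the two inputs and invariant under adding a common
#' constant to either phase series.
#'
#' @param phases_j,phases_k equal-length numeric vectors of per-window phases
#'   (radians), `N >= 2`, all finite
#' @return scalar in `[0, 1]`
#' @export
plv <- function(phases_j, phases_k) {
  if (length(phases_j) != length(phases_k)) {
    stop("phase series have different lengths")
  }
  stopifnot(length(phases_j) >= 2, all(is.finite(phases_j)),
            all(is.finite(phases_k)))
  Mod(sum(exp(1i * (phases_j - phases_k)))) / length(phases_j)
}

#' Representative phase of one analysis window
#'
#' The phase of the wavelet coefficient at the window's center sample (the
#' default, simplest well-defined choice), or the circular mean of the phases
#' across the window's samples when `method = "circular_mean"`.
#'
#' @param stack a [morlet_transform()] result for one channel
#' @param start_ms window start (0-based ms relative to the stack's first
#'   sample)
#' @param freq_idx row index into `stack$freqs`
#' @param grid an [analysis_grid()]
#' @param method `"center"` or `"circular_mean"`
#' @return phase in `(-pi, pi]`, or `NA` if the window touches
#'   boundary-invalid coefficients
#' @export
window_phase <- function(stack, start_ms, freq_idx, grid,
                         method = c("center", "circular_mean")) {
  method <- match.arg(method)
  n <- ncol(stack$coeffs)
  m <- stack$margin[freq_idx]
  if (method == "center") {
    cidx <- ms_to_sample(start_ms + grid$win_ms / 2, stack$fs)
    if (cidx <= m || cidx > n - m) return(NA_real_)
    c0 <- stack$coeffs[freq_idx, cidx]
    if (Mod(c0) == 0) return(NA_real_)
    Arg(c0)
  } else {
    idx <- interval_samples(start_ms, start_ms + grid$win_ms, stack$fs, n)
    if (min(idx) <= m || max(idx) > n - m) return(NA_real_)
    z <- sum(exp(1i * Arg(stack$coeffs[freq_idx, idx])))
    if (Mod(z) == 0) return(NA_real_)
    Arg(z)
  }
}

## Scope masks over the (2k x 2k) pair matrix of global electrode indices
## 1..2k (subject 1 -> 1..k, subject 2 -> k+1..2k). Unordered pairs j < k;
## self-pairs excluded. intra_1: 60*59/2 = 1770 pairs at k = 60, inter:
## 60*60 = 3600 pairs, total k(2k-1) = 7140 per frequency.
scope_masks <- function(k) {
  m <- 2 * k
  up <- upper.tri(matrix(0, m, m))
  sub <- c(rep(1L, k), rep(2L, k))
  same1 <- outer(sub == 1L, sub == 1L, `&`)
  same2 <- outer(sub == 2L, sub == 2L, `&`)
  list(intra_1 = up & same1, intra_2 = up & same2,
       inter = up & !(same1 | same2))
}

#' Mean coherence of a scope within a frequency band
#'
#' Arithmetic mean of the pairwise phase-locking values over the electrode
#' pairs of the scope (both electrodes in subject 1 or 2, or one in each) and
#' over the band's grid frequencies.
#'
#' @param plv_array numeric array `2k x 2k x n_freq` of pairwise PLVs (only
#'   the upper triangle is read)
#' @param freqs frequencies along the third dimension
#' @param band two-element range in Hz (inclusive)
#' @param scope `"intra_1"`, `"intra_2"` or `"inter"`
#' @return scalar mean coherence
#' @export
aggregate_coherence <- function(plv_array, freqs, band,
                                scope = c("inter", "intra_1", "intra_2")) {
  scope <- match.arg(scope)
  k <- dim(plv_array)[1] / 2
  msk <- scope_masks(k)[[scope]]
  if (!any(msk)) stop("empty scope")
  fidx <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(fidx)) stop("band outside frequency axis")
  mean(vapply(fidx, function(i) mean(plv_array[, , i][msk]), numeric(1)))
}

#' Pairwise phase-locking values of one segment
#'
#' Computes `c_jk` for all unordered electrode pairs of the dyad at every
#' frequency, from a phase array of per-window phases.
#'
#' @param phases numeric array `2k x n_freq x N` of per-window phases
#' @return array `2k x 2k x n_freq`; upper and lower triangles are symmetric,
#'   the diagonal is 1
#' @export
pairwise_plv <- function(phases) {
  d <- dim(phases)
  stopifnot(length(d) == 3, d[3] >= 2)
  out <- array(NA_real_, c(d[1], d[1], d[2]))
  for (f in seq_len(d[2])) {
    E <- exp(1i * phases[, f, , drop = TRUE])
    if (is.null(dim(E))) E <- matrix(E, d[1], d[3])
    out[, , f] <- Mod(E %*% Conj(t(E))) / d[3]
  }
  out
}

#' Segment-wise intra- and inter-brain coherence of a session
#'
#' End-to-end driver: Morlet-transforms every scalp channel of both subjects,
#' takes one representative phase per 80 ms window (windows restart at each
#' segment onset; windows overlapping masked or boundary-invalid samples are
#' dropped), forms the phase-locking value for every electrode pair and
#' frequency, and averages into intra- and inter-brain band coherences per
#' trial segment. Segments with fewer than two valid windows are excluded
#' with a logged reason.
#'
#' @param rec a [dual_recording()] (preprocessed)
#' @param segs a [segment_table()]
#' @param grid an [analysis_grid()]
#' @param mask optional [build_mask()] result
#' @param segments segment ids to analyze (default: the seven segments used
#'   in the readiness correlation, s9 and s0-s5)
#' @param n_cycles Morlet width
#' @param phase_method see [window_phase()]
#' @return data.frame: `trial`, `segment`, `band`, `scope`, `mean_plv`,
#'   `n_windows`; attribute `"dropped"` lists uncomputable segments
#' @export
dyad_coherence <- function(rec, segs, grid, mask = NULL,
                           segments = c("s9", "s0", "s1", "s2", "s3", "s4", "s5"),
                           n_cycles = 7, phase_method = "center") {
  validate_recording(rec)
  fs <- rec$fs
  k <- n_scalp(rec)
  freqs <- grid$freqs
  nf <- length(freqs)
  n <- ncol(rec$samples[[1]])

  seg_use <- segs[segs$segment %in% segments, ]
  wins <- vector("list", nrow(seg_use))
  for (i in seq_len(nrow(seg_use))) {
    wins[[i]] <- segment_windows(seg_use$onset_ms[i], seg_use$offset_ms[i],
                                 grid, fs, mask)
  }
  ## a window is usable only if its center clears the largest kernel margin
  max_margin <- ceiling(4 * n_cycles / (2 * pi * min(freqs)) * fs)
  all_centers <- unlist(lapply(wins, function(w) w$center_ms))
  center_samp <- ms_to_sample(unique(all_centers), fs)
  centers_ms <- unique(all_centers)
  ok <- center_samp > max_margin & center_samp <= n - max_margin
  centers_ms <- centers_ms[ok]
  center_samp <- center_samp[ok]

  ## phase array: 2k x nf x n_centers. The center-phase default reads the
  ## coefficients only at window centers (direct kernel products); the
  ## circular-mean alternative needs the full transform per channel.
  PH <- array(NA_real_, c(2 * k, nf, length(centers_ms)))
  use_center <- identical(phase_method, "center")
  win_samp <- round(grid$win_ms * fs / 1000)
  km <- if (use_center) morlet_kernel_matrix(fs, freqs, n_cycles)
  bank <- if (!use_center) morlet_bank(n, fs, freqs, n_cycles)
  for (s in 1:2) {
    scalp <- which(rec$channel_types[[s]] == "scalp")
    for (ci in seq_along(scalp)) {
      row <- (s - 1L) * k + ci
      if (use_center) {
        C <- morlet_at(rec$samples[[s]][scalp[ci], ], fs, freqs, center_samp,
                       n_cycles, km)
        PH[row, , ] <- Arg(C)
      } else {
        st <- morlet_apply(rec$samples[[s]][scalp[ci], ], bank)
        for (w in seq_along(centers_ms)) {
          idx <- (center_samp[w] - win_samp %/% 2):(center_samp[w] + win_samp %/% 2 - 1)
          idx <- idx[idx >= 1 & idx <= n]
          PH[row, , w] <- Arg(rowSums(exp(1i * Arg(st$coeffs[, idx, drop = FALSE]))))
        }
      }
    }
  }

  scopes <- c("inter", "intra_1", "intra_2")
  bmem <- band_membership(grid)
  msks <- scope_masks(k)
  res <- list()
  dropped <- list()
  for (i in seq_len(nrow(seg_use))) {
    widx <- match(wins[[i]]$center_ms, centers_ms)
    widx <- widx[!is.na(widx)]
    if (length(widx) < 2) {
      dropped[[length(dropped) + 1]] <- data.frame(
        trial = seg_use$trial[i], segment = seg_use$segment[i],
        reason = sprintf("only %d valid window(s)", length(widx)))
      next
    }
    pl <- pairwise_plv(PH[, , widx, drop = FALSE])
    for (band in names(grid$bands)) {
      fidx <- which(bmem == band)
      for (sc in scopes) {
        v <- mean(vapply(fidx, function(fi) mean(pl[, , fi][msks[[sc]]]),
                         numeric(1)))
        res[[length(res) + 1]] <- data.frame(
          trial = seg_use$trial[i], segment = seg_use$segment[i],
          band = band, scope = sc, mean_plv = v, n_windows = length(widx))
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(trial = integer(0), segment = character(0), band = character(0),
               scope = character(0), mean_plv = numeric(0), n_windows = integer(0))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  out
}
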