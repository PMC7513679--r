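#' Leader readiness from the segment table
#'
#' Leader readiness is the promptness of the leader's movement onset on the
#' follower's cue: the shorter segment s1 (follower tap to leader movement
#' onset), the higher the readiness. The readiness score is therefore the
#' negated s1 duration, so that larger scores mean better team coordination
#' and positive correlations read naturally. Trials are split into high/low
#' readiness classes at the 35th/65th percentile of s1 durations (linear
#' interpolation between order statistics, `quantile` type 7): high readiness
#' below the 35th percentile, low readiness above the 65th, the rest
#' "middle". To pool the split over several teams, compute the cutoffs on the
#' pooled durations and pass them via `cutoffs`.
#'
#' @param segs a [segment_table()]
#' @param percentiles two percentile cutoffs (default 35/65)
#' @param cutoffs optional fixed cutoffs in ms `c(low, high)` (e.g. pooled
#'   over all teams), bypassing the percentile computation
#' @return data.frame of class `readiness_table`: `trial`, `s1_ms`,
#'   `score` (= -s1_ms), `class` in {high, low, middle}; attribute
#'   `"cutoffs_ms"`. Trials without an s1 row are excluded with a message.
#' @export
leader_readiness <- function(segs, percentiles = c(35, 65), cutoffs = NULL) {
  s1 <- segs[segs$segment == "s1", ]
  all_trials <- unique(segs$trial)
  missing <- setdiff(all_trials, s1$trial)
  if (length(missing)) {
    message("excluding trial(s) without s1: ", paste(missing, collapse = ", "))
  }
  dur <- s1$offset_ms - s1$onset_ms
  if (is.null(cutoffs)) {
    cutoffs <- quantile(dur, percentiles / 100, type = 7, names = FALSE)
  }
  cls <- rep("middle", nrow(s1))
  cls[dur < cutoffs[1]] <- "high"
  cls[dur > cutoffs[2]] <- "low"
  if (all(cls == "middle")) {
    message("degenerate readiness split: no class contrast (all durations ",
            "inside the percentile cutoffs)")
  }
  out <- data.frame(trial = s1$trial, s1_ms = dur, score = -dur, class = cls)
  attr(out, "cutoffs_ms") <- cutoffs
  class(out) <- c("readiness_table", "data.frame")
  out
}

#' Pearson correlation with 5 percent tail exclusion
#'
#' Drops observations whose x value lies in the lowest or highest 5 percent
#' of x, together with observations whose y value lies in the lowest or
#' highest 5 percent of y (union of exclusions; quantile type 7, values equal
#' to the cutoff retained), then computes the Pearson correlation and its
#' two-sided p value on the remainder. This guards the coherence-readiness
#' correlations against spurious effects of outliers.
#'
#' @param x,y paired numeric vectors, at least 10 pairs
#' @param trim tail fraction per side (default 0.05)
#' @param method `"pearson"` (default) or `"spearman"`
#' @return list `r`, `p`, `n_used`; `r` is `NA` (flagged via `degenerate`)
#'   when a variable has zero variance after trimming
#' @export
trimmed_correlation <- function(x, y, trim = 0.05, method = "pearson") {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need at least 10 paired observations")
  qx <- quantile(x, c(trim, 1 - trim), type = 7, names = FALSE)
  qy <- quantile(y, c(trim, 1 - trim), type = 7, names = FALSE)
  keep <- x >= qx[1] & x <= qx[2] & y >= qy[1] & y <= qy[2]
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) < 3 || var(xs) == 0 || var(ys) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_used = length(xs),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(xs, ys, method = method,
                                  alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value, n_used = length(xs),
       degenerate = FALSE)
}

## Conventional significance tiers used in the report grid.
significance_tier <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*",
  ifelse(p < 0.10, "+", "")))))
}

#' Coherence-readiness correlation scan
#'
#' For every combination of trial segment, frequency band and scope
#' (inter-brain, intra-brain per subject), correlates the per-trial mean
#' coherence with the readiness score using [trimmed_correlation()]. One row
#' per cell with the correlation, p value, sample size and a conventional
#' significance tier (+ p<0.10, * p<0.05, ** p<0.01, *** p<0.001; no
#' multiple-testing correction by default, matching per-cell reporting).
#' Cells without data are absent from the result, not zero.
#'
#' @param coh output of [dyad_coherence()] (possibly concatenated over teams
#'   with unique trial ids)
#' @param readiness a [leader_readiness()] table keyed by the same trial ids
#' @param segments,bands,scopes subsets to scan (defaults: everything present)
#' @param trim tail fraction for [trimmed_correlation()]
#' @param method correlation method
#' @param p_adjust optional p-value adjustment (`"BH"`), off by default
#' @return data.frame: `segment`, `band`, `scope`, `r`, `p`, `tier`, `n_used`
#' @export
coherence_readiness_scan <- function(coh, readiness,
                                     segments = unique(coh$segment),
                                     bands = unique(coh$band),
                                     scopes = unique(coh$scope),
                                     trim = 0.05, method = "pearson",
                                     p_adjust = NULL) {
  res <- list()
  for (sg in segments) for (bd in bands) for (sc in scopes) {
    cell <- coh[coh$segment == sg & coh$band == bd & coh$scope == sc, ]
    m <- merge(cell, readiness, by = "trial")
    if (nrow(m) < 10) next
    tc <- trimmed_correlation(m$mean_plv, m$score, trim = trim, method = method)
    res[[length(res) + 1]] <- data.frame(segment = sg, band = bd, scope = sc,
                                         r = tc$r, p = tc$p, n_used = tc$n_used)
  }
  if (!length(res)) {
    return(data.frame(segment = character(0), band = character(0),
                      scope = character(0), r = numeric(0), p = numeric(0),
                      tier = character(0), n_used = integer(0)))
  }
  out <- do.call(rbind, res)
  if (!is.null(p_adjust)) out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$tier <- significance_tier(out$p)
  out[c("segment", "band", "scope", "r", "p", "tier", "n_used")]
}
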