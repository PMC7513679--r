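## Behavioral segment identifiers in within-trial temporal order. Each room
## clearing trial starts with restacking/alignment (s9), runs through tap
## preparation (s0), the follower-to-leader tap interval (s1, the leader
## readiness measure), movement and entry (s2-s4), and breaks coordination
## while clearing the room (s5-s7a) before rebuilding it (s7b, s8).
SEGMENT_IDS <- c("s9", "s0", "s1", "s2", "s3", "s4", "s5", "s6",
                 "s7a", "s7b", "s8")

#' Segment identifiers in within-trial order
#' @return character vector of the 11 behavioral segment ids
#' @export
segment_ids <- function() SEGMENT_IDS

#' Per-trial behavioral segment table
#'
#' Validates and orders a table of behavioral segments: one row per
#' (trial, segment) with half-open `[onset_ms, offset_ms)` intervals.
#' Segments within a trial must be non-overlapping; every offset must exceed
#' its onset; segment ids must be known.
#'
#' @param df data.frame with columns `trial`, `segment`, `onset_ms`,
#'   `offset_ms`
#' @return data.frame of class `segment_table`, sorted by (trial, onset)
#' @export
segment_table <- function(df) {
  need <- c("trial", "segment", "onset_ms", "offset_ms")
  if (!all(need %in% names(df))) {
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  df$segment <- as.character(df$segment)
  bad <- setdiff(unique(df$segment), SEGMENT_IDS)
  if (length(bad)) stop("unknown segment id(s): ", paste(bad, collapse = ", "))
  if (any(df$offset_ms <= df$onset_ms)) {
    i <- which(df$offset_ms <= df$onset_ms)[1]
    stop("segment ", df$segment[i], " of trial ", df$trial[i],
         " has offset <= onset")
  }
  df <- df[order(df$trial, df$onset_ms), ]
  for (tr in unique(df$trial)) {
    d <- df[df$trial == tr, ]
    if (nrow(d) > 1 && any(d$onset_ms[-1] < d$offset_ms[-nrow(d)])) {
      stop("overlapping segments within trial ", tr)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Read a segment table from a TSV file
#'
#' @param path delimited file with columns `trial`, `segment`, `onset_ms`,
#'   `offset_ms`
#' @return a validated [segment_table()]
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  segment_table(data.table::fread(path, sep = "\t", data.table = FALSE))
}

#' Write a segment table to TSV
#' @param segs a [segment_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_segments <- function(segs, path) {
  data.table::fwrite(as.data.frame(segs), path, sep = "\t")
  invisible(path)
}

#' Segment durations in milliseconds
#' @param segs a [segment_table()]
#' @return numeric vector `offset_ms - onset_ms` along rows
#' @export
segment_durations <- function(segs) segs$offset_ms - segs$onset_ms
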