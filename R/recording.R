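#' Synchronized two-subject EEG recording
#'
#' Container for a dual-EEG session: one channels-by-time matrix per subject
#' (microvolts), a shared sampling rate, per-subject channel tables
#' distinguishing scalp from EOG channels, and the team role of each subject.
#'
#' @param samples list of two numeric matrices, channels x time, in microvolts;
#'   rownames are channel labels
#' @param fs sampling rate in Hz (shared by both subjects)
#' @param channel_types list of two character vectors (`"scalp"` or `"eog"`)
#'   along the rows of the corresponding matrix
#' @param roles character vector of length 2, a permutation of
#'   `c("leader", "follower")`, giving each subject's team role
#' @param t0 recording start time in milliseconds (time coordinates are
#'   0-based and milliseconds throughout)
#' @return object of class `dual_recording`
#' @export
dual_recording <- function(samples, fs, channel_types, roles = c("leader", "follower"),
                           t0 = 0) {
  rec <- structure(list(samples = samples, fs = fs,
                        channel_types = channel_types, roles = roles, t0 = t0),
                   class = "dual_recording")
  validate_recording(rec)
  rec
}

#' Validate a dual recording's invariants
#'
#' Both subjects must share the sampling rate and sample count, channel labels
#' must be unique within subject, the scalp channel counts must match across
#' subjects, and all samples must be finite.
#' @param rec a [dual_recording()]
#' @return `rec`, invisibly; errors describe the violated invariant
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "dual_recording"))
  if (length(rec$samples) != 2L) stop("a dual recording needs exactly 2 subjects")
  if (!is.numeric(rec$fs) || rec$fs <= 0) stop("fs must be a positive sampling rate")
  if (!setequal(rec$roles, c("leader", "follower"))) {
    stop("roles must assign one leader and one follower")
  }
  ns <- vapply(rec$samples, ncol, 1L)
  if (ns[1] != ns[2]) {
    stop("subjects have mismatched sample counts (", ns[1], " vs ", ns[2], ")")
  }
  for (s in 1:2) {
    X <- rec$samples[[s]]
    if (is.null(rownames(X))) stop("subject ", s, ": channel labels missing")
    if (anyDuplicated(rownames(X))) stop("subject ", s, ": duplicated channel labels")
    if (length(rec$channel_types[[s]]) != nrow(X)) {
      stop("subject ", s, ": channel_types length mismatch")
    }
    if (!all(is.finite(X))) stop("subject ", s, ": non-finite samples")
  }
  k <- vapply(1:2, function(s) sum(rec$channel_types[[s]] == "scalp"), 1L)
  if (k[1] != k[2]) stop("subjects have different scalp channel counts")
  invisible(rec)
}

#' Number of scalp electrodes per subject
#' @param rec a [dual_recording()]
#' @export
n_scalp <- function(rec) sum(rec$channel_types[[1]] == "scalp")

#' Scalp channel labels of one subject
#' @param rec a [dual_recording()]
#' @param subject 1 or 2
#' @export
scalp_labels <- function(rec, subject = 1) {
  rownames(rec$samples[[subject]])[rec$channel_types[[subject]] == "scalp"]
}

#' Recording duration in milliseconds
#' @param rec a [dual_recording()]
#' @export
recording_duration_ms <- function(rec) ncol(rec$samples[[1]]) * 1000 / rec$fs

#' @export
print.dual_recording <- function(x, ...) {
  cat("<dual_recording> fs =", x$fs, "Hz,",
      ncol(x$samples[[1]]), "samples (", round(recording_duration_ms(x) / 1000, 1),
      "s ),", n_scalp(x), "scalp +",
      sum(x$channel_types[[1]] == "eog"), "EOG channels/subject\n")
  cat("  roles:", paste(seq_along(x$roles), x$roles, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Write a dual recording to a directory
#'
#' Native on-disk format: one plain-text numeric matrix per subject
#' (`subject1.tsv`, `subject2.tsv`; samples in rows, channels in columns with a
#' header of labels), a channel sidecar (`channels.tsv`) and a JSON metadata
#' file (`recording.json` with fs, t0 and roles). Everything is text so that
#' round trips are reproducible bit-for-bit after one write-read cycle.
#'
#' @param rec a [dual_recording()]
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = rec$fs, t0 = rec$t0, roles = rec$roles)
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  chan <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(subject = s, label = rownames(rec$samples[[s]]),
               type = rec$channel_types[[s]])
  }))
  data.table::fwrite(chan, file.path(path, "channels.tsv"), sep = "\t")
  for (s in 1:2) {
    M <- t(rec$samples[[s]])
    data.table::fwrite(data.table::as.data.table(M),
                       file.path(path, sprintf("subject%d.tsv", s)), sep = "\t")
  }
  invisible(path)
}

#' Load a dual recording from a directory
#'
#' Reads the native container written by [write_recording()]. An optional
#' `subject_map` restricts/reorders channels per subject; a requested label
#' missing from the file is a descriptive error naming the label and subject.
#'
#' @param path directory produced by [write_recording()]
#' @param subject_map optional list of two character vectors of channel labels
#'   to select, in order, per subject
#' @return a validated [dual_recording()]
#' @export
load_recording <- function(path, subject_map = NULL) {
  if (!dir.exists(path)) stop("recording directory not found: ", path)
  meta <- jsonlite::read_json(file.path(path, "recording.json"), simplifyVector = TRUE)
  chan <- data.table::fread(file.path(path, "channels.tsv"), sep = "\t",
                            data.table = FALSE)
  samples <- vector("list", 2)
  types <- vector("list", 2)
  for (s in 1:2) {
    M <- as.matrix(data.table::fread(file.path(path, sprintf("subject%d.tsv", s)),
                                     sep = "\t", data.table = FALSE))
    labels <- colnames(M)
    ctypes <- chan$type[chan$subject == s][match(labels, chan$label[chan$subject == s])]
    if (!is.null(subject_map)) {
      want <- subject_map[[s]]
      missing <- setdiff(want, labels)
      if (length(missing)) {
        stop("channel(s) ", paste(missing, collapse = ", "),
             " missing for subject ", s)
      }
      idx <- match(want, labels)
      M <- M[, idx, drop = FALSE]
      labels <- want
      ctypes <- ctypes[idx]
    }
    X <- t(M)
    rownames(X) <- labels
    samples[[s]] <- X
    types[[s]] <- ctypes
  }
  dual_recording(samples, fs = meta$fs, channel_types = types,
                 roles = meta$roles, t0 = meta$t0 %||% 0)
}
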