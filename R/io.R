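#' fNIRS recording container
#'
#' One participant's continuous multichannel hemodynamic time series (HbO
#' concentration) with stimulus annotations and group label.  Annotations
#' use onsets in seconds, 0-based, and half-open intervals
#' `[onset, onset + duration)`.
#'
#' @param signal numeric matrix `[time x channels]`.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids channel labels; defaults to `ch1..chC`.
#' @param subject_id participant identifier.
#' @param group group label, `"MDD"` or `"HC"` (or `NA`).
#' @param annotations data frame with columns `onset` (s), `duration` (s),
#'   `label` (one of happy/calm/fear/noise/rest); must lie within the
#'   recording.
#' @return a validated `recording` object.
#' @export
recording <- function(signal, fs, channel_ids = NULL, subject_id = "s01",
                      group = NA_character_, annotations = NULL) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 1 || ncol(signal) < 1) stop("signal needs >= 1 sample and >= 1 channel")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(signal)))
  if (length(channel_ids) != ncol(signal)) {
    stop("channel_ids length ", length(channel_ids), " != ", ncol(signal), " channels")
  }
  colnames(signal) <- channel_ids
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    need <- c("onset", "duration", "label")
    if (!all(need %in% names(annotations))) {
      stop("annotations need columns: ", paste(need, collapse = ", "))
    }
    dur_total <- nrow(signal) / fs
    ends <- annotations$onset + annotations$duration
    bad <- which(annotations$onset < 0 | ends > dur_total + 1e-9)
    if (length(bad) > 0) {
      stop("annotation(s) outside recording [0, ", signif(dur_total, 6), "] s: ",
           paste(sprintf("#%d (%s %.6g+%.6gs)", bad, annotations$label[bad],
                         annotations$onset[bad], annotations$duration[bad]),
                 collapse = "; "))
    }
  }
  structure(list(subject_id = subject_id, group = group,
                 channel_ids = channel_ids, fs = fs, signal = signal,
                 annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("recording", x$subject_id, "(", x$group, "):",
      nrow(x$signal), "samples x", ncol(x$signal), "channels @", x$fs, "Hz\n")
  invisible(x)
}

#' Read / write recordings (TSV + JSON sidecar)
#'
#' On-disk format: a TSV with one row per sample and one column per channel
#' (header = channel ids), plus a JSON sidecar `<path>.json` holding
#' `subject_id`, `group`, `fs`, `channel_ids` and `annotations`.  Numeric
#' values are written with 17 significant digits so that
#' `read_recording(write_recording(rec, p))` reproduces every field exactly.
#'
#' @param path TSV file path (sidecar derived by appending `.json`).
#' @param rec a `recording`.
#' @return `read_recording` returns a `recording`; `write_recording`
#'   invisibly returns `path`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing JSON sidecar: ", meta_path)
  meta <- jsonlite::fromJSON(meta_path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric", check.names = FALSE)
  if (!identical(header, as.character(meta$channel_ids))) {
    stop("TSV header does not match sidecar channel_ids\n  TSV: ",
         paste(header, collapse = ","), "\n  sidecar: ",
         paste(meta$channel_ids, collapse = ","))
  }
  ann <- meta$annotations
  if (!is.null(ann) && length(ann) > 0) ann <- as.data.frame(ann) else ann <- NULL
  recording(as.matrix(dat), fs = meta$fs, channel_ids = meta$channel_ids,
            subject_id = meta$subject_id, group = meta$group,
            annotations = ann)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  txt <- apply(rec$signal, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(c(paste(rec$channel_ids, collapse = "\t"), txt), path)
  ann <- rec$annotations
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               fs = rec$fs, channel_ids = rec$channel_ids,
               annotations = if (is.null(ann)) list() else ann)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Removes drifts, respiration (0.2-0.5 Hz) and cardiac (> 1 Hz) components
#' from hemodynamic signals with a default 0.01-0.2 Hz pass band.  The
#' filter is applied in the frequency domain with the squared magnitude
#' response of an order-4 Butterworth band-pass (the amplitude response of
#' forward-backward filtering), which is zero-phase by construction and
#' exactly linear.
#'
#' @param rec a `recording` or numeric matrix `[time x channels]`.
#' @param low,high band edges in Hz; requires `0 < low < high < fs/2`.
#' @param fs sampling rate, required when `rec` is a bare matrix.
#' @param order Butterworth order (default 4).
#' @return same type as `rec`, filtered.
#' @export
bandpass <- function(rec, low = 0.01, high = 0.2, fs = NULL, order = 4) {
  is_rec <- inherits(rec, "recording")
  sig <- if (is_rec) rec$signal else as.matrix(rec)
  if (is_rec) fs <- rec$fs
  if (is.null(fs)) stop("fs required when filtering a bare matrix")
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2; got low=", low, " high=", high,
         " fs/2=", fs / 2)
  }
  n <- nrow(sig)
  freqs <- seq(0, n - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum folding
  # |H|^2 of an order-`order` Butterworth band-pass (forward-backward gain)
  gain_lp <- 1 / (1 + (freqs / high)^(2 * order))
  gain_hp <- (freqs / low)^(2 * order) / (1 + (freqs / low)^(2 * order))
  gain <- gain_lp * gain_hp
  out <- Re(stats::mvfft(stats::mvfft(sig) * gain, inverse = TRUE)) / n
  colnames(out) <- colnames(sig)
  if (is_rec) {
    rec$signal <- out
    rec
  } else out
}

#' Extract one stimulus category from a recording
#'
#' Concatenates, in temporal order, all trials of the requested stimulus
#' category ("happy", "calm", "fear", "noise", or "full" = every non-rest
#' trial).  Trial samples are taken over the half-open interval
#' `[onset, onset + duration)`: 0-based start sample `round(onset * fs)`,
#' `round(duration * fs)` samples.
#'
#' @param rec a `recording` with annotations.
#' @param category one of `"happy"`, `"calm"`, `"fear"`, `"noise"`, `"full"`.
#' @param full_excludes_noise when `TRUE`, `"full"` drops white-noise trials;
#'   default `FALSE` ("all stimuli" = all four trial types).
#' @return a `stimulus_segment`: `category`, `signal` (concatenated),
#'   `trials` (source annotation row indices), `fs`, `channel_ids`.
#' @export
segment <- function(rec, category, full_excludes_noise = FALSE) {
  stopifnot(inherits(rec, "recording"))
  valid <- c("happy", "calm", "fear", "noise", "full")
  if (!category %in% valid) {
    stop("category must be one of ", paste(valid, collapse = ", "))
  }
  ann <- rec$annotations
  if (is.null(ann)) stop("recording has no annotations")
  wanted <- if (category == "full") {
    if (full_excludes_noise) c("happy", "calm", "fear") else
      c("happy", "calm", "fear", "noise")
  } else category
  rows <- which(ann$label %in% wanted)
  if (length(rows) == 0) stop("no '", category, "' trials in annotations")
  rows <- rows[order(ann$onset[rows])]
  pieces <- lapply(rows, function(i) {
    start <- round(ann$onset[i] * rec$fs)  # 0-based
    len <- round(ann$duration[i] * rec$fs)
    rec$signal[(start + 1):(start + len), , drop = FALSE]
  })
  structure(list(category = category,
                 signal = do.call(rbind, pieces),
                 trials = rows, fs = rec$fs,
                 channel_ids = rec$channel_ids),
            class = "stimulus_segment")
}

#' @export
print.stimulus_segment <- function(x, ...) {
  cat("stimulus_segment '", x$category, "': ", nrow(x$signal), " samples x ",
      ncol(x$signal), " channels (", length(x$trials), " trials)\n", sep = "")
  invisible(x)
}
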