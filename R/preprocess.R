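#' Continuous single-channel recording
#'
#' Lightweight container for a continuous LFP/iEEG trace prior to
#' segmentation.
#'
#' @param samples Numeric vector of signal values.
#' @param fs Sampling rate (Hz).
#' @param subject_id,channel_id Identifiers carried through the pipeline.
#' @return A list of class `eeg_recording`.
#' @export
recording <- function(samples, fs, subject_id = "subject",
                      channel_id = "ch1") {
  stopifnot(fs > 0, length(samples) >= 1, is.numeric(samples))
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, channel_id = channel_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Center a recording around zero and invert its polarity
#'
#' Subtracts the mean and flips the sign: out = -(x - mean(x)). Inversion
#' brings rat and human recordings to the same polarity convention as the
#' model output; it preserves variance and all band-power ratios. Apply it
#' only to data configured for inversion (model output is not inverted).
#'
#' @param rec An `eeg_recording`.
#' @param invert Flip the polarity after centering (default TRUE).
#' @return The transformed `eeg_recording`.
#' @examples
#' r <- recording(c(1, 2, 3), fs = 1)
#' center_and_invert(r)$samples # 1 0 -1
#' @export
center_and_invert <- function(rec, invert = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples - mean(rec$samples)
  rec$samples <- if (invert) -x else x
  rec
}

# Biquad notch coefficients (RBJ audio-EQ cookbook form). Returns b, a
# normalized to a0 = 1; quality factor Q sets the -3 dB width f0/Q.
notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Remove line noise with a narrow notch filter
#'
#' Second-order IIR notch (quality factor `Q`, so the -3 dB width is
#' `freq/Q` Hz) applied forward-backward with [signal::filtfilt()] for zero
#' phase distortion. Power at the notch frequency is attenuated by well
#' over 20 dB while the passband outside freq +/- 2 Hz stays within 1 dB.
#'
#' @param rec An `eeg_recording`.
#' @param freq Notch center frequency in Hz (default 50, European mains).
#' @param Q Quality factor of the notch.
#' @return The filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq = 50, Q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (freq >= rec$fs / 2)
    stop("notch frequency must be below the Nyquist rate")
  co <- notch_coefficients(freq, rec$fs, Q)
  rec$samples <- as.numeric(
    signal::filtfilt(signal::Arma(b = co$b, a = co$a), rec$samples))
  rec
}

#' Cut a recording into fixed-length consecutive segments
#'
#' Non-overlapping windows of `window` seconds, anchored at the first
#' sample; a trailing remainder shorter than one window is dropped. Segment
#' order preserves time order.
#'
#' @param rec An `eeg_recording`.
#' @param window Window length in seconds (default 5).
#' @param labels Optional integer labels (1--4), one per produced segment
#'   or one per sample-window position; attached as true labels.
#' @return A `segment_set` (possibly empty, with a warning if the recording
#'   is shorter than one window).
#' @examples
#' r <- recording(rnorm(23 * 512), fs = 512)
#' length(segment_recording(r)) # 4 segments, 3 s dropped
#' @export
segment_recording <- function(rec, window = 5, labels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_win <- round(window * rec$fs)
  if (n_win < 2) stop("window too short for the sampling rate")
  n_seg <- length(rec$samples) %/% n_win
  if (n_seg == 0) {
    warning("recording shorter than one window: no segments produced")
    return(structure(list(), class = "segment_set", labels = integer(0)))
  }
  if (!is.null(labels) && length(labels) != n_seg)
    stop("labels must have one entry per produced segment (", n_seg, ")")
  segs <- lapply(seq_len(n_seg), function(i) {
    new_segment(rec$samples[((i - 1) * n_win + 1):(i * n_win)], rec$fs,
                true_label = if (is.null(labels)) NA_integer_ else labels[i])
  })
  structure(segs, class = "segment_set",
            labels = if (is.null(labels)) rep(NA_integer_, n_seg)
                     else as.integer(labels))
}

#' Read a recording from a delimited text file
#'
#' Accepts a one-column numeric file or a CSV with a `value` column.
#' Metadata (fs, subject, channel, whether to invert polarity) comes from a
#' YAML sidecar if present (`<file>.yaml`) or from the arguments.
#'
#' @param path Path to the signal file.
#' @param fs Sampling rate; overridden by a sidecar `fs` field.
#' @param subject_id,channel_id Identifiers; sidecar fields win.
#' @return An `eeg_recording` with an `invert` attribute (logical) when the
#'   sidecar declares one.
#' @export
read_recording <- function(path, fs = NULL, subject_id = "subject",
                           channel_id = "ch1") {
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  fs <- meta$fs %||% fs
  if (is.null(fs)) stop("sampling rate not given and no sidecar found")
  first <- readLines(path, n = 1)
  x <- if (grepl("[A-Za-z]", first)) {
    tab <- utils::read.csv(path)
    if (!"value" %in% names(tab)) stop("CSV input must have a 'value' column")
    tab$value
  } else {
    scan(path, quiet = TRUE)
  }
  rec <- recording(x, fs, meta$subject_id %||% subject_id,
                   meta$channel_id %||% channel_id)
  attr(rec, "invert") <- isTRUE(meta$invert)
  rec
}

#' Read per-segment labels from a CSV file
#' @param path CSV with columns `segment_index`, `label`.
#' @return Integer label vector ordered by segment index.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("segment_index", "label") %in% names(tab)))
  labs <- as.integer(tab$label[order(tab$segment_index)])
  if (!all(labs %in% 1:4)) stop("labels must be integers in 1..4")
  labs
}
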