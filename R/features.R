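#' Names of the eleven per-segment signal features, in canonical order
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("mean", "b0power", "b1power", "b2power", "b3power", "b4power",
    "alphdiff", "spikeabs", "sigvar", "autocorrel", "linelen")
}

# Frequency band edges (Hz) for the five band-power features; the upper
# edge of b4 is the segment's own Nyquist rate.
band_edges <- function(fs) {
  list(b0 = c(0, 0.5), b1 = c(0.5, 4), b2 = c(4, 12), b3 = c(12, 64),
       b4 = c(64, fs / 2 + 1))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed subwindows (default one
#' second) with 50% overlap, per-window mean removal, density scaling so
#' that `sum(psd) * fs / nfft` recovers the (detrended, windowed) signal
#' power. One-sided; the DC bin holds only within-window drift because each
#' window is demeaned.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Subwindow length in seconds.
#' @return List with `freq` (Hz) and `psd` (signal^2 / Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1) {
  n <- round(window_s * fs)
  if (length(x) < n) n <- length(x)
  w <- signal::hanning(n)
  step <- max(1, floor(n / 2))
  starts <- seq(1, length(x) - n + 1, by = step)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + (Mod(stats::fft(seg))^2)[1:nf]
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  # fold two-sided power into the one-sided estimate (not DC/Nyquist)
  inner <- 2:(nf - if (n %% 2 == 0) 1 else 0)
  psd[inner] <- 2 * psd[inner]
  list(freq = seq(0, by = fs / n, length.out = nf), psd = psd)
}

#' Average band power of a segment
#'
#' Mean of the Welch PSD over bins whose center frequency falls in the
#' half-open band [lo, hi).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges in Hz.
#' @return Average power density in the band (signal^2 / Hz).
#' @export
band_power <- function(x, fs, lo, hi) {
  W <- welch_psd(x, fs)
  sel <- W$freq >= lo & W$freq < hi
  if (!any(sel)) return(0)
  mean(W$psd[sel])
}

#' Dominant frequency band of a segment
#'
#' The band carrying the largest integrated (summed) Welch-PSD power among
#' 0.5--4, 4--12, 12--64 and >64 Hz. Integrated rather than per-bin average
#' power is compared, so a broad band is not penalized for its width; this
#' is the quantity that matches the visual impression of which rhythm
#' dominates a trace.
#'
#' @param x Numeric signal (or an `eeg_segment`).
#' @param fs Sampling rate; ignored when `x` is a segment.
#' @return The winning band as a factor level in
#'   `c("0.5-4", "4-12", "12-64", ">64")`.
#' @export
dominant_band <- function(x, fs = NULL) {
  if (inherits(x, "eeg_segment")) { fs <- x$fs; x <- x$samples }
  stopifnot(!is.null(fs))
  W <- welch_psd(x, fs)
  bands <- list(`0.5-4` = c(0.5, 4), `4-12` = c(4, 12),
                `12-64` = c(12, 64), `>64` = c(64, fs / 2 + 1))
  tot <- vapply(bands, function(b)
    sum(W$psd[W$freq >= b[1] & W$freq < b[2]]), numeric(1))
  factor(names(bands)[which.max(tot)], levels = names(bands))
}

#' Autocorrelation at a fixed time lag
#'
#' Pearson correlation of x[1:(n-k)] with x[(k+1):n] where
#' k = round(lag_s * fs), at least one sample.
#'
#' @param x Numeric signal.
#' @param lag_s Lag in seconds (default 5 ms).
#' @param fs Sampling rate (Hz).
#' @return Correlation in [-1, 1]; 0 with a warning for a zero-variance
#'   signal (correlation undefined).
#' @export
autocorrelation_at_lag <- function(x, lag_s = 0.005, fs) {
  k <- max(1L, as.integer(round(lag_s * fs)))
  n <- length(x)
  if (k >= n) stop("lag must be shorter than the signal")
  if (stats::var(x) == 0) {
    warning("zero-variance signal: autocorrelation undefined, returning 0")
    return(0)
  }
  stats::cor(x[1:(n - k)], x[(k + 1):n])
}

#' Compute the eleven signal features of one segment
#'
#' Signal mean; average band power in 0--0.5, 0.5--4, 4--12, 12--64 and
#' >64 Hz (Welch estimate); `alphdiff`, the distance between the 0.95 and
#' 0.05 quantiles; `spikeabs`, the number of samples outside the Tukey
#' fences Q1 - 1.5 IQR and Q3 + 1.5 IQR; signal variance; autocorrelation
#' at 5 ms lag; and line length, the sum of absolute successive
#' differences. All features are computed on the raw segment;
#' normalization happens later across a dataset.
#'
#' Quantiles use the linear-interpolation convention (R type 7) and the
#' variance/z-scores the sample (n-1) denominator. Outliers are counted
#' per sample, not merged into events.
#'
#' @param seg An `eeg_segment`, or a numeric vector with `fs` supplied.
#' @param fs Sampling rate when `seg` is a bare vector.
#' @return Named numeric vector of length 11 in [feature_names()] order.
#' @examples
#' seg <- simulate_wendling(wendling_state_configs()$ictal, 2, seed = 1)
#' compute_features(seg)["b2power"]
#' @export
compute_features <- function(seg, fs = NULL) {
  if (inherits(seg, "eeg_segment")) { fs <- seg$fs; x <- seg$samples }
  else { x <- as.numeric(seg); stopifnot(!is.null(fs)) }
  if (length(x) < 2 * max(1, round(0.005 * fs)))
    stop("segment too short for feature computation")
  q <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  iqr <- q[3] - q[2]
  bp <- vapply(band_edges(fs), function(b) band_power(x, fs, b[1], b[2]),
               numeric(1))
  ac <- if (stats::var(x) == 0) {
    warning("zero-variance segment: autocorrelation set to 0")
    0
  } else autocorrelation_at_lag(x, 0.005, fs)
  stats::setNames(
    c(mean(x), bp,
      q[4] - q[1],
      sum(x < q[2] - 1.5 * iqr | x > q[3] + 1.5 * iqr),
      stats::var(x), ac, sum(abs(diff(x)))),
    feature_names())
}

#' Feature matrix of a segment set
#'
#' Applies [compute_features()] to every segment and stacks the results
#' into a segments x 11 matrix carrying the true labels (if any) and the
#' dataset identifier.
#'
#' @param segs A `segment_set` (or plain list of `eeg_segment`s).
#' @param dataset_id Text identifier of the dataset (used in provenance).
#' @return A `feature_matrix`: numeric matrix with attributes `labels`,
#'   `dataset_id`, `fs`, and later `norm_stats` once normalized.
#' @export
segment_features <- function(segs, dataset_id = "dataset") {
  stopifnot(length(segs) >= 1)
  fm <- t(vapply(segs, compute_features, numeric(11)))
  labs <- if (!is.null(attr(segs, "labels"))) attr(segs, "labels")
          else vapply(segs, function(s)
            if (inherits(s, "eeg_segment")) s$true_label else NA_integer_,
            integer(1))
  structure(fm, class = c("feature_matrix", class(fm)),
            labels = labs, dataset_id = dataset_id, fs = segs[[1]]$fs,
            normalized = FALSE)
}

#' z-normalize a feature matrix across segments
#'
#' Column-wise (x - mean) / sd with the sample (n-1) standard deviation,
#' computed across all segments of the dataset. The statistics are stored
#' so that other data can be brought to the same scale and the projection
#' is reproducible. A zero-variance column is set to 0 with a warning.
#'
#' @param fm A `feature_matrix` (at least 2 rows).
#' @param stats Optional precomputed list with `mean` and `sd` vectors; by
#'   default the matrix's own statistics are used.
#' @return The normalized `feature_matrix` with attribute `norm_stats`.
#' @export
znormalize <- function(fm, stats = NULL) {
  stopifnot(is.matrix(fm), nrow(fm) >= 2)
  if (is.null(stats))
    stats <- list(mean = colMeans(fm),
                  sd = apply(fm, 2, stats::sd))
  z <- sweep(fm, 2, stats$mean, "-")
  degenerate <- stats$sd == 0
  if (any(degenerate)) {
    warning("zero-variance feature column(s) set to 0: ",
            paste(colnames(fm)[degenerate], collapse = ", "))
    stats$sd[degenerate] <- Inf
  }
  z <- sweep(z, 2, stats$sd, "/")
  attributes(z) <- attributes(fm)
  dim(z) <- dim(fm); dimnames(z) <- dimnames(fm)
  attr(z, "norm_stats") <- stats
  attr(z, "normalized") <- TRUE
  z
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features (%s, %s)\n",
              nrow(x), ncol(x), attr(x, "dataset_id"),
              if (isTRUE(attr(x, "normalized"))) "z-normalized" else "raw"))
  invisible(x)
}
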