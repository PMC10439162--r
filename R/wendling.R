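#' Wendling neural mass model parameters
#'
#' Builds the full parameter set of the four-population Wendling model of
#' hippocampal dynamics. The synaptic gains `A` (excitation), `B` (slow
#' dendritic inhibition) and `G` (fast somatic inhibition) control the
#' amplitude of the corresponding postsynaptic potentials and are the knobs
#' that move the model between brain-state regimes; everything else is the
#' standard parameterization.
#'
#' The connectivity constants are derived from the base connectivity `C`:
#' C1 = C, C2 = C7 = 0.8 C, C3 = C4 = 0.25 C, C5 = 0.3 C, C6 = 0.1 C.
#'
#' @param A Excitatory synaptic gain (mV).
#' @param B Slow-inhibitory synaptic gain (mV).
#' @param G Fast-inhibitory synaptic gain (mV).
#' @param a,b,g Inverse time constants of the excitatory, slow-inhibitory and
#'   fast-inhibitory synaptic kernels (1/s).
#' @param C Base connectivity constant (dimensionless).
#' @param v0 Sigmoid midpoint potential (mV).
#' @param e0 Half of the maximum population firing rate (1/s).
#' @param r Sigmoid steepness (1/mV).
#' @param noise_mean,noise_std Mean and standard deviation of the Gaussian
#'   input firing-rate noise p(t) (1/s).
#' @return A list of class `wendling_params` with all model constants,
#'   including the derived C1..C7.
#' @examples
#' p <- wendling_params(A = 3.5, B = 13.2, G = 10.76)
#' p$C2 # 0.8 * 135
#' @export
wendling_params <- function(A = 5, B = 22, G = 10,
                            a = 100, b = 30, g = 350, C = 135,
                            v0 = 6, e0 = 2.5, r = 0.56,
                            noise_mean = 90, noise_std = 30) {
  stopifnot(a > 0, b > 0, g > 0, C > 0, e0 > 0, r > 0, noise_std >= 0)
  p <- list(A = A, B = B, G = G, a = a, b = b, g = g, C = C,
            C1 = C, C2 = 0.8 * C, C3 = 0.25 * C, C4 = 0.25 * C,
            C5 = 0.3 * C, C6 = 0.1 * C, C7 = 0.8 * C,
            v0 = v0, e0 = e0, r = r,
            noise_mean = noise_mean, noise_std = noise_std)
  class(p) <- "wendling_params"
  p
}

#' Canonical brain-state configurations
#'
#' The four A/B/G synaptic-gain configurations that make the Wendling model
#' reproduce the four types of epileptic brain state: interictal (baseline
#' fluctuations), preonset (sporadic high-amplitude spikes), onset
#' (low-amplitude fast 15--40 Hz oscillations) and ictal (sustained rhythmic
#' 4--10 Hz activity). Labels are fixed integers 1--4 in that order.
#'
#' @return Named list of four `wendling_params` objects, each with a
#'   `label` attribute in 1:4.
#' @examples
#' cfg <- wendling_state_configs()
#' names(cfg)
#' cfg$ictal$A
#' @export
wendling_state_configs <- function() {
  abg <- list(
    interictal = c(A = 3.5, B = 13.2, G = 10.76),
    preonset   = c(A = 4.6, B = 20.4, G = 11.48),
    onset      = c(A = 7.7, B = 4.3,  G = 15.1),
    ictal      = c(A = 8.7, B = 11.4, G = 2.1)
  )
  out <- lapply(seq_along(abg), function(i) {
    v <- abg[[i]]
    p <- wendling_params(A = v[["A"]], B = v[["B"]], G = v[["G"]])
    attr(p, "label") <- i
    p
  })
  names(out) <- names(abg)
  out
}

#' State labels and their names
#' @return Named integer vector mapping state names to labels 1:4.
#' @export
brain_state_labels <- function() {
  c(interictal = 1L, preonset = 2L, onset = 3L, ictal = 4L)
}

#' Population firing-rate sigmoid
#'
#' S(v) = 2 e0 / (1 + exp(r (v0 - v))): the static nonlinearity converting
#' mean membrane potential into population firing rate. Bounded in
#' (0, 2 e0) and strictly increasing.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param params A `wendling_params` object supplying v0, e0, r.
#' @return Firing rate(s) in 1/s.
#' @examples
#' wendling_sigmoid(6, wendling_params()) # e0 = 2.5 at the midpoint
#' @export
wendling_sigmoid <- function(v, params = wendling_params()) {
  2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
}

#' Time derivative of the Wendling state
#'
#' The ten-equation system: five second-order postsynaptic-potential channels
#' y0..y4 with derivatives y5..y9. Channel i obeys
#' \eqn{\dot y_i = y_{i+5}}, \eqn{\dot y_{i+5} = K k u - 2 k y_{i+5} - k^2 y_i}
#' with gain/rate pairs (A,a) for the pyramidal output (input S(y1-y2-y3))
#' and the excitatory feedback (input p(t) + C2 S(C1 y0)), (B,b) for slow
#' inhibition (input C4 S(C3 y0)) and for the slow-onto-fast channel
#' (input S(C3 y0)), and (G,g) for fast inhibition
#' (input C7 S(C5 y0 - C6 y4)). Model output is y1 - y2 - y3.
#'
#' This R implementation is the readable reference; simulation uses an
#' equivalent compiled Euler stepper.
#'
#' @param state Numeric vector of length 10 (y0..y9).
#' @param p_t Instantaneous noise drive (1/s).
#' @param params A `wendling_params` object.
#' @return Numeric vector of length 10: d(state)/dt.
#' @export
wendling_derivatives <- function(state, p_t, params) {
  if (any(!is.finite(state)))
    stop("non-finite model state: numerical divergence")
  y <- state
  S <- function(v) wendling_sigmoid(v, params)
  with(params, {
    c(y[6], y[7], y[8], y[9], y[10],
      A * a * S(y[2] - y[3] - y[4]) - 2 * a * y[6] - a^2 * y[1],
      A * a * (p_t + C2 * S(C1 * y[1])) - 2 * a * y[7] - a^2 * y[2],
      B * b * C4 * S(C3 * y[1]) - 2 * b * y[8] - b^2 * y[3],
      G * g * C7 * S(C5 * y[1] - C6 * y[5]) - 2 * g * y[9] - g^2 * y[4],
      B * b * S(C3 * y[1]) - 2 * b * y[10] - b^2 * y[5])
  })
}

#' Simulate one labeled segment of model output
#'
#' Integrates the Wendling model with fixed-step Euler, drawing one Gaussian
#' noise value p(t) per integration step, discards a `burn_in` transient
#' from an all-zero initial state, and returns the output y1 - y2 - y3
#' sampled at `fs`.
#'
#' By default the integration grid equals the output grid (`fs_int = fs`,
#' one noise draw per output sample), the discrete implementation under
#' which the four state configurations express their characteristic
#' signatures; dt = 1/512 is well inside the Euler stability bound 2/g.
#' Because the noise is an input firing rate (not a Wiener increment) its
#' variance is not rescaled with the step, so a finer `fs_int` lowers the
#' effective noise density and visibly weakens the noise-driven fast rhythm
#' of the onset state.
#'
#' @param params A `wendling_params` object (typically one of
#'   [wendling_state_configs()]).
#' @param duration Segment duration in seconds.
#' @param fs Output sampling rate (Hz).
#' @param seed Optional integer seed (reproducibility of the noise path).
#' @param fs_int Internal integration rate (Hz); must be an integer
#'   multiple of `fs`; the output is decimated from it.
#' @param burn_in Transient discarded before the retained window (s).
#' @return An `eeg_segment`: list with `samples`, `fs`, `true_label`
#'   (taken from the config's `label` attribute, or NA).
#' @examples
#' cfg <- wendling_state_configs()
#' seg <- simulate_wendling(cfg$ictal, duration = 2, seed = 1)
#' length(seg$samples) # 2 * 512
#' @export
simulate_wendling <- function(params, duration = 5, fs = 512, seed = NULL,
                              fs_int = fs, burn_in = 2) {
  stopifnot(duration > 0, fs > 0, fs_int >= fs)
  dec <- fs_int / fs
  if (abs(dec - round(dec)) > 1e-9)
    stop("fs_int must be an integer multiple of fs")
  dec <- as.integer(round(dec))
  if (!is.null(seed)) set.seed(seed)
  n_out <- round(duration * fs)
  n_steps <- n_out * dec + round(burn_in * fs_int)
  y <- wendling_euler(n_steps, 1 / fs_int, numeric(10), unclass(params))
  kept <- y[(round(burn_in * fs_int) + 1):n_steps]
  samples <- kept[seq(dec, length(kept), by = dec)]
  new_segment(samples, fs, true_label = attr(params, "label") %||% NA_integer_)
}

#' Simulate a labeled set of segments for all four brain states
#'
#' Generates `n_per_type` independent five-second realizations per canonical
#' state configuration (4 * n_per_type segments in total), each carrying its
#' generating label. Per-segment seeds are derived deterministically from
#' the master seed (master + running segment index), so the set is
#' reproducible and segments are mutually independent noise realizations.
#'
#' @param n_per_type Segments per brain state.
#' @param duration,fs,fs_int,burn_in Passed to [simulate_wendling()].
#' @param seed Master seed.
#' @return A `segment_set`: list of `eeg_segment`s with a `labels`
#'   attribute (integer vector).
#' @examples
#' ss <- simulate_type_set(2, duration = 1, seed = 7)
#' segment_labels(ss) # 1 1 2 2 3 3 4 4
#' @export
simulate_type_set <- function(n_per_type = 100, duration = 5, fs = 512,
                              seed = 1, fs_int = fs, burn_in = 2) {
  stopifnot(n_per_type >= 1)
  cfgs <- wendling_state_configs()
  segs <- vector("list", 4L * n_per_type)
  idx <- 0L
  for (cfg in cfgs) {
    for (i in seq_len(n_per_type)) {
      idx <- idx + 1L
      segs[[idx]] <- simulate_wendling(cfg, duration = duration, fs = fs,
                                       seed = seed + idx, fs_int = fs_int,
                                       burn_in = burn_in)
    }
  }
  structure(segs, class = "segment_set",
            labels = vapply(segs, function(s) s$true_label, integer(1)))
}

new_segment <- function(samples, fs, true_label = NA_integer_) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 true_label = as.integer(true_label)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  lab <- if (is.na(x$true_label)) "unlabeled"
         else names(brain_state_labels())[x$true_label]
  cat(sprintf("<eeg_segment> %d samples @ %g Hz (%.2f s), %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, lab))
  invisible(x)
}

#' @export
print.segment_set <- function(x, ...) {
  labs <- attr(x, "labels")
  cat(sprintf("<segment_set> %d segments @ %g Hz\n", length(x), x[[1]]$fs))
  if (!all(is.na(labs)))
    print(table(factor(labs, levels = 1:4,
                       labels = names(brain_state_labels()))))
  invisible(x)
}

#' Labels of a segment set
#' @param x A `segment_set`.
#' @return Integer vector of true labels (NA where unlabeled).
#' @export
segment_labels <- function(x) attr(x, "labels")

`%||%` <- function(a, b) if (is.null(a)) b else a
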