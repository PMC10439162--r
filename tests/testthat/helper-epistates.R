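# Shared fixtures (built in code, cached per test run) and independent
# brute-force oracles used across the suite.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# A small labeled segment set: 12 segments per state, full study settings
# otherwise (5 s at 512 Hz).
small_type_set <- function() {
  cached("small_type_set", simulate_type_set(12, duration = 5, seed = 101))
}

# One full-scale self-classification run (100 segments per state) per
# seed, as in the model self-classification experiment.
selfclass_run <- function(seed) {
  cached(paste0("selfclass_", seed), {
    ss <- simulate_type_set(100, duration = 5, seed = seed)
    proto <- fit_prototypes(ss, seed = seed)
    pred <- predict(proto, ss)
    list(segments = ss, prototypes = proto, predictions = pred,
         report = evaluate_predictions(pred))
  })
}

# --- independent oracles -------------------------------------------------

# Nearest centroid by exhaustive distance enumeration.
oracle_nearest <- function(points, centroids) {
  apply(points, 1, function(p) {
    which.min(apply(centroids, 1, function(c) sqrt(sum((p - c)^2))))
  })
}

# Tukey outlier count from first principles: type-7 quantiles computed by
# the interpolation formula, then fence comparison.
oracle_tukey_count <- function(x) {
  q7 <- function(p) {
    xs <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75); iqr <- q3 - q1
  sum(x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr)
}

# Transition-probability estimate by explicit pair counting.
oracle_transitions <- function(labels) {
  tm <- matrix(0, 4, 4)
  for (i in 1:4) {
    idx <- which(labels[-length(labels)] == i)
    if (length(idx) == 0) next
    for (j in 1:4) tm[i, j] <- sum(labels[idx + 1] == j) / length(idx)
  }
  tm
}

# Fixed point of the zero-noise model by direct iteration of the
# equilibrium relations y_i = (K_i / k_i) * input_i.
oracle_fixed_point <- function(params, p_drive, iter = 5000) {
  p <- params
  y <- numeric(5)
  S <- function(v) wendling_sigmoid(v, p)
  for (it in seq_len(iter)) {
    y_new <- c(
      (p$A / p$a) * S(y[2] - y[3] - y[4]),
      (p$A / p$a) * (p_drive + p$C2 * S(p$C1 * y[1])),
      (p$B / p$b) * p$C4 * S(p$C3 * y[1]),
      (p$G / p$g) * p$C7 * S(p$C5 * y[1] - p$C6 * y[5]),
      (p$B / p$b) * S(p$C3 * y[1]))
    y <- y + 0.2 * (y_new - y)
  }
  y
}
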