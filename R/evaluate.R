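#' Confusion matrix of predicted versus true brain states
#'
#' @param true,predicted Integer label vectors (values 1--4) of equal
#'   length.
#' @return 4 x 4 integer matrix, rows = true type, columns = predicted.
#' @examples
#' confusion_matrix(c(1, 1, 4), c(1, 4, 4))
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("label sequences differ in length")
  if (!all(true %in% 1:4) || !all(predicted %in% 1:4))
    stop("labels must be integers in 1..4")
  cm <- matrix(tabulate(4L * (true - 1L) + predicted, nbins = 16L),
               nrow = 4, byrow = TRUE,
               dimnames = list(true = names(brain_state_labels()),
                               predicted = names(brain_state_labels())))
  cm
}

#' Per-type and type-averaged sensitivity and PPV
#'
#' Per type t, sensitivity = cm[t,t] / row sum (TP / (TP + FN)) and
#' PPV = cm[t,t] / column sum (TP / (TP + FP)); a value is undefined (NA)
#' when its denominator is zero. Type averages are taken over defined
#' types only, so a type absent from the truth does not enter the
#' sensitivity average, while a type that is predicted but never true
#' contributes a PPV of 0 (penalizing false alarms).
#'
#' @param cm A 4 x 4 confusion matrix from [confusion_matrix()].
#' @return A `performance_report`: list with `per_type_sensitivity`,
#'   `per_type_ppv`, `mean_sensitivity`, `mean_ppv`, `n_segments`,
#'   `types_present`, and the confusion matrix.
#' @export
sensitivity_ppv <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 4), all(cm >= 0))
  rs <- rowSums(cm); cs <- colSums(cm)
  if (all(rs == 0)) stop("empty confusion matrix")
  sens <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  ppv <- ifelse(cs > 0, diag(cm) / cs, NA_real_)
  structure(list(per_type_sensitivity = sens,
                 per_type_ppv = ppv,
                 mean_sensitivity = mean(sens, na.rm = TRUE),
                 mean_ppv = mean(ppv, na.rm = TRUE),
                 n_segments = sum(cm),
                 types_present = which(rs > 0),
                 confusion = cm),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Brain-state classification performance\n")
  tab <- rbind(sensitivity = x$per_type_sensitivity,
               ppv = x$per_type_ppv)
  print(round(tab, 3))
  cat(sprintf("mean sensitivity %.3f | mean PPV %.3f | %d segments\n",
              x$mean_sensitivity, x$mean_ppv, x$n_segments))
  if (!is.null(x$p_sensitivity))
    cat(sprintf("surrogate p: sensitivity %.4g, PPV %.4g (%d surrogates)\n",
                x$p_sensitivity, x$p_ppv, x$n_surrogates))
  invisible(x)
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: confusion matrix plus [sensitivity_ppv()], with an
#' optional Markov-chain surrogate test attached.
#'
#' @param pred A `state_predictions` data.frame (or integer vector of
#'   predicted labels).
#' @param true True labels; taken from `pred$true_label` when omitted.
#' @param surrogates Number of Markov-chain surrogates (0 = no test).
#' @param seed Seed for surrogate generation.
#' @return A `performance_report`, with fields `p_sensitivity`, `p_ppv`,
#'   `n_surrogates` when surrogate testing was requested.
#' @export
evaluate_predictions <- function(pred, true = NULL, surrogates = 0,
                                 seed = 1) {
  predicted <- if (is.data.frame(pred)) pred$predicted_label else pred
  if (is.null(true)) {
    stopifnot(is.data.frame(pred))
    true <- pred$true_label
  }
  if (any(is.na(true))) stop("true labels contain NA")
  rep <- sensitivity_ppv(confusion_matrix(true, predicted))
  if (surrogates > 0) {
    st <- surrogate_test(true, rep, n = surrogates, seed = seed)
    rep$p_sensitivity <- st$sensitivity$p_value
    rep$p_ppv <- st$ppv$p_value
    rep$n_surrogates <- surrogates
    rep$surrogate <- st
  }
  rep
}

#' Estimate a Markov transition matrix from a label sequence
#'
#' Maximum-likelihood estimate: probs[i, j] = count(i -> j) / count(i -> .)
#' for every visited source state. A state that appears only as the final
#' observation (or a constant single-label sequence) gets a self-transition
#' of 1; such rows are flagged in the `unvisited` attribute.
#'
#' @param true Integer label sequence (values 1--4), length >= 2.
#' @return 4 x 4 row-stochastic matrix with attribute `unvisited` (logical
#'   per row: TRUE where no outgoing transition was observed).
#' @examples
#' estimate_transitions(c(1, 1, 2, 2))
#' @export
estimate_transitions <- function(true) {
  stopifnot(length(true) >= 2, all(true %in% 1:4))
  counts <- matrix(0, 4, 4)
  from <- true[-length(true)]; to <- true[-1]
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  rs <- rowSums(counts)
  present <- sort(unique(true))
  unvisited <- rs == 0
  probs <- counts / ifelse(rs > 0, rs, 1)
  for (i in which(unvisited & seq_len(4) %in% present))
    probs[i, i] <- 1  # state seen only as a final observation
  dimnames(probs) <- list(from = names(brain_state_labels()),
                          to = names(brain_state_labels()))
  attr(probs, "unvisited") <- unvisited
  probs
}

# Stationary distribution of a transition matrix restricted to the states
# that actually occur; falls back to the empirical frequency when the
# eigen problem is degenerate.
stationary_distribution <- function(tm, states) {
  sub <- tm[states, states, drop = FALSE]
  ev <- eigen(t(sub))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  if (all(abs(v) < 1e-12) || any(!is.finite(v))) v <- rep(1, length(states))
  v <- abs(v) / sum(abs(v))
  p <- numeric(4); p[states] <- v
  p
}

#' Simulate a label sequence from a Markov chain
#'
#' @param tm 4 x 4 transition matrix ([estimate_transitions()] output or a
#'   hand-built row-stochastic matrix).
#' @param n Sequence length.
#' @param init Initial-state distribution over 1..4; default: stationary
#'   distribution of the chain restricted to states with outgoing mass.
#' @return Integer label sequence of length n.
#' @export
simulate_markov <- function(tm, n, init = NULL) {
  stopifnot(n >= 1)
  states <- which(rowSums(tm) > 0)
  if (is.null(init)) init <- stationary_distribution(tm, states)
  out <- integer(n)
  out[1] <- sample.int(4, 1, prob = init)
  for (t in seq_len(n - 1)) {
    p <- tm[out[t], ]
    if (sum(p) <= 0) p <- init  # defensive: dead-end row
    out[t + 1] <- sample.int(4, 1, prob = p)
  }
  out
}

#' Markov-chain surrogate test of classification performance
#'
#' Generates `n` surrogate label sequences of the same length as the true
#' sequence from the data-specific transition matrix, scores each
#' surrogate against the true labels, and reports, per metric, the
#' fraction of realizations (all surrogates plus the single original) that
#' achieved the same or a higher value than the observed one. The p-value
#' is therefore (#\{surrogate >= observed\} + 1) / (n + 1) and lies in
#' (0, 1].
#'
#' @param true Integer true-label sequence.
#' @param observed A `performance_report` for the real predictions.
#' @param tm Transition matrix; estimated from `true` when NULL.
#' @param n Number of surrogates.
#' @param seed Seed for surrogate generation.
#' @return List with elements `sensitivity` and `ppv`, each a
#'   `surrogate_test_result`: `observed_metric`, `surrogate_metrics`,
#'   `p_value`, plus the `init` distribution used.
#' @export
surrogate_test <- function(true, observed, tm = NULL, n = 1000, seed = 1) {
  stopifnot(n >= 1, inherits(observed, "performance_report"))
  if (is.null(tm)) tm <- estimate_transitions(true)
  set.seed(seed)
  init <- stationary_distribution(tm, which(rowSums(tm) > 0))
  sens <- numeric(n); ppv <- numeric(n)
  for (i in seq_len(n)) {
    surr <- simulate_markov(tm, length(true), init = init)
    r <- sensitivity_ppv(confusion_matrix(true, surr))
    sens[i] <- r$mean_sensitivity
    ppv[i] <- r$mean_ppv
  }
  mk <- function(obs, surr) {
    structure(list(observed_metric = obs, surrogate_metrics = surr,
                   p_value = (sum(surr >= obs) + 1) / (n + 1),
                   init = init),
              class = "surrogate_test_result")
  }
  list(sensitivity = mk(observed$mean_sensitivity, sens),
       ppv = mk(observed$mean_ppv, ppv))
}

#' Group-level surrogate test across individuals
#'
#' One surrogate chain is drawn per individual per realization; the group
#' statistic is the unweighted mean of the individuals' type-averaged
#' metrics, and the p-value counts realizations (surrogates plus the
#' original) with a group mean at least as high as observed.
#'
#' @param truths List of true-label sequences, one per individual.
#' @param reports List of `performance_report`s, aligned with `truths`.
#' @param n Number of surrogate realizations.
#' @param seed Seed.
#' @return As [surrogate_test()], for the group means.
#' @export
group_surrogate_test <- function(truths, reports, n = 1000, seed = 1) {
  stopifnot(length(truths) >= 1, length(truths) == length(reports))
  tms <- lapply(truths, estimate_transitions)
  inits <- lapply(tms, function(tm)
    stationary_distribution(tm, which(rowSums(tm) > 0)))
  set.seed(seed)
  m <- length(truths)
  sens <- matrix(0, n, m); ppv <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      surr <- simulate_markov(tms[[j]], length(truths[[j]]),
                              init = inits[[j]])
      r <- sensitivity_ppv(confusion_matrix(truths[[j]], surr))
      sens[i, j] <- r$mean_sensitivity
      ppv[i, j] <- r$mean_ppv
    }
  }
  obs_sens <- mean(vapply(reports, `[[`, numeric(1), "mean_sensitivity"))
  obs_ppv <- mean(vapply(reports, `[[`, numeric(1), "mean_ppv"))
  mk <- function(obs, surr) {
    structure(list(observed_metric = obs, surrogate_metrics = surr,
                   p_value = (sum(surr >= obs) + 1) / (n + 1)),
              class = "surrogate_test_result")
  }
  list(sensitivity = mk(obs_sens, rowMeans(sens)),
       ppv = mk(obs_ppv, rowMeans(ppv)))
}

#' @export
print.surrogate_test_result <- function(x, ...) {
  cat(sprintf(
    "surrogate test: observed %.4f vs %d surrogates (mean %.4f), p = %.4g\n",
    x$observed_metric, length(x$surrogate_metrics),
    mean(x$surrogate_metrics), x$p_value))
  invisible(x)
}
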