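test_that("confusion matrix counts true/predicted pairs exactly", {
  cm <- confusion_matrix(c(1, 1, 4), c(1, 4, 4))
  expect_equal(cm[1, 1], 1); expect_equal(cm[1, 4], 1)
  expect_equal(cm[4, 4], 1); expect_equal(sum(cm), 3)
  ident <- confusion_matrix(c(2, 3, 3, 1), c(2, 3, 3, 1))
  expect_equal(ident, diag(c(1, 1, 2, 0)), ignore_attr = TRUE)
  set.seed(14)
  true <- sample(1:4, 200, replace = TRUE)
  pred <- sample(1:4, 200, replace = TRUE)
  perm <- sample(200)
  expect_equal(confusion_matrix(true[perm], pred[perm]),
               confusion_matrix(true, pred))
  expect_error(confusion_matrix(1:3, 1:4), "length")
  expect_error(confusion_matrix(c(1, 5), c(1, 1)), "1..4")
})

test_that("sensitivity and PPV follow their defining ratios", {
  cm <- matrix(0, 4, 4); cm[1, 1] <- 3; cm[1, 2] <- 1
  r <- sensitivity_ppv(cm)
  expect_equal(unname(r$per_type_sensitivity[1]), 0.75)  # TP 3, FN 1
  expect_equal(unname(r$per_type_ppv[1]), 1)
  expect_true(is.na(r$per_type_sensitivity[3]))  # type never true
  perfect <- sensitivity_ppv(diag(c(5, 5, 5, 5)))
  expect_equal(unname(perfect$per_type_sensitivity), rep(1, 4))
  expect_equal(unname(perfect$per_type_ppv), rep(1, 4))
  expect_equal(perfect$mean_sensitivity, 1)
  expect_error(sensitivity_ppv(matrix(0, 4, 4)), "empty")
})

test_that("absent types leave the average; false alarms drag PPV to zero", {
  # no onset (type 3) in the truth, but it is sometimes predicted
  cm <- matrix(0, 4, 4)
  cm[1, 1] <- 8; cm[2, 2] <- 6; cm[4, 4] <- 7; cm[1, 3] <- 4
  r <- sensitivity_ppv(cm)
  expect_equal(r$types_present, c(1, 2, 4), ignore_attr = TRUE)
  expect_true(is.na(r$per_type_sensitivity[3]))
  expect_equal(unname(r$per_type_ppv[3]), 0)  # predicted but never true
  expect_equal(r$mean_sensitivity,
               mean(c(8 / 12, 1, 1)))
  expect_equal(r$mean_ppv, mean(c(1, 1, 0, 1)))
})

test_that("random predictions on balanced labels hit the 25% chance level", {
  set.seed(15)
  true <- rep(1:4, each = 100)
  sens <- replicate(40, {
    pred <- sample(1:4, 400, replace = TRUE)
    sensitivity_ppv(confusion_matrix(true, pred))$mean_sensitivity
  })
  expect_equal(mean(sens), 0.25, tolerance = 0.02)
})

test_that("transition estimation matches hand counts and handles edges", {
  tm <- estimate_transitions(c(1, 1, 2, 2))
  expect_equal(tm[1, 1], 0.5); expect_equal(tm[1, 2], 0.5)
  expect_equal(tm[2, 2], 1)
  set.seed(16)
  labs <- sample(1:4, 300, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  est <- estimate_transitions(labs)
  expect_equal(unclass(est), oracle_transitions(labs), ignore_attr = TRUE)
  visited <- rowSums(est) > 0
  expect_equal(unname(rowSums(est)[visited]), rep(1, sum(visited)))
  # constant sequence: self-transition 1, flagged
  const <- estimate_transitions(c(2, 2, 2))
  expect_equal(const[2, 2], 1)
  # a state seen only as the final observation gets a self-loop
  tail_only <- estimate_transitions(c(1, 1, 3))
  expect_equal(tail_only[3, 3], 1)
  expect_true(attr(tail_only, "unvisited")[3])
  expect_error(estimate_transitions(1L))
})

test_that("balanced label sequences estimate a near-uniform chain", {
  # the simulated dataset has equal amounts of every type; in a randomly
  # ordered balanced sequence every transition is equally likely
  set.seed(17)
  shuffled <- sample(rep(1:4, each = 100))
  tm_shuffled <- estimate_transitions(shuffled)
  expect_lt(max(abs(tm_shuffled - 0.25)), 0.12)
  expect_equal(unname(rowSums(tm_shuffled)), rep(1, 4), tolerance = 1e-12)
})

test_that("markov surrogates reproduce chain statistics", {
  tm <- matrix(0.25, 4, 4)
  set.seed(18)
  seqs <- simulate_markov(tm, 4000)
  expect_equal(unname(tabulate(seqs, 4) / 4000), rep(0.25, 4),
               tolerance = 0.05)
  # absorbing chain stays put
  absorbing <- diag(4)
  s <- simulate_markov(absorbing, 50, init = c(0, 0, 1, 0))
  expect_equal(s, rep(3L, 50))
})

test_that("surrogate p-values implement the counting definition", {
  true <- rep(1:4, times = 30)
  # perfect predictions: no uniform-chain surrogate of length 120 reaches
  # sensitivity 1, so p attains its floor 1/(n+1)
  perfect <- sensitivity_ppv(confusion_matrix(true, true))
  st <- surrogate_test(true, perfect, tm = matrix(0.25, 4, 4), n = 400,
                       seed = 19)
  expect_equal(st$sensitivity$p_value, 1 / 401)
  expect_equal(st$ppv$p_value, 1 / 401)
  expect_length(st$sensitivity$surrogate_metrics, 400)
  # an always-wrong classifier scores 0: every realization ties or beats it
  wrong <- sensitivity_ppv(confusion_matrix(true, (true %% 4) + 1))
  expect_equal(wrong$mean_sensitivity, 0)
  st0 <- surrogate_test(true, wrong, tm = matrix(0.25, 4, 4), n = 100,
                        seed = 19)
  expect_equal(st0$sensitivity$p_value, 1)
})

test_that("surrogate sensitivity concentrates at chance on balanced data", {
  true <- rep(1:4, each = 100)
  obs <- sensitivity_ppv(confusion_matrix(true, true))
  st <- surrogate_test(true, obs, tm = matrix(0.25, 4, 4), n = 300,
                       seed = 20)
  expect_lt(abs(mean(st$sensitivity$surrogate_metrics) - 0.25), 0.02)
  expect_lt(max(abs(st$sensitivity$surrogate_metrics - 0.25)), 0.15)
})

test_that("p-values shrink as the observed metric grows, draws fixed", {
  true <- rep(1:4, times = 25)
  obs_template <- sensitivity_ppv(confusion_matrix(true, true))
  ps <- vapply(c(0.1, 0.25, 0.4, 0.8), function(m) {
    obs <- obs_template; obs$mean_sensitivity <- m; obs$mean_ppv <- m
    surrogate_test(true, obs, tm = matrix(0.25, 4, 4), n = 200,
                   seed = 21)$sensitivity$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("a single-individual group test equals the individual test", {
  true <- rep(1:4, times = 25)
  obs <- sensitivity_ppv(confusion_matrix(true, true))
  single <- surrogate_test(true, obs, n = 150, seed = 22)
  grp <- group_surrogate_test(list(true), list(obs), n = 150, seed = 22)
  expect_equal(grp$sensitivity$p_value, single$sensitivity$p_value)
  expect_equal(grp$sensitivity$surrogate_metrics,
               single$sensitivity$surrogate_metrics)
  # group statistic is the unweighted mean of individual metrics
  obs2 <- obs; obs2$mean_sensitivity <- 0.5
  grp2 <- group_surrogate_test(list(true, true), list(obs, obs2),
                               n = 50, seed = 22)
  expect_equal(grp2$sensitivity$observed_metric,
               mean(c(obs$mean_sensitivity, 0.5)))
})

test_that("evaluate_predictions wires predictions to the report", {
  run <- selfclass_run(1)
  rep <- evaluate_predictions(run$predictions, surrogates = 100, seed = 23)
  expect_s3_class(rep, "performance_report")
  expect_equal(rep$n_segments, 400)
  expect_lt(rep$p_sensitivity, 0.05)
  expect_error(evaluate_predictions(data.frame(
    predicted_label = 1L, true_label = NA_integer_, segment_index = 1L)),
    "NA")
})
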