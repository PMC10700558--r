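test_that("the binomial chance bound reproduces the 56.5% rule", {
  expect_equal(round(binomial_exclusion_threshold(240, 0.05), 1), 56.5)

  # brute-force exact binomial tail oracle: smallest success count whose
  # upper tail probability drops below alpha/2
  k <- min(which(pbinom(0:240 - 1, 240, 0.5, lower.tail = FALSE) < 0.025)) - 1
  expect_lt(abs(binomial_exclusion_threshold(240, 0.05) - 100 * k / 240), 0.3)

  # limit: the bound approaches chance as n grows
  expect_lt(binomial_exclusion_threshold(1e8), 50.01)
  expect_error(binomial_exclusion_threshold(0), ">=")
})

test_that("exclusion rules drop guessers, drop lapses, flag RT outliers", {
  set.seed(41)
  d <- generate_experiment_design("II")
  good <- simulate_agent(d, model_params(4.4, NULL, 0, model = "M0"),
                         lapse = 0.01)
  good$participant_id <- "good"
  # guessing participant: 55% context accuracy by construction
  bad <- good
  bad$participant_id <- "bad"
  ctx <- which(bad$block_type == "context" & bad$f1_hz != bad$f2_hz)
  n_ok <- round(0.55 * length(ctx))
  corr_choice <- ifelse(bad$f2_hz > bad$f1_hz, "second_higher", "first_higher")
  wrong_choice <- ifelse(bad$f2_hz > bad$f1_hz, "first_higher", "second_higher")
  bad$choice[ctx] <- c(corr_choice[ctx[1:n_ok]],
                       wrong_choice[ctx[(n_ok + 1):length(ctx)]])
  bad$choice[bad$block_type == "toe"] <- "first_higher"
  bad$correct <- NULL; bad$correct <- NA
  bad$correct <- with(bad, ifelse(f1_hz == f2_hz | choice == "none", NA,
    (f2_hz > f1_hz & choice == "second_higher") |
      (f2_hz < f1_hz & choice == "first_higher")))
  ex <- apply_exclusions(rbind(good, bad))
  expect_equal(ex$report$excluded_participants, "bad")
  expect_false("bad" %in% ex$trials$participant_id)
  expect_equal(sum(ex$trials$choice == "none"), 0L)
  expect_equal(ex$report$n_unanswered_dropped, sum(good$choice == "none"))
  # catch trials are kept but not scored for fitting
  expect_true(any(ex$trials$f1_hz == ex$trials$f2_hz))
  expect_false(any(ex$trials$include[ex$trials$f1_hz == ex$trials$f2_hz]))
})

test_that("RT outlier flags are per participant and per fitted segment", {
  d <- generate_experiment_design("II", seed = 43)
  a <- simulate_agent(d, model_params(4.4, NULL, 0, model = "M0"), lapse = 0)
  a$participant_id <- "p1"
  # all RTs identical: zero outliers
  a$rt_ms <- 800
  expect_equal(apply_exclusions(a)$report$n_rt_outliers_flagged, 0L)
  # one extreme RT in the 3-5 segment is the only flagged trial
  set.seed(44)
  a$rt_ms <- rep(c(780, 800, 820), length.out = nrow(a))
  i <- which(a$block == 4)[10]
  seg <- a$block >= 3
  a$rt_ms[i] <- mean(a$rt_ms[seg]) + 6 * sd(a$rt_ms[seg])
  ex <- apply_exclusions(a)
  expect_equal(ex$report$n_rt_outliers_flagged, 1L)
  expect_true(ex$trials$rt_outlier[ex$trials$trial_index == a$trial_index[i]])
})

test_that("the TOE index folds accuracy biases around the range mean", {
  # identical accuracy in both directions: index 0
  f1 <- c(25, 27, 29, 31, 33, 35)
  flat <- make_toe_accuracy_table(f1, rep(0.7, 6), rep(0.7, 6))
  expect_equal(compute_itoe(flat)$i_toe, 0)

  # hand-computed toy: folded mean bias 0.2333, overall accuracy 0.7
  toy <- make_toe_accuracy_table(f1,
    acc_up = c(0.5, 0.6, 0.65, 0.75, 0.8, 0.9),
    acc_dn = c(0.9, 0.8, 0.75, 0.65, 0.6, 0.5))
  res <- compute_itoe(toy)
  expect_equal(res$i_toe, 100 * (0.2333333 / 0.7), tolerance = 1e-5)
  expect_equal(res$i_toe_low, res$i_toe_high, tolerance = 1e-9)
  expect_equal(res$overall_accuracy, 0.7)
  expect_equal(res$bias$bias, c(-0.4, -0.2, -0.1, 0.1, 0.2, 0.4))

  # invariant to response-button relabeling: the index depends only on
  # correctness, not on which physical response encoded it
  relab <- toy
  relab$choice <- ifelse(relab$choice == "first_higher",
                         "second_higher", "first_higher")
  expect_equal(compute_itoe(relab)$i_toe, res$i_toe)

  expect_error(compute_itoe(toy[toy$f2_hz > toy$f1_hz, ]), "missing")
})

test_that("a static observer shows no TOE beyond a shuffled null", {
  set.seed(45)
  blocks <- do.call(rbind, lapply(1:10, function(i) generate_toe_block("II")))
  a <- simulate_agent(blocks, model_params(4.4, NULL, 0, model = "M0"),
                      lapse = 0)
  pt <- itoe_permutation_test(a)
  expect_lt(abs(pt$observed), quantile(abs(pt$null), 0.95) + 1e-9)
  expect_gt(pt$p_value, 0.05)
})

test_that("the TOE index grows as the precision ratio shrinks", {
  set.seed(46)
  mean_itoe <- function(logr) mean(replicate(50, {
    blocks <- do.call(rbind, lapply(1:2, function(i) generate_toe_block("II")))
    p <- model_params(4.4, setNames(logr, "4"), 0)
    a <- simulate_agent(blocks, p, lapse = 0)
    compute_itoe(a)$i_toe
  }))
  itoes <- sapply(c(1, 0, -1, -2), mean_itoe)
  expect_true(all(diff(itoes) > 0))
})

test_that("the accuracy-curve intercept comes from a robust bias regression", {
  f1 <- c(25, 27, 29, 31, 33, 35)
  # bias exactly 0.1 * (F1 - 30): curves cross at 30 Hz
  toy <- make_toe_accuracy_table(f1,
    acc_up = 0.7 + 0.05 * (f1 - 30), acc_dn = 0.7 - 0.05 * (f1 - 30))
  ti <- toe_intercept(toy)
  expect_true(ti$valid)
  expect_equal(ti$intercept_hz, 30, tolerance = 1e-6)

  # noise-free linear bias: Huber fit equals ordinary least squares
  res <- compute_itoe(toy)
  ols <- lm(bias ~ f1_hz, data = res$bias)
  expect_equal(ti$slope, unname(coef(ols)[2]), tolerance = 1e-6)

  # constant nonzero bias: flat, invalid
  const <- make_toe_accuracy_table(f1, rep(0.8, 6), rep(0.6, 6))
  expect_false(toe_intercept(const)$valid)

  # crossing outside the presented range (bias zero at 41 Hz): invalid
  shifted <- make_toe_accuracy_table(f1,
    acc_up = 0.5 + 0.025 * (f1 - 41), acc_dn = 0.5 - 0.025 * (f1 - 41))
  ts <- toe_intercept(shifted)
  expect_false(ts$valid)
  expect_true(is.na(ts$intercept_hz))
  expect_equal(ts$crossing_hz, 41, tolerance = 1e-6)
})

test_that("psychometric threshold inverts the logit at 75% accuracy", {
  # large simulated sample from a symmetric logistic with slope log(3)/3
  set.seed(47)
  df <- rep(-8:8, each = 400)
  p2 <- plogis(log(3) / 3 * df)
  t <- make_trials(rep(30, length(df)), 30 + df,
                   ifelse(runif(length(df)) < p2, "second_higher",
                          "first_higher"),
                   block = 1, block_type = "context")
  fit <- psychometric_threshold(t)
  expect_equal(fit$threshold_hz_75, 3, tolerance = 0.15)
  expect_equal(fit$threshold_hz_75, log(3) / fit$slope)

  # step responder: separation, threshold clamped to 0
  ts <- make_trials(rep(30, 100), 30 + rep(c(-4, 4), 50),
                    rep(c("first_higher", "second_higher"), 50),
                    block = 1, block_type = "context")
  expect_warning(fs <- psychometric_threshold(ts), "separation")
  expect_equal(fs$threshold_hz_75, 0)

  # simulated static observer in the group-typical precision range
  set.seed(48)
  d <- do.call(rbind, lapply(1:3, function(b) {
    set.seed(48 + b); generate_context_block("II", b)
  }))
  a <- simulate_agent(d, model_params(4.4, NULL, 0, model = "M0"), lapse = 0)
  thr <- psychometric_threshold(a)$threshold_hz_75
  expect_gt(thr, 2); expect_lt(thr, 5)
})

test_that("d-prime uses the log-linear rate correction", {
  mk <- function(n_hit, n_sig, n_fa, n_noise) {
    rbind(make_trials(rep(30, n_sig), rep(34, n_sig),
                      c(rep("second_higher", n_hit),
                        rep("first_higher", n_sig - n_hit))),
          make_trials(rep(30, n_noise), rep(26, n_noise),
                      c(rep("second_higher", n_fa),
                        rep("first_higher", n_noise - n_fa))))
  }
  r0 <- d_prime(mk(500, 1000, 500, 1000))
  expect_equal(r0$d_prime, 0)
  r1 <- d_prime(mk(800, 1000, 200, 1000))
  expect_equal(r1$d_prime, qnorm(0.8) - qnorm(0.2), tolerance = 0.01)
  expect_equal(r1$d_prime, 1.683, tolerance = 0.01)
  # extreme rates stay finite
  r2 <- d_prime(mk(50, 50, 0, 50))
  expect_true(is.finite(r2$d_prime))
})

test_that("adaptation metrics summarize the four threshold measures", {
  m <- adaptation_metrics(list(detection = c(0.5, 0.5),
                               disappearance = c(0.58, 0.58)))
  expect_equal(m$adaptation_effect, 0.08)

  m2 <- adaptation_metrics(list(detection = c(0.6, 0.6),
                                disappearance = c(0.6, 0.6)))
  expect_equal(m2$intra_individual_sd, 0)
  expect_equal(unname(m2$dispersion_units["0"]), 4L)

  m3 <- adaptation_metrics(list(detection = c(0.5, 0.52),
                                disappearance = c(0.48, 0.5)))
  expect_equal(m3$intra_individual_sd, sd(c(0.5, 0.52, 0.48, 0.5)))
  expect_equal(m3$intra_individual_sd, 0.01633, tolerance = 1e-3)

  # dispersion bins partition the line: every measure in exactly one unit
  set.seed(49)
  for (i in 1:20) {
    x <- round(runif(4, 0, 1), 3)
    mm <- adaptation_metrics(list(detection = x[1:2], disappearance = x[3:4]))
    expect_equal(sum(mm$dispersion_units), 4L)
  }
  expect_error(adaptation_metrics(list(detection = 0.5,
                                       disappearance = c(0.5, 0.5))),
               "two")
})
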