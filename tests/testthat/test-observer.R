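test_that("belief update matches the explicit precision-tracking recursion", {
  # u equal to the current mean leaves the mean unchanged
  s <- belief_state(30, 0.5)
  expect_equal(belief_update(s, 30, 2.5)$mean, 30)

  # frozen expected values: pi_mu = 2*pi_u, pi_x = pi_u (r = 1) gives
  # pi_theta = (2/3) pi_u, tau' = 0.6
  s2 <- belief_update(s, 32, 1)
  expect_equal(s2$learning_rate, 0.6)
  expect_equal(s2$mean, 31.2)

  # same numbers from the independent precision oracle, arbitrary pi_u
  for (pi_u in c(0.5, 1, 7)) {
    o <- precision_oracle_update(30, pi_u / 0.5, 32, pi_u, pi_u / 1)
    expect_equal(s2$mean, o$mu, tolerance = 1e-12)
    expect_equal(s2$learning_rate, o$tau, tolerance = 1e-12)
  }

  # r -> 0 freezes the belief: iterating drives tau to 0
  s3 <- belief_state(30, 0.5)
  for (i in 1:200) s3 <- belief_update(s3, 35, 1e-12)
  expect_lt(s3$learning_rate, 0.01)

  expect_error(belief_update(s, Inf, 1), "finite")
})

test_that("limit learning rate is the fixed point of the recursion", {
  expect_equal(learning_rate_limit(0), 0)

  # iterated-recursion oracle at r = 1 (golden-ratio conjugate)
  tau <- 0.5
  repeat {
    t2 <- 1 - 1 / (1 + tau + 1)
    if (abs(t2 - tau) < 1e-14) break
    tau <- t2
  }
  expect_equal(learning_rate_limit(1), tau, tolerance = 1e-12)
  expect_equal(learning_rate_limit(1), (sqrt(5) - 1) / 2, tolerance = 1e-12)

  # asymptote for huge r
  expect_equal(learning_rate_limit(1e6), 1 - 1e-6, tolerance = 1e-5)

  # fixed-point agreement on a log grid, and strict monotonicity in r
  rs <- 10^seq(-2, 2, length.out = 25)
  lims <- learning_rate_limit(rs)
  for (i in seq_along(rs)) {
    tau <- 0.5
    for (k in 1:5000) tau <- 1 - 1 / (1 + tau + rs[i])
    expect_equal(lims[i], tau, tolerance = 1e-10)
  }
  expect_true(all(diff(lims) > 0))
  expect_error(learning_rate_limit(-1), "non-negative")
})

test_that("dynamic trial decision contracts the first stimulus to the prior", {
  p <- model_params(0, 0, 0)  # pi_u = 1, r = 1

  # symmetric trial: q = 1/2
  s <- belief_state(30, 0.618)
  expect_equal(trial_decision_dynamic(s, 30, 30, p)$comp$q, 0.5)

  # frozen stepwise evaluation at the learning-rate fixed point
  s <- belief_state(30, learning_rate_limit(1))
  out <- trial_decision_dynamic(s, 29, 31, p)
  expect_equal(out$comp$mu1, 29.38197, tolerance = 1e-5)
  expect_equal(out$comp$mu2, 30.38197, tolerance = 1e-5)
  expect_equal(out$comp$mu1 - out$comp$mu2, -1, tolerance = 1e-4)
  expect_equal(out$comp$alpha, 0.6360098, tolerance = 1e-6)
  expect_equal(out$comp$q, 0.1842055, tolerance = 1e-6)
  # the contraction halves the veridical -2 Hz contrast
  expect_gt(out$comp$mu1 - out$comp$mu2, -2)
  # post-trial state is the post-u2 belief
  expect_equal(out$state$mean, out$comp$mu2)

  # saturated bias forces the answer
  pb <- model_params(0, 0, 50)
  expect_equal(trial_decision_dynamic(s, 29, 31, pb)$comp$q, 1, tolerance = 1e-9)
})

test_that("static decision uses the veridical contrast (erf oracle)", {
  erf_quad <- function(x)  # independent quadrature evaluation of erf
    sign(x) * 2 / sqrt(pi) * integrate(function(t) exp(-t^2), 0, abs(x))$value
  p0 <- model_params(0, NULL, 0, model = "M0")
  expect_equal(trial_decision_static(30, 30, p0), 0.5)
  expect_equal(trial_decision_static(32, 30, p0),
               0.5 * (1 + erf_quad(1)), tolerance = 1e-8)
  expect_equal(trial_decision_static(32, 30, p0), 0.9213504, tolerance = 1e-6)
  pb <- model_params(0, NULL, -0.3, model = "M0")
  expect_equal(trial_decision_static(30, 30, pb),
               0.5 * (1 + erf_quad(-0.3)), tolerance = 1e-8)
  expect_equal(trial_decision_static(30, 30, pb), 0.3356866, tolerance = 1e-6)
})

test_that("closed-form contrast equals the sequential recursion", {
  set.seed(42)
  for (i in 1:1000) {
    s <- belief_state(runif(1, 20, 40), runif(1, 0.05, 1))
    r <- exp(runif(1, -4, 4))
    u1 <- runif(1, 20, 40); u2 <- runif(1, 20, 40)
    p <- model_params(runif(1, -2, 6), log(r), 0)
    seq_contrast <- with(trial_decision_dynamic(s, u1, u2, p)$comp, mu1 - mu2)
    expect_equal(contrast_closed_form(s, u1, u2, r), seq_contrast,
                 tolerance = 1e-10)
  }
})

test_that("q is monotone in bias and, for M0, in the stimulus contrast", {
  s <- belief_state(30, 0.6)
  qs <- sapply(seq(-2, 2, by = 0.25), function(b)
    trial_decision_dynamic(s, 29, 31, model_params(0, 0, b))$comp$q)
  expect_true(all(diff(qs) > 0))
  p0 <- model_params(1, NULL, 0, model = "M0")
  q0 <- sapply(seq(-4, 4, by = 0.5), function(d)
    trial_decision_static(30 + d, 30, p0))
  expect_true(all(diff(q0) > 0))
})

test_that("session log-likelihood follows the Bernoulli response model", {
  # single symmetric trial: ln(1/2)
  t1 <- make_trials(30, 30, "first_higher")
  p <- model_params(0, setNames(1, "4"), 0)
  ll <- session_loglik(t1, p, init = belief_state(1, 0.6))
  expect_equal(ll$loglik, log(0.5))

  # manual sum over a short M0 sequence
  p0 <- model_params(4.4, NULL, 0.2, model = "M0")
  tt <- make_trials(c(30, 30, 30), c(26, 34, 28),
                    c("first_higher", "second_higher", "second_higher"))
  q <- sapply(seq_len(3), function(i)
    trial_decision_static(tt$f1_hz[i] / 30, tt$f2_hz[i] / 30, p0))
  manual <- log(q[1]) + log(1 - q[2]) + log(1 - q[3])
  expect_equal(session_loglik(tt, p0)$loglik, manual, tolerance = 1e-12)

  # excluded trials drive beliefs but add no likelihood term
  tt$include <- c(TRUE, FALSE, TRUE)
  pm <- model_params(4.4, setNames(0, "4"), 0)
  full <- session_loglik(within(tt, include <- TRUE), pm)
  part <- session_loglik(tt, pm)
  expect_equal(part$q, full$q)          # identical belief trajectory
  expect_equal(part$n_included, 2L)
  expect_equal(part$loglik,
               log(pmin(pmax(full$q[1], 1e-9), 1 - 1e-9)) +
                 log(1 - pmin(pmax(full$q[3], 1e-9), 1 - 1e-9)))

  expect_error(session_loglik(tt[0, ], p0), "empty")
  bad <- tt; bad$choice[1] <- "up"
  expect_error(session_loglik(bad, p0), "choice")
})

test_that("M0 likelihood is order-invariant; M1 generally is not", {
  set.seed(7)
  d <- generate_toe_block("II", 4)
  p0 <- model_params(4.4, NULL, 0, model = "M0")
  a <- simulate_agent(d, model_params(4.4, setNames(-1, "4"), 0), lapse = 0)
  perm <- sample(nrow(a))
  expect_equal(session_loglik(a, p0)$loglik,
               session_loglik(a[perm, ], p0)$loglik, tolerance = 1e-10)
  pm <- model_params(4.4, setNames(-1, "4"), 0)
  expect_gt(abs(session_loglik(a, pm)$loglik -
                  session_loglik(a[perm, ], pm)$loglik), 1e-6)
})

test_that("the generating parameters beat perturbed ones on average", {
  set.seed(11)
  gen <- model_params(4.4, setNames(-0.5, "4"), 0)
  pert <- model_params(3.6, setNames(0.8, "4"), 0.3)
  diffs <- replicate(60, {
    a <- simulate_agent(generate_toe_block("II", 4), gen, lapse = 0)
    session_loglik(a, gen)$loglik - session_loglik(a, pert)$loglik
  })
  expect_gt(mean(diffs), 0)
})
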