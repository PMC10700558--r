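# Shared fixture builders. All randomness in tests is seeded locally.

# A bare trial table with the full schema, choices optional.
make_trials <- function(f1, f2, choice = NA_character_, block = 4L,
                        block_type = "toe", id = "s01", rt = 800) {
  n <- length(f1)
  t <- data.frame(participant_id = rep(id, n), experiment = rep("II", n),
                  block = rep(as.integer(block), length.out = n),
                  block_type = rep(block_type, length.out = n),
                  trial_index = seq_len(n), f1_hz = f1, f2_hz = f2,
                  choice = rep(choice, length.out = n),
                  rt_ms = rep(rt, length.out = n),
                  correct = NA, stringsAsFactors = FALSE)
  t$correct <- ifelse(t$f1_hz == t$f2_hz | is.na(t$choice) |
                        t$choice == "none", NA,
                      (t$f2_hz > t$f1_hz & t$choice == "second_higher") |
                        (t$f2_hz < t$f1_hz & t$choice == "first_higher"))
  t
}

# TOE-block table realizing exact per-cell accuracies: acc_up[f] on trials
# with F2 = f+2, acc_dn[f] on trials with F2 = f-2, n trials per cell.
make_toe_accuracy_table <- function(f1_levels, acc_up, acc_dn, n = 20L) {
  rows <- list()
  for (i in seq_along(f1_levels)) {
    f <- f1_levels[i]
    k_up <- round(acc_up[i] * n); k_dn <- round(acc_dn[i] * n)
    rows[[length(rows) + 1]] <- make_trials(
      rep(f, n), rep(f + 2, n),
      c(rep("second_higher", k_up), rep("first_higher", n - k_up)))
    rows[[length(rows) + 1]] <- make_trials(
      rep(f, n), rep(f - 2, n),
      c(rep("first_higher", k_dn), rep("second_higher", n - k_dn)))
  }
  do.call(rbind, rows)
}

# Independent precision-tracking oracle for the belief update: propagate
# (mu, pi_mu) explicitly through full-prior formation and Bayes rule.
precision_oracle_update <- function(mu, pi_mu, u, pi_u, pi_x) {
  pi_theta <- pi_mu * pi_x / (pi_mu + pi_x)
  pi_post <- pi_u + pi_theta
  list(mu = (pi_u * u + pi_theta * mu) / pi_post,
       pi_mu = pi_post, tau = pi_u / pi_post)
}
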