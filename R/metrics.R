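# Behavioral statistics and filtering rules of the three experiments.

#' Binomial chance-performance bound
#'
#' Upper limit of the two-sided normal-approximation confidence interval
#' (with continuity correction) around chance performance, as a percentage.
#' Participants whose context-block accuracy falls below this bound are
#' indistinguishable from guessing. With 240 trials and alpha 0.05 the bound
#' is 56.5%.
#'
#' @param n_trials number of scored trials.
#' @param alpha two-sided type-I level.
#' @return the bound in percent.
#' @export
binomial_exclusion_threshold <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1)
  p <- 0.5
  100 * (p + qnorm(1 - alpha / 2) * sqrt(p * (1 - p) / n_trials) +
           0.5 / n_trials)
}

#' Apply the exclusion rules
#'
#' Drops participants whose accuracy over the scored context-block trials
#' (catch trials and unanswered trials removed) falls below the binomial
#' chance bound; drops unanswered trials; flags (but keeps) reaction-time
#' outliers more than three standard deviations from the participant's mean,
#' computed separately per fitted segment (blocks 1-2 and blocks 3-5).
#' Flagged trials keep driving belief updates during fitting but contribute
#' no likelihood term.
#'
#' @param trials a trial table (several participants allowed).
#' @param accuracy_threshold percent bound; default computed from each
#'   participant's scored context-trial count via
#'   \code{\link{binomial_exclusion_threshold}}.
#' @param rt_sd_limit SD multiple for the RT flag.
#' @return list with \code{trials} (filtered, plus logical columns
#'   \code{rt_outlier} and \code{include}) and \code{report} describing every
#'   action taken.
#' @export
apply_exclusions <- function(trials, accuracy_threshold = NULL,
                             rt_sd_limit = 3) {
  stopifnot(is.data.frame(trials))
  answered <- !is.na(trials$choice) & trials$choice != "none"
  scored <- answered & trials$block_type == "context" &
    trials$f1_hz != trials$f2_hz
  acc <- tapply(trials$correct[scored], trials$participant_id[scored], mean)
  nsc <- tapply(scored, trials$participant_id, sum)
  thr <- if (is.null(accuracy_threshold))
    binomial_exclusion_threshold(pmax(nsc[names(acc)], 1)) else
    rep(accuracy_threshold, length(acc))
  dropped <- names(acc)[100 * acc < thr]
  n_unanswered <- sum(!answered)
  keep <- answered & !(trials$participant_id %in% dropped)
  out <- trials[keep, , drop = FALSE]
  # RT outliers per participant per fitted segment
  out$rt_outlier <- FALSE
  if (nrow(out)) {
    seg <- ifelse(out$block <= 2, "12", "345")
    grp <- interaction(out$participant_id, seg, drop = TRUE)
    for (g in levels(grp)) {
      i <- which(grp == g)
      m <- mean(out$rt_ms[i]); s <- sd(out$rt_ms[i])
      if (is.finite(s) && s > 0)
        out$rt_outlier[i] <- abs(out$rt_ms[i] - m) > rt_sd_limit * s
    }
  }
  out$include <- !out$rt_outlier &
    !(out$block_type == "context" & out$f1_hz == out$f2_hz)
  rownames(out) <- NULL
  list(trials = out,
       report = list(excluded_participants = dropped,
                     context_accuracy_pct = 100 * acc,
                     threshold_pct = setNames(thr, names(acc)),
                     n_unanswered_dropped = n_unanswered,
                     n_rt_outliers_flagged = sum(out$rt_outlier)))
}

#' Time-order-effect index
#'
#' For each first-stimulus frequency F1, the performance bias is the accuracy
#' when F2 is 2 Hz above F1 minus the accuracy when it is 2 Hz below. A
#' contraction of the first percept toward the range mean helps on one side
#' of the mean and hurts on the other, so the biases are folded by the side
#' of the range mean (positive sign above the mean, negative below) before
#' averaging; the index is 100 times the folded mean bias divided by the
#' overall accuracy, making a contraction bias positive and zero the
#' no-effect point. Sub-indices over the F1 values below vs above the range
#' mean are also returned.
#'
#' @param trials TOE-block trials of one participant (answered trials).
#' @param f1_levels the six F1 values of the design; default the sorted
#'   distinct F1 values present.
#' @return an object of class \code{toe_result}: \code{i_toe}, \code{bias}
#'   (per-F1 table), \code{i_toe_low}, \code{i_toe_high},
#'   \code{overall_accuracy}.
#' @export
compute_itoe <- function(trials, f1_levels = NULL) {
  t <- trials[!is.na(trials$correct), , drop = FALSE]
  if (is.null(f1_levels)) f1_levels <- sort(unique(t$f1_hz))
  mid <- mean(f1_levels)
  bias <- vapply(f1_levels, function(f) {
    up <- t$correct[t$f1_hz == f & t$f2_hz > f]
    dn <- t$correct[t$f1_hz == f & t$f2_hz < f]
    if (!length(up) || !length(dn))
      stop("missing trials for F1 = ", f)
    mean(up) - mean(dn)
  }, numeric(1))
  s <- sign(f1_levels - mid)
  acc <- mean(t$correct)
  fold <- s * bias
  structure(list(
    i_toe = 100 * mean(fold) / acc,
    i_toe_low = 100 * mean(fold[f1_levels < mid]) / acc,
    i_toe_high = 100 * mean(fold[f1_levels > mid]) / acc,
    bias = data.frame(f1_hz = f1_levels, bias = bias),
    overall_accuracy = acc), class = "toe_result")
}

#' Permutation test for the TOE index
#'
#' Builds the null distribution of the TOE index under no
#' direction-accuracy association by permuting trial correctness within each
#' F1 level (which preserves per-F1 accuracy and trial counts while breaking
#' any dependence on whether F2 lay above or below F1).
#'
#' @param trials TOE-block trials of one agent or participant.
#' @param n_perm number of permutations.
#' @return list with \code{observed} (the TOE index), \code{null} (vector of
#'   permuted indices) and \code{p_value} (one-sided, add-one corrected).
#' @export
itoe_permutation_test <- function(trials, n_perm = 199L) {
  t <- trials[!is.na(trials$correct), , drop = FALSE]
  observed <- compute_itoe(t)$i_toe
  groups <- split(seq_len(nrow(t)), t$f1_hz)
  null <- replicate(n_perm, {
    sh <- t
    for (i in groups) sh$correct[i] <- t$correct[sample(i)]
    compute_itoe(sh)$i_toe
  })
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1))
}

#' Intercept of the two accuracy curves
#'
#' Fits a robust (Huber) linear regression of the per-F1 performance bias on
#' F1 and returns the frequency at which the fitted bias crosses zero, i.e.
#' where the two accuracy curves (F2 above vs below F1) intersect - an
#' estimate of the center of the learned prior. Flagged invalid when the
#' crossing falls outside the presented F1 range or the bias is flat.
#'
#' @param trials TOE-block trials of one participant, or a \code{toe_result}.
#' @param f1_levels passed to \code{\link{compute_itoe}}.
#' @return list with \code{intercept_hz} (NA when invalid), \code{valid},
#'   \code{slope}, \code{offset}.
#' @export
toe_intercept <- function(trials, f1_levels = NULL) {
  res <- if (inherits(trials, "toe_result")) trials else
    compute_itoe(trials, f1_levels)
  ols <- stats::lm(bias ~ f1_hz, data = res$bias)
  co <- if (max(abs(stats::residuals(ols))) < 1e-10) {
    coef(ols)  # exact linear bias: the Huber fit coincides with OLS
  } else {
    coef(MASS::rlm(bias ~ f1_hz, data = res$bias, psi = MASS::psi.huber,
                   k = 1.345, acc = 1e-8, maxit = 100))
  }
  a <- unname(co[1]); c1 <- unname(co[2])
  if (!is.finite(c1) || abs(c1) < 1e-6)
    return(list(intercept_hz = NA_real_, valid = FALSE,
                slope = c1, offset = a))
  x0 <- -a / c1
  rng <- range(res$bias$f1_hz)
  valid <- x0 >= rng[1] && x0 <= rng[2]
  list(intercept_hz = if (valid) x0 else NA_real_, valid = valid,
       slope = c1, offset = a, crossing_hz = x0)
}

#' Psychometric threshold in the context blocks
#'
#' Fits P(answer "second higher") as a logistic function of the signed
#' frequency difference F2 - F1 (binomial GLM, logit link) and returns the
#' frequency difference at which predicted accuracy reaches 75%, i.e.
#' \code{log(3) / slope} under the symmetric-curve assumption (the intercept
#' is retained in the output).
#'
#' @param trials context-block trials of one participant (answered trials).
#' @return an object of class \code{psychometric_fit}: \code{threshold_hz_75},
#'   \code{slope}, \code{intercept}, \code{separation} (TRUE when responses
#'   were step-like and the threshold was clamped to 0).
#' @export
psychometric_threshold <- function(trials) {
  t <- trials[!is.na(trials$choice) & trials$choice != "none", , drop = FALSE]
  if (!nrow(t)) stop("no answered trials")
  df <- t$f2_hz - t$f1_hz
  y <- as.integer(t$choice == "second_higher")
  fit <- suppressWarnings(glm(y ~ df, family = binomial()))
  b1 <- unname(coef(fit)[2]); b0 <- unname(coef(fit)[1])
  nz <- df != 0
  sep <- !is.finite(b1) || b1 > 50 ||
    (any(nz) && all(y[nz] == as.integer(df[nz] > 0)))
  thr <- if (sep) {
    warning("near-perfect separation; threshold clamped to 0")
    0
  } else max(log(3) / b1, 0)
  structure(list(threshold_hz_75 = thr, slope = b1, intercept = b0,
                 separation = sep), class = "psychometric_fit")
}

#' Signal-detection sensitivity
#'
#' Treats "F2 higher than F1" trials as signal. d-prime is
#' \code{qnorm(hit) - qnorm(fa)} with the log-linear rate correction (0.5
#' added to each count, 1 to each total), which keeps the index finite at
#' extreme rates; the criterion is \code{-(qnorm(hit) + qnorm(fa)) / 2}.
#'
#' @param trials answered 2AFC trials of one participant.
#' @return list with \code{d_prime}, \code{criterion}, \code{hit_rate},
#'   \code{fa_rate} (corrected rates).
#' @export
d_prime <- function(trials) {
  t <- trials[!is.na(trials$choice) & trials$choice != "none" &
                trials$f1_hz != trials$f2_hz, , drop = FALSE]
  sig <- t$f2_hz > t$f1_hz
  say2 <- t$choice == "second_higher"
  hit <- (sum(say2 & sig) + 0.5) / (sum(sig) + 1)
  fa <- (sum(say2 & !sig) + 0.5) / (sum(!sig) + 1)
  list(d_prime = qnorm(hit) - qnorm(fa),
       criterion = -(qnorm(hit) + qnorm(fa)) / 2,
       hit_rate = hit, fa_rate = fa)
}

#' Detection-threshold summary of a method-of-limits series
#'
#' Mean threshold, intra-individual standard deviation (n-1 denominator over
#' the four measures), adaptation effect (mean disappearance minus mean
#' detection intensity) and the dispersion histogram of the measures around
#' the participant mean, binned in 0.06 mA units (unit 0 covers
#' [-0.03, 0.03) mA).
#'
#' @param series a \code{threshold_series} from
#'   \code{\link{simulate_method_of_limits}}, or a list with numeric
#'   \code{detection} and \code{disappearance} of two measures each.
#' @return list with \code{mean_threshold}, \code{intra_individual_sd},
#'   \code{adaptation_effect} (all mA) and \code{dispersion_units} (counts
#'   for units -3..3).
#' @export
adaptation_metrics <- function(series) {
  de <- series$detection; di <- series$disappearance
  if (length(de) != 2L || length(di) != 2L)
    stop("expected exactly two detection and two disappearance measures")
  x <- c(de, di)
  dev <- x - mean(x)
  edges <- c(-Inf, -0.15, -0.09, -0.03, 0.03, 0.09, 0.15, Inf)
  units <- cut(dev, edges, right = FALSE, labels = as.character(-3:3))
  list(mean_threshold = mean(x),
       intra_individual_sd = sd(x),
       adaptation_effect = mean(di) - mean(de),
       dispersion_units = table(units))
}
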