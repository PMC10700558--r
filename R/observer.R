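#' @useDynLib toebayes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm rnorm dnorm runif rlnorm optim sd coef glm
#'   binomial setNames pbeta rgamma quantile cor
NULL

#' Error function
#'
#' The Gauss error function, evaluated through the normal CDF.
#'
#' @param x numeric vector.
#' @return \code{erf(x)} elementwise.
#' @export
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Observer parameters
#'
#' Parameters of the 2AFC observers. The dynamic observer (\code{"M1"}) learns
#' a belief about the stimulus feature across stimuli under a prior of
#' sameness with precision ratio \code{r = pi_u / pi_x}; the static observer
#' (\code{"M0"}) decides on the veridical contrast and has no \code{log_r}.
#'
#' @param log_pi_u log sensory precision (precision of the likelihood of a
#'   single stimulus, on the model's feature scale).
#' @param log_r log precision ratio. For \code{"M1"} either a single value or
#'   a named numeric vector giving one value per block (names are block
#'   numbers, e.g. \code{c("3" = 1.1, "4" = -0.9, "5" = -0.5)}). Must be
#'   \code{NULL} for \code{"M0"}.
#' @param bias response bias \code{b}, added to the decision variable inside
#'   the error function.
#' @param model \code{"M1"} (dynamic) or \code{"M0"} (static).
#' @return an object of class \code{toe_params}.
#' @examples
#' model_params(log_pi_u = 4.4, log_r = -1, bias = 0)
#' model_params(log_pi_u = 4.4, model = "M0")
#' @export
model_params <- function(log_pi_u, log_r = NULL, bias = 0,
                         model = c("M1", "M0")) {
  model <- match.arg(model)
  stopifnot(is.numeric(log_pi_u), length(log_pi_u) == 1L, is.finite(log_pi_u),
            is.numeric(bias), length(bias) == 1L, is.finite(bias))
  if (model == "M0") {
    if (!is.null(log_r))
      stop("the static observer M0 has no precision ratio parameter")
  } else {
    if (is.null(log_r))
      stop("the dynamic observer M1 requires `log_r`")
    if (!is.numeric(log_r) || any(!is.finite(log_r)))
      stop("`log_r` must be finite numeric")
  }
  structure(list(log_pi_u = log_pi_u, log_r = log_r, bias = bias,
                 model = model),
            class = "toe_params")
}

#' Belief state of the dynamic observer
#'
#' The running Gaussian posterior over the latent stimulus feature,
#' parameterized by its mean and by the learning rate \code{tau}
#' (equivalently the posterior precision \code{pi_u / tau}).
#'
#' @param mean posterior mean over the feature.
#' @param learning_rate learning rate \code{tau} in (0, 1].
#' @return an object of class \code{belief_state}.
#' @export
belief_state <- function(mean, learning_rate) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(learning_rate), length(learning_rate) == 1L,
            is.finite(learning_rate))
  if (learning_rate <= 0 || learning_rate > 1)
    stop("`learning_rate` must lie in (0, 1]")
  structure(list(mean = mean, learning_rate = learning_rate),
            class = "belief_state")
}

# Resolve a precision ratio from either a toe_params or a bare number.
.resolve_r <- function(params) {
  if (inherits(params, "toe_params")) {
    if (params$model == "M0")
      stop("M0 carries no precision ratio; belief updating is undefined")
    exp(unname(params$log_r[1L]))
  } else if (is.numeric(params) && length(params) == 1L && is.finite(params)) {
    params  # interpreted as r directly
  } else stop("`params` must be a toe_params object or a single numeric r")
}

#' One Bayesian belief update
#'
#' Combines the current belief with the prior of sameness to form the full
#' prior, then assimilates one stimulus. The learning rate follows the
#' recursion \code{tau' = 1 - 1 / (1 + tau + r)} and the mean moves by
#' \code{tau'} times the prediction error. The same transition applies between
#' any two consecutive stimuli, within and between trials.
#'
#' @param state a \code{\link{belief_state}}.
#' @param u observed stimulus feature (model scale).
#' @param params a \code{\link{model_params}} for M1, or a single numeric
#'   precision ratio \code{r}.
#' @return the updated \code{belief_state}.
#' @examples
#' s <- belief_state(30, 0.5)
#' belief_update(s, 32, 1)  # tau' = 0.6, mean 31.2
#' @export
belief_update <- function(state, u, params) {
  stopifnot(inherits(state, "belief_state"))
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u))
    stop("`u` must be a single finite number")
  r <- .resolve_r(params)
  tau <- 1 - 1 / (1 + state$learning_rate + r)
  belief_state(state$mean + tau * (u - state$mean), tau)
}

#' Limit learning rate
#'
#' Fixed point of the learning-rate recursion: the value the learning rate
#' converges to when the same precision ratio applies over a long stimulus
#' sequence, \code{(-r + sqrt(r * (r + 4))) / 2}.
#'
#' @param r precision ratio(s), \code{>= 0}.
#' @return limit learning rate(s) in \code{[0, 1)}.
#' @examples
#' learning_rate_limit(1)  # the golden-ratio conjugate, 0.618...
#' @export
learning_rate_limit <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("`r` must be finite and non-negative")
  (-r + sqrt(r * (r + 4))) / 2
}

#' One trial of the dynamic observer
#'
#' Assimilates the two stimuli of a trial in sequence, then computes the
#' decision variable \code{R = alpha * (mu1 - mu2)} with confidence weight
#' \code{alpha = sqrt(pi_u / (2 * (tau1 + tau2)))} and the probability
#' \code{q = (1 + erf(R + b)) / 2} of answering "first stimulus higher".
#'
#' @param state belief state at trial onset.
#' @param u1,u2 the two stimulus features (model scale).
#' @param params a \code{\link{model_params}} with \code{model = "M1"}; the
#'   first element of \code{log_r} is used.
#' @return a list with the trial computation (\code{theta}, \code{pi_theta},
#'   \code{tau1}, \code{tau2}, \code{mu1}, \code{mu2}, \code{alpha},
#'   \code{R}, \code{q}) and the post-trial \code{state} for carry-over.
#' @export
trial_decision_dynamic <- function(state, u1, u2, params) {
  stopifnot(inherits(params, "toe_params"), params$model == "M1")
  r <- .resolve_r(params)
  pi_u <- exp(params$log_pi_u)
  pi_mu <- pi_u / state$learning_rate
  pi_x <- pi_u / r
  s1 <- belief_update(state, u1, r)
  s2 <- belief_update(s1, u2, r)
  alpha <- sqrt(pi_u / (2 * (s1$learning_rate + s2$learning_rate)))
  R <- alpha * (s1$mean - s2$mean)
  q <- pnorm((R + params$bias) * sqrt(2))
  list(comp = list(theta = state$mean,
                   pi_theta = pi_mu * pi_x / (pi_mu + pi_x),
                   tau1 = s1$learning_rate, tau2 = s2$learning_rate,
                   mu1 = s1$mean, mu2 = s2$mean,
                   alpha = alpha, R = R, q = q),
       state = s2)
}

#' One trial of the static observer
#'
#' Decision on the veridical contrast: \code{R = sqrt(pi_u) / 2 * (u1 - u2)},
#' \code{q = (1 + erf(R + b)) / 2}. No state is consumed or produced.
#'
#' @param u1,u2 the two stimulus features (model scale).
#' @param params a \code{\link{model_params}} with \code{model = "M0"}.
#' @return probability of answering "first stimulus higher".
#' @export
trial_decision_static <- function(u1, u2, params) {
  stopifnot(inherits(params, "toe_params"), params$model == "M0")
  R <- 0.5 * sqrt(exp(params$log_pi_u)) * (u1 - u2)
  pnorm((R + params$bias) * sqrt(2))
}

#' Closed-form within-trial contrast
#'
#' The posterior contrast \code{mu1 - mu2} of the dynamic observer expressed
#' directly in the stimuli and the two within-trial learning rates:
#' \deqn{(u1 - u2) - (1 - \tau_1 \tau_2)(u1 - \mu_0) + (1 - \tau_2)(u2 - \mu_0)}
#' It decomposes the contrast into the veridical difference plus two
#' contraction terms pulling each stimulus toward the trial-onset prior mean.
#' Algebraically identical to running the sequential update twice.
#'
#' @param state belief state at trial onset (supplies \code{mu0, tau0}).
#' @param u1,u2 the two stimulus features.
#' @param r precision ratio.
#' @return the contrast \code{mu1 - mu2}.
#' @export
contrast_closed_form <- function(state, u1, u2, r) {
  stopifnot(inherits(state, "belief_state"))
  tau1 <- 1 - 1 / (1 + state$learning_rate + r)
  tau2 <- 1 - 1 / (1 + tau1 + r)
  (u1 - u2) - (1 - tau1 * tau2) * (u1 - state$mean) +
    (1 - tau2) * (u2 - state$mean)
}

# Per-trial precision ratio vector for a trial table under M1 params.
.trial_r <- function(trials, params) {
  lr <- params$log_r
  if (is.null(names(lr)) || length(lr) == 1L)
    return(rep(exp(unname(lr[1L])), nrow(trials)))
  idx <- match(as.character(trials$block), names(lr))
  if (anyNA(idx))
    stop("`log_r` has no value for block(s): ",
         paste(unique(trials$block[is.na(idx)]), collapse = ", "))
  exp(unname(lr[idx]))
}

# Default initial state on the model scale: prior mean at the 30 Hz standard
# (the midpoint of the context stimulus range), learning rate at its limit
# value for the first trial's precision ratio. Initial values only matter for
# the first few trials.
.default_init <- function(r1, freq_ref) {
  tau0 <- max(learning_rate_limit(r1), 1e-6)
  belief_state(30 / freq_ref, tau0)
}

#' Response probabilities over a trial table
#'
#' Computes the probability of answering "first stimulus higher" for every
#' trial, carrying the dynamic observer's belief across trials (and across
#' block boundaries). Frequencies are mapped to the model scale by dividing by
#' \code{freq_ref}; the fitted precision parameters refer to that scale.
#'
#' @param trials a trial table with columns \code{f1_hz}, \code{f2_hz} and
#'   (for block-wise \code{log_r}) \code{block}.
#' @param params a \code{\link{model_params}}.
#' @param init initial \code{\link{belief_state}} on the model scale, or
#'   \code{NULL} for the default (mean at the 30 Hz standard, limit learning
#'   rate of the first block).
#' @param freq_ref reference frequency (Hz) dividing the raw frequencies
#'   before they enter the observer. The default 30 is the standard stimulus
#'   of the context blocks; precisions reported in the source task regime
#'   (log pi_u around 4.4) refer to this relative scale.
#' @return list with \code{q} (per-trial probability), \code{state} (final
#'   belief state or NULL for M0) and the within-trial diagnostics.
#' @export
predict_q <- function(trials, params, init = NULL, freq_ref = 30) {
  stopifnot(inherits(params, "toe_params"), is.data.frame(trials))
  if (nrow(trials) == 0L) stop("empty trial table")
  u1 <- trials$f1_hz / freq_ref
  u2 <- trials$f2_hz / freq_ref
  if (any(!is.finite(u1)) || any(!is.finite(u2)))
    stop("non-finite stimulus frequencies")
  dyn <- params$model == "M1"
  if (dyn) {
    rvec <- .trial_r(trials, params)
    if (is.null(init)) init <- .default_init(rvec[1L], freq_ref)
    stopifnot(inherits(init, "belief_state"))
  } else {
    rvec <- rep(1, nrow(trials))
  }
  out <- cpp_trial_q(u1, u2, rvec, exp(params$log_pi_u), params$bias,
                     as.integer(dyn),
                     if (dyn) init$mean else 0,
                     if (dyn) init$learning_rate else 1)
  list(q = out$q,
       state = if (dyn) belief_state(out$mu_end, out$tau_end) else NULL,
       tau1 = out$tau1, tau2 = out$tau2,
       mu1 = out$mu1, mu2 = out$mu2, mu_pre = out$mu_pre)
}

#' Bernoulli log-likelihood of a choice sequence
#'
#' Sums \code{log q} over trials answered "first higher" and \code{log(1-q)}
#' over trials answered "second higher". Trials flagged as excluded (or
#' unanswered) still drive the belief dynamics but contribute no likelihood
#' term. Probabilities are clipped to \code{[1e-9, 1 - 1e-9]}.
#'
#' @param trials trial table with columns \code{f1_hz}, \code{f2_hz},
#'   \code{choice} (\code{"first_higher"}, \code{"second_higher"} or
#'   \code{"none"}) and optionally a logical \code{include} column.
#' @param params a \code{\link{model_params}}.
#' @param init,freq_ref passed to \code{\link{predict_q}}.
#' @return list with \code{loglik}, the per-trial \code{q} series, and the
#'   final belief \code{state}.
#' @export
session_loglik <- function(trials, params, init = NULL, freq_ref = 30) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("empty trial table")
  bad <- setdiff(unique(trials$choice),
                 c("first_higher", "second_higher", "none", NA))
  if (length(bad))
    stop("unknown choice codes: ", paste(bad, collapse = ", "))
  pred <- predict_q(trials, params, init = init, freq_ref = freq_ref)
  q <- pmin(pmax(pred$q, 1e-9), 1 - 1e-9)
  include <- if ("include" %in% names(trials)) trials$include else
    rep(TRUE, nrow(trials))
  include <- include & trials$choice %in% c("first_higher", "second_higher")
  ll <- sum(ifelse(trials$choice[include] == "first_higher",
                   log(q[include]), log(1 - q[include])))
  list(loglik = ll, q = pred$q, state = pred$state, n_included = sum(include))
}
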