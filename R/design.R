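# Experimental designs and agent/cohort simulators.
#
# Functions draw from R's global RNG; call set.seed() (or pass `seed` where a
# function offers it) for reproducibility.

.toe_f1 <- list(II = c(25, 27, 29, 31, 33, 35),
                III = c(21, 23, 25, 27, 29, 31))

.trial_cols <- c("participant_id", "experiment", "block", "block_type",
                 "trial_index", "f1_hz", "f2_hz", "choice", "rt_ms",
                 "correct")

.empty_trials <- function() {
  data.frame(participant_id = character(), experiment = character(),
             block = integer(), block_type = character(),
             trial_index = integer(), f1_hz = numeric(), f2_hz = numeric(),
             choice = character(), rt_ms = numeric(), correct = logical(),
             stringsAsFactors = FALSE)
}

.make_trials <- function(f1, f2, experiment, block, block_type) {
  n <- length(f1)
  data.frame(participant_id = rep(NA_character_, n),
             experiment = rep(experiment, n),
             block = rep(as.integer(block), n),
             block_type = rep(block_type, n),
             trial_index = rep(NA_integer_, n),
             f1_hz = f1, f2_hz = f2,
             choice = rep(NA_character_, n),
             rt_ms = rep(NA_real_, n),
             correct = rep(NA, n),
             stringsAsFactors = FALSE)
}

#' Generate one context-setting block
#'
#' 85 trials in which the first stimulus is always the 30 Hz standard and the
#' second spans 22-38 Hz in 1 Hz steps: the 17 possible pairs repeated five
#' times, presented as five cycles each internally shuffled (40 trials with
#' F2 above the standard, 40 below, 5 catch trials with F2 equal to it).
#'
#' @param experiment \code{"II"} or \code{"III"} (the context design is the
#'   same in both).
#' @param block block number to stamp on the rows (1-3).
#' @return a trial table of 85 rows.
#' @export
generate_context_block <- function(experiment = "II", block = 1L) {
  experiment <- match.arg(experiment, c("II", "III"))
  f2_set <- 22:38
  f2 <- unlist(lapply(1:5, function(i) sample(f2_set)))
  .make_trials(rep(30, 85), f2, experiment, block, "context")
}

#' Generate one time-order-effect block
#'
#' 96 trials; the first frequency takes six values (centered on 30 Hz in
#' experiment II, 26 Hz in experiment III) and the second is always exactly
#' 2 Hz above or below it: 12 pairs presented eight times each, in a
#' pseudo-random order in which successive trials never repeat the identical
#' pair.
#'
#' @param experiment \code{"II"} or \code{"III"}.
#' @param block block number to stamp on the rows (4-5).
#' @param max_retry resampling cap for the no-immediate-repeat shuffle.
#' @return a trial table of 96 rows.
#' @export
generate_toe_block <- function(experiment = "II", block = 4L,
                               max_retry = 10000L) {
  experiment <- match.arg(experiment, c("II", "III"))
  f1_set <- .toe_f1[[experiment]]
  pairs <- expand.grid(f1 = f1_set, d = c(-2, 2))
  n_pairs <- nrow(pairs)
  # Sequential draw proportional to remaining counts, excluding the previous
  # pair; restart on the (rare) dead end where only the previous pair remains.
  for (i in seq_len(max_retry)) {
    counts <- rep(8L, n_pairs)
    ord <- integer(8L * n_pairs)
    prev <- 0L
    ok <- TRUE
    for (t in seq_along(ord)) {
      avail <- which(counts > 0L)
      avail <- avail[avail != prev]
      if (!length(avail)) { ok <- FALSE; break }
      k <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = counts[avail])
      ord[t] <- k
      counts[k] <- counts[k] - 1L
      prev <- k
    }
    if (ok) {
      f1 <- pairs$f1[ord]
      return(.make_trials(f1, f1 + pairs$d[ord], experiment, block, "toe"))
    }
  }
  stop("could not find a no-immediate-repeat order within the retry cap")
}

#' Generate a full experiment design
#'
#' Three context-setting blocks followed by two time-order-effect blocks,
#' 447 trials in total, with within-experiment trial indices filled in.
#'
#' @param experiment \code{"II"} or \code{"III"}.
#' @param seed optional integer seed.
#' @return a trial table of 447 rows.
#' @export
generate_experiment_design <- function(experiment = "II", seed = NULL) {
  experiment <- match.arg(experiment, c("II", "III"))
  if (!is.null(seed)) set.seed(seed)
  blocks <- c(lapply(1:3, function(b) generate_context_block(experiment, b)),
              lapply(4:5, function(b) generate_toe_block(experiment, b)))
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.derive_correct <- function(trials) {
  ifelse(trials$f1_hz == trials$f2_hz | is.na(trials$choice) |
           trials$choice == "none", NA,
         (trials$f2_hz > trials$f1_hz & trials$choice == "second_higher") |
           (trials$f2_hz < trials$f1_hz & trials$choice == "first_higher"))
}

#' Simulate an agent on a design
#'
#' Fills the choice column by drawing Bernoulli responses from the observer's
#' per-trial probability (the dynamic observer's belief carries across trials
#' and blocks, with one precision ratio per block when \code{log_r} is
#' block-named). Reaction times are lognormal and exist only to exercise
#' RT-based filters; unanswered trials occur with probability \code{lapse}.
#'
#' @param design a trial table from \code{\link{generate_experiment_design}}.
#' @param params a \code{\link{model_params}}.
#' @param rt_meanlog,rt_sdlog lognormal RT parameters (ms scale:
#'   \code{exp(rt_meanlog)} is the median RT in ms).
#' @param lapse probability of an unanswered trial.
#' @param init,freq_ref passed to \code{\link{predict_q}}.
#' @return the design with \code{choice}, \code{rt_ms} and \code{correct}
#'   filled in.
#' @export
simulate_agent <- function(design, params, rt_meanlog = log(800),
                           rt_sdlog = 0.4, lapse = 1e-4,
                           init = NULL, freq_ref = 30) {
  q <- predict_q(design, params, init = init, freq_ref = freq_ref)$q
  n <- nrow(design)
  first <- runif(n) < q
  design$choice <- ifelse(first, "first_higher", "second_higher")
  design$choice[runif(n) < lapse] <- "none"
  design$rt_ms <- rlnorm(n, rt_meanlog, rt_sdlog)
  design$rt_ms[design$choice == "none"] <- NA_real_
  design$correct <- .derive_correct(design)
  design
}

#' Cohort hyperparameters
#'
#' Gaussian hyperparameters from which per-subject observer parameters are
#' drawn. The two presets reproduce the group-typical values of the source
#' task regime: log sensory precision around 4.3-4.5 (sd ~0.7-0.8), response
#' bias of opposite sign in the two groups (-0.1 vs +0.1, sd 0.2), a high
#' precision ratio in the context blocks (log r 1.1, sd 1.9) and a lower,
#' group-dependent one in the TOE blocks (block 4: 0.40 +/- 1.8 for
#' \code{"NT"} vs -0.96 +/- 1.3 for \code{"ASD"}).
#'
#' @param group \code{"NT"} or \code{"ASD"} preset, or \code{"custom"}.
#' @param n number of subjects.
#' @param log_pi_u,bias length-2 numeric (mean, sd) on the fitting scale.
#' @param log_r_mean,log_r_sd length-5 numeric, one per block.
#' @param model generating model for all subjects.
#' @param rt_meanlog,rt_sdlog,lapse response-time and lapse settings.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(group = c("NT", "ASD", "custom"), n = 17L,
                        log_pi_u = NULL, bias = NULL,
                        log_r_mean = NULL, log_r_sd = NULL,
                        model = c("M1", "M0"),
                        rt_meanlog = log(800), rt_sdlog = 0.4,
                        lapse = 1e-4) {
  group <- match.arg(group)
  model <- match.arg(model)
  defaults <- switch(group,
    NT = list(log_pi_u = c(4.5, 0.8), bias = c(-0.1, 0.2),
              log_r_mean = c(1.1, 1.1, 1.1, 0.40, 0.40),
              log_r_sd = c(1.9, 1.9, 1.9, 1.8, 1.8)),
    ASD = list(log_pi_u = c(4.3, 0.7), bias = c(0.1, 0.2),
               log_r_mean = c(1.1, 1.1, 1.1, -0.96, -0.96),
               log_r_sd = c(1.9, 1.9, 1.9, 1.3, 1.3)),
    custom = list(log_pi_u = c(4.4, 0.8), bias = c(0, 0.2),
                  log_r_mean = c(1.1, 1.1, 1.1, -0.3, -0.3),
                  log_r_sd = c(1.9, 1.9, 1.9, 1.6, 1.6)))
  spec <- list(group = group, n = as.integer(n),
               log_pi_u = if (is.null(log_pi_u)) defaults$log_pi_u else log_pi_u,
               bias = if (is.null(bias)) defaults$bias else bias,
               log_r_mean = if (is.null(log_r_mean)) defaults$log_r_mean else log_r_mean,
               log_r_sd = if (is.null(log_r_sd)) defaults$log_r_sd else log_r_sd,
               model = model, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
               lapse = lapse)
  stopifnot(spec$n >= 0L, length(spec$log_pi_u) == 2L, spec$log_pi_u[2] >= 0,
            length(spec$bias) == 2L, spec$bias[2] >= 0,
            length(spec$log_r_mean) == 5L, length(spec$log_r_sd) == 5L,
            all(spec$log_r_sd >= 0))
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a cohort
#'
#' Draws per-subject parameters from the cohort hyperparameters and simulates
#' each subject on a freshly generated design. Each subject gets an
#' independent design and RNG substream derived from \code{seed}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param experiment \code{"II"} or \code{"III"}.
#' @param seed optional integer seed.
#' @param id_prefix prefix for participant ids.
#' @return list with \code{trials} (stacked trial table) and \code{truth}
#'   (one row per subject with the generating parameters).
#' @export
simulate_cohort <- function(spec, experiment = "II", seed = NULL,
                            id_prefix = spec$group) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$n == 0L)
    return(list(trials = .empty_trials(),
                truth = data.frame(participant_id = character())))
  trials <- vector("list", spec$n)
  truth <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    id <- sprintf("%s%03d", id_prefix, i)
    lpu <- rnorm(1, spec$log_pi_u[1], spec$log_pi_u[2])
    b <- rnorm(1, spec$bias[1], spec$bias[2])
    lr <- rnorm(5, spec$log_r_mean, spec$log_r_sd)
    params <- if (spec$model == "M1")
      model_params(lpu, setNames(lr, as.character(1:5)), b) else
      model_params(lpu, NULL, b, model = "M0")
    design <- generate_experiment_design(experiment)
    tt <- simulate_agent(design, params, rt_meanlog = spec$rt_meanlog,
                         rt_sdlog = spec$rt_sdlog, lapse = spec$lapse)
    tt$participant_id <- id
    trials[[i]] <- tt
    truth[[i]] <- data.frame(participant_id = id, group = spec$group,
                             model = spec$model, log_pi_u = lpu, bias = b,
                             log_r_b1 = lr[1], log_r_b2 = lr[2],
                             log_r_b3 = lr[3], log_r_b4 = lr[4],
                             log_r_b5 = lr[5], stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}

#' Method-of-limits agent
#'
#' Generative model for the four threshold measures of the detection task:
#' the intensity ramps up in 0.02 mA steps until the agent reports detection,
#' continues to 1.5 times that value, then ramps down until the sensation
#' disappears, the whole procedure run twice. Detection measures are the true
#' threshold plus i.i.d. Gaussian criterion noise; disappearance measures are
#' additionally shifted upward by the adaptation effect \code{delta}. All
#' measures are quantized to the 0.02 mA ramp grid and floored at zero.
#'
#' @param threshold_ma true detection threshold (mA).
#' @param delta_ma adaptation shift (mA, \code{>= 0}); the \code{"NT"} preset
#'   uses 0.08 with noise 0.05, the \code{"ASD"} preset 0 with noise 0.01.
#' @param sigma_ma criterion noise SD (mA).
#' @param step_ma ramp step (mA per second).
#' @param turnaround multiplier of the first detection value at which the
#'   ramp reverses (recorded for completeness; it does not enter the
#'   measures).
#' @return an object of class \code{limits_agent_spec}.
#' @export
limits_agent_spec <- function(threshold_ma = 0.6, delta_ma = 0.08,
                              sigma_ma = 0.05, step_ma = 0.02,
                              turnaround = 1.5) {
  stopifnot(threshold_ma >= 0, delta_ma >= 0, step_ma > 0, turnaround > 1)
  if (sigma_ma < 0) stop("`sigma_ma` must be non-negative")
  structure(list(threshold_ma = threshold_ma, delta_ma = delta_ma,
                 sigma_ma = sigma_ma, step_ma = step_ma,
                 turnaround = turnaround),
            class = "limits_agent_spec")
}

#' Simulate a method-of-limits threshold series
#'
#' @param spec a \code{\link{limits_agent_spec}}.
#' @return an object of class \code{threshold_series}: lists \code{detection}
#'   and \code{disappearance}, two measures each (mA).
#' @export
simulate_method_of_limits <- function(spec) {
  stopifnot(inherits(spec, "limits_agent_spec"))
  snap <- function(x) pmax(round(x / spec$step_ma) * spec$step_ma, 0)
  detection <- snap(spec$threshold_ma + rnorm(2, 0, spec$sigma_ma))
  disappearance <- snap(spec$threshold_ma + spec$delta_ma +
                          rnorm(2, 0, spec$sigma_ma))
  structure(list(detection = detection, disappearance = disappearance),
            class = "threshold_series")
}
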