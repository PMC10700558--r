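# Subject-level MAP estimation with Laplace evidence, the two-phase
# multisession protocol, and simulation-based recovery/confusion studies.

#' Gaussian priors on the fitting scale
#'
#' Weakly informative defaults spanning the scales on which group-typical
#' estimates live (log sensory precision around 4-5, log precision ratio
#' between about -3 and 3, bias within about +/-0.5).
#'
#' @param log_pi_u,log_r,bias length-2 numeric (mean, sd).
#' @return an object of class \code{prior_spec}.
#' @export
prior_spec <- function(log_pi_u = c(3, 2), log_r = c(0, 2), bias = c(0, 1)) {
  stopifnot(length(log_pi_u) == 2L, log_pi_u[2] > 0,
            length(log_r) == 2L, log_r[2] > 0,
            length(bias) == 2L, bias[2] > 0)
  structure(list(log_pi_u = log_pi_u, log_r = log_r, bias = bias),
            class = "prior_spec")
}

# Assemble parameter bookkeeping for a fit: names, prior means/sds.
.fit_layout <- function(model, r_blocks, priors) {
  nm <- c("log_pi_u", "bias")
  mu <- c(priors$log_pi_u[1], priors$bias[1])
  sdv <- c(priors$log_pi_u[2], priors$bias[2])
  if (model == "M1") {
    rn <- if (is.null(r_blocks)) "log_r" else paste0("log_r_b", r_blocks)
    nm <- c(nm, rn)
    mu <- c(mu, rep(priors$log_r[1], length(rn)))
    sdv <- c(sdv, rep(priors$log_r[2], length(rn)))
  }
  list(names = nm, mu = mu, sd = sdv)
}

.params_from_theta <- function(theta, model, r_blocks) {
  if (model == "M0")
    return(model_params(theta[1], NULL, theta[2], model = "M0"))
  lr <- theta[-(1:2)]
  names(lr) <- if (is.null(r_blocks)) NULL else as.character(r_blocks)
  if (is.null(r_blocks)) lr <- unname(lr)[1]
  model_params(theta[1], lr, theta[2])
}

# Numerical Hessian of f at x by central second differences.
.num_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' MAP fit of one observer model
#'
#' Maximizes the Bernoulli log-likelihood plus the log Gaussian prior over
#' the fitting-scale parameters by multi-start local search (Nelder-Mead from
#' the prior mean and jittered draws), then forms the Laplace approximation
#' at the optimum: posterior covariance from the numerical Hessian and log
#' evidence \code{logjoint + d/2 log(2 pi) - log det(H) / 2}.
#'
#' @param trials trial table of one fitted segment (with \code{include}
#'   column; excluded trials still drive belief updates).
#' @param model \code{"M1"} or \code{"M0"}.
#' @param priors a \code{\link{prior_spec}}.
#' @param r_blocks for M1: \code{NULL} for a single shared log precision
#'   ratio, or an integer vector of block numbers to give each its own.
#' @param prior_overrides named list overriding individual prior entries
#'   (e.g. a recentered \code{log_pi_u} in phase 2).
#' @param n_starts number of optimizer starts (first at the prior mean).
#' @param init,freq_ref passed to \code{\link{session_loglik}}.
#' @param min_trials minimum number of included trials.
#' @return an object of class \code{fit_result}: \code{estimates} (named MAP
#'   vector), \code{covariance}, \code{posterior_sd}, \code{log_evidence},
#'   \code{loglik}, \code{model}, \code{converged}, \code{diagnostics}.
#' @export
map_fit <- function(trials, model = c("M1", "M0"), priors = prior_spec(),
                    r_blocks = NULL, prior_overrides = NULL,
                    n_starts = 5L, init = NULL, freq_ref = 30,
                    min_trials = 20L) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "prior_spec"))
  if (!is.null(prior_overrides))
    for (nm in names(prior_overrides)) priors[[nm]] <- prior_overrides[[nm]]
  inc <- if ("include" %in% names(trials)) trials$include else
    rep(TRUE, nrow(trials))
  inc <- inc & trials$choice %in% c("first_higher", "second_higher")
  if (sum(inc) < min_trials)
    stop("too few included trials (", sum(inc), " < ", min_trials, ")")
  lay <- .fit_layout(model, r_blocks, priors)
  d <- length(lay$names)
  negjoint <- function(theta) {
    p <- .params_from_theta(theta, model, r_blocks)
    ll <- session_loglik(trials, p, init = init, freq_ref = freq_ref)$loglik
    lp <- sum(dnorm(theta, lay$mu, lay$sd, log = TRUE))
    -(ll + lp)
  }
  starts <- rbind(lay$mu,
                  matrix(rnorm((n_starts - 1) * d, rep(lay$mu, each = n_starts - 1),
                               rep(lay$sd / 2, each = n_starts - 1)),
                         nrow = max(n_starts - 1, 0)))
  best <- NULL
  conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    o <- optim(starts[s, ], negjoint, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-8))
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- o$convergence == 0
    }
  }
  H <- .num_hessian(negjoint, best$par)
  reg <- FALSE
  ev <- tryCatch({
    ch <- chol(H)
    -best$value + d / 2 * log(2 * pi) - sum(log(diag(ch)))
  }, error = function(e) NA_real_)
  if (!is.finite(ev)) {
    reg <- TRUE
    H <- H + diag(pmax(1e-6, -min(eigen(H, symmetric = TRUE,
                                        only.values = TRUE)$values) + 1e-6), d)
    ch <- chol(H)
    ev <- -best$value + d / 2 * log(2 * pi) - sum(log(diag(ch)))
  }
  covm <- chol2inv(chol(H))
  dimnames(covm) <- list(lay$names, lay$names)
  est <- setNames(best$par, lay$names)
  p_hat <- .params_from_theta(best$par, model, r_blocks)
  ll_hat <- session_loglik(trials, p_hat, init = init,
                           freq_ref = freq_ref)$loglik
  structure(list(estimates = est, covariance = covm,
                 posterior_sd = sqrt(diag(covm)),
                 log_evidence = ev, loglik = ll_hat,
                 model = model, r_blocks = r_blocks,
                 params = p_hat, converged = conv,
                 prior = lay,
                 diagnostics = list(neg_log_joint = best$value,
                                    hessian_regularized = reg,
                                    n_included = sum(inc),
                                    n_starts = nrow(starts))),
            class = "fit_result")
}

#' Laplace log evidence of a fit
#'
#' @param fit a \code{fit_result}.
#' @return the Laplace log evidence (free-energy approximation) stored with
#'   the fit; deterministic given the fit.
#' @export
laplace_evidence <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  fit$log_evidence
}

#' Two-phase multisession fit of one subject
#'
#' Phase 1 fits both observers on the first two context blocks (the dynamic
#' observer with a single precision ratio, since both blocks share one
#' context) and forms the model-averaged estimate of the log sensory
#' precision. Phase 2 fits both observers on blocks 3-5 with the sensory
#' precision prior recentered on that estimate (SD from the model-averaged
#' phase-1 posterior), the dynamic observer carrying one precision ratio per
#' block and a continuous belief state across the three blocks.
#'
#' @param trials all five blocks of one participant (after
#'   \code{\link{apply_exclusions}}).
#' @param priors a \code{\link{prior_spec}}.
#' @param n_starts,freq_ref passed to \code{\link{map_fit}}.
#' @return an object of class \code{subject_fit_bundle}: \code{phase1},
#'   \code{phase2} (each a list of \code{fit_result} for M0 and M1),
#'   \code{bma_log_pi_u}, \code{bma_log_pi_u_sd}, \code{phase1_weights}.
#' @export
fit_subject_pipeline <- function(trials, priors = prior_spec(),
                                 n_starts = 5L, freq_ref = 30) {
  if (!all(1:5 %in% trials$block))
    stop("subject is missing blocks: ",
         paste(setdiff(1:5, unique(trials$block)), collapse = ", "))
  t12 <- trials[trials$block %in% 1:2, , drop = FALSE]
  t345 <- trials[trials$block %in% 3:5, , drop = FALSE]
  p1 <- list(
    M0 = map_fit(t12, "M0", priors, n_starts = n_starts, freq_ref = freq_ref),
    M1 = map_fit(t12, "M1", priors, r_blocks = NULL, n_starts = n_starts,
                 freq_ref = freq_ref))
  ev <- c(p1$M0$log_evidence, p1$M1$log_evidence)
  w <- exp(ev - max(ev)); w <- w / sum(w)
  est <- c(p1$M0$estimates["log_pi_u"], p1$M1$estimates["log_pi_u"])
  sds <- c(p1$M0$posterior_sd["log_pi_u"], p1$M1$posterior_sd["log_pi_u"])
  bma <- sum(w * est)
  bma_sd <- sqrt(sum(w * (sds^2 + est^2)) - bma^2)
  ov <- list(log_pi_u = c(bma, max(bma_sd, 1e-3)))
  p2 <- list(
    M0 = map_fit(t345, "M0", priors, prior_overrides = ov,
                 n_starts = n_starts, freq_ref = freq_ref),
    M1 = map_fit(t345, "M1", priors, r_blocks = 3:5, prior_overrides = ov,
                 n_starts = n_starts, freq_ref = freq_ref))
  structure(list(phase1 = p1, phase2 = p2,
                 bma_log_pi_u = bma, bma_log_pi_u_sd = bma_sd,
                 phase1_weights = setNames(w, c("M0", "M1"))),
            class = "subject_fit_bundle")
}

# Evidence matrix (subjects x models) from a list of bundles, per phase.
.evidence_matrix <- function(bundles, phase = c("phase2", "phase1")) {
  phase <- match.arg(phase)
  m <- t(vapply(bundles, function(b)
    c(M0 = b[[phase]]$M0$log_evidence, M1 = b[[phase]]$M1$log_evidence),
    numeric(2)))
  rownames(m) <- names(bundles)
  m
}

#' Fit every subject of a cohort
#'
#' Convenience wrapper running \code{\link{apply_exclusions}} and
#' \code{\link{fit_subject_pipeline}} per participant.
#'
#' @param trials stacked trial table.
#' @param priors,n_starts,freq_ref passed through.
#' @return list with \code{bundles} (named by participant), the phase-1 and
#'   phase-2 \code{evidence} matrices and the exclusion \code{report}.
#' @export
fit_cohort <- function(trials, priors = prior_spec(), n_starts = 5L,
                       freq_ref = 30) {
  ex <- apply_exclusions(trials)
  ids <- unique(ex$trials$participant_id)
  bundles <- lapply(ids, function(id)
    fit_subject_pipeline(ex$trials[ex$trials$participant_id == id, ],
                         priors = priors, n_starts = n_starts,
                         freq_ref = freq_ref))
  names(bundles) <- ids
  list(bundles = bundles,
       evidence_phase1 = .evidence_matrix(bundles, "phase1"),
       evidence_phase2 = .evidence_matrix(bundles, "phase2"),
       exclusions = ex$report)
}

#' Parameter recovery study
#'
#' Simulates a cohort, runs the full two-phase fitting pipeline, and reports
#' per-parameter correlation, bias and RMSE between the generating values and
#' the dynamic-model estimates, together with the behavioral cross-checks:
#' the correlation of fitted log sensory precision with simulated accuracy
#' and of fitted TOE-block log precision ratio with the simulated TOE index.
#'
#' Sensory precision is constant over the experiment, so its recovery is
#' scored on the final model-averaged estimate (phase-2, which pools all
#' five blocks through the recentered prior); the phase-1 context-block
#' estimate is kept as \code{est_log_pi_u_phase1} and is the one correlated
#' with accuracy, both being context-block quantities.
#'
#' @param spec a \code{\link{cohort_spec}} (or a list of them, stacked).
#' @param experiment \code{"II"} or \code{"III"}.
#' @param priors,n_starts passed to the fitting pipeline.
#' @param seed integer seed.
#' @return list with \code{truth_vs_est} (one row per subject),
#'   \code{summary} (per-parameter correlation/bias/RMSE),
#'   \code{cor_logpiu_accuracy}, \code{cor_logr_itoe}.
#' @export
parameter_recovery <- function(spec = list(cohort_spec("NT", 15),
                                           cohort_spec("ASD", 15)),
                               experiment = "II", priors = prior_spec(),
                               n_starts = 5L, seed = 1L) {
  set.seed(seed)
  if (inherits(spec, "cohort_spec")) spec <- list(spec)
  sims <- lapply(spec, simulate_cohort, experiment = experiment)
  trials <- do.call(rbind, lapply(sims, `[[`, "trials"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  fits <- fit_cohort(trials, priors = priors, n_starts = n_starts)
  rows <- lapply(names(fits$bundles), function(id) {
    b <- fits$bundles[[id]]
    tt <- trials[trials$participant_id == id, ]
    scored <- !is.na(tt$correct)
    itoe <- compute_itoe(tt[tt$block_type == "toe", ])$i_toe
    e1 <- b$phase1$M1$estimates
    e2 <- b$phase2$M1$estimates
    ev2 <- c(b$phase2$M0$log_evidence, b$phase2$M1$log_evidence)
    w2 <- exp(ev2 - max(ev2)); w2 <- w2 / sum(w2)
    lpu_final <- sum(w2 * c(b$phase2$M0$estimates[["log_pi_u"]],
                            b$phase2$M1$estimates[["log_pi_u"]]))
    data.frame(participant_id = id,
               est_log_pi_u = lpu_final,
               est_log_pi_u_phase1 = b$bma_log_pi_u,
               est_bias = e1[["bias"]],
               est_log_r_b3 = e2[["log_r_b3"]],
               est_log_r_b4 = e2[["log_r_b4"]],
               est_log_r_b5 = e2[["log_r_b5"]],
               accuracy = mean(tt$correct[scored]),
               i_toe = itoe, stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  tv <- merge(truth, est, by = "participant_id")
  pairs <- list(log_pi_u = c("log_pi_u", "est_log_pi_u"),
                bias = c("bias", "est_bias"),
                log_r_b4 = c("log_r_b4", "est_log_r_b4"),
                log_r_b5 = c("log_r_b5", "est_log_r_b5"))
  summary <- do.call(rbind, lapply(names(pairs), function(p) {
    x <- tv[[pairs[[p]][1]]]; y <- tv[[pairs[[p]][2]]]
    data.frame(parameter = p, correlation = cor(x, y),
               bias = mean(y - x), rmse = sqrt(mean((y - x)^2)))
  }))
  lr_true <- c(tv$log_r_b4, tv$log_r_b5)
  lr_est <- c(tv$est_log_r_b4, tv$est_log_r_b5)
  list(truth_vs_est = tv, summary = summary,
       cor_log_r_blockwise = cor(lr_true, lr_est),
       cor_logpiu_accuracy = cor(tv$est_log_pi_u_phase1, tv$accuracy),
       cor_logr_itoe = cor((tv$est_log_r_b4 + tv$est_log_r_b5) / 2, tv$i_toe),
       evidence_phase2 = fits$evidence_phase2)
}

#' Model confusion study
#'
#' Simulates one cohort under each generating observer, fits both observers
#' to every subject via the two-phase pipeline, and runs random-effects BMS
#' on the phase-2 evidences of each cohort, tabulating which model is
#' selected.
#'
#' @param n_per_model subjects per generating model.
#' @param m1_spec,m0_spec cohort specs for the two generating models; the
#'   defaults use strong learning effects under M1 (TOE-block log r near -1,
#'   moderate spread) and matched precision/bias under M0.
#' @param priors,n_starts,seed passed through.
#' @return list with \code{confusion} (2x2 table of generating vs selected
#'   model by expected frequency), \code{bms} (per-cohort \code{bms_result}),
#'   \code{pep} (protected exceedance probabilities of M1 in each cohort).
#' @export
model_confusion <- function(n_per_model = 17L,
                            m1_spec = NULL, m0_spec = NULL,
                            priors = prior_spec(), n_starts = 5L,
                            seed = 1L) {
  set.seed(seed)
  if (is.null(m1_spec))
    m1_spec <- cohort_spec("custom", n_per_model,
                           log_r_mean = c(1.1, 1.1, 1.1, -1, -1),
                           log_r_sd = c(0.5, 0.5, 0.5, 0.5, 0.5))
  if (is.null(m0_spec))
    m0_spec <- cohort_spec("custom", n_per_model, model = "M0")
  res <- lapply(list(M1 = m1_spec, M0 = m0_spec), function(sp) {
    sim <- simulate_cohort(sp, id_prefix = paste0("sim", sp$model))
    fits <- fit_cohort(sim$trials, priors = priors, n_starts = n_starts)
    rfx_bms(fits$evidence_phase2)
  })
  winner <- vapply(res, function(b)
    names(which.max(b$expected_frequency)), character(1))
  confusion <- table(generating = factor(c("M1", "M0"),
                                         levels = c("M0", "M1")),
                     selected = factor(winner[c("M1", "M0")],
                                       levels = c("M0", "M1")))
  list(confusion = confusion, bms = res,
       pep = vapply(res, function(b) b$pep[["M1"]], numeric(1)))
}
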