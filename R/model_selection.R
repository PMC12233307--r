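#' Configuration of the Bayesian linear-model inversion
#'
#' The three confidence observation models are linear in their
#' coefficients with Gaussian noise, so their log model evidence (free
#' energy) is available in closed form; no variational approximation is
#' needed. Coefficients get a zero-mean Gaussian prior of scale
#' `prior_sd_alpha`; the noise is either fixed (`"fixed_sd"`) or given a
#' conjugate inverse-gamma prior (`"conjugate"`, the default), in which
#' case the coefficient prior covariance is `sigma^2 prior_sd_alpha^2 I`
#' (normal-inverse-gamma form) and the marginal is a multivariate t.
#'
#' @param prior_sd_alpha prior scale of the coefficients (> 0), applied to
#'   standardized predictors when `standardize_predictors` is on.
#' @param noise_model `"conjugate"` or `"fixed_sd"`.
#' @param noise_sd residual SD for `"fixed_sd"`.
#' @param noise_a,noise_b inverse-gamma hyperparameters for `"conjugate"`.
#' @param standardize_predictors z-score non-intercept predictors per
#'   participant before inversion (keeps the prior scale comparable
#'   across models)?
#' @return An object of class `evidence_config`.
#' @export
evidence_config <- function(prior_sd_alpha = 5,
                            noise_model = c("conjugate", "fixed_sd"),
                            noise_sd = 0.1, noise_a = 1e-3, noise_b = 1e-3,
                            standardize_predictors = TRUE) {
  noise_model <- match.arg(noise_model)
  stopifnot(prior_sd_alpha > 0, noise_sd > 0, noise_a > 0, noise_b > 0)
  structure(list(prior_sd_alpha = prior_sd_alpha, noise_model = noise_model,
                 noise_sd = noise_sd, noise_a = noise_a, noise_b = noise_b,
                 standardize_predictors = standardize_predictors),
            class = "evidence_config")
}

#' Design matrix and response of a confidence observation model
#'
#' Builds, for one participant, the response `y = C / scale_max` (the
#' reported confidence normalized to 0-1) and the model's predictors from
#' the per-trial attention times of the selected (`dt1_ms`) and
#' non-selected (`dt2_ms`) option: an intercept, `(dt1 - dt2)` in seconds
#' (sequential and hybrid), and `1 / (dt1 + dt2)` in 1/s (parallel and
#' hybrid). Trials with zero total attention time are dropped for models
#' with an inverse term and reported in the result.
#'
#' @param data per-trial rows with `dt1_ms`, `dt2_ms`, `C`.
#' @param model `"hybrid"`, `"sequential"` or `"parallel"`.
#' @param scale_max top of the rating scale.
#' @param standardize z-score the non-intercept columns? The scaling is
#'   recorded in the attributes so fitted coefficients can be mapped back
#'   to natural units.
#' @return list with `X` (design matrix), `y`, `n_dropped`, and
#'   `scaling` (per-column centre/scale used, `NULL` if none).
#' @export
model_design <- function(data, model = c("hybrid", "sequential", "parallel"),
                         scale_max = 10, standardize = TRUE) {
  model <- match.arg(model)
  d <- data[!is.na(data$dt1_ms) & !is.na(data$dt2_ms) & !is.na(data$C), ]
  total_s <- (d$dt1_ms + d$dt2_ms) / 1000
  n_dropped <- 0L
  if (model %in% c("hybrid", "parallel")) {
    drop <- total_s <= 0
    n_dropped <- sum(drop)
    d <- d[!drop, ]; total_s <- total_s[!drop]
  }
  diff_s <- (d$dt1_ms - d$dt2_ms) / 1000
  X <- switch(model,
    sequential = cbind(intercept = 1, dt_diff = diff_s),
    parallel = cbind(intercept = 1, inv_total = 1 / total_s),
    hybrid = cbind(intercept = 1, dt_diff = diff_s, inv_total = 1 / total_s))
  scaling <- NULL
  if (standardize && nrow(X) > 1) {
    cols <- setdiff(colnames(X), "intercept")
    scaling <- lapply(cols, function(cn) {
      mu <- mean(X[, cn]); s <- sd(X[, cn])
      if (s == 0) s <- 1
      list(column = cn, center = mu, scale = s)
    })
    names(scaling) <- cols
    for (cn in cols)
      X[, cn] <- (X[, cn] - scaling[[cn]]$center) / scaling[[cn]]$scale
  }
  list(X = X, y = d$C / scale_max, n_dropped = n_dropped, scaling = scaling)
}

#' Exact log evidence of a Bayesian linear model
#'
#' Closed-form log marginal likelihood (free energy; the variational
#' bound is tight for this conjugate family) of `y = X b + e` with prior
#' `b ~ N(0, prior_sd_alpha^2 I)`. With the conjugate noise model the
#' prior on `b` scales with the residual variance
#' (`b | s2 ~ N(0, s2 prior_sd_alpha^2 I)`, `s2 ~ IG(a, b)`) and the
#' marginal is multivariate t; with fixed noise the marginal is Gaussian.
#'
#' @param X design matrix (more rows than columns).
#' @param y response vector.
#' @param cfg an [evidence_config()].
#' @return Log evidence in nats.
#' @export
log_evidence_linear <- function(X, y, cfg = evidence_config()) {
  stopifnot(inherits(cfg, "evidence_config"))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than predictors")
  if (length(y) != n) stop("X and y sizes disagree")
  v0 <- cfg$prior_sd_alpha^2
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  if (cfg$noise_model == "fixed_sd") {
    s2 <- cfg$noise_sd^2
    # marginal y ~ N(0, s2 I + v0 X X'): integrate the coefficients out
    # with posterior precision M = X'X / s2 + I / v0
    M <- XtX / s2 + diag(1 / v0, p)
    cholM <- tryCatch(chol(M), error = function(e) stop("singular Gram matrix"))
    h <- Xty / s2
    m <- backsolve(cholM, backsolve(cholM, h, transpose = TRUE))
    logdetM <- 2 * sum(log(diag(cholM)))
    -0.5 * (n * log(2 * pi * s2) + p * log(v0) + logdetM +
              yty / s2 - sum(h * m))
  } else {
    A <- XtX + diag(1 / v0, p)       # posterior precision (up to s2)
    cholA <- tryCatch(chol(A), error = function(e) stop("singular Gram matrix"))
    bn <- backsolve(cholA, backsolve(cholA, Xty, transpose = TRUE))
    logdetA <- 2 * sum(log(diag(cholA)))
    quad <- yty - sum(Xty * bn)       # y'y - bn' A bn
    a0 <- cfg$noise_a; b0 <- cfg$noise_b
    an <- a0 + n / 2
    bn_ig <- b0 + quad / 2
    if (bn_ig <= 0) stop("degenerate posterior scale; check inputs")
    lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn_ig) -
      (n / 2) * log(2 * pi) - (p / 2) * log(v0) - 0.5 * logdetA
  }
}

#' Score the three confidence models for every participant
#'
#' Builds each model's design from the per-trial attention times and
#' computes the conjugate log evidence, yielding the participants x
#' models free-energy table submitted to [rfx_bms()], plus the posterior
#' mean coefficients used for model predictions.
#'
#' @param data per-trial rows with `participant_id`, `dt1_ms`, `dt2_ms`,
#'   `C`.
#' @param cfg an [evidence_config()].
#' @param scale_max top of the rating scale.
#' @param models model names, in the column order of the output.
#' @return list with `F` (matrix participants x models of log evidences),
#'   `posterior` (per participant and model: posterior mean coefficients
#'   in natural units), `n_dropped` per participant.
#' @export
fit_confidence_models <- function(data, cfg = evidence_config(),
                                  scale_max = 10,
                                  models = c("hybrid", "sequential",
                                             "parallel")) {
  ids <- unique(data$participant_id)
  Fm <- matrix(NA_real_, length(ids), length(models),
               dimnames = list(ids, models))
  posterior <- list()
  n_dropped <- setNames(integer(length(ids)), ids)
  for (id in ids) {
    d <- data[data$participant_id == id, ]
    for (m in models) {
      des <- model_design(d, m, scale_max,
                          standardize = cfg$standardize_predictors)
      Fm[id, m] <- log_evidence_linear(des$X, des$y, cfg)
      posterior[[paste(id, m, sep = ".")]] <- data.frame(
        participant_id = id, model = m,
        t(posterior_mean_natural(des, cfg)))
      n_dropped[id] <- max(n_dropped[id], des$n_dropped)
    }
  }
  list(F = Fm, posterior = rbind_rows(unname(posterior)),
       n_dropped = n_dropped)
}

# Posterior mean coefficients mapped back to natural (unstandardized)
# units, named alpha0 / alpha1 / alpha2 by predictor role.
posterior_mean_natural <- function(des, cfg) {
  X <- des$X; y <- des$y
  p <- ncol(X)
  A <- crossprod(X) + diag(1 / cfg$prior_sd_alpha^2, p)
  b <- solve(A, crossprod(X, y))[, 1]
  names(b) <- colnames(X)
  if (!is.null(des$scaling)) {
    for (cn in names(des$scaling)) {
      sc <- des$scaling[[cn]]
      b[cn] <- b[cn] / sc$scale
      b["intercept"] <- b["intercept"] - b[cn] * sc$center
    }
  }
  out <- c(alpha0 = unname(b["intercept"]),
           alpha1 = NA_real_, alpha2 = NA_real_)
  if ("dt_diff" %in% names(b)) out["alpha1"] <- unname(b["dt_diff"])
  if ("inv_total" %in% names(b)) {
    slot <- if ("dt_diff" %in% names(b)) "alpha2" else "alpha1"
    out[slot] <- unname(b["inv_total"])
  }
  out
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants with
#' a Dirichlet population distribution. Given the participants x models
#' log-evidence matrix `F`, iterates the standard variational updates -
#' posterior model assignments
#' `u_nk ~ exp(F_nk + psi(alpha_k) - psi(sum alpha))` normalized over
#' models, then `alpha_k = alpha0_k + sum_n u_nk` - to convergence. Model
#' frequencies are the Dirichlet mean `alpha / sum(alpha)`; exceedance
#' probabilities (the probability that a model is the most frequent in
#' the population) are estimated from seeded Dirichlet draws.
#'
#' @param F matrix of log evidences, participants x models (finite).
#' @param alpha0 Dirichlet prior counts.
#' @param tol convergence tolerance on `max |delta alpha|`.
#' @param max_iter iteration cap (error on non-convergence).
#' @param n_dirichlet_samples Monte-Carlo draws for the exceedance
#'   probabilities.
#' @param seed integer seed for the Dirichlet sampling.
#' @return An object of class `bms_result`: list with `dirichlet_alpha`,
#'   `model_frequency`, `exceedance_prob`, `assignments` (u matrix),
#'   `n_iter`, `n_dirichlet_samples`, `seed`.
#' @export
rfx_bms <- function(F, alpha0 = c(1, 1, 1), tol = 1e-6, max_iter = 1e4,
                    n_dirichlet_samples = 1e6, seed = 1L) {
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("F must be finite")
  K <- ncol(F)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, K)
  stopifnot(length(alpha0) == K, all(alpha0 > 0))
  alpha <- alpha0
  u <- NULL
  for (it in seq_len(max_iter)) {
    lg <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    u <- exp(lg)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
    if (it == max_iter)
      stop("RFX-BMS did not converge after ", max_iter,
           " iterations (last delta = ", format(delta), ")")
  }
  ep <- withr::with_seed(seed, {
    draws <- matrix(rgamma(n_dirichlet_samples * K,
                           shape = rep(alpha, each = n_dirichlet_samples)),
                    ncol = K)
    win <- max.col(draws, ties.method = "first")
    tabulate(win, K) / n_dirichlet_samples
  })
  res <- list(dirichlet_alpha = setNames(alpha, colnames(F)),
              model_frequency = setNames(alpha / sum(alpha), colnames(F)),
              exceedance_prob = setNames(ep, colnames(F)),
              assignments = u, n_iter = it,
              n_dirichlet_samples = n_dirichlet_samples, seed = seed)
  class(res) <- "bms_result"
  res
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> random-effects Bayesian model selection\n")
  m <- rbind(`Dirichlet alpha` = x$dirichlet_alpha,
             `model frequency` = x$model_frequency,
             `exceedance prob` = x$exceedance_prob)
  print(round(m, 4))
  invisible(x)
}

#' Model-recovery confusion matrix
#'
#' For each generative confidence model, simulates a cohort, recomputes
#' the attention times from the gaze streams, inverts all three models
#' and runs [rfx_bms()], recording which model wins by exceedance
#' probability. Diagonal dominance of the resulting confusion table is
#' the standard sanity check of the whole selection procedure.
#'
#' @param base_cfg a [generative_config()] used as template; its `model`
#'   and `seed` fields are overridden.
#' @param evidence_cfg an [evidence_config()].
#' @param n_reps cohorts per generative model.
#' @param seed integer seed.
#' @param n_dirichlet_samples draws for the exceedance probabilities
#'   (reduced by default to keep recovery runs fast).
#' @param use_truth_dt use the generator's true attention times instead
#'   of re-extracting them from gaze (faster; default FALSE exercises the
#'   full pipeline).
#' @return list with `confusion` (3x3 matrix of winner counts, generative
#'   model in rows) and `details` (one row per run).
#' @export
model_recovery <- function(base_cfg = generative_config(),
                           evidence_cfg = evidence_config(), n_reps = 1,
                           seed = 1L, n_dirichlet_samples = 1e5,
                           use_truth_dt = FALSE) {
  models <- c("hybrid", "sequential", "parallel")
  confusion <- matrix(0L, 3, 3, dimnames = list(generated = models,
                                                winner = models))
  details <- list()
  for (gen in models) {
    for (rep in seq_len(n_reps)) {
      cfg <- base_cfg
      cfg$model <- gen
      # the pure-inverse-time readout has no alpha2 slot
      if (gen != "hybrid" && !is.null(cfg$alpha$alpha2)) {
        if (gen == "parallel") cfg$alpha$alpha1 <- cfg$alpha$alpha2
        cfg$alpha$alpha2 <- NULL
      }
      cfg$seed <- stage_seed(seed + 131 * rep + match(gen, models), "recover")
      ds <- simulate_dataset(cfg)
      tab <- if (use_truth_dt) {
        merge(ds$truth[, c("participant_id", "trial_index", "dt1_ms",
                           "dt2_ms")],
              ds$trials[, c("participant_id", "trial_index", "C")],
              by = c("participant_id", "trial_index"))
      } else {
        attention_times_table(ds$gaze, ds$trials, cfg$geometry,
                              span = cfg$dt_span,
                              stim_off_ms = cfg$timeline$stim_off_ms)
      }
      tab <- tab[!is.na(tab$C), ]
      fits <- fit_confidence_models(tab, evidence_cfg,
                                    scale_max = cfg$rating_scale_max)
      bms <- rfx_bms(fits$F, n_dirichlet_samples = n_dirichlet_samples,
                     seed = cfg$seed)
      winner <- names(which.max(bms$exceedance_prob))
      confusion[gen, winner] <- confusion[gen, winner] + 1L
      details[[paste(gen, rep)]] <- data.frame(
        generated = gen, rep = rep, winner = winner,
        ep_winner = max(bms$exceedance_prob),
        mf_winner = bms$model_frequency[winner])
    }
  }
  list(confusion = confusion, details = rbind_rows(unname(details)))
}

#' Per-trial attention times of selected vs non-selected option
#'
#' Recovers, from the measured gaze streams, the observation time of the
#' selected (`dt1_ms`) and non-selected (`dt2_ms`) option over the chosen
#' span - the inputs of the confidence observation models. Only trials
#' with a response are returned.
#'
#' @param gaze,trials dataset tables (see [simulate_dataset()] formats).
#' @param geometry a [screen_geometry()].
#' @param span `"soff_ud"` (GO to decision, default) or `"son_soff_ud"`.
#' @param stim_off_ms,min_dwell_ms,max_gap_ms as in
#'   [compute_metrics_table()].
#' @return data.frame with `participant_id`, `trial_index`, `dt1_ms`,
#'   `dt2_ms`, `C`.
#' @export
attention_times_table <- function(gaze, trials, geometry,
                                  span = c("soff_ud", "son_soff_ud"),
                                  stim_off_ms = 4000, min_dwell_ms = 100,
                                  max_gap_ms = 80) {
  span <- match.arg(span)
  metrics <- compute_metrics_table(gaze, trials, geometry, stim_off_ms,
                                   min_dwell_ms, max_gap_ms)
  use <- if (span == "soff_ud") "SOffUD" else c("SOn", "SOffUD")
  m <- metrics[metrics$interval %in% use, ]
  agg <- stats::aggregate(cbind(t_left_ms, t_right_ms) ~
                            participant_id + trial_index, data = m, FUN = sum)
  if (!"selected_side" %in% names(trials)) {
    trials$selected_side <- selected_side_from_button(trials$button,
                                                      trials$experiment)
  }
  out <- merge(agg, trials[, c("participant_id", "trial_index",
                               "selected_side", "C")],
               by = c("participant_id", "trial_index"))
  out <- out[out$selected_side %in% c("left", "right"), ]
  sel_right <- out$selected_side == "right"
  out$dt1_ms <- ifelse(sel_right, out$t_right_ms, out$t_left_ms)
  out$dt2_ms <- ifelse(sel_right, out$t_left_ms, out$t_right_ms)
  out[, c("participant_id", "trial_index", "dt1_ms", "dt2_ms", "C")]
}
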