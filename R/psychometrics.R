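#' Quartile-bin trials by log looking-time ratio
#'
#' Ranks trials by their log looking-time ratio and splits them into four
#' equal-count bins (any remainder goes to the lower bins). Each bin is
#' summarised by the within-bin median log-ratio and the fraction of
#' right-button choices.
#'
#' @param log_ratios per-trial log looking-time ratios.
#' @param right_choice logical (or 0/1) vector: right button pressed?
#' @return data.frame with 4 rows: `x_q` (median log-ratio), `p_q`
#'   (proportion of right choices), `n_q` (trial count).
#' @export
quartile_bins <- function(log_ratios, right_choice) {
  stopifnot(length(log_ratios) == length(right_choice))
  ok <- !is.na(log_ratios) & !is.na(right_choice)
  log_ratios <- log_ratios[ok]
  right_choice <- as.numeric(right_choice[ok])
  n <- length(log_ratios)
  if (n < 8) stop("need at least 8 valid trials to form quartile bins")
  ord <- order(log_ratios)
  base <- n %/% 4L
  rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= rem)  # remainder to lower bins
  bin <- rep(seq_len(4L), times = sizes)
  x_sorted <- log_ratios[ord]
  y_sorted <- right_choice[ord]
  data.frame(
    x_q = vapply(1:4, function(q) median(x_sorted[bin == q]), numeric(1)),
    p_q = vapply(1:4, function(q) mean(y_sorted[bin == q]), numeric(1)),
    n_q = sizes)
}

#' Fit the psychometric logistic to quartile bins
#'
#' Maximises the binomial likelihood of the binned right-choice counts
#' under `P_R = 1 / (1 + exp(-(beta0 + beta1 * x)))` where `x` is the log
#' looking-time ratio. Fitting uses iteratively reweighted least squares
#' on the four points; a separated fit (all-or-nothing bins) is capped at
#' `|beta1| <= beta1_max` and flagged.
#'
#' @param bins data.frame from [quartile_bins()] (columns `x_q`, `p_q`,
#'   `n_q`).
#' @param beta1_max cap on the slope magnitude under separation.
#' @return list with `beta0`, `beta1`, `deviance`, and `capped` (was the
#'   slope truncated?).
#' @export
fit_logistic <- function(bins, beta1_max = 25) {
  stopifnot(nrow(bins) == 4, all(is.finite(bins$x_q)))
  f <- .fit_logistic_fast(bins$x_q, bins$p_q, bins$n_q, beta1_max)
  list(beta0 = f[1], beta1 = f[2], deviance = f[3], capped = f[4] > 0)
}

# Core IRLS fit; returns c(beta0, beta1, deviance, capped).
.fit_logistic_fast <- function(x, p, n, beta1_max = 25) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, x), p, weights = n, family = binomial()))
  b <- unname(fit$coefficients)
  capped <- 0
  if (!all(is.finite(b)) || abs(b[2]) > beta1_max) {
    capped <- 1
    b[2] <- sign(if (is.finite(b[2])) b[2] else cor(x, p)) * beta1_max
    # refit the intercept at the capped slope
    off <- b[2] * x
    fit0 <- suppressWarnings(
      glm.fit(matrix(1, length(x)), p, weights = n, family = binomial(),
              offset = off))
    b[1] <- fit0$coefficients[1]
  }
  dev <- suppressWarnings(binom_deviance(x, p, n, b))
  c(b[1], b[2], dev, capped)
}

binom_deviance <- function(x, p, n, b) {
  mu <- plogis(b[1] + b[2] * x)
  eps <- 1e-12
  2 * sum(n * (p * log(pmax(p, eps) / mu) +
                 (1 - p) * log(pmax(1 - p, eps) / (1 - mu))))
}

#' Shuffle-permutation test of the psychometric slope
#'
#' Permutes the four (p_q, n_q) pairs across the four quartile positions,
#' refits the logistic for each shuffle, and locates the observed slope in
#' the shuffle distribution. With four bins there are only 24 distinct
#' orderings, so the test is evaluated either by drawing `n_shuffles`
#' orderings with replacement (matching the classical 10,000-shuffle
#' recipe) or by exact enumeration of all 24. The p-value uses the
#' add-one correction `(1 + #\{beta1_shuffle >= beta1_obs\}) / (n + 1)` and
#' the significance flag applies the 95th-percentile criterion to the
#' shuffle distribution.
#'
#' @param bins data.frame from [quartile_bins()].
#' @param n_shuffles number of sampled shuffles (ignored when
#'   `exact = TRUE`).
#' @param seed integer seed for the sampled mode (`NULL`: current stream).
#' @param exact enumerate all 24 orderings instead of sampling?
#' @param beta1_max slope cap passed to the refits.
#' @return list with `beta1_obs`, `perm_p`, `significant` (observed slope
#'   strictly above the 95th percentile of the shuffle slopes), and
#'   `beta1_shuffle_unique` (the 24 slopes, one per ordering).
#' @export
permutation_test_beta1 <- function(bins, n_shuffles = 10000, seed = NULL,
                                   exact = FALSE, beta1_max = 25) {
  stopifnot(nrow(bins) == 4)
  obs <- .fit_logistic_fast(bins$x_q, bins$p_q, bins$n_q, beta1_max)[2]
  perms <- all_perms4()
  b_perm <- vapply(seq_len(nrow(perms)), function(i) {
    idx <- perms[i, ]
    .fit_logistic_fast(bins$x_q, bins$p_q[idx], bins$n_q[idx], beta1_max)[2]
  }, numeric(1))
  run <- function() {
    draw <- if (exact) {
      seq_len(24L)
    } else {
      sample.int(24L, n_shuffles, replace = TRUE)
    }
    b_shuf <- b_perm[draw]
    n <- length(b_shuf)
    list(beta1_obs = obs,
         perm_p = (1 + sum(b_shuf >= obs)) / (n + 1),
         significant = obs > quantile(b_shuf, 0.95, names = FALSE),
         beta1_shuffle_unique = b_perm)
  }
  if (is.null(seed) || exact) run() else withr::with_seed(seed, run())
}

# The 24 orderings of 4 elements, one per row.
all_perms4 <- function() {
  idx <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  m <- as.matrix(idx[apply(idx, 1, function(r) length(unique(r)) == 4), ])
  dimnames(m) <- NULL
  m
}

#' Group-level t-test with JZS Bayes factor
#'
#' One-sample, paired or two-sample t-test of participant-level values,
#' reported with the JZS (Cauchy-prior) Bayes factor in favour of the
#' null.
#'
#' @param values numeric vector (participant-level statistics).
#' @param values2 second group for two-sample / paired comparisons.
#' @param mu0 null value for the one-sample test.
#' @param paired paired comparison (requires `values2`)?
#' @param prior_scale Cauchy prior scale of the Bayes factor.
#' @return data.frame with `t_stat`, `df`, `ci_low`, `ci_high`, `p_value`,
#'   `bf01`, `n1`, `n2`.
#' @export
group_ttest <- function(values, values2 = NULL, mu0 = 0, paired = FALSE,
                        prior_scale = sqrt(2) / 2) {
  values <- values[!is.na(values)]
  if (!is.null(values2)) values2 <- values2[!is.na(values2)]
  if (length(values) < 2) stop("need at least 2 values per group")
  if (is.null(values2)) {
    if (sd(values) == 0) stop("zero variance in values")
    tt <- t.test(values, mu = mu0)
    n1 <- length(values); n2 <- NA_integer_
    bf <- jzs_bayes_factor(unname(tt$statistic), n1 = n1,
                           prior_scale = prior_scale)
  } else if (paired) {
    stopifnot(length(values) == length(values2))
    d <- values - values2
    if (sd(d) == 0) stop("zero variance in paired differences")
    tt <- t.test(values, values2, paired = TRUE)
    n1 <- length(values); n2 <- n1
    bf <- jzs_bayes_factor(unname(tt$statistic), n1 = n1,
                           prior_scale = prior_scale)
  } else {
    if (sd(values) == 0 && sd(values2) == 0)
      stop("zero variance in both groups")
    tt <- t.test(values, values2, var.equal = TRUE)
    n1 <- length(values); n2 <- length(values2)
    bf <- jzs_bayes_factor(unname(tt$statistic), n1 = n1, n2 = n2,
                           prior_scale = prior_scale)
  }
  data.frame(t_stat = unname(tt$statistic), df = unname(tt$parameter),
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             p_value = tt$p.value, bf01 = bf, n1 = n1, n2 = n2)
}

#' JZS (Cauchy-prior) Bayes factor for a t-test
#'
#' Default Bayes factor for the point null against a Cauchy prior with
#' scale `prior_scale` on the standardized effect size, computed by
#' numerical integration over the prior. For two-sample designs the
#' effective sample size is `n1 * n2 / (n1 + n2)` with `n1 + n2 - 2`
#' degrees of freedom.
#'
#' @param t_stat observed t statistic.
#' @param n1 sample size (first group).
#' @param n2 optional second-group size (two-sample design).
#' @param prior_scale Cauchy scale `r` (default `sqrt(2)/2`).
#' @return `bf01`, the Bayes factor in favour of the null (`1/bf10`).
#' @export
jzs_bayes_factor <- function(t_stat, n1, n2 = NULL, prior_scale = sqrt(2) / 2) {
  stopifnot(is.finite(t_stat), n1 >= 2)
  if (is.null(n2)) {
    n_eff <- n1; df <- n1 - 1
  } else {
    n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  r <- prior_scale
  # marginal likelihood under H1, integrating the noncentral t over the
  # Cauchy(0, r) prior via the scale-mixture (inverse-gamma on g) form
  integrand <- function(g) {
    (1 + n_eff * g)^(-1 / 2) *
      (1 + t_stat^2 / ((1 + n_eff * g) * df))^(-(df + 1) / 2) *
      (2 * pi)^(-1 / 2) * r * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }
  m1 <- integrate(integrand, 0, Inf, rel.tol = 1e-10,
                  stop.on.error = FALSE)
  if (m1$message != "OK" && m1$message != "the integral is probably divergent")
    stop("JZS quadrature did not converge: ", m1$message)
  m0 <- (1 + t_stat^2 / df)^(-(df + 1) / 2)
  unname(m0 / m1$value)
}

#' Two-sample Kolmogorov-Smirnov comparison of decision times
#'
#' @param dt_a,dt_b decision-time samples (ms), both nonempty.
#' @return list with `D` (statistic) and `p_value`.
#' @export
compare_dt_distributions <- function(dt_a, dt_b) {
  dt_a <- dt_a[!is.na(dt_a)]; dt_b <- dt_b[!is.na(dt_b)]
  stopifnot(length(dt_a) > 0, length(dt_b) > 0)
  ks <- suppressWarnings(ks.test(dt_a, dt_b))
  list(D = unname(ks$statistic), p_value = ks$p.value)
}

#' Per-participant confidence / decision-time correlation
#'
#' Pearson correlation between the reported confidence rating and the
#' decision time over each participant's valid trials, followed by a
#' one-sample group t-test of the correlation coefficients against zero.
#' Participants with fewer than `min_trials` valid trials or zero variance
#' in either variable are skipped and listed.
#'
#' @param trials trial table with `participant_id`, `C`,
#'   `decision_time_ms` (already exclusion-filtered).
#' @param min_trials minimum valid trials per participant.
#' @param fisher_z test Fisher-z transformed correlations instead of raw
#'   `r`?
#' @return list with `per_participant` (id, r, n), `group` (a
#'   [group_ttest()] row, `NULL` with < 2 usable participants), and
#'   `skipped`.
#' @export
correlate_confidence_dt <- function(trials, min_trials = 3,
                                    fisher_z = FALSE) {
  ids <- unique(trials$participant_id)
  rows <- list(); skipped <- character(0)
  for (id in ids) {
    d <- trials[trials$participant_id == id &
                  !is.na(trials$C) & !is.na(trials$decision_time_ms), ]
    if (nrow(d) < min_trials || sd(d$C) == 0 ||
        sd(d$decision_time_ms) == 0) {
      skipped <- c(skipped, id)
      next
    }
    rows[[id]] <- data.frame(participant_id = id,
                             r = cor(d$C, d$decision_time_ms),
                             n = nrow(d))
  }
  per <- rbind_rows(rows)
  vals <- if (fisher_z) atanh(pmin(pmax(per$r, -0.999999), 0.999999)) else per$r
  group <- if (length(vals) >= 2 && sd(vals) > 0) group_ttest(vals) else NULL
  list(per_participant = per, group = group, skipped = skipped)
}

#' Psychometric fits for a whole cohort
#'
#' For every participant and analysis interval: bins the trials into
#' looking-time-ratio quartiles, fits the logistic, and runs the
#' shuffle-permutation test. Right-choice is coded from the button pressed
#' (not the image side), which is what makes the motor-reversal variant
#' produce negative slopes.
#'
#' @param metrics metrics table from [compute_metrics_table()].
#' @param trials exclusion-filtered trial table.
#' @param intervals which intervals to fit.
#' @param n_shuffles,seed,beta1_max passed to [permutation_test_beta1()].
#' @param min_trials minimum valid trials per participant and interval.
#' @return data.frame with one row per participant x interval: `beta0`,
#'   `beta1`, `perm_p`, `significant`, `n_trials`, `capped` (plus skipped
#'   participants flagged with `NA` fits).
#' @export
fit_psychometrics <- function(metrics, trials,
                              intervals = c("SOn", "SOffUD"),
                              n_shuffles = 10000, seed = NULL,
                              beta1_max = 25, min_trials = 8) {
  merged <- merge(metrics[metrics$interval %in% intervals,
                          c("participant_id", "trial_index", "interval",
                            "log_ratio")],
                  trials[, c("participant_id", "trial_index", "button")],
                  by = c("participant_id", "trial_index"))
  merged <- merged[merged$button != "none", ]
  ids <- unique(merged$participant_id)
  rows <- list()
  k <- 0L
  for (id in ids) {
    for (iv in intervals) {
      k <- k + 1L
      d <- merged[merged$participant_id == id & merged$interval == iv, ]
      d <- d[is.finite(d$log_ratio), ]
      if (nrow(d) < min_trials) {
        rows[[k]] <- data.frame(participant_id = id, interval = iv,
                                beta0 = NA_real_, beta1 = NA_real_,
                                perm_p = NA_real_, significant = NA,
                                n_trials = nrow(d), capped = NA)
        next
      }
      bins <- quartile_bins(d$log_ratio, d$button == "right")
      fit <- fit_logistic(bins, beta1_max)
      pt <- permutation_test_beta1(
        bins, n_shuffles,
        seed = if (is.null(seed)) NULL else stage_seed(seed + k, "psychometrics"),
        beta1_max = beta1_max)
      rows[[k]] <- data.frame(participant_id = id, interval = iv,
                              beta0 = fit$beta0, beta1 = fit$beta1,
                              perm_p = pt$perm_p,
                              significant = pt$significant,
                              n_trials = nrow(d), capped = fit$capped)
    }
  }
  rbind_rows(rows)
}
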