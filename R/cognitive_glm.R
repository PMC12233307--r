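#' Z-score a vector
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation, computed
#' over non-missing values.
#'
#' @param values numeric vector with at least two distinct values.
#' @param name label used in the error message for degenerate input.
#' @return Standardized vector (NAs preserved in place).
#' @export
zscore <- function(values, name = deparse(substitute(values))) {
  ok <- !is.na(values)
  if (sum(ok) < 2 || sd(values[ok]) == 0)
    stop("cannot z-score '", name, "': fewer than 2 distinct values")
  out <- values
  out[ok] <- (values[ok] - mean(values[ok])) / sd(values[ok])
  out
}

# Build the z-scored rating design for one participant's valid trials.
rating_design <- function(d, interactions = FALSE) {
  X <- cbind(intercept = 1,
             C = zscore(d$C, "C"), R = zscore(d$R, "R"),
             I = zscore(d$I, "I"), CM = zscore(d$CM, "CM"))
  if (interactions) {
    X <- cbind(X,
               "R:I" = X[, "R"] * X[, "I"],
               "R:CM" = X[, "R"] * X[, "CM"],
               "I:CM" = X[, "I"] * X[, "CM"])
  }
  X
}

ols_fit <- function(X, y) {
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)  # rank-deficient design
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  data.frame(coefficient = colnames(X), estimate = unname(fit$coefficients),
             se = unname(se), stringsAsFactors = FALSE)
}

#' Observation-time regression on the cognitive indices
#'
#' Ordinary least squares of the proportion of interval time spent on the
#' selected option against the z-scored confidence (C), reward (R),
#' interest (I) and complexity (CM) ratings plus the RxI, RxCM and IxCM
#' interactions (products of the z-scored main effects). Fitted per
#' participant and interval. The proportion response is left on its
#' natural 0-1 scale.
#'
#' @param data one participant's merged trials x metrics rows for one
#'   interval: columns `t_selected_frac`, `C`, `R`, `I`, `CM`.
#' @param min_trials minimum number of complete trials (must exceed the 8
#'   parameters).
#' @return data.frame with `coefficient`, `estimate`, `se`, and attribute
#'   `n_trials`; `NULL` for a rank-deficient design.
#' @export
fit_observation_glm <- function(data, min_trials = 12) {
  d <- data[complete.cases(data[, c("t_selected_frac", "C", "R", "I", "CM")]), ]
  if (nrow(d) < min_trials)
    stop("need at least ", min_trials, " complete trials, got ", nrow(d))
  X <- rating_design(d, interactions = TRUE)
  out <- ols_fit(X, d$t_selected_frac)
  if (!is.null(out)) attr(out, "n_trials") <- nrow(d)
  out
}

#' Change-of-target regression on the cognitive indices
#'
#' Ordinary least squares of the z-scored alternation metric (`n_cot` or
#' `f_cot`) against the z-scored C, R, I, CM ratings (no interactions),
#' per participant and interval.
#'
#' @param data one participant's rows for one interval: the metric column
#'   plus `C`, `R`, `I`, `CM`.
#' @param metric `"n_cot"` or `"f_cot"`.
#' @param min_trials minimum number of complete trials.
#' @return As [fit_observation_glm()].
#' @export
fit_cot_glm <- function(data, metric = c("n_cot", "f_cot"), min_trials = 8) {
  metric <- match.arg(metric)
  d <- data[complete.cases(data[, c(metric, "C", "R", "I", "CM")]), ]
  if (nrow(d) < min_trials)
    stop("need at least ", min_trials, " complete trials, got ", nrow(d))
  X <- rating_design(d, interactions = FALSE)
  out <- ols_fit(X, zscore(d[[metric]], metric))
  if (!is.null(out)) attr(out, "n_trials") <- nrow(d)
  out
}

#' Group-level tests of per-participant regression coefficients
#'
#' One-sample t-test of each coefficient across participants against
#' zero, with its JZS Bayes factor.
#'
#' @param fits data.frame stacking per-participant fits, with columns
#'   `participant_id`, `coefficient`, `estimate` (and optionally grouping
#'   columns such as `interval` / `response`, which are preserved).
#' @param by extra grouping columns to test within.
#' @param p_adjust `"none"` (default, mirroring uncorrected reporting) or
#'   any method of [stats::p.adjust()] applied across the returned tests.
#' @return data.frame, one row per coefficient (x grouping), with the
#'   [group_ttest()] columns and `n_participants`.
#' @export
group_coefficient_tests <- function(fits, by = intersect(
                                      c("response", "interval"), names(fits)),
                                    p_adjust = "none") {
  if (length(unique(fits$participant_id)) < 2)
    stop("need at least 2 participants with valid fits")
  groups <- unique(fits[, c(by, "coefficient"), drop = FALSE])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(fits))
    for (col in c(by, "coefficient"))
      sel <- sel & fits[[col]] == groups[[col]][i]
    est <- fits$estimate[sel]
    est <- est[!is.na(est)]
    res <- cbind(groups[i, , drop = FALSE],
                 group_ttest(est), n_participants = length(est))
    res
  })
  out <- rbind_rows(rows)
  if (p_adjust != "none")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Cognitive-factor regressions for a whole cohort
#'
#' Runs [fit_observation_glm()] (response `t_selected_frac`) and
#' [fit_cot_glm()] (responses `n_cot`, `f_cot`) for every participant and
#' interval, and stacks the coefficients. Participants whose design is
#' rank-deficient or who have too few complete trials are reported in
#' `skipped`, not silently dropped.
#'
#' @param metrics metrics table from [compute_metrics_table()].
#' @param trials exclusion-filtered trial table with the rating columns.
#' @param intervals intervals to fit.
#' @return list with `coefficients` (participant, response, interval,
#'   coefficient, estimate, se, n_trials) and `skipped` (participant,
#'   response, interval, reason).
#' @export
fit_cognitive_glms <- function(metrics, trials,
                               intervals = c("SOn", "SOffUD", "SOffPD")) {
  merged <- merge(metrics, trials[, c("participant_id", "trial_index",
                                      "C", "R", "I", "CM")],
                  by = c("participant_id", "trial_index"))
  specs <- list(
    list(response = "t_selected_frac",
         fit = function(d) fit_observation_glm(d)),
    list(response = "n_cot", fit = function(d) fit_cot_glm(d, "n_cot")),
    list(response = "f_cot", fit = function(d) fit_cot_glm(d, "f_cot")))
  rows <- list(); skipped <- list(); k <- 0L
  for (id in unique(merged$participant_id)) {
    for (iv in intervals) {
      d <- merged[merged$participant_id == id & merged$interval == iv, ]
      for (s in specs) {
        k <- k + 1L
        res <- tryCatch(s$fit(d), error = function(e) conditionMessage(e))
        if (is.character(res) || is.null(res)) {
          skipped[[k]] <- data.frame(
            participant_id = id, response = s$response, interval = iv,
            reason = if (is.null(res)) "rank-deficient design" else res)
        } else {
          rows[[k]] <- cbind(participant_id = id, response = s$response,
                             interval = iv, res,
                             n_trials = attr(res, "n_trials"))
        }
      }
    }
  }
  list(coefficients = rbind_rows(rows),
       skipped = rbind_rows(skipped))
}
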