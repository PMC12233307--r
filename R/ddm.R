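#' Drift-diffusion parameters
#'
#' Parameters of the bounded evidence accumulator. Evidence `x(t)` starts
#' at 0 and evolves as `dx = mu dt + sigma dW`; the first crossing of the
#' symmetric bounds at `theta` / `-theta` determines the choice (option 1
#' for the upper bound) and the decision time. For the sequential
#' (gaze-gated) variant the drift is `mu1` while option 1 is attended and
#' `-mu2` while option 2 is attended; under the symmetric-value assumption
#' `mu1 = -mu2 = mu0/2` the drift magnitude is constant.
#'
#' @param mu drift of the parallel accumulator (difference of option
#'   values, 1/s). Ignored by the sequential simulator.
#' @param mu1,mu2 option values for the sequential accumulator (1/s).
#' @param mu0 convenience for the symmetric case: sets `mu1 = mu0/2`,
#'   `mu2 = -mu0/2` and `mu = mu0` unless these are given explicitly.
#' @param sigma diffusion noise scale (> 0).
#' @param theta bound magnitude (> 0).
#' @param dt_ms Euler integration step, ms.
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(mu = 0, mu1 = NULL, mu2 = NULL, mu0 = NULL,
                       sigma = 1, theta = 1, dt_ms = 1) {
  if (!is.null(mu0)) {
    if (is.null(mu1)) mu1 <- mu0 / 2
    if (is.null(mu2)) mu2 <- -mu0 / 2
    if (missing(mu)) mu <- mu0
  }
  if (is.null(mu1)) mu1 <- mu / 2
  if (is.null(mu2)) mu2 <- -mu / 2
  stopifnot(sigma > 0, theta > 0, dt_ms > 0)
  p <- list(mu = mu, mu1 = mu1, mu2 = mu2, sigma = sigma, theta = theta,
            dt_ms = dt_ms)
  if (dt_ms / 1000 > (theta / sigma)^2 / 20)
    warning("integration step is coarse relative to (theta/sigma)^2; ",
            "first-passage estimates may be biased")
  class(p) <- "ddm_params"
  p
}

# First crossing of +/- theta given a per-step drift vector (1/s units).
# Returns the crossing step index (NA if none), the sign, and the full
# evidence path. Shared by both public simulators and the generator.
.fp_run <- function(drift_per_s, sigma, theta, dt_s) {
  n <- length(drift_per_s)
  x <- cumsum(drift_per_s * dt_s + sigma * sqrt(dt_s) * rnorm(n))
  hit <- which(abs(x) >= theta)
  if (length(hit) == 0L) {
    list(step = NA_integer_, sign = 0, x = x)
  } else {
    k <- hit[1L]
    list(step = k, sign = sign(x[k]), x = x)
  }
}

#' Simulate one parallel drift-diffusion trial
#'
#' Euler-Maruyama integration of the constant-drift accumulator until the
#' first bound crossing or `max_time_s`, whichever comes first.
#'
#' @param params a [ddm_params()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param max_time_s simulation horizon in seconds; if no bound is reached
#'   the trial ends with `choice = "none"`.
#' @param return_trace keep the full evidence path (`times`, `x`)?
#' @return A list of class `sim_trace` with `choice` (`"option1"`,
#'   `"option2"` or `"none"`), `decision_time_ms`, and for the sequential
#'   simulator the per-option attention times `dt1_ms`, `dt2_ms` and
#'   accumulated evidence `dx1`, `dx2`.
#' @export
simulate_ddm_parallel <- function(params, seed = NULL, max_time_s = 8,
                                  return_trace = FALSE) {
  stopifnot(inherits(params, "ddm_params"))
  run_one <- function() {
    dt_s <- params$dt_ms / 1000
    n <- ceiling(max_time_s / dt_s)
    r <- .fp_run(rep(params$mu, n), params$sigma, params$theta, dt_s)
    trace_out(r, params, dt_s, attended = NULL, return_trace)
  }
  if (is.null(seed)) run_one() else withr::with_seed(seed, run_one())
}

#' Simulate one sequential (gaze-gated) drift-diffusion trial
#'
#' As [simulate_ddm_parallel()], but the drift follows the attention
#' schedule: `mu1` while option 1 is attended, `-mu2` while option 2 is
#' attended, and 0 during saccade gaps not covered by the schedule.
#'
#' @inheritParams simulate_ddm_parallel
#' @param schedule a data.frame with columns `side` (`"option1"`/
#'   `"option2"`, or `"right"`/`"left"` which map to option 1/2),
#'   `start_ms`, `end_ms`; must cover the simulation horizon (gaps are
#'   allowed and contribute zero drift).
#' @export
simulate_ddm_sequential <- function(params, schedule, seed = NULL,
                                    max_time_s = 8, return_trace = FALSE) {
  stopifnot(inherits(params, "ddm_params"))
  dt_s <- params$dt_ms / 1000
  n <- ceiling(max_time_s / dt_s)
  att <- attended_steps(schedule, n, params$dt_ms)
  if (max(schedule$end_ms) < max_time_s * 1000 - params$dt_ms)
    stop("attention schedule does not cover the simulation horizon")
  drift <- rep(0, n)
  drift[att == 1L] <- params$mu1
  drift[att == 2L] <- -params$mu2
  run_one <- function() {
    r <- .fp_run(drift, params$sigma, params$theta, dt_s)
    trace_out(r, params, dt_s, attended = att, return_trace)
  }
  if (is.null(seed)) run_one() else withr::with_seed(seed, run_one())
}

# Map a dwell schedule onto per-step attended option (0 = none).
attended_steps <- function(schedule, n_steps, dt_ms) {
  side <- as.character(schedule$side)
  side[side == "right"] <- "option1"
  side[side == "left"] <- "option2"
  if (!all(side %in% c("option1", "option2")))
    stop("schedule sides must be option1/option2 (or right/left)")
  att <- integer(n_steps)
  t_mid <- (seq_len(n_steps) - 0.5) * dt_ms  # step midpoints, ms
  for (i in seq_along(side)) {
    in_dwell <- t_mid >= schedule$start_ms[i] & t_mid < schedule$end_ms[i]
    att[in_dwell] <- if (side[i] == "option1") 1L else 2L
  }
  att
}

trace_out <- function(r, params, dt_s, attended, return_trace) {
  choice <- c("option2", "none", "option1")[r$sign + 2]
  k <- if (is.na(r$step)) length(r$x) else r$step
  out <- list(
    choice = choice,
    decision_time_ms = if (is.na(r$step)) NA_real_ else r$step * params$dt_ms,
    params = params
  )
  if (!is.null(attended)) {
    used <- attended[seq_len(k)]
    out$dt1_ms <- sum(used == 1L) * params$dt_ms
    out$dt2_ms <- sum(used == 2L) * params$dt_ms
    inc <- c(r$x[1], diff(r$x))[seq_len(k)]
    out$dx1 <- sum(inc[used == 1L])
    out$dx2 <- -sum(inc[used == 2L])  # evidence in favour of option 2
  }
  if (return_trace) {
    out$times <- seq_len(length(r$x)) * params$dt_ms
    out$x <- r$x
    if (!is.null(attended)) out$attended <- attended
  }
  class(out) <- "sim_trace"
  out
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> choice = %s, decision time = %s ms\n", x$choice,
              format(x$decision_time_ms)))
  if (!is.null(x$dt1_ms))
    cat(sprintf("  attention: dt1 = %g ms, dt2 = %g ms\n", x$dt1_ms, x$dt2_ms))
  invisible(x)
}

#' Closed-form confidence of the parallel accumulator
#'
#' Confidence at decision time `t` equals the probability of having chosen
#' the better option given that a bound was hit at `t`:
#' `g(t) = Phi(theta / (sigma * sqrt(t)))` with `Phi` the standard normal
#' CDF. The accumulated diffusion standard deviation grows as
#' `sigma * sqrt(t)`, which is the scaling used by default; a linear
#' `sigma * t` alternative is exposed for sensitivity analyses. Confidence
#' depends on the decision time only - not on how attention was split -
#' and decreases monotonically with `t`.
#'
#' @param theta,sigma bound and noise scale (> 0).
#' @param t_s decision time(s), seconds (> 0).
#' @param scaling `"sqrt"` (default) or `"linear"` time-scaling of the
#'   accumulated noise.
#' @return Probability in (0.5, 1).
#' @export
confidence_parallel <- function(theta, sigma, t_s, scaling = c("sqrt", "linear")) {
  scaling <- match.arg(scaling)
  stopifnot(theta > 0, sigma > 0)
  if (any(t_s <= 0)) stop("t_s must be positive")
  s_t <- if (scaling == "sqrt") sigma * sqrt(t_s) else sigma * t_s
  pnorm(theta / s_t)
}

#' Closed-form confidence of the sequential accumulator
#'
#' Under the symmetric-value assumption (`mu1 = -mu2 = mu0/2`, sign
#' unknown), the probability that option 1 is the better one given the
#' times `dt1_s`, `dt2_s` spent attending each option is the logistic
#' `1 / (1 + exp(-2 mu0 (dt1 - dt2) / sigma^2))`: it depends on the
#' attention-time difference only, not on the total decision time.
#'
#' @param mu0 value magnitude (1/s).
#' @param sigma noise scale (> 0).
#' @param dt1_s,dt2_s attention times in seconds (>= 0).
#' @return Probability in (0, 1); exactly 0.5 when `dt1_s == dt2_s`.
#' @export
confidence_sequential <- function(mu0, sigma, dt1_s, dt2_s) {
  stopifnot(sigma > 0)
  if (any(dt1_s < 0) || any(dt2_s < 0)) stop("attention times must be >= 0")
  plogis(2 * mu0 * (dt1_s - dt2_s) / sigma^2)
}

#' Confidence observation-model specification
#'
#' The three linear observation models that map per-trial attention times
#' onto reported confidence:
#' * parallel: `C = alpha0 + alpha1 / (dt1 + dt2)`
#' * sequential: `C = alpha0 + alpha1 (dt1 - dt2)`
#' * hybrid: `C = alpha0 + alpha1 (dt1 - dt2) + alpha2 / (dt1 + dt2)`
#'
#' Models are referred to by name throughout (the parallel readout is a
#' function of total time, the sequential one of the time difference; the
#' hybrid nests both).
#'
#' @param name `"hybrid"`, `"sequential"` or `"parallel"`.
#' @param alpha0 baseline confidence.
#' @param alpha1 weight of `(dt1 - dt2)` in 1/s for sequential/hybrid, or
#'   of `1/(dt1 + dt2)` in s for the parallel model.
#' @param alpha2 weight of `1/(dt1 + dt2)` in s (hybrid only).
#' @return An object of class `confidence_model_spec`.
#' @export
confidence_model_spec <- function(name = c("hybrid", "sequential", "parallel"),
                                  alpha0 = 0, alpha1 = 0, alpha2 = NULL) {
  name <- match.arg(name)
  if (name == "hybrid" && is.null(alpha2))
    stop("the hybrid model needs alpha2")
  if (name != "hybrid" && !is.null(alpha2))
    stop("alpha2 is only meaningful for the hybrid model")
  structure(list(name = name, alpha0 = alpha0, alpha1 = alpha1,
                 alpha2 = alpha2),
            class = "confidence_model_spec")
}

#' Predicted confidence of an observation model
#'
#' Evaluates the linear prediction of a [confidence_model_spec()] for
#' given attention times. No clipping is applied here; clipping to the
#' rating range happens only inside the synthetic generator.
#'
#' @param spec a [confidence_model_spec()].
#' @param dt1_s,dt2_s attention times for the selected and non-selected
#'   option, seconds. Vectors are recycled to common length.
#' @return Numeric vector of predicted confidence values.
#' @export
predict_confidence <- function(spec, dt1_s, dt2_s) {
  stopifnot(inherits(spec, "confidence_model_spec"))
  total <- dt1_s + dt2_s
  if (spec$name %in% c("parallel", "hybrid") && any(total <= 0))
    stop("dt1_s + dt2_s must be positive for models with an inverse-time term")
  switch(spec$name,
    parallel   = spec$alpha0 + spec$alpha1 / total,
    sequential = spec$alpha0 + spec$alpha1 * (dt1_s - dt2_s),
    hybrid     = spec$alpha0 + spec$alpha1 * (dt1_s - dt2_s) +
                 spec$alpha2 / total)
}

#' First-passage probability of the upper bound
#'
#' Standard closed-form identity for the constant-drift diffusion with
#' symmetric bounds: `P(upper) = 1 / (1 + exp(-2 mu theta / sigma^2))`.
#' Serves as the analytic oracle against which the simulators are tested.
#'
#' @param mu drift (1/s).
#' @param sigma,theta noise scale and bound (> 0).
#' @return Probability of hitting `+theta` before `-theta`.
#' @export
fp_prob_upper <- function(mu, sigma, theta) {
  stopifnot(sigma > 0, theta > 0)
  plogis(2 * mu * theta / sigma^2)
}
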