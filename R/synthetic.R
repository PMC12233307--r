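#' Simulate an alternating attention schedule
#'
#' Produces the sequence of dwells a participant makes while weighing two
#' lateral options: sides strictly alternate, dwell durations are
#' gamma-distributed, and consecutive dwells are separated by a fixed
#' saccade gap. The first side is drawn at random. The schedule covers
#' `[0, horizon_ms)`; the last dwell is truncated at the horizon.
#'
#' @param horizon_ms span to cover, ms (> 0).
#' @param dwell_mean_ms,dwell_shape mean and shape of the gamma dwell law.
#'   An infinite mean yields a single dwell covering the horizon.
#' @param gap_ms saccade gap between dwells, ms.
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @param first_side force the first side (`"left"`/`"right"`) instead of
#'   drawing it.
#' @return data.frame with columns `side` (`"left"`/`"right"`),
#'   `start_ms`, `end_ms`; ordered, non-overlapping, alternating.
#' @export
simulate_attention_schedule <- function(horizon_ms, dwell_mean_ms = 700,
                                        dwell_shape = 4, gap_ms = 40,
                                        seed = NULL, first_side = NULL) {
  stopifnot(horizon_ms > 0, dwell_mean_ms > 0, dwell_shape > 0, gap_ms >= 0)
  run <- function() {
    side <- if (is.null(first_side)) {
      sample(c("left", "right"), 1L)
    } else {
      match.arg(first_side, c("left", "right"))
    }
    starts <- numeric(0); ends <- numeric(0); sides <- character(0)
    t <- 0
    while (t < horizon_ms) {
      dur <- if (is.finite(dwell_mean_ms)) {
        rgamma(1L, shape = dwell_shape,
               scale = dwell_mean_ms / dwell_shape)
      } else {
        horizon_ms - t
      }
      dur <- max(dur, 1)  # degenerate zero-length dwells are not emitted
      end <- min(t + dur, horizon_ms)
      sides <- c(sides, side); starts <- c(starts, t); ends <- c(ends, end)
      t <- end + gap_ms
      side <- if (side == "left") "right" else "left"
    }
    data.frame(side = sides, start_ms = starts, end_ms = ends,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a gaze sample stream from an attention schedule
#'
#' Emits samples at the geometry's sampling rate over `[0, duration_ms)`.
#' During a dwell, samples are Gaussian-jittered around the centre of that
#' side's AOI and flagged valid; between dwells (saccade gaps, or before /
#' after the schedule) samples are flagged invalid and placed at the
#' screen centre.
#'
#' @param schedule a dwell schedule as from [simulate_attention_schedule()].
#'   An empty schedule yields an all-invalid stream.
#' @param geometry a [screen_geometry()].
#' @param jitter_sd_px isotropic jitter SD in pixels (0 puts every in-dwell
#'   sample exactly at the AOI centre).
#' @param duration_ms stream duration; defaults to the schedule end.
#' @param seed optional integer seed.
#' @return data.frame with columns `t_ms`, `x_px`, `y_px`, `valid` (0/1);
#'   `t_ms` is strictly increasing.
#' @export
generate_gaze_stream <- function(schedule, geometry, jitter_sd_px = 20,
                                 duration_ms = NULL, seed = NULL) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (is.null(duration_ms)) {
    duration_ms <- if (nrow(schedule)) max(schedule$end_ms) else 0
  }
  period <- 1000 / geometry$sample_rate_hz
  n <- round(duration_ms / period)
  if (n <= 0)
    return(data.frame(t_ms = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), valid = integer(0)))
  run <- function() {
    t_ms <- (seq_len(n) - 1L) * period
    cx <- c(left = (geometry$aoi_left[1] + geometry$aoi_left[3]) / 2,
            right = (geometry$aoi_right[1] + geometry$aoi_right[3]) / 2)
    cy <- (geometry$aoi_left[2] + geometry$aoi_left[4]) / 2
    x <- rep(geometry$width_px / 2, n)
    y <- rep(geometry$height_px / 2, n)
    valid <- integer(n)
    if (nrow(schedule)) {
      idx <- findInterval(t_ms, schedule$start_ms)
      in_dwell <- idx > 0 & t_ms < schedule$end_ms[pmax(idx, 1L)]
      k <- sum(in_dwell)
      if (k) {
        sides <- schedule$side[idx[in_dwell]]
        x[in_dwell] <- cx[sides] + rnorm(k, sd = jitter_sd_px)
        y[in_dwell] <- cy + rnorm(k, sd = jitter_sd_px)
        valid[in_dwell] <- 1L
      }
    }
    data.frame(t_ms = t_ms, x_px = x, y_px = y, valid = valid)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate discrete ratings from latent trial variables
#'
#' Maps the model confidence and a per-trial difficulty latent onto the
#' four reported indices. Confidence is the true model confidence plus
#' reporting noise, discretised onto the rating scale. The other three
#' indices are loaded on the difficulty latent (complexity positively,
#' reward and interest mildly negatively) plus a shared appraisal noise
#' term that correlates reward and interest with each other.
#'
#' @param true_confidence vector of model confidence values in `[0, 1]`.
#' @param difficulty standardized per-trial difficulty latent (vector of
#'   the same length; larger = harder, e.g. minus the absolute value
#'   difference, z-scored).
#' @param noise_sd reporting noise of the confidence rating (0-1 scale).
#' @param scale_max top of the rating scale (9 or 10).
#' @param cognitive_noise_sd reporting noise of the R / I / CM ratings.
#' @param loadings named numeric vector with elements `cm`, `r`, `i`,
#'   `shared` controlling how strongly each index follows the difficulty
#'   latent and the shared reward-interest appraisal term.
#' @param seed optional integer seed.
#' @return data.frame with integer columns `C`, `R`, `I`, `CM`, each in
#'   `[0, scale_max]`.
#' @export
ratings_from_latents <- function(true_confidence, difficulty = NULL,
                                 noise_sd = 0.05, scale_max = 10L,
                                 cognitive_noise_sd = 0.15,
                                 loadings = c(cm = 0.25, r = -0.1,
                                              i = -0.08, shared = 0.1),
                                 seed = NULL) {
  if (any(true_confidence < 0 | true_confidence > 1))
    stop("true_confidence must lie in [0, 1]")
  n <- length(true_confidence)
  if (is.null(difficulty)) difficulty <- numeric(n)
  stopifnot(length(difficulty) == n)
  run <- function() {
    disc <- function(latent) {
      as.integer(pmin(pmax(round(scale_max * latent), 0), scale_max))
    }
    shared <- loadings[["shared"]] * rnorm(n)
    data.frame(
      C = disc(true_confidence + rnorm(n, sd = noise_sd)),
      R = disc(0.6 + loadings[["r"]] * difficulty + shared +
                 rnorm(n, sd = cognitive_noise_sd)),
      I = disc(0.6 + loadings[["i"]] * difficulty + shared +
                 rnorm(n, sd = cognitive_noise_sd)),
      CM = disc(0.5 + loadings[["cm"]] * difficulty +
                  rnorm(n, sd = cognitive_noise_sd))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete synthetic experiment
#'
#' Generates, for every participant and trial: an alternating attention
#' schedule, a gaze sample stream, a choice and decision time from a
#' bounded diffusion (gaze-gated drift for the sequential and hybrid
#' generative models, constant drift for the parallel one), and the four
#' ratings, with the confidence rating produced by the configured
#' observation model from the true attention times. Everything is
#' reproducible from `cfg$seed`.
#'
#' Per trial, the two option values are drawn from
#' `N(value_mean, value_sd)`; both options being appetitive on average is
#' what makes looking time predict choice under gaze-gated drift. Evidence
#' accumulation starts at the GO signal; the first bound crossing inside
#' the response window gives the choice and decision time, and a trial
#' with no crossing is emitted with `button = "none"`. The true attention
#' times entering the confidence model are accumulated over `cfg$dt_span`
#' (GO-to-decision by default) for the selected (`dt1`) and non-selected
#' (`dt2`) option.
#'
#' @param cfg a [generative_config()].
#' @return A list of class `synthetic_dataset` with data.frames `gaze`
#'   (participant_id, trial_index, t_ms, x_px, y_px, valid), `trials`
#'   (participant_id, experiment, trial_index, go_time_ms, stim_on_ms,
#'   button, selected_side, decision_time_ms, C, R, I, CM) and `truth`
#'   (per-trial latents: dt1_ms, dt2_ms, confidence_true, model, alpha and
#'   diffusion parameters).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generative_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  tl <- cfg$timeline
  go_ms <- tl$stim_on_ms
  horizon_ms <- tl$stim_on_ms + tl$stim_off_ms
  dt_ms <- cfg$ddm$dt_ms
  n_steps <- round(tl$response_window_ms / dt_ms)
  spec <- confidence_model_spec(
    cfg$model, alpha0 = cfg$alpha$alpha0, alpha1 = cfg$alpha$alpha1,
    alpha2 = if (cfg$model == "hybrid") cfg$alpha$alpha2 else NULL)

  gaze_l <- vector("list", cfg$n_participants * cfg$n_trials)
  trials_l <- vector("list", cfg$n_participants)
  truth_l <- vector("list", cfg$n_participants)

  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    v_right <- rnorm(cfg$n_trials, cfg$ddm$value_mean, cfg$ddm$value_sd)
    v_left <- rnorm(cfg$n_trials, cfg$ddm$value_mean, cfg$ddm$value_sd)
    button <- character(cfg$n_trials)
    selected <- character(cfg$n_trials)
    dt_dec <- rep(NA_real_, cfg$n_trials)
    dt1 <- rep(NA_real_, cfg$n_trials)
    dt2 <- rep(NA_real_, cfg$n_trials)
    conf_true <- rep(NA_real_, cfg$n_trials)

    for (tr in seq_len(cfg$n_trials)) {
      sched <- simulate_attention_schedule(
        horizon_ms, cfg$dwell_mean_ms, cfg$dwell_shape, cfg$gap_ms)
      # diffusion runs from GO over the response window
      off <- clip_schedule(sched, go_ms, go_ms + tl$response_window_ms)
      off$start_ms <- off$start_ms - go_ms
      off$end_ms <- off$end_ms - go_ms
      att <- attended_steps(off, n_steps, dt_ms)
      drift <- if (cfg$model == "parallel") {
        rep(v_right[tr] - v_left[tr], n_steps)
      } else {
        d <- numeric(n_steps)
        d[att == 1L] <- v_right[tr]   # attending right: evidence for right
        d[att == 2L] <- -v_left[tr]   # attending left: evidence for left
        d
      }
      r <- .fp_run(drift, cfg$ddm$sigma, cfg$ddm$theta, dt_ms / 1000)

      if (is.na(r$step)) {
        button[tr] <- "none"; selected[tr] <- "none"
      } else {
        dt_dec[tr] <- r$step * dt_ms
        selected[tr] <- if (r$sign > 0) "right" else "left"
        button[tr] <- if (cfg$experiment == "rLAN") {
          if (selected[tr] == "right") "left" else "right"
        } else {
          selected[tr]
        }
      }

      # true attention times for the confidence model
      sel_side <- if (selected[tr] == "none") NA_character_ else selected[tr]
      k <- if (is.na(r$step)) n_steps else r$step
      used <- att[seq_len(k)]
      t_right <- sum(used == 1L) * dt_ms
      t_left <- sum(used == 2L) * dt_ms
      if (cfg$dt_span == "son_soff_ud") {
        son <- clip_schedule(sched, 0, go_ms)
        t_right <- t_right + sum((son$end_ms - son$start_ms)[son$side == "right"])
        t_left <- t_left + sum((son$end_ms - son$start_ms)[son$side == "left"])
      }
      if (!is.na(sel_side)) {
        dt1[tr] <- if (sel_side == "right") t_right else t_left
        dt2[tr] <- if (sel_side == "right") t_left else t_right
        total_s <- (dt1[tr] + dt2[tr]) / 1000
        if (spec$name == "sequential" || total_s > 0) {
          conf_true[tr] <- min(max(predict_confidence(
            spec, dt1[tr] / 1000, dt2[tr] / 1000), 0), 1)
        }
      }

      g <- generate_gaze_stream(sched, cfg$geometry, cfg$jitter_sd_px,
                                duration_ms = horizon_ms)
      g <- cbind(participant_id = pid, trial_index = tr, g)
      gaze_l[[(p - 1L) * cfg$n_trials + tr]] <- g
    }

    diff_raw <- -abs(v_right - v_left)
    difficulty <- if (length(diff_raw) > 1 && sd(diff_raw) > 0) {
      as.numeric(scale(diff_raw))
    } else {
      numeric(length(diff_raw))
    }
    conf_for_rating <- ifelse(is.na(conf_true), 0.5, conf_true)
    ratings <- ratings_from_latents(
      conf_for_rating, difficulty, noise_sd = cfg$rating_noise_sd,
      scale_max = cfg$rating_scale_max,
      cognitive_noise_sd = cfg$cognitive_noise_sd)
    ratings[selected == "none", ] <- NA_integer_

    trials_l[[p]] <- data.frame(
      participant_id = pid, experiment = cfg$experiment,
      trial_index = seq_len(cfg$n_trials), go_time_ms = go_ms,
      stim_on_ms = tl$stim_on_ms, button = button,
      selected_side = selected, decision_time_ms = dt_dec,
      C = ratings$C, R = ratings$R, I = ratings$I, CM = ratings$CM,
      stringsAsFactors = FALSE)
    truth_l[[p]] <- data.frame(
      participant_id = pid, trial_index = seq_len(cfg$n_trials),
      dt1_ms = dt1, dt2_ms = dt2, confidence_true = conf_true,
      model = cfg$model, alpha0 = cfg$alpha$alpha0,
      alpha1 = cfg$alpha$alpha1,
      alpha2 = if (cfg$model == "hybrid") cfg$alpha$alpha2 else NA_real_,
      mu = v_right - v_left, sigma = cfg$ddm$sigma, theta = cfg$ddm$theta,
      stringsAsFactors = FALSE)
  }

  out <- list(
    gaze = as.data.frame(data.table::rbindlist(gaze_l)),
    trials = as.data.frame(data.table::rbindlist(trials_l)),
    truth = as.data.frame(data.table::rbindlist(truth_l)),
    config = cfg
  )
  class(out) <- "synthetic_dataset"
  out
}

# Intersect a dwell schedule with [from_ms, to_ms).
clip_schedule <- function(schedule, from_ms, to_ms) {
  s <- schedule[schedule$end_ms > from_ms & schedule$start_ms < to_ms, ,
                drop = FALSE]
  s$start_ms <- pmax(s$start_ms, from_ms)
  s$end_ms <- pmin(s$end_ms, to_ms)
  s
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d participants x %d trials (%s, %s model)\n",
    x$config$n_participants, x$config$n_trials, x$config$experiment,
    x$config$model))
  cat(sprintf("  gaze samples: %d rows; responses: %d/%d trials\n",
              nrow(x$gaze), sum(x$trials$button != "none"), nrow(x$trials)))
  invisible(x)
}
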