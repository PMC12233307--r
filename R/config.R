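#' Screen and AOI geometry
#'
#' Describes the display and the two lateral areas of interest (AOIs) that
#' contain the option images. Defaults correspond to a 1920x1080 display
#' with 265x256 px images centred vertically and placed at one quarter and
#' three quarters of the screen width, each AOI being the image frame
#' padded by `aoi_pad_px` on every side (the empty frame left behind after
#' stimulus offset is treated as the same target region as the image).
#'
#' @param width_px,height_px screen size in pixels.
#' @param image_w_px,image_h_px option image size in pixels.
#' @param aoi_pad_px padding added around each image frame, pixels.
#' @param sample_rate_hz gaze sampling rate of the eye tracker.
#' @return An object of class `screen_geometry`: a list with the screen
#'   size, the sampling rate, and `aoi_left` / `aoi_right` rectangles as
#'   numeric vectors `c(x0, y0, x1, y1)` (half-open on the right/bottom).
#' @examples
#' geom <- screen_geometry()
#' geom$aoi_left
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            image_w_px = 265L, image_h_px = 256L,
                            aoi_pad_px = 25L, sample_rate_hz = 60) {
  stopifnot(width_px > 0, height_px > 0, sample_rate_hz > 0,
            image_w_px > 0, image_h_px > 0, aoi_pad_px >= 0)
  half_w <- image_w_px / 2 + aoi_pad_px
  half_h <- image_h_px / 2 + aoi_pad_px
  cx_left <- width_px / 4
  cx_right <- 3 * width_px / 4
  cy <- height_px / 2
  geom <- list(
    width_px = width_px, height_px = height_px,
    sample_rate_hz = sample_rate_hz,
    aoi_left = c(cx_left - half_w, cy - half_h, cx_left + half_w, cy + half_h),
    aoi_right = c(cx_right - half_w, cy - half_h, cx_right + half_w, cy + half_h)
  )
  # AOIs must stay disjoint and on screen
  stopifnot(geom$aoi_left[3] < geom$aoi_right[1],
            geom$aoi_left[1] >= 0, geom$aoi_right[3] <= width_px,
            geom$aoi_left[2] >= 0, geom$aoi_left[4] <= height_px)
  class(geom) <- "screen_geometry"
  geom
}

#' Trial phase timeline
#'
#' Durations of the phases of one trial, in ms. The decision-relevant span
#' starts at Stimulus-On; `t = 0` of a trial's gaze stream is the
#' Stimulus-On onset and the GO signal occurs at `stim_on_ms`. The earlier
#' fixation and context phases are carried for completeness but no gaze is
#' generated for them.
#'
#' @param stim_on_ms Stimulus-On duration (4000 by default; 2000 in the
#'   short-observation variant).
#' @param stim_off_ms Stimulus-Off duration after the GO signal.
#' @param response_window_ms time allowed to report the choice, counted
#'   from GO; must not exceed `stim_off_ms`.
#' @param fixation1_ms,context_ms,fixation2_ms pre-stimulus phases.
#' @return An object of class `trial_timeline` (a named list).
#' @export
trial_timeline <- function(stim_on_ms = 4000, stim_off_ms = 4000,
                           response_window_ms = 4000,
                           fixation1_ms = 1000, context_ms = 4000,
                           fixation2_ms = 1000) {
  tl <- list(fixation1_ms = as.numeric(fixation1_ms),
             context_ms = as.numeric(context_ms),
             fixation2_ms = as.numeric(fixation2_ms),
             stim_on_ms = as.numeric(stim_on_ms),
             stim_off_ms = as.numeric(stim_off_ms),
             response_window_ms = as.numeric(response_window_ms))
  if (any(unlist(tl) < 0)) stop("all timeline durations must be >= 0")
  if (response_window_ms > stim_off_ms)
    stop("response_window_ms must not exceed stim_off_ms")
  class(tl) <- "trial_timeline"
  tl
}

#' Configuration of the synthetic experiment generator
#'
#' Bundles every knob of [simulate_dataset()]. The defaults emulate the
#' study conditions of the emulated paradigm: 80 trials per participant, a
#' 4 s Stimulus-On interval (2 s for `experiment = "sLAN"`), alternating
#' gamma-distributed dwells calibrated to roughly 1.3 target alternations
#' per second, and a bounded diffusion whose first passage after the GO
#' signal produces decision times averaging about 1.4 s.
#'
#' @param n_participants,n_trials cohort size.
#' @param experiment one of `"LAN"` (options disappear at GO), `"LAS"`
#'   (options stay on screen), `"rLAN"` (button side reversed with respect
#'   to the chosen image side), `"sLAN"` (2 s Stimulus-On).
#' @param model generative confidence model: `"hybrid"`, `"sequential"` or
#'   `"parallel"` (see [predict_confidence()]). For `"hybrid"` and
#'   `"sequential"` the diffusion drift is gaze-gated (the attended
#'   option's value drives the accumulator); for `"parallel"` the drift is
#'   the constant value difference.
#' @param alpha named list of confidence observation-model coefficients
#'   `alpha0` (baseline), `alpha1` (per second, weight of the attention
#'   time difference) and `alpha2` (seconds, weight of the inverse total
#'   attention time).
#' @param ddm named list with `sigma` (diffusion noise, 1/sqrt(s) units),
#'   `theta` (bound magnitude), `dt_ms` (Euler step), `value_mean` and
#'   `value_sd` (per-trial option values, drift units 1/s). Option values
#'   are drawn positively on average: both options are appetitive, which is
#'   what couples gaze to choice under gaze-gated drift.
#' @param dwell_mean_ms,dwell_shape gamma dwell-duration law (mean and
#'   shape).
#' @param gap_ms saccade gap between consecutive dwells, ms.
#' @param jitter_sd_px isotropic Gaussian jitter of gaze samples around the
#'   AOI centre.
#' @param rating_noise_sd reporting noise added to the model confidence (on
#'   the 0-1 scale) before discretisation.
#' @param cognitive_noise_sd reporting noise of the reward / interest /
#'   complexity ratings (0-1 scale).
#' @param rating_scale_max top of the rating scale (9 or 10).
#' @param dt_span interval over which the generative attention times
#'   entering the confidence model are accumulated: `"soff_ud"` (GO to
#'   decision; default) or `"son_soff_ud"` (Stimulus-On onset to decision).
#' @param timeline a [trial_timeline()]; built from `experiment` if `NULL`.
#' @param geometry a [screen_geometry()].
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return An object of class `generative_config` (a named list).
#' @export
generative_config <- function(n_participants = 20L, n_trials = 80L,
                              experiment = c("LAN", "LAS", "rLAN", "sLAN"),
                              model = c("hybrid", "sequential", "parallel"),
                              alpha = list(alpha0 = 0.5, alpha1 = 0.15,
                                           alpha2 = 0.3),
                              ddm = list(sigma = 0.8, theta = 1.2, dt_ms = 1,
                                         value_mean = 0.7, value_sd = 0.45),
                              dwell_mean_ms = 700, dwell_shape = 4,
                              gap_ms = 40, jitter_sd_px = 20,
                              rating_noise_sd = 0.05,
                              cognitive_noise_sd = 0.15,
                              rating_scale_max = 10L,
                              dt_span = c("soff_ud", "son_soff_ud"),
                              timeline = NULL, geometry = screen_geometry(),
                              seed = 1L) {
  experiment <- match.arg(experiment)
  model <- match.arg(model)
  dt_span <- match.arg(dt_span)
  if (n_participants < 1 || n_trials < 1)
    stop("n_participants and n_trials must be positive")
  if (dwell_mean_ms <= 0 || dwell_shape <= 0)
    stop("dwell parameters must be positive")
  if (!rating_scale_max %in% c(9L, 10L))
    stop("rating_scale_max must be 9 or 10")
  ddm <- modifyList(list(sigma = 0.8, theta = 1.2, dt_ms = 1,
                         value_mean = 0.7, value_sd = 0.45), ddm)
  alpha <- modifyList(list(alpha0 = 0.5, alpha1 = 0.15, alpha2 = 0.3), alpha)
  stopifnot(ddm$sigma > 0, ddm$theta > 0, ddm$dt_ms > 0)
  if (is.null(timeline)) {
    timeline <- trial_timeline(
      stim_on_ms = if (experiment == "sLAN") 2000 else 4000)
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_trials = as.integer(n_trials),
              experiment = experiment, model = model, alpha = alpha,
              ddm = ddm, dwell_mean_ms = dwell_mean_ms,
              dwell_shape = dwell_shape, gap_ms = gap_ms,
              jitter_sd_px = jitter_sd_px,
              rating_noise_sd = rating_noise_sd,
              cognitive_noise_sd = cognitive_noise_sd,
              rating_scale_max = as.integer(rating_scale_max),
              dt_span = dt_span, timeline = timeline, geometry = geometry,
              seed = as.integer(seed))
  class(cfg) <- "generative_config"
  cfg
}

#' @export
print.generative_config <- function(x, ...) {
  cat(sprintf(
    "<generative_config> %d participants x %d trials, %s experiment\n",
    x$n_participants, x$n_trials, x$experiment))
  cat(sprintf("  confidence model: %s (alpha0=%.3g, alpha1=%.3g/s, alpha2=%.3g s)\n",
              x$model, x$alpha$alpha0, x$alpha$alpha1, x$alpha$alpha2))
  cat(sprintf("  diffusion: sigma=%.3g, theta=%.3g, dt=%g ms; dwell mean %g ms\n",
              x$ddm$sigma, x$ddm$theta, x$ddm$dt_ms, x$dwell_mean_ms))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read / write a generator configuration as JSON
#'
#' The JSON document mirrors [generative_config()] field by field, so a
#' configuration can be version-controlled next to the outputs it produced.
#'
#' @param path file path.
#' @param cfg a `generative_config`.
#' @return `read_config_json()` returns a `generative_config`;
#'   `write_config_json()` returns `path` invisibly.
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tl <- raw$timeline
  geom_args <- raw$geometry
  raw$timeline <- NULL
  raw$geometry <- NULL
  cfg <- do.call(generative_config, c(
    raw,
    list(timeline = if (is.null(tl)) NULL else do.call(trial_timeline, as.list(tl)))
  ))
  if (!is.null(geom_args)) {
    geom <- geom_args
    class(geom) <- "screen_geometry"
    cfg$geometry <- geom
  }
  cfg
}

#' @rdname read_config_json
#' @export
write_config_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "generative_config"))
  out <- unclass(cfg)
  out$timeline <- unclass(out$timeline)
  out$geometry <- unclass(out$geometry)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Deterministic per-stage seed derivation: one user-facing seed expands
# into independent stage seeds so any stage can be rerun in isolation.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, metrics = 2L, psychometrics = 3L, glm = 4L,
              fit_models = 5L, bms = 6L, recover = 7L, report = 8L)
  if (is.character(stage)) stage <- stages[[stage]]
  as.integer((as.double(seed) * 48271 + 1000003 * stage) %% 2147483629)
}
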