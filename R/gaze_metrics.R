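#' Reduce a gaze stream to per-AOI dwell segments
#'
#' Each sample is labelled by the AOI it falls in (invalid samples are
#' off-AOI by definition). Consecutive same-side samples form a dwell;
#' same-side runs separated by off-AOI stretches no longer than
#' `max_gap_ms` are merged; dwells shorter than `min_dwell_ms` are
#' discarded. A dwell's end is the time of its last sample plus one sample
#' period, so a single sample carries one period of dwell time.
#'
#' @param samples data.frame with `t_ms` (nondecreasing), `x_px`, `y_px`,
#'   `valid` (0/1).
#' @param geometry a [screen_geometry()].
#' @param min_dwell_ms minimum dwell duration kept, ms.
#' @param max_gap_ms maximum internal off-AOI gap merged into a dwell, ms.
#' @param trial_id label used in error messages.
#' @return data.frame with `side` (`"left"`/`"right"`), `start_ms`,
#'   `end_ms`; ordered and non-overlapping.
#' @export
extract_dwells <- function(samples, geometry, min_dwell_ms = 100,
                           max_gap_ms = 80, trial_id = NULL) {
  stopifnot(inherits(geometry, "screen_geometry"))
  empty <- data.frame(side = character(0), start_ms = numeric(0),
                      end_ms = numeric(0))
  if (!nrow(samples)) return(empty)
  if (is.unsorted(samples$t_ms))
    stop("gaze timestamps are not time-ordered",
         if (!is.null(trial_id)) paste0(" in trial ", trial_id) else "")
  period <- if (nrow(samples) > 1) {
    median(diff(samples$t_ms))
  } else {
    1000 / geometry$sample_rate_hz
  }
  lab <- aoi_label(samples, geometry)
  if (!any(lab != "off")) return(empty)

  r <- rle(lab)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values != "off"
  runs <- data.frame(side = r$values[keep],
                     start_ms = samples$t_ms[starts_i[keep]],
                     end_ms = samples$t_ms[ends_i[keep]] + period,
                     stringsAsFactors = FALSE)
  # merge same-side runs across short off-AOI gaps
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      j <- nrow(merged)
      gap <- runs$start_ms[i] - merged$end_ms[j]
      if (runs$side[i] == merged$side[j] && gap <= max_gap_ms) {
        merged$end_ms[j] <- runs$end_ms[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end_ms - runs$start_ms >= min_dwell_ms, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

# Per-sample AOI label: "left", "right" or "off".
aoi_label <- function(samples, geometry) {
  in_rect <- function(r) {
    samples$x_px >= r[1] & samples$x_px < r[3] &
      samples$y_px >= r[2] & samples$y_px < r[4]
  }
  lab <- rep("off", nrow(samples))
  ok <- samples$valid > 0 & !is.na(samples$x_px) & !is.na(samples$y_px)
  lab[ok & in_rect(geometry$aoi_left)] <- "left"
  lab[ok & in_rect(geometry$aoi_right)] <- "right"
  lab
}

#' Analysis intervals of one trial
#'
#' Builds the three half-open intervals used throughout: Stimulus-On
#' (`SOn`, stimulus onset to GO), Stimulus-Off until the decision
#' (`SOffUD`, GO to report) and past the decision (`SOffPD`, report to end
#' of the response window). For a trial with no response, `SOffUD` spans
#' the whole response window and `SOffPD` is empty. In the
#' always-visible control the post-GO phases are Stimulus-On on screen but
#' play the same roles, so the same interval names are used.
#'
#' @param go_time_ms GO signal time, trial-relative ms.
#' @param decision_time_ms time from GO to the button press (`NA` if no
#'   response).
#' @param stim_off_ms duration of the post-GO phase.
#' @return data.frame with `interval`, `start_ms`, `end_ms`.
#' @export
trial_intervals <- function(go_time_ms, decision_time_ms, stim_off_ms = 4000) {
  dec <- if (is.na(decision_time_ms)) stim_off_ms else
    min(decision_time_ms, stim_off_ms)
  data.frame(
    interval = c("SOn", "SOffUD", "SOffPD"),
    start_ms = c(0, go_time_ms, go_time_ms + dec),
    end_ms = c(go_time_ms, go_time_ms + dec, go_time_ms + stim_off_ms),
    stringsAsFactors = FALSE)
}

#' Per-interval observation-time and change-of-target metrics
#'
#' Clips each dwell to each interval and sums per-side observation times;
#' counts changes of target (adjacent dwell pairs with different sides) in
#' the interval where the second dwell of the pair starts, and divides by
#' the interval duration in seconds to obtain the alternation frequency.
#' A zero-length interval yields `NA` metrics rather than divisions by
#' zero.
#'
#' @param dwells dwell segments as from [extract_dwells()].
#' @param intervals data.frame as from [trial_intervals()].
#' @param selected_side `"left"`, `"right"` or `"none"`; with `"none"` the
#'   selected-fraction column is `NA`.
#' @param eps_ms regulariser of the log looking-time ratio (see
#'   [log_time_ratio()]); defaults to one sample period at 60 Hz.
#' @return data.frame, one row per interval: `interval`, `t_left_ms`,
#'   `t_right_ms`, `t_selected_frac`, `n_cot`, `f_cot` (Hz), `log_ratio`.
#' @export
compute_trial_metrics <- function(dwells, intervals, selected_side = "none",
                                  eps_ms = 1000 / 60) {
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$start_ms[i]; b <- intervals$end_ms[i]
    len_ms <- b - a
    if (len_ms <= 0) {
      return(data.frame(interval = intervals$interval[i], t_left_ms = NA_real_,
                        t_right_ms = NA_real_, t_selected_frac = NA_real_,
                        n_cot = NA_integer_, f_cot = NA_real_,
                        log_ratio = NA_real_))
    }
    clipped <- pmin(dwells$end_ms, b) - pmax(dwells$start_ms, a)
    clipped <- pmax(clipped, 0)
    t_left <- sum(clipped[dwells$side == "left"])
    t_right <- sum(clipped[dwells$side == "right"])
    n_cot <- 0L
    if (nrow(dwells) > 1) {
      is_cot <- dwells$side[-1] != dwells$side[-nrow(dwells)]
      second_start <- dwells$start_ms[-1]
      n_cot <- sum(is_cot & second_start >= a & second_start < b)
    }
    t_sel <- switch(selected_side, left = t_left, right = t_right, NA_real_)
    data.frame(interval = intervals$interval[i], t_left_ms = t_left,
               t_right_ms = t_right, t_selected_frac = t_sel / len_ms,
               n_cot = as.integer(n_cot), f_cot = n_cot / (len_ms / 1000),
               log_ratio = log_time_ratio(t_right, t_left, eps_ms))
  })
  do.call(rbind, out)
}

#' Regularised log looking-time ratio
#'
#' `log((T_R + eps) / (T_L + eps))`: the psychometric regressor. The
#' regulariser keeps the ratio finite when one side was never fixated; its
#' default is one sample period at 60 Hz, the smallest measurable dwell.
#'
#' @param t_right_ms,t_left_ms per-side observation times, ms (>= 0).
#' @param eps_ms positive regulariser, ms.
#' @return `log((t_right_ms + eps_ms) / (t_left_ms + eps_ms))`.
#' @export
log_time_ratio <- function(t_right_ms, t_left_ms, eps_ms = 1000 / 60) {
  if (any(t_right_ms < 0) || any(t_left_ms < 0))
    stop("observation times must be >= 0")
  stopifnot(eps_ms > 0)
  log((t_right_ms + eps_ms) / (t_left_ms + eps_ms))
}

#' Apply the trial-exclusion rule
#'
#' A trial is discarded iff its decision time is negative, strictly longer
#' than `max_dt_ms`, or absent (no response). A decision time of exactly
#' `max_dt_ms` is kept.
#'
#' @param trials trial table with `participant_id` and `decision_time_ms`.
#' @param max_dt_ms upper bound of admissible decision times, ms.
#' @return list with `kept` (the retained rows) and `report` (counts per
#'   participant and exclusion reason).
#' @export
exclude_trials <- function(trials, max_dt_ms = 4000) {
  dt <- trials$decision_time_ms
  reason <- rep(NA_character_, nrow(trials))
  reason[is.na(dt)] <- "no_response"
  reason[!is.na(dt) & dt < 0] <- "negative_dt"
  reason[!is.na(dt) & dt > max_dt_ms] <- "too_slow"
  kept <- trials[is.na(reason), , drop = FALSE]
  excl <- data.frame(participant_id = trials$participant_id,
                     reason = reason)[!is.na(reason), , drop = FALSE]
  report <- if (nrow(excl)) {
    as.data.frame(table(participant_id = excl$participant_id,
                        reason = excl$reason),
                  responseName = "n_excluded")
  } else {
    data.frame(participant_id = character(0), reason = character(0),
               n_excluded = integer(0))
  }
  list(kept = kept, report = report[report$n_excluded > 0, , drop = FALSE])
}

#' Image side selected, given the button pressed
#'
#' In the motor-reversal variant the button and the image side are
#' swapped; everywhere else they coincide.
#'
#' @param button `"left"`, `"right"` or `"none"` (vector).
#' @param experiment experiment label(s); `"rLAN"` triggers the reversal.
#' @return Character vector of selected image sides.
#' @export
selected_side_from_button <- function(button, experiment) {
  flip <- c(left = "right", right = "left", none = "none")
  ifelse(experiment == "rLAN", flip[button], button)
}

#' Per-trial metrics table for a whole dataset
#'
#' Runs dwell extraction and [compute_trial_metrics()] over every trial of
#' a gaze table, using each trial's GO and decision times to build the
#' analysis intervals.
#'
#' @param gaze gaze table (`participant_id`, `trial_index`, `t_ms`,
#'   `x_px`, `y_px`, `valid`).
#' @param trials trial table (`participant_id`, `trial_index`,
#'   `go_time_ms`, `button`, `decision_time_ms`, and either
#'   `selected_side` or `experiment` from which it is derived).
#' @param geometry a [screen_geometry()].
#' @param stim_off_ms duration of the post-GO phase, ms.
#' @param min_dwell_ms,max_gap_ms,eps_ms passed to [extract_dwells()] and
#'   [compute_trial_metrics()].
#' @return data.frame, one row per trial x interval, with the columns of
#'   [compute_trial_metrics()] plus `participant_id` and `trial_index`.
#' @export
compute_metrics_table <- function(gaze, trials, geometry,
                                  stim_off_ms = 4000, min_dwell_ms = 100,
                                  max_gap_ms = 80, eps_ms = 1000 / 60) {
  if (!"selected_side" %in% names(trials)) {
    trials$selected_side <- selected_side_from_button(trials$button,
                                                      trials$experiment)
  }
  gaze_split <- split(gaze[, c("t_ms", "x_px", "y_px", "valid")],
                      paste(gaze$participant_id, gaze$trial_index))
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    g <- gaze_split[[paste(tr$participant_id, tr$trial_index)]]
    if (is.null(g)) g <- gaze[0, c("t_ms", "x_px", "y_px", "valid")]
    dw <- extract_dwells(g, geometry, min_dwell_ms,
                         max_gap_ms,
                         trial_id = paste(tr$participant_id, tr$trial_index))
    iv <- trial_intervals(tr$go_time_ms, tr$decision_time_ms, stim_off_ms)
    m <- compute_trial_metrics(dw, iv, tr$selected_side, eps_ms)
    rows[[i]] <- cbind(participant_id = tr$participant_id,
                       trial_index = tr$trial_index, m)
  }
  as.data.frame(data.table::rbindlist(rows))
}
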