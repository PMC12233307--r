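#' Confidence-quartile versus decision-time summary
#'
#' Splits each participant's trials into quartiles of reported confidence,
#' pools trials across participants, and summarises the decision time per
#' confidence quartile (mean and standard error). When fitted observation
#' models are supplied, each model's per-trial predicted confidence
#' (posterior-mean coefficients applied to the trial's attention times) is
#' averaged within the same quartiles, giving the model curves that
#' accompany the data summary. Participants with fewer than four distinct
#' confidence values cannot be split and are skipped (and listed).
#'
#' @param data per-trial rows with `participant_id`, `C`,
#'   `decision_time_ms`, and (for model predictions) `dt1_ms`, `dt2_ms`.
#' @param posterior optional posterior coefficient table from
#'   [fit_confidence_models()].
#' @param scale_max top of the rating scale.
#' @return list with `quartiles` (q, mean_confidence, mean_dt_ms,
#'   se_dt_ms, n_trials), `model_predictions` (model, q,
#'   mean_pred_confidence) or `NULL`, and `skipped`.
#' @export
confidence_dt_quartile_summary <- function(data, posterior = NULL,
                                           scale_max = 10) {
  keep <- !is.na(data$C) & !is.na(data$decision_time_ms)
  data <- data[keep, ]
  ids <- unique(data$participant_id)
  rows <- list(); skipped <- character(0)
  for (id in ids) {
    d <- data[data$participant_id == id, ]
    if (length(unique(d$C)) < 4) {
      skipped <- c(skipped, id)
      next
    }
    # rank-based quartiles; ties broken by trial order for determinism
    r <- rank(d$C, ties.method = "first")
    d$q <- ceiling(4 * r / nrow(d))
    rows[[id]] <- d
  }
  if (!length(rows)) stop("no participant had 4 distinct confidence values")
  pooled <- rbind_rows(rows)
  qs <- lapply(1:4, function(q) {
    d <- pooled[pooled$q == q, ]
    data.frame(q = q, mean_confidence = mean(d$C) / scale_max,
               mean_dt_ms = mean(d$decision_time_ms),
               se_dt_ms = sd(d$decision_time_ms) / sqrt(nrow(d)),
               n_trials = nrow(d))
  })
  quartiles <- do.call(rbind, qs)
  preds <- NULL
  if (!is.null(posterior) && all(c("dt1_ms", "dt2_ms") %in% names(pooled))) {
    pr <- list()
    for (m in unique(posterior$model)) {
      pc <- rep(NA_real_, nrow(pooled))
      for (id in unique(pooled$participant_id)) {
        co <- posterior[posterior$participant_id == id &
                          posterior$model == m, ]
        if (!nrow(co)) next
        sel <- pooled$participant_id == id
        spec <- switch(m,
          hybrid = confidence_model_spec("hybrid", co$alpha0, co$alpha1,
                                         co$alpha2),
          sequential = confidence_model_spec("sequential", co$alpha0,
                                             co$alpha1),
          parallel = confidence_model_spec("parallel", co$alpha0,
                                           co$alpha1))
        pc[sel] <- predict_confidence(spec, pooled$dt1_ms[sel] / 1000,
                                      pooled$dt2_ms[sel] / 1000)
      }
      pr[[m]] <- data.frame(
        model = m, q = 1:4,
        mean_pred_confidence = vapply(1:4, function(q)
          mean(pc[pooled$q == q], na.rm = TRUE), numeric(1)))
    }
    preds <- rbind_rows(unname(pr))
  }
  list(quartiles = quartiles, model_predictions = preds, skipped = skipped)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end and writes every artifact to
#' `out_dir` as CSV (tables) or JSON (scalar results), plus a run
#' manifest recording the configuration, the stage seeds and every output
#' file. Three modes:
#'
#' * `"simulate"`: generate a synthetic dataset and write `gaze.csv`,
#'   `trials.csv`, `truth.csv` and `config.json`.
#' * `"analyze"`: read gaze and trial tables (defaults to the files a
#'   previous simulate run left in `out_dir`), apply the exclusion rule,
#'   compute the metrics table, psychometric fits and group tests,
#'   cognitive-factor regressions, confidence-model free energies,
#'   random-effects model selection, and the confidence-quartile /
#'   decision-time summary.
#' * `"recover"`: run the 3x3 model-recovery harness.
#'
#' @param config a [generative_config()] or the path of its JSON form.
#' @param mode `"simulate"`, `"analyze"` or `"recover"`.
#' @param out_dir output directory (created if missing).
#' @param gaze_path,trials_path input tables for `"analyze"` mode.
#' @param seed overrides `config$seed` when given; each stage derives its
#'   own seed from it deterministically.
#' @param evidence_cfg an [evidence_config()] for the model inversion.
#' @param n_dirichlet_samples draws for the exceedance probabilities.
#' @param quiet suppress progress messages?
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, mode = c("simulate", "analyze", "recover"),
                         out_dir, gaze_path = NULL, trials_path = NULL,
                         seed = NULL, evidence_cfg = evidence_config(),
                         n_dirichlet_samples = 1e6, quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_config_json(config)
  stopifnot(inherits(config, "generative_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  emit_csv <- function(obj, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(obj, path)
    outputs <<- c(outputs, name)
  }
  emit_json <- function(obj, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <<- c(outputs, name)
  }

  if (mode == "simulate") {
    cfg <- config
    cfg$seed <- stage_seed(config$seed, "simulate")
    say("simulating ", cfg$n_participants, " participants x ",
        cfg$n_trials, " trials (", cfg$experiment, ", ", cfg$model, ")")
    ds <- simulate_dataset(cfg)
    emit_csv(ds$gaze, "gaze.csv")
    emit_csv(ds$trials, "trials.csv")
    emit_csv(ds$truth, "truth.csv")
    write_config_json(config, file.path(out_dir, "config.json"))
    outputs <- c(outputs, "config.json")
  } else if (mode == "analyze") {
    if (is.null(gaze_path)) gaze_path <- file.path(out_dir, "gaze.csv")
    if (is.null(trials_path)) trials_path <- file.path(out_dir, "trials.csv")
    gaze <- read_table_checked(gaze_path, c("participant_id", "trial_index",
                                            "t_ms", "x_px", "y_px", "valid"))
    trials <- read_table_checked(trials_path,
                                 c("participant_id", "trial_index",
                                   "go_time_ms", "button",
                                   "decision_time_ms", "C", "R", "I", "CM"))
    say("loaded ", nrow(gaze), " gaze samples, ", nrow(trials), " trials")

    excl <- exclude_trials(trials)
    kept <- excl$kept
    say("exclusion rule kept ", nrow(kept), "/", nrow(trials), " trials")
    emit_csv(excl$report, "exclusions.csv")

    metrics <- compute_metrics_table(gaze, trials, config$geometry,
                                     stim_off_ms = config$timeline$stim_off_ms)
    emit_csv(metrics, "metrics.csv")

    psy_seed <- stage_seed(config$seed, "psychometrics")
    fits <- fit_psychometrics(metrics, kept, seed = psy_seed)
    emit_csv(fits, "psychometric_fits.csv")
    group_psy <- lapply(split(fits, fits$interval), function(f) {
      b <- f$beta1[!is.na(f$beta1)]
      if (length(b) >= 2 && sd(b) > 0) group_ttest(b) else NULL
    })
    emit_json(group_psy, "psychometric_group_tests.json")

    glms <- fit_cognitive_glms(metrics, kept)
    emit_csv(glms$coefficients, "glm_coefficients.csv")
    if (!is.null(glms$skipped) && nrow(glms$skipped))
      emit_csv(glms$skipped, "glm_skipped.csv")
    group_glm <- group_coefficient_tests(glms$coefficients)
    emit_csv(group_glm, "glm_group_tests.csv")

    corr <- correlate_confidence_dt(kept)
    emit_json(list(per_participant = corr$per_participant,
                   group = corr$group, skipped = corr$skipped),
              "confidence_dt_correlation.json")

    att <- attention_times_table(gaze, kept, config$geometry,
                                 span = config$dt_span,
                                 stim_off_ms = config$timeline$stim_off_ms)
    cm <- fit_confidence_models(att, evidence_cfg,
                                scale_max = config$rating_scale_max)
    fe <- data.frame(participant_id = rownames(cm$F), cm$F,
                     row.names = NULL)
    emit_csv(fe, "free_energy.csv")
    bms_seed <- stage_seed(config$seed, "bms")
    bms <- rfx_bms(cm$F, n_dirichlet_samples = n_dirichlet_samples,
                   seed = bms_seed)
    say("exceedance winner: ", names(which.max(bms$exceedance_prob)))
    emit_json(list(dirichlet_alpha = as.list(bms$dirichlet_alpha),
                   model_frequency = as.list(bms$model_frequency),
                   exceedance_prob = as.list(bms$exceedance_prob),
                   n_dirichlet_samples = bms$n_dirichlet_samples,
                   seed = bms_seed,
                   evidence_config = unclass(evidence_cfg)),
              "bms.json")

    qsum_in <- merge(att, kept[, c("participant_id", "trial_index",
                                   "decision_time_ms")],
                     by = c("participant_id", "trial_index"))
    qsum <- confidence_dt_quartile_summary(qsum_in, cm$posterior,
                                           config$rating_scale_max)
    emit_csv(qsum$quartiles, "confidence_dt_quartiles.csv")
    if (!is.null(qsum$model_predictions))
      emit_csv(qsum$model_predictions, "confidence_dt_model_predictions.csv")
  } else {  # recover
    rec <- model_recovery(config, evidence_cfg,
                          seed = stage_seed(config$seed, "recover"))
    emit_csv(as.data.frame(as.table(rec$confusion),
                           responseName = "n_runs"),
             "recovery_confusion.csv")
    emit_csv(rec$details, "recovery_details.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gazeddm")),
    mode = mode, seed = config$seed,
    stage_seeds = lapply(
      setNames(nm = c("simulate", "psychometrics", "bms", "recover")),
      function(s) stage_seed(config$seed, s)),
    config = "config.json",
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (mode != "simulate") write_config_json(config,
                                            file.path(out_dir, "config.json"))
  invisible(manifest)
}

# CSV reader that names the file and the missing column in its error.
read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- as.data.frame(data.table::fread(path))
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  d
}
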