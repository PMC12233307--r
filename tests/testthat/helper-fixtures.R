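# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# A small simulated cohort plus its metrics table, per generative model.
cached_cohort <- function(model = "hybrid", n_participants = 6,
                          n_trials = 60, seed = 42) {
  key <- paste(model, n_participants, n_trials, seed, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  alpha <- switch(model,
    hybrid = list(alpha0 = 0.5, alpha1 = 0.15, alpha2 = 0.3),
    sequential = list(alpha0 = 0.5, alpha1 = 0.15),
    parallel = list(alpha0 = 0.5, alpha1 = 0.3))
  cfg <- generative_config(n_participants = n_participants,
                           n_trials = n_trials, model = model,
                           alpha = alpha, seed = seed)
  ds <- simulate_dataset(cfg)
  kept <- exclude_trials(ds$trials)$kept
  metrics <- compute_metrics_table(ds$gaze, kept, cfg$geometry)
  out <- list(cfg = cfg, ds = ds, kept = kept, metrics = metrics)
  .fixture_env[[key]] <- out
  out
}

# Brute-force per-sample oracle for interval dwell times and change-of-
# target counts: paints a 1 ms grid with the dwell side and scans it.
grid_metrics_oracle <- function(dwells, a, b) {
  if (b <= a) return(NULL)
  grid <- rep(NA_character_, b - a)
  for (i in seq_len(nrow(dwells))) {
    lo <- max(dwells$start_ms[i], a); hi <- min(dwells$end_ms[i], b)
    if (hi > lo) grid[(lo - a + 1):(hi - a)] <- dwells$side[i]
  }
  t_left <- sum(grid == "left", na.rm = TRUE)
  t_right <- sum(grid == "right", na.rm = TRUE)
  # CoT: adjacent dwell pairs differing in side, counted where the second
  # dwell starts
  n_cot <- 0L
  if (nrow(dwells) > 1) {
    for (i in 2:nrow(dwells)) {
      if (dwells$side[i] != dwells$side[i - 1] &&
          dwells$start_ms[i] >= a && dwells$start_ms[i] < b)
        n_cot <- n_cot + 1L
    }
  }
  list(t_left = t_left, t_right = t_right, n_cot = n_cot)
}

# Random non-overlapping alternstripe dwell set for property tests.
random_dwells <- function(n, horizon_ms = 4000) {
  starts <- sort(runif(n, 0, horizon_ms - 150))
  ends <- pmin(starts + runif(n, 30, 600), horizon_ms)
  # enforce non-overlap
  for (i in seq_len(n - 1)) ends[i] <- min(ends[i], starts[i + 1])
  keep <- ends - starts > 1
  data.frame(side = sample(c("left", "right"), n, replace = TRUE)[keep],
             start_ms = round(starts[keep]), end_ms = round(ends[keep]))
}
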