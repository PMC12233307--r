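test_that("model designs carry the right predictors and normalization", {
  d <- data.frame(dt1_ms = c(2000, 1000, 1500), dt2_ms = c(1000, 1000, 500),
                  C = c(7, 5, 9))
  hy <- model_design(d, "hybrid", standardize = FALSE)
  se <- model_design(d, "sequential", standardize = FALSE)
  pa <- model_design(d, "parallel", standardize = FALSE)
  expect_identical(ncol(hy$X), 3L)
  expect_identical(ncol(se$X), 2L)
  expect_identical(ncol(pa$X), 2L)
  expect_equal(hy$y, c(0.7, 0.5, 0.9))
  expect_equal(unname(hy$X[1, ]), c(1, 1, 1 / 3))
  # zero-total-time trials are dropped only where an inverse term exists
  d0 <- rbind(d, data.frame(dt1_ms = 0, dt2_ms = 0, C = 5))
  expect_identical(model_design(d0, "hybrid")$n_dropped, 1L)
  expect_identical(model_design(d0, "sequential")$n_dropped, 0L)
  # standardization is recorded and reversible
  hs <- model_design(d, "hybrid", standardize = TRUE)
  expect_named(hs$scaling, c("dt_diff", "inv_total"))
  expect_equal(mean(hs$X[, "dt_diff"]), 0)
})

test_that("the conjugate log evidence matches brute-force integration", {
  set.seed(14)
  x <- rnorm(5); y <- 0.3 + 0.5 * x + rnorm(5, sd = 0.2)
  X <- cbind(1, x)

  # residual sum over a (b0, b1) grid, evaluated in closed form so the
  # brute-force integration stays cheap
  n <- length(y)
  Sx <- sum(x); Sxx <- sum(x^2); Sy <- sum(y); Sxy <- sum(x * y)
  Syy <- sum(y^2)
  b_grid <- seq(-6, 6, length.out = 601)
  dg <- b_grid[2] - b_grid[1]
  B0 <- matrix(b_grid, 601, 601)
  B1 <- t(B0)
  RSS <- Syy - 2 * B0 * Sy - 2 * B1 * Sxy + 2 * B0 * B1 * Sx +
    n * B0^2 + B1^2 * Sxx

  # fixed-noise model: integrate the Gaussian likelihood x prior over the
  # coefficient grid
  cfg_f <- evidence_config(prior_sd_alpha = 2, noise_model = "fixed_sd",
                           noise_sd = 0.2)
  lik <- (2 * pi * 0.2^2)^(-n / 2) * exp(-RSS / (2 * 0.2^2)) *
    dnorm(B0, 0, 2) * dnorm(B1, 0, 2)
  oracle_f <- log(sum(lik) * dg^2)
  expect_equal(log_evidence_linear(X, y, cfg_f), oracle_f, tolerance = 1e-3)

  # conjugate model: add a (log-spaced, trapezoid) grid over the noise
  # variance; the coefficient prior scales with the noise SD
  cfg_c <- evidence_config(prior_sd_alpha = 2, noise_model = "conjugate",
                           noise_a = 2, noise_b = 0.5)
  s2_grid <- exp(seq(log(5e-4), log(50), length.out = 200))
  dig <- function(s2) 0.5^2 / gamma(2) * s2^(-3) * exp(-0.5 / s2)
  vals <- vapply(s2_grid, function(s2) {
    lk <- (2 * pi * s2)^(-n / 2) * exp(-RSS / (2 * s2)) *
      dnorm(B0, 0, 2 * sqrt(s2)) * dnorm(B1, 0, 2 * sqrt(s2))
    sum(lk) * dg^2 * dig(s2)
  }, numeric(1))
  oracle_c <- log(sum(diff(s2_grid) * (head(vals, -1) + tail(vals, -1)) / 2))
  expect_equal(log_evidence_linear(X, y, cfg_c), oracle_c, tolerance = 1e-3)
})

test_that("log evidence penalizes complexity and ignores row order", {
  set.seed(15)
  cfg <- evidence_config(prior_sd_alpha = 5)
  worse <- replicate(100, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30, sd = 0.3)
    X1 <- cbind(1, x)
    X2 <- cbind(X1, rnorm(30))  # pure-noise extra predictor
    log_evidence_linear(X2, y, cfg) - log_evidence_linear(X1, y, cfg)
  })
  expect_lt(mean(worse), 0)

  x <- rnorm(20); y <- x + rnorm(20)
  X <- cbind(1, x)
  ord <- sample(20)
  expect_equal(log_evidence_linear(X, y, cfg),
               log_evidence_linear(X[ord, ], y[ord], cfg))
  expect_error(log_evidence_linear(X[1:2, ], y[1:2], cfg), "more observations")
})

test_that("random-effects model selection follows the Dirichlet algebra", {
  # identical evidences: complete symmetry
  F_eq <- matrix(0, nrow = 10, ncol = 3,
                 dimnames = list(NULL, c("hybrid", "sequential", "parallel")))
  b <- rfx_bms(F_eq, n_dirichlet_samples = 2e5, seed = 3)
  expect_equal(unname(b$model_frequency), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(unname(b$exceedance_prob), rep(1 / 3, 3), tolerance = 0.01)

  # one model better by 1000 nats for 20 participants: counts 21/1/1
  F_dom <- cbind(hybrid = rep(1000, 20), sequential = 0, parallel = 0)
  bd <- rfx_bms(F_dom, n_dirichlet_samples = 2e5, seed = 3)
  expect_equal(unname(bd$dirichlet_alpha), c(21, 1, 1), tolerance = 1e-6)
  expect_equal(unname(bd$model_frequency), c(21, 1, 1) / 23, tolerance = 1e-6)
  expect_equal(unname(bd$exceedance_prob), c(1, 0, 0), tolerance = 1e-4)

  # within-participant shift invariance: only evidence differences count
  set.seed(6)
  F_r <- matrix(rnorm(12 * 3, sd = 2), 12, 3)
  F_s <- F_r + rnorm(12)  # participant-specific constants
  b1 <- rfx_bms(F_r, n_dirichlet_samples = 1e4, seed = 9)
  b2 <- rfx_bms(F_s, n_dirichlet_samples = 1e4, seed = 9)
  expect_equal(b1$dirichlet_alpha, b2$dirichlet_alpha, tolerance = 1e-6)
  expect_equal(b1$exceedance_prob, b2$exceedance_prob, tolerance = 1e-6)

  # frequencies are the exact Dirichlet mean and sum to one
  expect_equal(sum(b1$model_frequency), 1, tolerance = 1e-12)
  expect_equal(sum(b1$exceedance_prob), 1, tolerance = 1e-9)
})

test_that("the BMS updates match an independently coded fixed-point loop", {
  naive_bms_alpha <- function(F, alpha0 = rep(1, ncol(F)), iters = 5000) {
    alpha <- alpha0
    for (i in seq_len(iters)) {
      u <- matrix(0, nrow(F), ncol(F))
      for (n in seq_len(nrow(F))) {
        logu <- F[n, ] + digamma(alpha) - digamma(sum(alpha))
        u[n, ] <- exp(logu - max(logu))
        u[n, ] <- u[n, ] / sum(u[n, ])
      }
      alpha <- alpha0 + colSums(u)
    }
    alpha
  }
  set.seed(7)
  F_small <- matrix(rnorm(4, sd = 1.5), nrow = 2, ncol = 2)
  impl <- rfx_bms(F_small, alpha0 = c(1, 1), n_dirichlet_samples = 1e3,
                  seed = 1)
  expect_equal(unname(impl$dirichlet_alpha),
               unname(naive_bms_alpha(F_small)), tolerance = 1e-4)

  # single participant, flat prior: assignment is a digamma-corrected
  # softmax of the evidences, checked by direct evaluation
  F1 <- matrix(c(1.2, 0.1, -0.7), nrow = 1)
  r1 <- rfx_bms(F1, n_dirichlet_samples = 1e3, seed = 2, tol = 1e-10)
  a <- c(1, 1, 1)
  for (i in 1:200) {
    w <- exp(F1[1, ] + digamma(a) - digamma(sum(a)))
    w <- w / sum(w)
    a <- 1 + w
  }
  expect_equal(unname(r1$assignments[1, ]), unname(w), tolerance = 1e-6)
})

test_that("per-participant evidences separate the generating models", {
  cfg <- evidence_config()
  co_h <- cached_cohort("hybrid", n_participants = 6, n_trials = 60)
  att <- attention_times_table(co_h$ds$gaze, co_h$kept, co_h$cfg$geometry)
  fits <- fit_confidence_models(att)
  expect_identical(colnames(fits$F), c("hybrid", "sequential", "parallel"))
  expect_true(all(is.finite(fits$F)))
  # the generating model wins for most participants individually
  expect_gt(mean(apply(fits$F, 1, which.max) == 1), 0.8)
  # posterior-mean coefficients come back near the generating values
  post <- fits$posterior[fits$posterior$model == "hybrid", ]
  expect_lt(abs(mean(post$alpha1) - 0.15), 0.1)
  expect_lt(abs(mean(post$alpha2) - 0.3), 0.15)
})
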