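test_that("quartile bins match a sort-and-slice oracle", {
  # all right choices: every bin proportion is 1
  b <- quartile_bins(seq_len(40), rep(TRUE, 40))
  expect_equal(b$p_q, rep(1, 4))
  expect_equal(b$n_q, rep(10L, 4))

  # choices follow the sign of a symmetric log-ratio: proportions 0,0,1,1
  x <- c(-(20:1), 1:20) / 10
  b2 <- quartile_bins(x, x > 0)
  expect_equal(b2$p_q, c(0, 0, 1, 1))

  # random inputs vs brute force (remainder goes to the lower bins)
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(9:50, 1)
    lr <- rnorm(n); ch <- runif(n) > 0.5
    b3 <- quartile_bins(lr, ch)
    ord <- order(lr)
    sizes <- n %/% 4 + as.integer(seq_len(4) <= n %% 4)
    idx <- split(ord, rep(1:4, times = sizes))
    expect_equal(b3$p_q, vapply(idx, function(i) mean(ch[i]), numeric(1)),
                 ignore_attr = TRUE)
    expect_equal(b3$x_q, vapply(idx, function(i) median(lr[i]), numeric(1)),
                 ignore_attr = TRUE)
  }
  expect_error(quartile_bins(1:5, rep(TRUE, 5)), "at least 8")
})

test_that("the binned logistic fit recovers its own generating curve", {
  flat <- data.frame(x_q = c(-2, -0.5, 0.5, 2), p_q = rep(0.5, 4),
                     n_q = rep(100L, 4))
  f <- fit_logistic(flat)
  expect_lt(abs(f$beta1), 1e-6)

  # self-consistency: bins generated from the curve with beta0=0, beta1=1
  x <- c(-2, -0.5, 0.5, 2)
  gen <- data.frame(x_q = x, p_q = plogis(x), n_q = rep(1e4L, 4))
  f2 <- fit_logistic(gen)
  expect_lt(abs(f2$beta0), 0.05)
  expect_lt(abs(f2$beta1 - 1) / 1, 0.05)

  # antisymmetric proportions around 0.5 give a zero intercept
  sym <- data.frame(x_q = c(-1.5, -0.5, 0.5, 1.5),
                    p_q = c(0.2, 0.4, 0.6, 0.8), n_q = rep(50L, 4))
  expect_lt(abs(fit_logistic(sym)$beta0), 1e-6)

  # complete separation is capped and flagged
  sep <- data.frame(x_q = c(-2, -1, 1, 2), p_q = c(0, 0, 1, 1),
                    n_q = rep(20L, 4))
  fs <- fit_logistic(sep, beta1_max = 25)
  expect_true(fs$capped)
  expect_equal(fs$beta1, 25)
})

test_that("the shuffle-permutation test calibrates as expected", {
  # constant proportions: every shuffle ties, p ~ 1
  const <- data.frame(x_q = c(-1, -0.3, 0.3, 1), p_q = rep(0.4, 4),
                      n_q = rep(20L, 4))
  pt <- permutation_test_beta1(const, n_shuffles = 500, seed = 1)
  expect_gt(pt$perm_p, 0.9)
  expect_false(pt$significant)

  # strictly monotone proportions: only the identity ordering does as well
  mono <- data.frame(x_q = c(-1, -0.3, 0.3, 1), p_q = c(0.1, 0.35, 0.65, 0.9),
                     n_q = rep(25L, 4))
  ex <- permutation_test_beta1(mono, exact = TRUE)
  expect_equal(ex$perm_p, 2 / 25)  # add-one correction over 24 orderings
  expect_true(ex$significant)
  samp <- permutation_test_beta1(mono, n_shuffles = 10000, seed = 7)
  expect_gt(samp$perm_p, 0.025)
  expect_lt(samp$perm_p, 0.06)    # ~ 1/24 under sampling

  # invariant to order-preserving affine rescaling of the bin positions
  resc <- mono; resc$x_q <- 3 * mono$x_q + 1
  a <- permutation_test_beta1(mono, n_shuffles = 2000, seed = 5)
  b <- permutation_test_beta1(resc, n_shuffles = 2000, seed = 5)
  expect_equal(a$perm_p, b$perm_p)
  # slopes scale exactly by the inverse of the rescaling factor
  expect_equal(b$beta1_shuffle_unique, a$beta1_shuffle_unique / 3,
               tolerance = 1e-4)
})

test_that("group t-tests match hand computation and report Bayes factors", {
  sym <- c(-2, -1, 0, 1, 2)
  g <- group_ttest(sym)
  expect_equal(g$t_stat, 0)
  expect_equal(g$p_value, 1)
  expect_gt(g$bf01, 1)

  g2 <- group_ttest(c(1, 2, 3))
  expect_equal(g2$t_stat, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(g2$df, 2)

  g3 <- group_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(g3$t_stat, 0)
  expect_error(group_ttest(rep(1, 5)), "zero variance")
  expect_error(group_ttest(1), "at least 2")
})

test_that("the JZS Bayes factor matches a noncentral-t grid oracle", {
  oracle_bf01 <- function(t, n1, n2 = NULL, r = sqrt(2) / 2) {
    if (is.null(n2)) { neff <- n1; df <- n1 - 1 }
    else { neff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2 }
    delta <- seq(-40, 40, length.out = 80001)
    w <- stats::dcauchy(delta, 0, r)
    m1 <- sum(suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(neff))) * w) *
      (delta[2] - delta[1])
    stats::dt(t, df) / m1
  }
  for (case in list(list(0, 30, NULL), list(0.7, 22, 9), list(2.5, 15, NULL),
                    list(-1.2, 10, 12))) {
    impl <- jzs_bayes_factor(case[[1]], case[[2]], case[[3]])
    orac <- oracle_bf01(case[[1]], case[[2]], case[[3]])
    expect_lt(abs(impl - orac) / orac, 0.01)
  }
  # no effect favours the null; a huge effect crushes it
  expect_gt(jzs_bayes_factor(0, 30), 1)
  expect_lt(jzs_bayes_factor(8, 30), 1e-4)
  expect_gt(jzs_bayes_factor(0.5, 20), jzs_bayes_factor(3, 20))
  # the two-sample comparison that favoured the null in the motivating
  # study (t = 0.70, groups 22 and 9) lands on the same order of magnitude
  bf <- jzs_bayes_factor(0.70, 22, 9)
  expect_gt(bf, 1)
  expect_lt(bf, 20)
})

test_that("decision-time distribution comparison equals the ECDF oracle", {
  same <- compare_dt_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  disj <- compare_dt_distributions(c(1, 2, 3), c(10, 20, 30))
  expect_equal(disj$D, 1)
  set.seed(4)
  a <- rnorm(40); b <- rnorm(35, 0.3)
  d_impl <- compare_dt_distributions(a, b)$D
  grid <- sort(c(a, b))
  d_oracle <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  expect_equal(d_impl, d_oracle)
})

test_that("confidence / decision-time correlation handles signal and null", {
  tr <- data.frame(participant_id = "P01", C = 10:1,
                   decision_time_ms = seq(200, 2000, length.out = 10))
  cc <- correlate_confidence_dt(tr)
  expect_equal(cc$per_participant$r, -1)

  # independent confidence and decision time: group mean near zero
  set.seed(8)
  null_tr <- do.call(rbind, lapply(1:12, function(p) {
    data.frame(participant_id = sprintf("P%02d", p),
               C = sample(0:10, 60, replace = TRUE),
               decision_time_ms = runif(60, 200, 3800))
  }))
  cn <- correlate_confidence_dt(null_tr)
  expect_lt(abs(mean(cn$per_participant$r)), 0.1)
  expect_gt(cn$group$p_value, 0.01)

  # zero-variance participants are skipped, not fatal
  degen <- rbind(null_tr,
                 data.frame(participant_id = "P99", C = 5,
                            decision_time_ms = runif(20, 200, 3800)))
  expect_identical(correlate_confidence_dt(degen)$skipped, "P99")
})

test_that("synthetic cohorts reproduce the expected psychometric structure", {
  co <- cached_cohort("sequential", n_participants = 8, n_trials = 80)
  fits <- fit_psychometrics(co$metrics, co$kept, seed = 2,
                            n_shuffles = 2000)
  soff <- fits[fits$interval == "SOffUD" & !is.na(fits$beta1), ]
  # looking longer at a side predicts choosing it: positive slopes
  expect_gt(mean(soff$beta1), 0)
  expect_gte(mean(soff$significant), 0.5)
  # confidence correlates negatively with decision time in this paradigm
  cc <- correlate_confidence_dt(co$kept)
  expect_lt(mean(cc$per_participant$r), 0)
})
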