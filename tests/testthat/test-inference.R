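# sampler correctness is checked against independent oracles on reduced
# problems, then on structural invariants of the full model

test_that("collapsed 1-parameter posterior matches grid quadrature", {
  counts <- table2_counts()
  pin <- normal_prior(0, 1e-8)
  spec <- prior_spec("custom",
                     beta0 = normal_prior(log(0.19), 0.565),
                     beta1 = pin, beta2 = pin, beta3 = pin)
  fit <- fit_trial(counts, spec, mcmc_config(chains = 2, iter = 8000,
                                             burnin = 1000), seed = 7)
  d <- bayesfactorial:::pooled_draws(fit)
  oracle <- quad_1d(counts, log(0.19), 0.565)
  # agreement to two decimal places in mean and SD
  expect_within(mean(d[, "beta0"]), oracle$mean, 5e-3)
  expect_within(sd(d[, "beta0"]), oracle$sd, 5e-3)
  # pinned coordinates stay at their point mass
  expect_lt(max(abs(d[, c("beta1", "beta2", "beta3")])), 1e-6)
})

test_that("two-parameter reduction matches 2-D grid quadrature within 3 MCSE", {
  counts <- table2_counts()
  pin <- normal_prior(0, 1e-8)
  spec <- prior_spec("custom",
                     beta0 = normal_prior(log(0.19), 0.565),
                     beta1 = normal_prior(0, 0.565),
                     beta2 = pin, beta3 = pin)
  fit <- fit_trial(counts, spec, mcmc_config(chains = 2, iter = 10000,
                                             burnin = 1000), seed = 11)
  d <- bayesfactorial:::pooled_draws(fit)
  oracle <- quad_2d(counts, c(log(0.19), 0), c(0.565, 0.565))
  for (k in 1:2) {
    mcse <- mcse_mean(fit, k)
    expect_lt(abs(mean(d[, k]) - oracle$mean[k]), 3 * mcse + 1e-4)
    expect_equal(sd(d[, k]), oracle$sd[k], tolerance = 0.02)
  }
})

test_that("with no data the sampler recovers the support-constrained prior", {
  empty <- trial_counts(c(0, 1, 0, 1), c(0, 0, 1, 1), rep(0, 4), rep(0, 4))
  neu <- prior_spec("neutral")
  fit <- fit_trial(empty, neu, mcmc_config(chains = 3, iter = 20000,
                                           burnin = 2000), seed = 5)
  d <- bayesfactorial:::pooled_draws(fit)
  # independent route: rejection sampling from the same truncated prior
  set.seed(99)
  mu <- bayesfactorial:::prior_mu(neu)
  tau <- bayesfactorial:::prior_tau(neu)
  raw <- matrix(rnorm(4 * 4e5, rep(mu, each = 4e5), rep(tau, each = 4e5)),
                ncol = 4)
  eta_max <- pmax(raw[, 1], raw[, 1] + raw[, 2], raw[, 1] + raw[, 3],
                  raw[, 1] + raw[, 2] + raw[, 3] + raw[, 4])
  ref <- raw[eta_max < 0, , drop = FALSE]
  for (k in 1:4) {
    tol <- 3 * (mcse_mean(fit, k) + sd(ref[, k]) / sqrt(nrow(ref)))
    expect_lt(abs(mean(d[, k]) - mean(ref[, k])), tol)
    expect_equal(sd(d[, k]), sd(ref[, k]), tolerance = 0.05 * sd(ref[, k]))
  }
})

test_that("a near-degenerate prior dominates the data", {
  spec <- prior_spec("custom",
                     beta0 = normal_prior(-1.66, 1e-6),
                     beta1 = normal_prior(-0.1625, 1e-6),
                     beta2 = normal_prior(-0.1625, 1e-6),
                     beta3 = normal_prior(0, 1e-6))
  fit <- fit_trial(table2_counts(), spec, tiny_mcmc(), seed = 3)
  expect_equal(unname(coef(fit)), c(-1.66, -0.1625, -0.1625, 0),
               tolerance = 1e-4)
})

test_that("every stored draw satisfies the p < 1 support constraint", {
  fit <- fit_trial(table2_counts(), prior_spec("flat_intercept"),
                   tiny_mcmc(), seed = 13)
  d <- bayesfactorial:::pooled_draws(fit)
  eta_max <- pmax(d[, 1], d[, 1] + d[, 2], d[, 1] + d[, 3],
                  d[, 1] + d[, 2] + d[, 3] + d[, 4])
  expect_true(all(eta_max < 0))
})

test_that("sampling is deterministic given the seed and chains differ", {
  f1 <- fit_trial(table2_counts(), prior_spec("neutral"), tiny_mcmc(),
                  seed = 17)
  f2 <- fit_trial(table2_counts(), prior_spec("neutral"), tiny_mcmc(),
                  seed = 17)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws[, , 1], f1$draws[, , 2]))
  f3 <- fit_trial(table2_counts(), prior_spec("neutral"), tiny_mcmc(),
                  seed = 18)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("relabeling depth and duration swaps the marginal comparisons", {
  counts <- table2_counts()
  swapped <- trial_counts(counts$duration, counts$depth, counts$events,
                          counts$total)
  cfg <- mcmc_config(chains = 2, iter = 8000, burnin = 1000)
  f1 <- fit_trial(counts, prior_spec("neutral"), cfg, seed = 21)
  f2 <- fit_trial(swapped, prior_spec("neutral"), cfg, seed = 22)
  s1 <- summary(comparisons(f1))
  s2 <- summary(comparisons(f2))
  pick <- function(s, id) s[s$comparison == id, "rr_median"]
  expect_equal(pick(s1, "marginal_depth"), pick(s2, "marginal_duration"),
               tolerance = 0.02)
  expect_equal(pick(s1, "marginal_duration"), pick(s2, "marginal_depth"),
               tolerance = 0.02)
  expect_equal(pick(s1, "arm_deep72"), pick(s2, "arm_long335"),
               tolerance = 0.02)
})

test_that("discarding the historical baseline pushes RRs away from 1", {
  # sensitivity analysis: a vague intercept prior removes the upward pull
  # on the low observed control rate, so all arm RRs move away from the
  # null and every experimental arm crosses the RR futility threshold
  cfg <- mcmc_config(chains = 2, iter = 8000, burnin = 1000)
  f_flat <- fit_trial(table2_counts(), prior_spec("flat_intercept"), cfg,
                      seed = 23)
  f_neu <- fit_trial(table2_counts(), prior_spec("neutral"), cfg, seed = 24)
  s_flat <- summary(comparisons(f_flat))
  s_neu <- summary(comparisons(f_neu))
  arms <- s_flat$comparison %in% c("arm_deep72", "arm_long335",
                                   "arm_deep_long")
  expect_true(all(s_flat$rr_median[arms] > s_neu$rr_median[arms]))
  rep_flat <- monitoring_report(comparisons(f_flat),
                                rule_presets("futility-rr"))
  expect_true(attr(rep_flat, "all_arms_futile"))
})

test_that("partially empty designs are rejected by inference", {
  bad <- trial_counts(c(0, 1, 0, 1), c(0, 0, 1, 1),
                      c(1, 0, 1, 1), c(10, 0, 10, 10))
  expect_error(fit_trial(bad, prior_spec("neutral"), tiny_mcmc()),
               "empty cell: 32.0C_72h")
})

test_that("non-convergence is reported, not silently passed", {
  cfg <- mcmc_config(chains = 2, iter = 2000, burnin = 500,
                     rhat_limit = 0.5)  # unreachable on purpose
  expect_warning(fit_trial(table2_counts(), prior_spec("neutral"), cfg,
                           seed = 1),
                 "non-convergence")
})

test_that("comparison algebra is exact on hand-picked draws", {
  # all effects zero: every RR 1, every RD 0
  cmp0 <- comparisons(fake_fit(c(log(0.19), 0, 0, 0)))
  for (id in names(cmp0)) {
    expect_equal(cmp0[[id]]$rr, rep(1, 2))
    expect_equal(cmp0[[id]]$rd, rep(0, 2))
  }
  # multiplicative effects without interaction
  b <- c(-1.66, -0.1625, -0.1625, 0)
  cmp <- comparisons(fake_fit(b))
  expect_equal(cmp$marginal_depth$rr[1], exp(-0.1625))
  expect_equal(cmp$marginal_depth$rr[1], 0.85, tolerance = 2e-4)
  expect_equal(cmp$arm_deep72$rr[1], exp(b[2]))
  expect_equal(cmp$arm_deep_long$rr[1], exp(sum(b[2:4])))
  # risk differences from the cell probabilities, control minus treatment
  p <- cell_probabilities(b)
  expect_equal(cmp$arm_deep_long$rd[1], unname(p[1] - p[4]))
  expect_equal(cmp$marginal_duration$rd[1],
               unname((p[1] + p[2]) / 2 - (p[3] + p[4]) / 2))
})

test_that("draws persist and reload losslessly", {
  fit <- fit_trial(table2_counts(), prior_spec("neutral"),
                   mcmc_config(chains = 2, iter = 500, burnin = 100,
                               rhat_limit = 1.3),
                   seed = 31)
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_equal(back$rhat, fit$rhat, tolerance = 1e-12)
  expect_equal(back$prior$name, "neutral")
  expect_equal(back$counts, fit$counts, ignore_attr = "labels")
})
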