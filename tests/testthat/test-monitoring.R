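draws_of <- function(rr, rd = numeric(length(rr)))
  structure(list(id = "x", label = "x", rr = rr, rd = rd),
            class = "comparison_draws")

test_that("threshold probabilities are strict-side fractions with ties set aside", {
  cmp <- draws_of(c(rep(0.5, 4), rep(1.5, 6)))
  expect_equal(as.numeric(threshold_probability(cmp, "rr", 0.9, "below")),
               0.4)
  expect_equal(as.numeric(threshold_probability(cmp, "rr", 0.9, "above")),
               0.6)
  # all draws at RR 1: nothing below 0.9
  expect_equal(as.numeric(threshold_probability(draws_of(rep(1, 50)),
                                                "rr", 0.9, "below")), 0)
  # draws exactly at the cutoff count as neither side
  tied <- draws_of(c(0.8, 0.9, 0.9, 1.1))
  below <- threshold_probability(tied, "rr", 0.9, "below")
  above <- threshold_probability(tied, "rr", 0.9, "above")
  expect_equal(as.numeric(below), 0.25)
  expect_equal(attr(below, "ties"), 0.5)
  expect_equal(as.numeric(below) + as.numeric(above) + attr(below, "ties"),
               1)
})

test_that("below-probabilities are nondecreasing in the cutoff", {
  set.seed(1)
  for (rep in 1:5) {
    cmp <- draws_of(exp(rnorm(200, 0, 0.4)))
    cuts <- seq(0.5, 2, by = 0.1)
    probs <- vapply(cuts, function(cc)
      as.numeric(threshold_probability(cmp, "rr", cc, "below")), numeric(1))
    expect_true(all(diff(probs) >= 0))
  }
})

test_that("rule semantics: futility triggers on low, safety/efficacy on high probability", {
  # 20% of draws show RR < 0.90: futility not triggered at the 0.10 line
  cmp <- draws_of(c(rep(0.8, 20), rep(1.2, 80)),
                  c(rep(0.06, 30), rep(-0.06, 70)))
  fut <- evaluate_rule(cmp, stopping_rule("futility_rr", 0.90, 0.10))
  expect_equal(fut$posterior_prob, 0.2)
  expect_false(fut$triggered)
  # 5% of draws show RR < 0.90: triggered
  cmp2 <- draws_of(c(rep(0.8, 5), rep(1.2, 95)))
  expect_true(evaluate_rule(cmp2,
                            stopping_rule("futility_rr", 0.90, 0.10))$triggered)
  # futility on the RD scale: Pr(RD > 0.01) = 0.3 >= 0.10, keep going
  expect_false(evaluate_rule(cmp, stopping_rule("futility_rd", 0.01,
                                                0.10))$triggered)
  # safety: Pr(RD < -0.05) = 0.7 > 0.5, stop
  saf <- evaluate_rule(cmp, stopping_rule("safety_rd", -0.05, 0.50))
  expect_equal(saf$posterior_prob, 0.7)
  expect_true(saf$triggered)
  # no harm signal at all: probability 0, not triggered
  none <- draws_of(rep(1, 10), rep(0, 10))
  expect_false(evaluate_rule(none, stopping_rule("safety_rd", -0.05,
                                                 0.50))$triggered)
  # efficacy needs overwhelming evidence
  eff <- draws_of(rep(0.7, 100))
  expect_true(evaluate_rule(eff, stopping_rule("efficacy_rr", 0.85,
                                               0.99))$triggered)
})

test_that("rule construction rejects mismatched scales", {
  expect_error(stopping_rule("futility_rr", -0.5, 0.1), "positive")
  expect_error(stopping_rule("safety_rd", 0.05, 0.5), "negative")
  expect_error(stopping_rule("futility_rr", 0.9, 1.5), "prob_threshold")
  expect_error(rule_presets("pocock"), "unknown rule preset")
})

test_that("presets encode the monitoring plan thresholds", {
  rl <- rule_presets()
  expect_equal(rl[["futility-rr"]]$effect_threshold, 0.90)
  expect_equal(rl[["futility-rr"]]$prob_threshold, 0.10)
  expect_equal(rl[["futility-rd"]]$effect_threshold, 0.01)
  expect_equal(rl[["safety-rd"]]$effect_threshold, -0.05)
  expect_equal(rl[["safety-rd"]]$prob_threshold, 0.50)
  expect_equal(rl[["efficacy-rr"]]$effect_threshold, 0.85)
  expect_equal(rl[["efficacy-rr"]]$prob_threshold, 0.99)
})

test_that("rules round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("- kind: futility_rr", "  effect_threshold: 0.90",
               "  prob_threshold: 0.10",
               "- kind: safety_rd", "  effect_threshold: -0.05",
               "  prob_threshold: 0.50"), path)
  rl <- read_rules(path)
  expect_equal(rl$futility_rr, stopping_rule("futility_rr", 0.90, 0.10))
  expect_equal(rl$safety_rd, stopping_rule("safety_rd", -0.05, 0.50))
  writeLines("presets: [futility-rr, efficacy-rr]", path)
  expect_equal(names(read_rules(path)), c("futility-rr", "efficacy-rr"))
})

test_that("the report evaluates every rule against every comparison", {
  fit <- fit_trial(table2_counts(), prior_spec("neutral"), tiny_mcmc(),
                   seed = 2)
  comps <- comparisons(fit)
  report <- monitoring_report(comps, rule_presets())
  expect_equal(nrow(report), 5 * 4)
  expect_setequal(unique(report$comparison), names(comps))
  # triggered is a pure function of probability and threshold
  lt <- report$kind %in% c("futility_rr", "futility_rd")
  expect_equal(report$triggered[lt],
               report$probability[lt] < report$prob_threshold[lt])
  expect_equal(report$triggered[!lt],
               report$probability[!lt] > report$prob_threshold[!lt])
  expect_error(monitoring_report(comps, list()), "empty rule list")
})

test_that("re-evaluating persisted draws reproduces the report exactly", {
  fit <- fit_trial(table2_counts(), prior_spec("neutral"),
                   mcmc_config(chains = 2, iter = 1000, burnin = 200),
                   seed = 4)
  r1 <- monitoring_report(comparisons(fit), rule_presets())
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path)
  r2 <- monitoring_report(comparisons(read_draws(path)), rule_presets())
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  expect_equal(attr(r1, "all_arms_futile"), attr(r2, "all_arms_futile"))
})

test_that("the trial-level flag needs all three experimental arms futile", {
  mk <- function(p_benefit) {
    # comparisons whose Pr(RR < 0.90) is p_benefit per arm
    comps <- lapply(bayesfactorial:::COMPARISON_IDS, function(id) {
      n <- 1000
      nb <- round(p_benefit[[id]] * n)
      structure(list(id = id, label = id,
                     rr = c(rep(0.8, nb), rep(1.2, n - nb)),
                     rd = rep(0, n)), class = "comparison_draws")
    })
    names(comps) <- bayesfactorial:::COMPARISON_IDS
    structure(comps, prior_name = "synthetic", class = "fmb_comparisons")
  }
  all_futile <- mk(list(marginal_depth = 0.5, marginal_duration = 0.5,
                        arm_deep72 = 0.05, arm_long335 = 0.04,
                        arm_deep_long = 0.02))
  rep1 <- monitoring_report(all_futile, rule_presets("futility-rr"))
  expect_true(attr(rep1, "all_arms_futile"))
  one_alive <- mk(list(marginal_depth = 0.5, marginal_duration = 0.5,
                       arm_deep72 = 0.2, arm_long335 = 0.04,
                       arm_deep_long = 0.02))
  rep2 <- monitoring_report(one_alive, rule_presets("futility-rr"))
  expect_false(attr(rep2, "all_arms_futile"))
})
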