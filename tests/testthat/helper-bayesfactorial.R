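# shared fixtures and independent oracles for the test suite

# absolute-difference expectation (expect_equal's tolerance is relative,
# which is the wrong scale for quantities near zero)
expect_within <- function(actual, expected, tol, label = NULL) {
  lab <- label %||% paste(deparse(substitute(actual)), "vs", expected)
  testthat::expect(abs(actual - expected) <= tol,
                   sprintf("%s: got %.5g, want %.5g +/- %.3g",
                           lab, actual, expected, tol))
  invisible(actual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table2_counts <- function() {
  trial_counts(depth    = c(0, 1, 0, 1),
               duration = c(0, 0, 1, 1),
               events   = c(7, 13, 15, 14),
               total    = c(95, 90, 96, 83))
}

tiny_mcmc <- function() mcmc_config(chains = 2, iter = 2000, burnin = 500, rhat_limit = 1.1)

# independent scalar log-posterior oracle: Bernoulli-product likelihood over
# cells plus normal prior log densities, coded without the package's C++ path
oracle_log_post <- function(beta, counts, mu, tau) {
  d <- as.data.frame(counts)
  eta <- beta[1] + beta[2] * d$depth + beta[3] * d$duration +
    beta[4] * d$depth * d$duration
  if (any(eta >= 0)) return(-Inf)
  p <- exp(eta)
  sum(d$events * log(p) + (d$total - d$events) * log(1 - p)) +
    sum(dnorm(beta, mu, tau, log = TRUE))
}

# dense grid quadrature for the collapsed 1-parameter model: all effect
# coefficients pinned at 0, every cell probability exp(b0)
quad_1d <- function(counts, mu0, tau0, lo = -6, hi = -1e-4, n = 40001) {
  g <- seq(lo, hi, length.out = n)
  ev <- sum(counts$events); tot <- sum(counts$total)
  loglik <- ev * g + (tot - ev) * log1p(-exp(g))
  logw <- loglik + dnorm(g, mu0, tau0, log = TRUE)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  m <- sum(w * g)
  list(mean = m, sd = sqrt(sum(w * (g - m)^2)))
}

# 2-D quadrature for the two-parameter reduction (b2 = b3 = 0): cells pool
# by depth level, p(depth 0) = exp(b0), p(depth 1) = exp(b0 + b1)
quad_2d <- function(counts, mu, tau, n = 601) {
  ev0 <- sum(counts$events[counts$depth == 0])
  n0 <- sum(counts$total[counts$depth == 0])
  ev1 <- sum(counts$events[counts$depth == 1])
  n1 <- sum(counts$total[counts$depth == 1])
  g0 <- seq(mu[1] - 5 * tau[1], min(-1e-4, mu[1] + 5 * tau[1]),
            length.out = n)
  g1 <- seq(mu[2] - 5 * tau[2], mu[2] + 5 * tau[2], length.out = n)
  lw <- outer(g0, g1, function(b0, b1) {
    eta1 <- b0 + b1
    ll <- ev0 * b0 + (n0 - ev0) * log1p(-exp(b0)) +
      ev1 * eta1 + (n1 - ev1) * log1p(-exp(pmin(eta1, -1e-12)))
    ifelse(eta1 >= 0, -Inf, ll) +
      dnorm(b0, mu[1], tau[1], log = TRUE) +
      dnorm(b1, mu[2], tau[2], log = TRUE)
  })
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m0 <- sum(rowSums(w) * g0); m1 <- sum(colSums(w) * g1)
  list(mean = c(m0, m1),
       sd = c(sqrt(sum(rowSums(w) * (g0 - m0)^2)),
              sqrt(sum(colSums(w) * (g1 - m1)^2))))
}

# Monte Carlo standard error of a posterior mean from the fit's ESS
mcse_mean <- function(fit, k) {
  d <- bayesfactorial:::pooled_draws(fit)
  sd(d[, k]) / sqrt(fit$ess[k])
}

# minimal fit-shaped object so comparison algebra can be checked on
# hand-picked coefficient draws
fake_fit <- function(betas, prior_name = "custom") {
  betas <- matrix(betas, ncol = 4)
  draws <- array(rbind(betas, betas), dim = c(nrow(betas), 4, 2),
                 dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3"),
                                 c("chain1", "chain2")))
  draws[, , 1] <- betas; draws[, , 2] <- betas
  structure(list(draws = draws, rhat = rep(1, 4), ess = rep(nrow(betas), 4),
                 prior = list(name = prior_name)),
            class = "fmb_fit")
}
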