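#' MCMC configuration
#'
#' Defaults follow the analysis configuration used for the Optimizing Cooling
#' Trial reanalysis: 3 chains of 40,000 kept iterations each after a 4,000
#' iteration burn-in.  [mcmc_config_sim()] is a reduced configuration
#' (3 x 4,000 after 1,000) intended for operating-characteristics runs where
#' thousands of fits are needed.
#'
#' @param chains number of chains (>= 2 so convergence can be diagnosed).
#' @param iter kept iterations per chain.
#' @param burnin discarded initial iterations per chain.
#' @param rhat_limit convergence warning threshold for the split Gelman-Rubin
#'   statistic.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iter = 40000L, burnin = 4000L,
                        rhat_limit = 1.01) {
  chains <- as.integer(chains); iter <- as.integer(iter)
  burnin <- as.integer(burnin)
  if (chains < 2L) stop("need at least 2 chains for diagnostics",
                        call. = FALSE)
  if (iter < 1L || burnin < 0L)
    stop("need iter >= 1 and burnin >= 0", call. = FALSE)
  structure(list(chains = chains, iter = iter, burnin = burnin,
                 rhat_limit = rhat_limit), class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_sim <- function(chains = 3L, iter = 4000L, burnin = 1000L,
                            rhat_limit = 1.05) {
  mcmc_config(chains, iter, burnin, rhat_limit)
}

# an admissible start near the prior mean: pull the intercept down until all
# cell probabilities are < 1, then jitter (0.1 on the log scale), shrinking
# the jitter if it lands outside the support
admissible_init <- function(counts, prior) {
  mu <- prior_mu(prior)
  tau <- prior_tau(prior)
  base <- mu
  eta_max <- function(b)
    max(b[1], b[1] + b[2], b[1] + b[3], b[1] + b[2] + b[3] + b[4])
  if (eta_max(base) > -0.1) base[1] <- base[1] - (eta_max(base) + 0.1)
  for (scale in 0.1 * 2^-(0:10)) {
    cand <- base + scale * pmin(tau, 1) * rnorm(4)
    lp <- .log_post_cpp(cand, counts$events, counts$total, mu, tau)
    if (is.finite(lp)) return(cand)
  }
  base
}

#' Fit the Bayesian log-binomial model to 2x2 factorial trial counts
#'
#' Samples the posterior of `(beta0, beta1, beta2, beta3)` in the model
#' `y ~ Bernoulli(p)`, `log p = beta0 + beta1*depth + beta2*duration +
#' beta3*depth*duration` under independent normal priors, subject to the
#' constraint that every cell probability stays below 1.  Sampling uses
#' univariate slice sampling with stepping out, one coordinate sweep per
#' iteration; the support constraint is enforced by a `-Inf` log posterior
#' outside it.  Each chain starts at an admissible jittered point near the
#' prior mean.  A single `seed` drives all chains deterministically.
#'
#' After sampling, the split Gelman-Rubin statistic is computed per
#' coefficient; the fit warns (rather than failing) if any exceeds
#' `mcmc$rhat_limit`.
#'
#' @param counts a [trial_counts] object; every cell must have `total > 0`.
#'   As a special case an all-empty design (all totals 0) is accepted and
#'   samples the support-constrained prior, which is how prior-recovery
#'   checks are run.
#' @param prior a [prior_spec]; defaults to the neutral set.
#' @param mcmc an [mcmc_config].
#' @param seed integer seed.
#' @return An object of class `fmb_fit` with components `draws` (an
#'   `iter x 4 x chains` array of kept draws), `rhat`, `ess`, `counts`,
#'   `prior`, `mcmc`, `seed`.
#' @examples
#' fit <- fit_trial(optimizing_cooling_counts(),
#'                  prior_spec("neutral"),
#'                  mcmc_config(chains = 2, iter = 2000, burnin = 500),
#'                  seed = 1)
#' summary(fit)
#' @export
fit_trial <- function(counts, prior = prior_spec("neutral"),
                      mcmc = mcmc_config(), seed = 1L) {
  stopifnot(inherits(counts, "trial_counts"), inherits(prior, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (any(counts$total == 0L) && any(counts$total > 0L))
    stop("fit_trial: all four cells need total > 0 (empty cell: ",
         paste(CELL_LABELS[counts$total == 0L], collapse = ", "), ")",
         call. = FALSE)
  set.seed(as.integer(seed))
  mu <- prior_mu(prior)
  tau <- prior_tau(prior)
  if (any(tau <= 0))
    stop("fit_trial: degenerate (tau = 0) priors cannot be sampled; ",
         "use a small positive tau", call. = FALSE)
  nkeep <- mcmc$iter
  draws <- array(NA_real_, dim = c(nkeep, 4L, mcmc$chains),
                 dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3"),
                                 paste0("chain", seq_len(mcmc$chains))))
  for (ch in seq_len(mcmc$chains)) {
    init <- admissible_init(counts, prior)
    d <- .slice_sample_cpp(counts$events, counts$total, mu, tau, init,
                           mcmc$burnin + nkeep, 1.0, 50L)
    draws[, , ch] <- d[(mcmc$burnin + 1):(mcmc$burnin + nkeep), , drop = FALSE]
  }
  rhat <- vapply(1:4, function(k) split_rhat(draws[, k, ]), numeric(1))
  ess <- vapply(1:4, function(k) ess_basic(draws[, k, ]), numeric(1))
  names(rhat) <- names(ess) <- dimnames(draws)[[2]]
  if (any(rhat >= mcmc$rhat_limit))
    warning(sprintf(
      "possible non-convergence: max split R-hat = %.4f (limit %.3f)",
      max(rhat), mcmc$rhat_limit), call. = FALSE)
  structure(list(draws = draws, rhat = rhat, ess = ess, counts = counts,
                 prior = prior, mcmc = mcmc, seed = as.integer(seed)),
            class = "fmb_fit")
}

# pooled draws matrix (chains stacked), ndraws x 4
pooled_draws <- function(fit) {
  d <- fit$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch]))
  colnames(out) <- dimnames(d)[[2]]
  out
}

#' @export
print.fmb_fit <- function(x, ...) {
  cat("Bayesian 2x2 factorial log-binomial fit\n")
  cat(sprintf("  data: n = %d, events = %d; prior: %s\n",
              sum(x$counts$total), sum(x$counts$events), x$prior$name))
  cat(sprintf("  %d chains x %d kept iterations (burn-in %d), seed %d\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$burnin, x$seed))
  cat(sprintf("  max split R-hat: %.4f\n", max(x$rhat)))
  invisible(x)
}

#' Posterior coefficient summaries
#'
#' @param object an `fmb_fit`.
#' @param prob credible-interval mass (default 0.95, equal-tailed).
#' @param ... unused.
#' @return `summary` returns a data frame with posterior mean, SD, median,
#'   credible limits, split R-hat and effective sample size per coefficient.
#' @export
summary.fmb_fit <- function(object, prob = 0.95, ...) {
  d <- pooled_draws(object)
  a <- (1 - prob) / 2
  out <- data.frame(
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    median = apply(d, 2, median),
    lower = apply(d, 2, quantile, a),
    upper = apply(d, 2, quantile, 1 - a),
    rhat = object$rhat,
    ess = round(object$ess))
  names(out)[4:5] <- sprintf("q%g", 100 * c(a, 1 - a))
  class(out) <- c("summary.fmb_fit", "data.frame")
  out
}

#' @export
print.summary.fmb_fit <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits)
  invisible(x)
}

#' @rdname summary.fmb_fit
#' @return `coef` returns the posterior medians of the four coefficients.
#' @export
coef.fmb_fit <- function(object, ...) {
  apply(pooled_draws(object), 2, median)
}

#' Posterior mortality risk per arm
#'
#' @param object an `fmb_fit`.
#' @param ... unused.
#' @return Data frame of posterior mean, median and 95% CrI of the event
#'   probability in each of the four cells.
#' @export
predict.fmb_fit <- function(object, ...) {
  d <- pooled_draws(object)
  p <- cbind(exp(d[, 1]),
             exp(d[, 1] + d[, 2]),
             exp(d[, 1] + d[, 3]),
             exp(rowSums(d)))
  data.frame(arm = CELL_LABELS,
             depth = CELL_ORDER[, "depth"], duration = CELL_ORDER[, "duration"],
             mean = colMeans(p),
             median = apply(p, 2, median),
             lower95 = apply(p, 2, quantile, 0.025),
             upper95 = apply(p, 2, quantile, 0.975))
}

#' Posterior-predictive replicate count tables
#'
#' Draws coefficient vectors from the posterior and simulates event counts
#' for each cell at the observed cell sizes.
#'
#' @param object an `fmb_fit`.
#' @param nsim number of replicate tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of [trial_counts] objects of length `nsim`.
#' @export
simulate.fmb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- pooled_draws(object)
  idx <- sample.int(nrow(d), nsim, replace = TRUE)
  lapply(idx, function(i) {
    p <- cell_probabilities(d[i, ])
    trial_counts(CELL_ORDER[, "depth"], CELL_ORDER[, "duration"],
                 rbinom(4, object$counts$total, p), object$counts$total)
  })
}

#' Pearson residuals at the posterior mean risks
#'
#' @param object an `fmb_fit`.
#' @param ... unused.
#' @return Named numeric vector, one residual per cell:
#'   `(events - total * p_hat) / sqrt(total * p_hat * (1 - p_hat))`.
#' @export
residuals.fmb_fit <- function(object, ...) {
  p_hat <- predict(object)$mean
  n <- object$counts$total
  y <- object$counts$events
  stats::setNames((y - n * p_hat) / sqrt(n * p_hat * (1 - p_hat)),
                  CELL_LABELS)
}

#' Persist and reload posterior draws
#'
#' Draws are written as a CSV with columns `chain, iteration,
#' beta0..beta3`; convergence diagnostics, the prior, the data and the MCMC
#' configuration go to a JSON side-car `<path>.meta.json` so a report can be
#' re-evaluated from disk exactly.
#'
#' @param fit an `fmb_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  tab <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch)
    data.frame(chain = ch, iteration = seq_len(dim(d)[1]), d[, , ch])))
  write.csv(tab, path, row.names = FALSE)
  meta <- list(
    rhat = as.list(fit$rhat), ess = as.list(fit$ess), seed = fit$seed,
    mcmc = unclass(fit$mcmc),
    prior = list(name = fit$prior$name, mu = prior_mu(fit$prior),
                 tau = prior_tau(fit$prior)),
    counts = as.data.frame(fit$counts)[, c("depth", "duration", "events",
                                           "total")])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_draws
#' @return `read_draws` returns an `fmb_fit` rebuilt from the two files.
#' @export
read_draws <- function(path) {
  tab <- read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  chains <- max(tab$chain)
  iter <- max(tab$iteration)
  draws <- array(NA_real_, dim = c(iter, 4L, chains),
                 dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3"),
                                 paste0("chain", seq_len(chains))))
  for (ch in seq_len(chains))
    draws[, , ch] <- as.matrix(tab[tab$chain == ch,
                                   c("beta0", "beta1", "beta2", "beta3")])
  counts <- trial_counts(meta$counts$depth, meta$counts$duration,
                         meta$counts$events, meta$counts$total)
  prior <- prior_spec("custom",
                      beta0 = normal_prior(meta$prior$mu[1], meta$prior$tau[1]),
                      beta1 = normal_prior(meta$prior$mu[2], meta$prior$tau[2]),
                      beta2 = normal_prior(meta$prior$mu[3], meta$prior$tau[3]),
                      beta3 = normal_prior(meta$prior$mu[4], meta$prior$tau[4]))
  prior$name <- meta$prior$name
  structure(list(draws = draws, rhat = unlist(meta$rhat),
                 ess = unlist(meta$ess), counts = counts, prior = prior,
                 mcmc = do.call(mcmc_config, meta$mcmc), seed = meta$seed),
            class = "fmb_fit")
}
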