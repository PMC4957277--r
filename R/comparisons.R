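COMPARISON_IDS <- c("marginal_depth", "marginal_duration",
                    "arm_deep72", "arm_long335", "arm_deep_long")

COMPARISON_LABELS <- c(
  marginal_depth    = "32.0C vs 33.5C (marginal)",
  marginal_duration = "120h vs 72h (marginal)",
  arm_deep72        = "32.0C for 72h vs standard",
  arm_long335       = "33.5C for 120h vs standard",
  arm_deep_long     = "32.0C for 120h vs standard")

#' Per-draw relative risks and risk differences for the five comparisons
#'
#' Converts posterior coefficient draws into the treatment comparisons of a
#' 2x2 factorial monitoring plan:
#' \describe{
#'   \item{arm comparisons}{each experimental arm versus standard care:
#'     RR = `exp(beta1)` (deeper only), `exp(beta2)` (longer only),
#'     `exp(beta1 + beta2 + beta3)` (both); RD = `p(0,0) - p(arm)`.}
#'   \item{marginal comparisons}{one factor averaged over the other:
#'     RR = `exp(beta1 + beta3/2)` (depth), `exp(beta2 + beta3/2)`
#'     (duration); RD = equal-weight mean of the two control-level cell
#'     probabilities minus the equal-weight mean of the two
#'     treatment-level cell probabilities.}
#' }
#' RD follows the convention `p_control - p_treatment`, so positive values
#' favor the experimental condition.  The per-draw number needed to treat is
#' `1/RD`; draws with `|RD| < 1e-12` are excluded from NNT summaries and
#' counted.
#'
#' @param fit an `fmb_fit` from [fit_trial()].
#' @return An object of class `fmb_comparisons`: a named list of five
#'   `comparison_draws` elements, each with fields `id`, `label`, `rr`, `rd`.
#' @export
comparisons <- function(fit) {
  stopifnot(inherits(fit, "fmb_fit"))
  d <- pooled_draws(fit)
  b0 <- d[, 1]; b1 <- d[, 2]; b2 <- d[, 3]; b3 <- d[, 4]
  p00 <- exp(b0); p10 <- exp(b0 + b1)
  p01 <- exp(b0 + b2); p11 <- exp(b0 + b1 + b2 + b3)
  make <- function(id, rr, rd)
    structure(list(id = id, label = COMPARISON_LABELS[[id]],
                   rr = rr, rd = rd), class = "comparison_draws")
  out <- list(
    marginal_depth = make("marginal_depth", exp(b1 + b3 / 2),
                          (p00 + p01) / 2 - (p10 + p11) / 2),
    marginal_duration = make("marginal_duration", exp(b2 + b3 / 2),
                             (p00 + p10) / 2 - (p01 + p11) / 2),
    arm_deep72 = make("arm_deep72", exp(b1), p00 - p10),
    arm_long335 = make("arm_long335", exp(b2), p00 - p01),
    arm_deep_long = make("arm_deep_long", exp(b1 + b2 + b3), p00 - p11))
  structure(out, prior_name = fit$prior$name, class = "fmb_comparisons")
}

#' @export
print.comparison_draws <- function(x, ...) {
  cat(sprintf("%s: %d draws, RR median %.3f, RD mean %.3f\n",
              x$label, length(x$rr), median(x$rr), mean(x$rd)))
  invisible(x)
}

#' Posterior summary table for all comparisons
#'
#' @param object an `fmb_comparisons`.
#' @param prob credible-interval mass (equal-tailed).
#' @param ... unused.
#' @return Data frame, one row per comparison: RR posterior median and CrI,
#'   `Pr(RR < 1)`, `Pr(RR < 0.90)`; RD posterior mean and CrI,
#'   `Pr(RD > 0.01)`, `Pr(RD < -0.05)`; NNT posterior median and the number
#'   of draws excluded from it for `|RD| < 1e-12`.
#' @export
summary.fmb_comparisons <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  rows <- lapply(object, function(cmp) {
    nnt_ok <- abs(cmp$rd) >= 1e-12
    data.frame(
      comparison = cmp$id,
      label = cmp$label,
      rr_median = median(cmp$rr),
      rr_lower = quantile(cmp$rr, a), rr_upper = quantile(cmp$rr, 1 - a),
      pr_rr_lt_1 = mean(cmp$rr < 1),
      pr_rr_lt_0.90 = mean(cmp$rr < 0.90),
      rd_mean = mean(cmp$rd),
      rd_lower = quantile(cmp$rd, a), rd_upper = quantile(cmp$rd, 1 - a),
      pr_rd_gt_0.01 = mean(cmp$rd > 0.01),
      pr_rd_lt_m0.05 = mean(cmp$rd < -0.05),
      nnt_median = median(1 / cmp$rd[nnt_ok]),
      nnt_excluded = sum(!nnt_ok),
      check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "prior_name") <- attr(object, "prior_name")
  out
}

#' @export
print.fmb_comparisons <- function(x, ...) {
  cat("Posterior comparisons (prior:", attr(x, "prior_name"), ")\n")
  s <- summary(x)
  cat(sprintf("  %-28s RR %5.2f (%.2f-%.2f)  Pr(RR<1) %3.0f%%  RD %+.2f\n",
              s$label, s$rr_median, s$rr_lower, s$rr_upper,
              100 * s$pr_rr_lt_1, s$rd_mean), sep = "")
  invisible(x)
}

#' Prior and posterior density plot for one comparison
#'
#' Draws the posterior density of the log RR of a comparison together with
#' its implied normal prior.
#'
#' @param x an `fmb_fit`.
#' @param id one of `"marginal_depth"`, `"marginal_duration"`,
#'   `"arm_deep72"`, `"arm_long335"`, `"arm_deep_long"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fmb_fit <- function(x, id = "marginal_duration", ...) {
  comps <- comparisons(x)
  cmp <- comps[[match.arg(id, COMPARISON_IDS)]]
  mu <- prior_mu(x$prior); tau <- prior_tau(x$prior)
  # implied normal prior on the comparison's log-RR scale
  w <- switch(cmp$id,
              marginal_depth = c(0, 1, 0, 0.5),
              marginal_duration = c(0, 0, 1, 0.5),
              arm_deep72 = c(0, 1, 0, 0),
              arm_long335 = c(0, 0, 1, 0),
              arm_deep_long = c(0, 1, 1, 1))
  pm <- sum(w * mu); ps <- sqrt(sum(w^2 * tau^2))
  dens <- density(log(cmp$rr))
  xs <- seq(min(dens$x, pm - 3 * ps), max(dens$x, pm + 3 * ps), length = 400)
  prior_d <- stats::dnorm(xs, pm, ps)
  graphics::plot(dens, main = cmp$label, xlab = "log RR",
                 ylim = c(0, max(dens$y, prior_d)), ...)
  graphics::lines(xs, prior_d, lty = 2)
  graphics::abline(v = 0, col = "grey")
  graphics::legend("topright", c("posterior", "prior"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
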