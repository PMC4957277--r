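#' Cell probabilities implied by the log-linear model coefficients
#'
#' The model for a subject in cell (depth d, duration u) is
#' `log p(d, u) = beta0 + beta1*d + beta2*u + beta3*d*u`, so
#' `p(d, u) = exp(beta0 + beta1*d + beta2*u + beta3*d*u)`.  A coefficient
#' vector is admissible only if all four cell probabilities are below 1.
#'
#' @param beta numeric vector `(beta0, beta1, beta2, beta3)`.
#' @return Named numeric vector of the four cell probabilities in canonical
#'   cell order (0,0), (1,0), (0,1), (1,1).
#' @export
cell_probabilities <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 4L)
  eta <- c(beta[1],
           beta[1] + beta[2],
           beta[1] + beta[3],
           beta[1] + beta[2] + beta[3] + beta[4])
  if (any(eta >= 0))
    stop("inadmissible coefficients: implied cell probability >= 1",
         call. = FALSE)
  stats::setNames(exp(eta), CELL_LABELS)
}

#' Log posterior density of the factorial log-binomial model
#'
#' Binomial log likelihood over the four cells plus independent normal prior
#' log densities for the coefficients.  Returns `-Inf` outside the support
#' (any implied cell probability at or above 1), which is how the `p < 1`
#' constraint is enforced during sampling.  Cells with `total = 0`
#' contribute nothing, so with an all-empty design the value is prior-only.
#'
#' @param beta numeric vector `(beta0, beta1, beta2, beta3)`.
#' @param counts a [trial_counts] object.
#' @param prior a [prior_spec].
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(beta, counts, prior) {
  stopifnot(is.numeric(beta), length(beta) == 4L,
            inherits(counts, "trial_counts"), inherits(prior, "prior_spec"))
  .log_post_cpp(as.numeric(beta), counts$events, counts$total,
                prior_mu(prior), prior_tau(prior))
}

# split-chain Gelman-Rubin statistic for a iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  n2 <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, var)
  W <- mean(vars)
  B <- n2 * var(means)
  if (W == 0) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# crude effective sample size from pooled autocorrelations (Geyer-truncated)
ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  W <- mean(apply(x, 2, var))
  if (W == 0) return(n * m)
  max_lag <- min(n - 1L, 500L)
  rho <- rep(0, max_lag)
  for (ch in seq_len(m)) {
    ac <- stats::acf(x[, ch], lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    rho <- rho + ac / m
  }
  s <- 0
  for (l in seq_len(max_lag)) {
    if (rho[l] < 0.01) break
    s <- s + rho[l]
  }
  n * m / (1 + 2 * s)
}
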