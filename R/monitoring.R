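#' Posterior probability that a comparison measure crosses a cutoff
#'
#' Computes the fraction of posterior draws of a comparison's RR or RD that
#' lie strictly on the stated side of a cutoff.  Draws exactly at the cutoff
#' count as neither side; their fraction is attached as the `"ties"`
#' attribute.
#'
#' @param comp a `comparison_draws` element of [comparisons()].
#' @param measure `"rr"` or `"rd"`.
#' @param cutoff the effect cutoff on the measure's scale.
#' @param side `"below"` or `"above"`.
#' @return Probability in `[0, 1]`.
#' @examples
#' # 10 hand-listed RR draws: 4 at 0.5, 6 at 1.5 -> Pr(RR < 0.9) = 0.4
#' cmp <- structure(list(id = "x", label = "x",
#'                       rr = c(rep(0.5, 4), rep(1.5, 6)), rd = numeric(10)),
#'                  class = "comparison_draws")
#' threshold_probability(cmp, "rr", 0.9, "below")
#' @export
threshold_probability <- function(comp, measure = c("rr", "rd"), cutoff,
                                  side = c("below", "above")) {
  stopifnot(inherits(comp, "comparison_draws"))
  measure <- match.arg(measure)
  side <- match.arg(side)
  x <- comp[[measure]]
  if (length(x) == 0L) stop("empty comparison draws", call. = FALSE)
  p <- if (side == "below") mean(x < cutoff) else mean(x > cutoff)
  structure(p, ties = mean(x == cutoff))
}

#' Stopping rules for Bayesian trial monitoring
#'
#' A rule pairs a clinically meaningful effect cutoff with a posterior
#' probability threshold:
#' \describe{
#'   \item{`futility_rr`}{stop when `Pr(RR < effect_threshold) <
#'     prob_threshold` - too little chance of a meaningful relative
#'     reduction.}
#'   \item{`futility_rd`}{stop when `Pr(RD > effect_threshold) <
#'     prob_threshold` - too little chance of a meaningful absolute
#'     reduction.}
#'   \item{`safety_rd`}{stop when `Pr(RD < effect_threshold) >
#'     prob_threshold` - too much chance of an absolute increase in harm
#'     (`effect_threshold` is negative).}
#'   \item{`efficacy_rr`}{stop when `Pr(RR < effect_threshold) >
#'     prob_threshold` - convincingly large chance of a meaningful benefit.}
#' }
#'
#' @param kind rule kind, see Details.
#' @param effect_threshold cutoff on the RR scale for `*_rr` kinds, on the
#'   RD scale for `*_rd` kinds.
#' @param prob_threshold probability threshold in (0, 1).
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(kind = c("futility_rr", "futility_rd", "safety_rd",
                                   "efficacy_rr"),
                          effect_threshold, prob_threshold) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(effect_threshold), length(effect_threshold) == 1L,
            prob_threshold > 0, prob_threshold < 1)
  if (endsWith(kind, "_rr") && effect_threshold <= 0)
    stop("RR-scale effect_threshold must be positive", call. = FALSE)
  if (kind == "safety_rd" && effect_threshold >= 0)
    stop("safety_rd expects a negative RD effect_threshold (an absolute ",
         "increase in harm)", call. = FALSE)
  measure <- if (endsWith(kind, "_rr")) "rr" else "rd"
  side <- switch(kind, futility_rr = "below", futility_rd = "above",
                 safety_rd = "below", efficacy_rr = "below")
  trigger_when <- switch(kind, futility_rr = "lt", futility_rd = "lt",
                         safety_rd = "gt", efficacy_rr = "gt")
  structure(list(kind = kind, measure = measure, side = side,
                 trigger_when = trigger_when,
                 effect_threshold = effect_threshold,
                 prob_threshold = prob_threshold),
            class = "stopping_rule")
}

#' @export
print.stopping_rule <- function(x, ...) {
  ineq <- if (x$side == "below") "<" else ">"
  trig <- if (x$trigger_when == "lt") "<" else ">"
  cat(sprintf("%s: trigger when Pr(%s %s %g | data) %s %g\n", x$kind,
              toupper(x$measure), ineq, x$effect_threshold, trig,
              x$prob_threshold))
  invisible(x)
}

#' Preset stopping rules of the cooling-trial monitoring plan
#'
#' \describe{
#'   \item{`"futility-rr"`}{`Pr(RR < 0.90) < 0.10` - futility unless a 10%
#'     relative mortality reduction remains plausible.}
#'   \item{`"futility-rd"`}{`Pr(RD > 0.01) < 0.10` - futility unless a 1%
#'     absolute reduction remains plausible.}
#'   \item{`"safety-rd"`}{`Pr(RD < -0.05) > 0.50` - safety stop when a 5%
#'     absolute mortality increase is more likely than not.}
#'   \item{`"efficacy-rr"`}{`Pr(RR < 0.85) > 0.99` - efficacy stop for a
#'     convincingly demonstrated 15% relative reduction.}
#' }
#'
#' @param names character vector of preset names; defaults to all four.
#' @return A named list of [stopping_rule] objects.
#' @export
rule_presets <- function(names = c("futility-rr", "futility-rd", "safety-rd",
                                   "efficacy-rr")) {
  all <- list(
    "futility-rr" = stopping_rule("futility_rr", 0.90, 0.10),
    "futility-rd" = stopping_rule("futility_rd", 0.01, 0.10),
    "safety-rd"   = stopping_rule("safety_rd", -0.05, 0.50),
    "efficacy-rr" = stopping_rule("efficacy_rr", 0.85, 0.99))
  bad <- setdiff(names, names(all))
  if (length(bad)) stop("unknown rule preset: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  all[names]
}

#' Read a stopping-rule set from YAML or JSON
#'
#' The file holds a list of `{kind, effect_threshold, prob_threshold}`
#' entries, or preset names under a top-level `presets` key.
#'
#' @param path YAML or JSON file.
#' @return Named list of [stopping_rule] objects.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$presets)) return(rule_presets(unlist(cfg$presets)))
  rules <- lapply(cfg, function(r)
    stopping_rule(r$kind, r$effect_threshold, r$prob_threshold))
  names(rules) <- vapply(rules, `[[`, character(1), "kind")
  rules
}

#' Evaluate one stopping rule against one comparison
#'
#' @param comp a `comparison_draws` element of [comparisons()].
#' @param rule a [stopping_rule].
#' @param prior_name label carried into the decision record.
#' @return A `stopping_decision`: list with `comparison`, `rule`,
#'   `posterior_prob` and logical `triggered`.
#' @export
evaluate_rule <- function(comp, rule, prior_name = "") {
  stopifnot(inherits(comp, "comparison_draws"),
            inherits(rule, "stopping_rule"))
  p <- as.numeric(threshold_probability(comp, rule$measure,
                                        rule$effect_threshold, rule$side))
  triggered <- if (rule$trigger_when == "lt") p < rule$prob_threshold
               else p > rule$prob_threshold
  structure(list(comparison = comp$id, rule = rule, posterior_prob = p,
                 triggered = triggered, prior_name = prior_name),
            class = "stopping_decision")
}

#' @export
print.stopping_decision <- function(x, ...) {
  cat(sprintf("%-18s %-12s p = %5.1f%%  %s\n", x$comparison, x$rule$kind,
              100 * x$posterior_prob,
              if (x$triggered) "TRIGGERED" else "not triggered"))
  invisible(x)
}

#' Monitoring report over comparisons and rules
#'
#' Evaluates every rule against every comparison and flags, at trial level,
#' whether all three experimental arms trigger a futility rule
#' (the condition under which the whole trial, rather than a single arm,
#' would stop for futility).  Marginal and per-arm comparisons are both
#' reported; which of them governs the trial-level verdict is left to the
#' monitoring committee, so the flag is computed from the per-arm rows.
#'
#' @param comps an `fmb_comparisons` from [comparisons()].
#' @param rules a named list of [stopping_rule] objects, e.g.
#'   [rule_presets()].
#' @return An object of class `monitoring_report`: a data frame with one row
#'   per (comparison, rule) holding the posterior probability (full
#'   precision) and the trigger verdict, with attributes `all_arms_futile`
#'   and `prior_name`.
#' @export
monitoring_report <- function(comps, rules) {
  stopifnot(inherits(comps, "fmb_comparisons"))
  if (!length(rules)) stop("monitoring_report: empty rule list",
                           call. = FALSE)
  prior_name <- attr(comps, "prior_name") %||% ""
  rows <- list()
  for (rn in names(rules)) for (cmp in comps) {
    dec <- evaluate_rule(cmp, rules[[rn]], prior_name)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = dec$comparison, rule = rn, kind = rules[[rn]]$kind,
      measure = rules[[rn]]$measure,
      effect_threshold = rules[[rn]]$effect_threshold,
      prob_threshold = rules[[rn]]$prob_threshold,
      probability = dec$posterior_prob, triggered = dec$triggered)
  }
  out <- do.call(rbind, rows)
  arm_ids <- c("arm_deep72", "arm_long335", "arm_deep_long")
  fut <- out[startsWith(out$kind, "futility") & out$comparison %in% arm_ids, ]
  all_futile <- length(unique(fut$comparison[fut$triggered])) == 3L &&
    nrow(fut) > 0L
  structure(out, all_arms_futile = all_futile, prior_name = prior_name,
            class = c("monitoring_report", "data.frame"))
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat("Bayesian monitoring report (prior:", attr(x, "prior_name"), ")\n")
  for (i in seq_len(nrow(x))) {
    ineq <- if (x$measure[i] == "rd" && startsWith(x$kind[i], "futility"))
      ">" else "<"
    cat(sprintf("  %-28s %-12s Pr(%s %s %g) = %3.0f%%  %s\n",
                COMPARISON_LABELS[[x$comparison[i]]], x$kind[i],
                toupper(x$measure[i]), ineq, x$effect_threshold[i],
                100 * x$probability[i],
                if (x$triggered[i]) "TRIGGERED" else "-"))
  }
  cat("  all experimental arms futile:",
      if (attr(x, "all_arms_futile")) "YES" else "no", "\n")
  invisible(x)
}

#' Write a monitoring report as JSON
#'
#' Probabilities are carried at full precision; the whole-percent rounding
#' of the text rendering is display-only.
#'
#' @param report a [monitoring_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "monitoring_report"))
  jsonlite::write_json(
    list(prior = attr(report, "prior_name"),
         all_arms_futile = attr(report, "all_arms_futile"),
         decisions = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
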