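#' Scenario for simulating a 2x2 factorial trial
#'
#' Defines the true event probabilities of the four arms, the planned total
#' enrollment, and the interim-look schedule (first look after `first_look`
#' subjects, then every `look_interval` subjects).  The defaults mirror the
#' cooling-trial design: 726 planned subjects, first safety look at 50, then
#' every 25.
#'
#' @param p numeric vector of the four true event probabilities in canonical
#'   cell order (0,0), (1,0), (0,1), (1,1), each in (0, 1).
#' @param max_n total planned enrollment.
#' @param first_look subjects enrolled before the first interim look.
#' @param look_interval spacing between subsequent looks.
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(p, max_n = 726L, first_look = 50L,
                           look_interval = 25L) {
  stopifnot(is.numeric(p), length(p) == 4L)
  if (any(p <= 0 | p >= 1))
    stop("cell probabilities must lie in (0, 1)", call. = FALSE)
  max_n <- as.integer(max_n); first_look <- as.integer(first_look)
  look_interval <- as.integer(look_interval)
  if (first_look < 1L || first_look > max_n || look_interval < 1L)
    stop("need 1 <= first_look <= max_n and look_interval >= 1",
         call. = FALSE)
  looks <- unique(c(seq.int(first_look, max_n, by = look_interval), max_n))
  structure(list(p = stats::setNames(p, CELL_LABELS), max_n = max_n,
                 first_look = first_look, look_interval = look_interval,
                 looks = looks),
            class = "trial_scenario")
}

#' Read a scenario from YAML or JSON
#'
#' Expects scalars `p00, p10, p01, p11, max_n, first_look, look_interval`
#' (cell keys are `p<depth><duration>`).
#'
#' @param path YAML or JSON file.
#' @return A [trial_scenario].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  trial_scenario(c(cfg$p00, cfg$p10, cfg$p01, cfg$p11),
                 cfg$max_n %||% 726L, cfg$first_look %||% 50L,
                 cfg$look_interval %||% 25L)
}

#' Simulate per-subject enrollment of a factorial trial
#'
#' Subjects are assigned to the four arms by permuted-block randomization
#' with block size 4 (one subject per arm per block, block order random), and
#' outcomes are drawn as Bernoulli with the assigned cell's true probability.
#' The record list is deterministic given the seed.
#'
#' @param scenario a [trial_scenario].
#' @param seed integer seed.
#' @return Data frame with `max_n` rows in enrollment order and 0/1 columns
#'   `depth`, `duration`, `outcome`.
#' @export
simulate_trial <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$max_n
  n_blocks <- ceiling(n / 4)
  cell <- unlist(lapply(seq_len(n_blocks), function(b) sample.int(4L)))[1:n]
  depth <- CELL_ORDER[cell, "depth"]
  duration <- CELL_ORDER[cell, "duration"]
  outcome <- rbinom(n, 1L, scenario$p[cell])
  data.frame(subject = seq_len(n), depth = depth, duration = duration,
             outcome = outcome)
}

#' Run one simulated trial through the interim-monitoring schedule
#'
#' At each scheduled look the accrued subjects are aggregated, the posterior
#' is refit, and the rule set is evaluated with [monitoring_report()].  The
#' trial stops at the first look where either all three experimental arms
#' trigger a futility rule or any efficacy rule triggers; otherwise it runs
#' to `max_n`.  Safety triggers are recorded per look but, matching a plan
#' that stops single arms rather than the trial, do not by themselves halt
#' the simulated trial.
#'
#' @param scenario a [trial_scenario].
#' @param rules named list of [stopping_rule] objects; may be empty, in
#'   which case the path runs to completion with no decisions.
#' @param prior a [prior_spec].
#' @param mcmc an [mcmc_config]; use [mcmc_config_sim()] for throughput.
#' @param seed integer seed (drives both enrollment and the per-look MCMC).
#' @return An object of class `trial_path`: list with `looks` (data frame of
#'   look, n, events, triggered flags), `stopped_at` (`NA` if run to
#'   completion), `stop_reason`, `records`, and `reports` (one
#'   [monitoring_report()] per look).
#' @export
run_interim_sequence <- function(scenario, rules, prior = prior_spec("neutral"),
                                 mcmc = mcmc_config_sim(), seed = 1L) {
  stopifnot(inherits(scenario, "trial_scenario"))
  records <- simulate_trial(scenario, seed = seed)
  reports <- list()
  look_rows <- list()
  stopped_at <- NA_integer_
  stop_reason <- "completed"
  for (li in seq_along(scenario$looks)) {
    n_look <- scenario$looks[li]
    if (!length(rules)) next
    acc <- records[seq_len(n_look), , drop = FALSE]
    counts <- aggregate_records(acc)
    rep_li <- tryCatch({
      fit <- fit_trial(counts, prior, mcmc, seed = seed + li)
      monitoring_report(comparisons(fit), rules)
    }, error = function(e)
      stop(sprintf("look %d (n = %d): %s", li, n_look, conditionMessage(e)),
           call. = FALSE))
    reports[[length(reports) + 1L]] <- rep_li
    efficacy <- any(rep_li$triggered & rep_li$kind == "efficacy_rr")
    all_futile <- attr(rep_li, "all_arms_futile")
    safety <- any(rep_li$triggered & rep_li$kind == "safety_rd")
    look_rows[[length(look_rows) + 1L]] <- data.frame(
      look = li, n = n_look, events = sum(acc$outcome),
      any_efficacy = efficacy, all_arms_futile = all_futile,
      any_safety = safety)
    if (efficacy || all_futile) {
      stopped_at <- n_look
      stop_reason <- if (efficacy) "efficacy" else "futility"
      break
    }
  }
  structure(list(
    looks = if (length(look_rows)) do.call(rbind, look_rows)
            else data.frame(),
    stopped_at = stopped_at, stop_reason = stop_reason,
    final_n = if (is.na(stopped_at)) scenario$max_n else stopped_at,
    records = records, reports = reports, scenario = scenario,
    seed = as.integer(seed)), class = "trial_path")
}

#' @export
print.trial_path <- function(x, ...) {
  cat(sprintf("Simulated trial path: %s at n = %d (%d looks evaluated)\n",
              x$stop_reason, x$final_n, length(x$reports)))
  invisible(x)
}

#' Operating characteristics of a monitoring plan
#'
#' Replicates [run_interim_sequence()] and reports, per rule, the frequency
#' of trials in which the rule triggered at any look for any comparison,
#' with the binomial Monte Carlo standard error `sqrt(f(1-f)/reps)`.  Under
#' an all-null scenario the efficacy-rule frequency estimates type I error;
#' under an effect scenario it estimates power.  Also reported: the trial
#' stopping frequency and the expected stopping sample size.
#'
#' @param scenario a [trial_scenario].
#' @param rules named list of [stopping_rule] objects.
#' @param prior a [prior_spec].
#' @param reps number of replicate trials.
#' @param mcmc an [mcmc_config]; reduced settings are the intended default.
#' @param seed integer seed; replicate r uses `seed + 1000 * r` offsets so
#'   results are reproducible and replicates independent.
#' @param progress print a replicate counter to stderr.
#' @return An object of class `oc_result`: list with `rules` (data frame of
#'   rule, trigger frequency, MCSE), `expected_n`, `stop_frequency`, `reps`,
#'   `seed`.
#' @export
operating_characteristics <- function(scenario, rules,
                                      prior = prior_spec("neutral"),
                                      reps = 100L,
                                      mcmc = mcmc_config_sim(),
                                      seed = 1L, progress = FALSE) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  trig <- matrix(FALSE, nrow = reps, ncol = length(rules),
                 dimnames = list(NULL, names(rules)))
  final_n <- integer(reps)
  stopped <- logical(reps)
  for (r in seq_len(reps)) {
    if (progress) message("replicate ", r, "/", reps)
    path <- run_interim_sequence(scenario, rules, prior, mcmc,
                                 seed = seed + 1000L * r)
    final_n[r] <- path$final_n
    stopped[r] <- !is.na(path$stopped_at)
    for (rn in names(rules))
      trig[r, rn] <- any(vapply(path$reports, function(rep_li)
        any(rep_li$triggered & rep_li$rule == rn), logical(1)))
  }
  freq <- colMeans(trig)
  structure(list(
    rules = data.frame(rule = names(rules), frequency = as.numeric(freq),
                       mcse = sqrt(freq * (1 - freq) / reps)),
    expected_n = mean(final_n), stop_frequency = mean(stopped),
    reps = reps, seed = as.integer(seed), scenario = scenario),
    class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d replicates:\n", x$reps))
  for (i in seq_len(nrow(x$rules)))
    cat(sprintf("  %-14s trigger frequency %.3f (MCSE %.3f)\n",
                x$rules$rule[i], x$rules$frequency[i], x$rules$mcse[i]))
  cat(sprintf("  stop frequency %.3f; expected stopping n %.1f\n",
              x$stop_frequency, x$expected_n))
  invisible(x)
}

#' Write operating characteristics to CSV and JSON
#'
#' @param oc an [operating_characteristics()] result.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_oc <- function(oc, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(oc, "oc_result"))
  tab <- cbind(oc$rules, reps = oc$reps)
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(rules = tab, expected_n = oc$expected_n,
           stop_frequency = oc$stop_frequency, reps = oc$reps,
           seed = oc$seed,
           scenario = list(p = as.list(oc$scenario$p),
                           max_n = oc$scenario$max_n,
                           first_look = oc$scenario$first_look,
                           look_interval = oc$scenario$look_interval)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
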