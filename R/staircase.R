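#' Transformed up-down staircase rule
#'
#' Parameters of the single-interval transformed adaptive rule: the level is
#' decreased after `n_down` consecutive hits and increased after `n_up`
#' consecutive misses (three-down/two-up by default). The step size shrinks
#' from `initial_step` to `small_step` once `reversals_to_shrink` reversals
#' have occurred, and the run stops at `reversals_to_stop` reversals.
#'
#' @param n_down Consecutive hits required to decrease the level.
#' @param n_up Consecutive misses required to increase the level.
#' @param initial_step Initial step size in dB.
#' @param small_step Step size in dB after the shrink point.
#' @param reversals_to_shrink Reversal count at which the step size shrinks.
#' @param reversals_to_stop Reversal count at which the run stops.
#' @param start_level Starting level in dB.
#' @return An object of class `staircase_rule`.
#' @export
staircase_rule <- function(n_down = 3, n_up = 2, initial_step = 10,
                           small_step = 2, reversals_to_shrink = 2,
                           reversals_to_stop = 11, start_level = 65) {
  if (initial_step <= 0 || small_step <= 0) stop("step sizes must be positive")
  if (n_down < 1 || n_up < 1) stop("consecutive counts must be >= 1")
  if (reversals_to_stop <= reversals_to_shrink)
    stop("'reversals_to_stop' must exceed 'reversals_to_shrink'")
  structure(
    list(n_down = n_down, n_up = n_up, initial_step = initial_step,
         small_step = small_step, reversals_to_shrink = reversals_to_shrink,
         reversals_to_stop = reversals_to_stop, start_level = start_level),
    class = "staircase_rule"
  )
}

#' Run a transformed up-down adaptive staircase
#'
#' Simulates the rule trial by trial against an observer. Hit/miss counters
#' reset on the opposite outcome and after any level change (the standard
#' transformed-rule convention). A reversal is a change in the direction of
#' level movement; the step size shrinks after `reversals_to_shrink`
#' reversals, and the run stops after `reversals_to_stop` reversals or
#' `max_trials` trials, whichever comes first.
#'
#' @param observer Function mapping a level (dB) to a hit probability in
#'   `[0, 1]`.
#' @param rule A [staircase_rule()].
#' @param max_trials Maximum number of trials.
#' @param seed Integer seed for the Bernoulli outcomes.
#' @return An object of class `staircase_run`: list with per-trial `levels`
#'   and logical `outcomes`, `reversal_indices`, `reversal_levels`,
#'   `reversal_steps` (step size in force at each reversal), and `converged`
#'   (`TRUE` when the reversal criterion, not the trial cap, ended the run).
#' @export
run_staircase <- function(observer, rule = staircase_rule(), max_trials = 200,
                          seed = 1) {
  stopifnot(is.function(observer), max_trials >= 1)
  withr_seed(seed, {
    levels <- numeric(max_trials)
    outcomes <- logical(max_trials)
    rev_idx <- integer(0); rev_lev <- numeric(0); rev_step <- numeric(0)
    level <- rule$start_level
    hits <- 0L; misses <- 0L
    last_dir <- 0L   # -1 down, +1 up, 0 none yet
    n_rev <- 0L
    i <- 0L
    while (i < max_trials && n_rev < rule$reversals_to_stop) {
      i <- i + 1L
      p <- observer(level)
      if (!is.finite(p) || p < 0 || p > 1)
        stop("observer returned a value outside [0, 1]")
      hit <- stats::runif(1) < p
      levels[i] <- level
      outcomes[i] <- hit
      if (hit) { hits <- hits + 1L; misses <- 0L } else { misses <- misses + 1L; hits <- 0L }
      step <- if (n_rev >= rule$reversals_to_shrink) rule$small_step else rule$initial_step
      dir <- 0L
      if (hits >= rule$n_down) dir <- -1L
      if (misses >= rule$n_up) dir <- +1L
      if (dir != 0L) {
        if (last_dir != 0L && dir != last_dir) {
          n_rev <- n_rev + 1L
          rev_idx <- c(rev_idx, i)
          rev_lev <- c(rev_lev, level)
          rev_step <- c(rev_step, step)
        }
        last_dir <- dir
        level <- level + dir * step
        hits <- 0L; misses <- 0L
      }
    }
    structure(
      list(levels = levels[seq_len(i)], outcomes = outcomes[seq_len(i)],
           reversal_indices = rev_idx, reversal_levels = rev_lev,
           reversal_steps = rev_step,
           converged = n_rev >= rule$reversals_to_stop, rule = rule),
      class = "staircase_run"
    )
  })
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "<staircase_run> %d trials, %d reversals, %s\n",
    length(x$levels), length(x$reversal_indices),
    if (x$converged) "converged" else "stopped at trial cap"
  ))
  invisible(x)
}

#' Threshold from staircase reversals
#'
#' Mean of the levels at reversal points that occurred in the small-step
#' phase. The estimate is flagged stable when those reversal levels span no
#' more than `stability_span` dB.
#'
#' @param run A [run_staircase()] result.
#' @param min_reversals Minimum number of usable reversals required.
#' @param stability_span Maximal dB span of reversal levels for the stable
#'   flag (default 2 dB).
#' @return List with `threshold` (dB), `stable` (logical), and
#'   `reversal_levels` used.
#' @export
threshold_from_reversals <- function(run, min_reversals = 4,
                                     stability_span = 2) {
  use <- run$reversal_steps == run$rule$small_step
  levs <- run$reversal_levels[use]
  if (length(levs) < min_reversals)
    stop("insufficient data: only ", length(levs),
         " small-step reversals, need ", min_reversals)
  list(threshold = mean(levs),
       stable = (max(levs) - min(levs)) <= stability_span,
       reversal_levels = levs)
}

#' Ideal-observer Monte Carlo for the transformed staircase
#'
#' Simulates staircase runs against an ideal observer: a deterministic step
#' psychometric function (hit if and only if the level is at or above the
#' observer's threshold), i.e. an observer not limited by internal noise.
#' Observer thresholds are drawn uniformly from `threshold_range` per
#' simulation. Once the staircase brackets the threshold, the deterministic
#' limit cycle is three hits followed by two misses, so the per-run
#' proportion correct converges to 3/5; across randomized thresholds the mean
#' proportion correct is close to 60% with runs spanning roughly 55--65%.
#'
#' The batch is advanced with a vectorized stepping kernel equivalent to
#' [run_staircase()] (equivalence is part of the test suite).
#'
#' @param n_sims Number of simulated runs.
#' @param max_steps Number of adaptive steps (trials) per run.
#' @param rule A [staircase_rule()].
#' @param seed Integer seed for the threshold draws.
#' @param threshold_range Range (dB) the observer thresholds are drawn from.
#' @return List with `mean_prop` (mean proportion of hits across runs),
#'   `range` (min/max per-run proportion), `props` (per-run proportions), and
#'   `thresholds`.
#' @export
simulate_ideal_observer_batch <- function(n_sims, max_steps = 100,
                                          rule = staircase_rule(reversals_to_stop = 1000),
                                          seed = 1,
                                          threshold_range = c(25, 55)) {
  stopifnot(n_sims >= 1, max_steps >= 1)
  thr <- withr_seed(seed, stats::runif(n_sims, threshold_range[1], threshold_range[2]))

  level <- rep(rule$start_level, n_sims)
  hits <- integer(n_sims); misses <- integer(n_sims)
  last_dir <- integer(n_sims); n_rev <- integer(n_sims)
  active <- rep(TRUE, n_sims)
  n_hits_total <- integer(n_sims); n_trials <- integer(n_sims)

  for (i in seq_len(max_steps)) {
    if (!any(active)) break
    hit <- active & (level >= thr)
    n_hits_total <- n_hits_total + hit
    n_trials <- n_trials + active
    hits <- ifelse(active & hit, hits + 1L, ifelse(active, 0L, hits))
    misses <- ifelse(active & !hit, misses + 1L, ifelse(active, 0L, misses))
    step <- ifelse(n_rev >= rule$reversals_to_shrink, rule$small_step, rule$initial_step)
    dir <- integer(n_sims)
    dir[active & hits >= rule$n_down] <- -1L
    dir[active & misses >= rule$n_up] <- +1L
    moved <- dir != 0L
    rev_now <- moved & last_dir != 0L & dir != last_dir
    n_rev <- n_rev + rev_now
    last_dir[moved] <- dir[moved]
    level <- level + dir * step
    hits[moved] <- 0L; misses[moved] <- 0L
    active <- active & n_rev < rule$reversals_to_stop
  }
  props <- n_hits_total / pmax(n_trials, 1L)
  list(mean_prop = mean(props), range = range(props), props = props,
       thresholds = thr)
}

#' Assemble an audiogram from staircase runs
#'
#' Per frequency: thresholds are extracted from each run's small-step
#' reversals, runs deviating more than `max_deviation` (fraction) from the
#' across-run mean threshold are discarded, and the remainder is averaged.
#' Confidence intervals are bias-corrected percentile bootstrap intervals
#' over the retained run thresholds (or over within-run reversal levels when
#' a single run survives).
#'
#' @param runs_by_frequency Named list: frequency (Hz, as name) to list of
#'   [run_staircase()] results.
#' @param max_deviation Maximal fractional deviation from the mean threshold
#'   before a run is discarded (default 0.10).
#' @param min_reversals Passed to [threshold_from_reversals()].
#' @param n_boot Bootstrap resamples for the CI.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `audiogram`: data frame with `frequency`,
#'   `threshold`, `ci_low`, `ci_high`, `n_runs_used`.
#' @export
assemble_audiogram <- function(runs_by_frequency, max_deviation = 0.1,
                               min_reversals = 4, n_boot = 2000,
                               conf = 0.95, seed = 1) {
  stopifnot(length(runs_by_frequency) >= 1, !is.null(names(runs_by_frequency)))
  rows <- lapply(seq_along(runs_by_frequency), function(k) {
    runs <- runs_by_frequency[[k]]
    thr_all <- vapply(runs, function(r)
      threshold_from_reversals(r, min_reversals)$threshold, numeric(1))
    # iterative trimming: drop the worst offender until all retained runs
    # sit within the deviation band around their own mean
    keep <- rep(TRUE, length(thr_all))
    repeat {
      dev <- abs(thr_all - mean(thr_all[keep]))
      bad <- keep & dev > max_deviation * abs(mean(thr_all[keep]))
      if (!any(bad)) break
      worst <- which(bad)[which.max(dev[bad])]
      keep[worst] <- FALSE
      if (!any(keep))
        stop("insufficient data: all runs discarded at frequency ",
             names(runs_by_frequency)[k])
    }
    thr <- thr_all[keep]
    est <- mean(thr)
    if (length(thr) > 1) {
      boots <- withr_seed(seed + k, {
        vapply(seq_len(n_boot), function(b)
          mean(sample(thr, replace = TRUE)), numeric(1))
      })
    } else {
      levs <- threshold_from_reversals(runs[keep][[1]], min_reversals)$reversal_levels
      boots <- withr_seed(seed + k, {
        vapply(seq_len(n_boot), function(b)
          mean(sample(levs, replace = TRUE)), numeric(1))
      })
    }
    ci <- bc_percentile_ci(boots, est, conf)
    data.frame(frequency = as.numeric(names(runs_by_frequency)[k]),
               threshold = est, ci_low = ci[1], ci_high = ci[2],
               n_runs_used = sum(keep))
  })
  structure(do.call(rbind, rows), class = c("audiogram", "data.frame"))
}

#' Expected reward probability with interleaved catch trials
#'
#' Diagnostic for the ideal observer under a catch-trial proportion `p`:
#' the staircase limit cycle yields 60% hits on test trials, so the expected
#' reward rate is `(1 - p) * 0.6 + p * r_catch`, where the catch contingency
#' `r_catch` depends on whether withholding a response on catch trials is
#' rewarded. Both conventions are reported.
#'
#' @param catch_proportion Proportion of catch trials in `[0, 1)`.
#' @param guess_rate Probability of a (false-positive) release on a catch
#'   trial.
#' @return Data frame with the two conventions (`reward_on_withhold`,
#'   `no_catch_reward`) and their expected reward probabilities.
#' @export
catch_reward_diagnostic <- function(catch_proportion, guess_rate = 0) {
  p <- catch_proportion
  data.frame(
    convention = c("reward_on_withhold", "no_catch_reward"),
    expected_reward = c((1 - p) * 0.6 + p * (1 - guess_rate),
                        (1 - p) * 0.6)
  )
}
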