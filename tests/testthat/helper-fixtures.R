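# Shared fixtures: small grids and observers used across test files.

# reduced tone complex (max ~1 kHz) so synthesis tests run at low sample rate
small_grid <- function() frequency_grid(250, 20, 41)

paper_grid <- function() default_ripple_grid()

# a small stimulus grid for fast end-to-end runs
mini_stimuli <- function(depths = c(0, 10, 20, 40, 70, 100)) {
  enumerate_stimulus_grid(densities = c(-1.2, 0, 1.2),
                          velocities = c(0, 8, 32),
                          depths = depths)
}

# deterministic smooth test matrix on the canonical 8 x 11 grid
smooth_mtf <- function(ratio = 0.07) {
  make_ground_truth_mtf(ground_truth_spec(inseparable_ratio = ratio))
}

# independent hand simulation of the transformed rule against a step
# observer: transparent reference implementation for oracle tests
hand_staircase <- function(threshold, rule, n_trials) {
  level <- rule$start_level
  hits <- 0; misses <- 0; last_dir <- 0; n_rev <- 0
  lev <- numeric(n_trials); out <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    hit <- level >= threshold
    lev[i] <- level; out[i] <- hit
    if (hit) { hits <- hits + 1; misses <- 0 } else { misses <- misses + 1; hits <- 0 }
    step <- if (n_rev >= rule$reversals_to_shrink) rule$small_step else rule$initial_step
    dir <- 0
    if (hits >= rule$n_down) dir <- -1
    if (misses >= rule$n_up) dir <- +1
    if (dir != 0) {
      if (last_dir != 0 && dir != last_dir) n_rev <- n_rev + 1
      last_dir <- dir
      level <- level + dir * step
      hits <- 0; misses <- 0
    }
  }
  list(levels = lev, outcomes = out)
}
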