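#' Ground-truth MTF specification
#'
#' Parameters of a synthetic sensitivity surface: a temporal band-pass
#' profile (Gaussian on the log-velocity axis) crossed with a spectral
#' low-pass profile (generalized-Gaussian falloff in absolute density), plus
#' an orthogonal rank-1 perturbation whose size sets the target second-to-
#' first singular value ratio, and an optional up/down gain applied to the
#' negative-density half.
#'
#' @param peak_velocity Velocity (Hz) of peak temporal sensitivity.
#' @param velocity_bw Band-pass bandwidth in octaves (Gaussian sigma on the
#'   log2-velocity axis).
#' @param corner_density Low-pass corner in cycles/octave.
#' @param rolloff Spectral falloff exponent.
#' @param inseparable_ratio Target `lambda_2 / lambda_1` of the sensitivity
#'   matrix, in `[0, 0.5]`.
#' @param updown_gain Gain applied to the upward (density < 0) half; 1 for a
#'   symmetric surface. The singular-value ratio is enforced before the gain
#'   is applied and is exact only for `updown_gain = 1`.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(peak_velocity = 10, velocity_bw = 1.8,
                              corner_density = 1.6, rolloff = 2,
                              inseparable_ratio = 0.07, updown_gain = 1) {
  if (inseparable_ratio < 0 || inseparable_ratio > 0.5)
    stop("'inseparable_ratio' must be in [0, 0.5]")
  if (updown_gain <= 0) stop("'updown_gain' must be positive")
  structure(
    list(peak_velocity = peak_velocity, velocity_bw = velocity_bw,
         corner_density = corner_density, rolloff = rolloff,
         inseparable_ratio = inseparable_ratio, updown_gain = updown_gain),
    class = "ground_truth_spec"
  )
}

#' Construct a ground-truth threshold MTF
#'
#' Builds the sensitivity surface as the outer product of the temporal and
#' spectral profiles of a [ground_truth_spec()]; adds a rank-1 perturbation
#' orthogonal to both profiles, scaled so the sensitivity matrix's
#' `lambda_2 / lambda_1` hits the requested ratio (exactly, by construction:
#' orthogonal rank-1 terms contribute independent singular values); applies
#' the up/down gain; and converts sensitivity to detection thresholds by
#' reciprocal mapping onto the `[5, 100]` percent-depth range.
#'
#' @param spec A [ground_truth_spec()].
#' @param velocities,densities Grid coordinates (defaults: the canonical
#'   8 x 11 grid).
#' @return An `mtf_matrix` of kind `"threshold"` with attributes
#'   `sensitivity` (the sensitivity `mtf_matrix`) and `lambda_ratio`
#'   (achieved second-to-first singular value ratio of the sensitivity).
#' @export
make_ground_truth_mtf <- function(spec,
                                  velocities = default_ripple_grid()$velocities,
                                  densities = default_ripple_grid()$densities) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  u <- velocity_pseudo_log(velocities)
  g <- 0.1 + exp(-(u - log2(spec$peak_velocity))^2 / (2 * spec$velocity_bw^2))
  h <- 0.1 + exp(-(abs(densities) / spec$corner_density)^spec$rolloff)
  sens <- outer(g, h)

  if (spec$inseparable_ratio > 0) {
    # perturbation shapes orthogonalized against the separable profiles;
    # weighted by the profiles themselves so the interaction lives where
    # sensitivity is high (keeps the surface positive), and even in density
    # so up/down symmetry is preserved
    g2_raw <- g * sin(seq(0, 2 * pi, length.out = length(velocities)))
    h2_raw <- h * cos(pi * densities / max(abs(densities)))
    g2 <- g2_raw - sum(g2_raw * g) / sum(g * g) * g
    h2 <- h2_raw - sum(h2_raw * h) / sum(h * h) * h
    lam1 <- sqrt(sum(g^2)) * sqrt(sum(h^2))
    scale <- spec$inseparable_ratio * lam1 /
      (sqrt(sum(g2^2)) * sqrt(sum(h2^2)))
    sens <- sens + scale * outer(g2, h2)
    if (min(sens) <= 0)
      stop("unreachable inseparable_ratio: sensitivity went non-positive")
  }

  if (spec$updown_gain != 1)
    sens[, densities < 0] <- sens[, densities < 0] * spec$updown_gain

  sv <- svd(sens)$d
  thr_raw <- 1 / sens
  thr <- 5 + (thr_raw - min(thr_raw)) / (max(thr_raw) - min(thr_raw)) * 95
  out <- mtf_matrix(thr, velocities, densities, value_kind = "threshold",
                    origin_interpolated = TRUE)
  attr(out, "sensitivity") <- mtf_matrix(sens, velocities, densities,
                                         value_kind = "sensitivity",
                                         origin_interpolated = TRUE)
  attr(out, "lambda_ratio") <- sv[2] / sv[1]
  out
}

#' Synthetic observer model
#'
#' A generative observer for trial simulation: detection probability per
#' stimulus follows the four-parameter Weibull with the cell's ground-truth
#' threshold (the position parameter is back-derived from the midpoint
#' threshold and the common slope), plus a bimodal latency model (a
#' truncated log-normal hit component inside the 0.220--0.800 s window whose
#' median decreases with depth relative to threshold, and a miss component
#' beyond 0.800 s).
#'
#' @param threshold_mtf `mtf_matrix` of ground-truth thresholds (percent).
#' @param beta Common psychometric slope.
#' @param gamma Guess rate.
#' @param lambda_rate Lapse rate; `gamma + lambda_rate < 1`.
#' @param catch_proportion Proportion of catch trials interleaved.
#' @param d_range Static-noise duration range `c(low, high)` in seconds.
#' @param latency_floor,latency_ceiling Hit-latency medians (s) at very high
#'   and near-threshold relative depth.
#' @param latency_sdlog Log-scale spread of the hit-latency component.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(threshold_mtf, beta = 3.6, gamma = 0.05,
                           lambda_rate = 0.02, catch_proportion = 0.15,
                           d_range = c(1, 3),
                           latency_floor = 0.38, latency_ceiling = 0.62,
                           latency_sdlog = 0.12) {
  if (gamma + lambda_rate >= 1) stop("require gamma + lambda_rate < 1")
  thr <- unclass(threshold_mtf)
  if (any(thr <= 0 | thr > 100, na.rm = TRUE))
    stop("thresholds must lie in (0, 100]")
  structure(
    list(threshold_mtf = threshold_mtf, beta = beta, gamma = gamma,
         lambda_rate = lambda_rate, catch_proportion = catch_proportion,
         d_range = d_range, latency_floor = latency_floor,
         latency_ceiling = latency_ceiling, latency_sdlog = latency_sdlog),
    class = "observer_model"
  )
}

#' Species presets for the synthetic observer
#'
#' Descriptive defaults: human (slope 3.6, guess rate 0.05, 15% catch
#' trials, static noise 1--3 s, temporal peak near 10 Hz) and monkey (slope
#' 2.6, guess rate 0.25, 35% catch trials, static noise 1.5--3.5 s, temporal
#' peak near 45 Hz).
#'
#' @param species `"human"` or `"monkey"`.
#' @param inseparable_ratio Target singular-value ratio of the ground truth.
#' @param velocities,densities Grid coordinates.
#' @return An `observer_model`.
#' @export
observer_preset <- function(species = c("human", "monkey"),
                            inseparable_ratio = 0.07,
                            velocities = default_ripple_grid()$velocities,
                            densities = default_ripple_grid()$densities) {
  species <- match.arg(species)
  if (species == "human") {
    spec <- ground_truth_spec(peak_velocity = 10,
                              inseparable_ratio = inseparable_ratio)
    mtf <- make_ground_truth_mtf(spec, velocities, densities)
    obs <- observer_model(mtf, beta = 3.6, gamma = 0.05, lambda_rate = 0.02,
                          catch_proportion = 0.15, d_range = c(1, 3))
  } else {
    spec <- ground_truth_spec(peak_velocity = 45,
                              inseparable_ratio = inseparable_ratio)
    mtf <- make_ground_truth_mtf(spec, velocities, densities)
    obs <- observer_model(mtf, beta = 2.6, gamma = 0.25, lambda_rate = 0.05,
                          catch_proportion = 0.35, d_range = c(1.5, 3.5))
  }
  obs$species <- species
  obs
}

#' Simulate response latencies
#'
#' Hit latencies are log-normal, truncated to the 0.220--0.800 s hit window
#' by inverse-CDF sampling, with a median that decreases monotonically from
#' `latency_ceiling` near threshold toward `latency_floor` at high relative
#' depth (the chronometric rule). Miss latencies fall beyond 0.800 s.
#'
#' @param observer An [observer_model()].
#' @param outcome Character vector of `"hit"`/`"miss"`.
#' @param depth Depths (percent) per trial.
#' @param threshold Cell thresholds (percent) per trial.
#' @return Latencies in seconds (vector aligned with `outcome`).
#' @export
simulate_latency <- function(observer, outcome, depth, threshold) {
  n <- length(outcome)
  depth <- rep_len(depth, n); threshold <- rep_len(threshold, n)
  lat <- numeric(n)
  is_hit <- outcome == "hit"
  if (any(is_hit)) {
    r <- pmax(depth[is_hit] / pmax(threshold[is_hit], 1e-6), 1)
    med <- observer$latency_floor +
      (observer$latency_ceiling - observer$latency_floor) * exp(-(r - 1))
    lo <- stats::plnorm(0.220, log(med), observer$latency_sdlog)
    hi <- stats::plnorm(0.800, log(med), observer$latency_sdlog)
    u <- stats::runif(sum(is_hit), lo, hi)
    lat[is_hit] <- stats::qlnorm(u, log(med), observer$latency_sdlog)
  }
  if (any(!is_hit)) {
    lat[!is_hit] <- 0.82 + stats::rlnorm(sum(!is_hit), log(0.25), 0.5)
  }
  lat
}

#' Simulate a trial-level response table
#'
#' Method-of-constant-stimuli simulation: every modulated grid entry is
#' repeated `n_reps` times; catch trials (static noise) are interleaved at
#' the observer's catch proportion; static-noise duration is uniform on the
#' observer's range, independent of everything else; presentation order is
#' randomized. Detection follows the Weibull model with the observer's cell
#' thresholds; latencies follow [simulate_latency()] and determine the
#' recorded outcome through [classify_response()].
#'
#' @param observer An [observer_model()].
#' @param stimuli A [enumerate_stimulus_grid()] result.
#' @param n_reps Repetitions per modulated entry (>= 1).
#' @param seed Integer seed.
#' @param subject,species Identifier tags recorded per trial.
#' @param n_blocks Number of session blocks trials are assigned to.
#' @return Data frame of trial records: `subject`, `species`, `block`,
#'   `density`, `velocity`, `depth`, `static_duration`, `latency`,
#'   `is_catch`, `outcome`.
#' @export
simulate_trial_table <- function(observer, stimuli, n_reps = 8, seed = 1,
                                 subject = "s1", species = "synthetic",
                                 n_blocks = 1) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(stimuli, "stimulus_set"), n_reps >= 1)
  if (nrow(stimuli$entries) == 0) stop("empty stimulus set")
  entries <- stimuli$entries[rep(seq_len(nrow(stimuli$entries)), each = n_reps), ]
  n_test <- nrow(entries)
  n_catch <- round(observer$catch_proportion / (1 - observer$catch_proportion) * n_test)
  trials <- rbind(entries,
                  stimuli$catch_entry[rep(1, n_catch), , drop = FALSE])
  trials$is_catch <- c(rep(FALSE, n_test), rep(TRUE, n_catch))

  vel <- attr(observer$threshold_mtf, "velocities")
  dens <- attr(observer$threshold_mtf, "densities")
  thr_m <- unclass(observer$threshold_mtf)
  ri <- match(trials$velocity, vel); ci <- match(trials$density, dens)
  if (anyNA(ri) || anyNA(ci))
    stop("stimulus grid has cells outside the observer's threshold MTF")
  cell_thr <- thr_m[cbind(ri, ci)]

  withr_seed(seed, {
    alpha <- cell_thr / log(2)^(1 / observer$beta)
    f <- 1 - exp(-(trials$depth / alpha)^observer$beta)
    p <- observer$gamma + (1 - observer$gamma - observer$lambda_rate) * f
    p[trials$is_catch | trials$depth == 0] <- observer$gamma
    detected <- stats::runif(nrow(trials)) < p
    latency <- simulate_latency(observer,
                                ifelse(detected, "hit", "miss"),
                                trials$depth, cell_thr)
    out <- data.frame(
      subject = subject, species = species,
      block = sample(rep_len(seq_len(n_blocks), nrow(trials))),
      density = trials$density, velocity = trials$velocity,
      depth = trials$depth,
      static_duration = stats::runif(nrow(trials), observer$d_range[1],
                                     observer$d_range[2]),
      latency = latency,
      is_catch = trials$is_catch,
      outcome = classify_response(latency)
    )
    out <- out[sample(nrow(out)), ]
    rownames(out) <- NULL
    out
  })
}

#' Write / read a trial table as delimited text
#'
#' @param trials Trial data frame from [simulate_trial_table()] (or with the
#'   same column schema).
#' @param path CSV path.
#' @return `path` invisibly (`write_trials`); the data frame (`read_trials`).
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
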