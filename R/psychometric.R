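#' Four-parameter Weibull psychometric parameters
#'
#' `alpha` is the position (threshold-criterion) parameter on the modulation
#' depth axis (percent), `beta` the slope, `gamma` the guess rate (false
#' positives on catch trials) and `lambda` the lapse rate (misses at maximal
#' depth).
#'
#' @param alpha Position parameter, > 0 (percent modulation depth).
#' @param beta Slope parameter, > 0.
#' @param gamma Guess rate in `[0, 1)`.
#' @param lambda Lapse rate in `[0, 1)`; `gamma + lambda < 1`.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(alpha, beta, gamma = 0, lambda = 0) {
  if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be positive")
  if (gamma < 0 || lambda < 0 || gamma + lambda >= 1)
    stop("require gamma >= 0, lambda >= 0 and gamma + lambda < 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "weibull_params")
}

#' Cumulative-Weibull detection probability
#'
#' `P(x) = gamma + (1 - gamma - lambda) * (1 - exp(-(x/alpha)^beta))`,
#' monotone non-decreasing in the modulation depth `x`.
#'
#' @param params A [weibull_params()] object.
#' @param x Modulation depth(s) in percent, `0 <= x <= 100`.
#' @return Detection probabilities.
#' @export
weibull_prob <- function(params, x) {
  if (any(x < 0 | x > 100)) stop("'x' must be in [0, 100] percent")
  f <- 1 - exp(-(x / params$alpha)^params$beta)
  params$gamma + (1 - params$gamma - params$lambda) * f
}

#' Midpoint detection threshold of a fitted Weibull curve
#'
#' The depth at which performance reaches the midpoint between the lower
#' (`gamma`) and upper (`1 - lambda`) bounds of the psychometric curve:
#' in closed form `alpha * log(2)^(1/beta)`, independent of `gamma` and
#' `lambda`.
#'
#' @param params A [weibull_params()] object or a `psychometric_fit`.
#' @return Threshold in percent modulation depth.
#' @export
weibull_threshold <- function(params) {
  if (inherits(params, "psychometric_fit")) params <- params$params
  params$alpha * log(2)^(1 / params$beta)
}

#' Per-level detection performance table
#'
#' @param levels Modulation depths in percent (distinct).
#' @param n_presented Trials presented per level.
#' @param n_hits Hits per level, `0 <= n_hits <= n_presented`.
#' @return An object of class `performance_table` (a data frame).
#' @export
performance_table <- function(levels, n_presented, n_hits) {
  stopifnot(length(levels) == length(n_presented),
            length(levels) == length(n_hits))
  if (any(n_hits < 0 | n_hits > n_presented))
    stop("'n_hits' must satisfy 0 <= n_hits <= n_presented")
  if (anyDuplicated(levels)) stop("'levels' must be distinct")
  structure(
    data.frame(level = levels, n_presented = n_presented, n_hits = n_hits),
    class = c("performance_table", "data.frame")
  )
}

#' Tabulate a trial table into a performance table
#'
#' Counts hits and presentations per modulation depth from a trial-level
#' response table (columns `depth` and `outcome`, the latter with values
#' `"hit"`/`"miss"`; `"early"`/`"discarded"` trials are dropped).
#'
#' @param trials Data frame of trial records.
#' @return A [performance_table()].
#' @export
tabulate_performance <- function(trials) {
  keep <- trials$outcome %in% c("hit", "miss")
  trials <- trials[keep, , drop = FALSE]
  levs <- sort(unique(trials$depth))
  n <- vapply(levs, function(l) sum(trials$depth == l), integer(1))
  k <- vapply(levs, function(l)
    sum(trials$depth == l & trials$outcome == "hit"), integer(1))
  performance_table(levs, n, k)
}

#' Default weakly informative priors for the Weibull fit
#'
#' Beta priors for guess and lapse rates on bounded supports, a truncated
#' normal for the position parameter and a log-normal for the slope; centered
#' on the ranges typical of ripple-detection psychometrics (slopes around
#' 2.5--3.6, guess rates up to ~35%). All hyperparameters are configurable.
#'
#' @param alpha_mean,alpha_sd Normal prior (truncated to `(0, 100]`) for
#'   `alpha`.
#' @param beta_meanlog,beta_sdlog Log-normal prior for `beta`.
#' @param gamma_shape1,gamma_shape2,gamma_max Beta prior for `gamma` scaled to
#'   `[0, gamma_max]`.
#' @param lambda_shape1,lambda_shape2,lambda_max Beta prior for `lambda`
#'   scaled to `[0, lambda_max]`.
#' @return A prior specification list.
#' @export
default_priors <- function(alpha_mean = 30, alpha_sd = 30,
                           beta_meanlog = log(3), beta_sdlog = 0.5,
                           gamma_shape1 = 2, gamma_shape2 = 20, gamma_max = 0.5,
                           lambda_shape1 = 2, lambda_shape2 = 20,
                           lambda_max = 0.25) {
  list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
       beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
       gamma_shape1 = gamma_shape1, gamma_shape2 = gamma_shape2,
       gamma_max = gamma_max,
       lambda_shape1 = lambda_shape1, lambda_shape2 = lambda_shape2,
       lambda_max = lambda_max)
}

log_prior <- function(theta, priors) {
  stats::dnorm(theta[1], priors$alpha_mean, priors$alpha_sd, log = TRUE) +
    stats::dlnorm(theta[2], priors$beta_meanlog, priors$beta_sdlog, log = TRUE) +
    stats::dbeta(theta[3] / priors$gamma_max, priors$gamma_shape1,
                 priors$gamma_shape2, log = TRUE) - log(priors$gamma_max) +
    stats::dbeta(theta[4] / priors$lambda_max, priors$lambda_shape1,
                 priors$lambda_shape2, log = TRUE) - log(priors$lambda_max)
}

binom_loglik <- function(theta, table) {
  p <- theta[3] + (1 - theta[3] - theta[4]) *
    (1 - exp(-(table$level / theta[1])^theta[2]))
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  sum(table$n_hits * log(p) + (table$n_presented - table$n_hits) * log(1 - p))
}

fit_start_values <- function(table, priors) {
  prop <- table$n_hits / pmax(table$n_presented, 1)
  g0 <- min(max(min(prop), 0.001), priors$gamma_max * 0.9)
  l0 <- min(max(1 - max(prop), 0.001), priors$lambda_max * 0.9)
  mid <- g0 + (1 - g0 - l0) / 2
  above <- which(prop >= mid & table$level > 0)
  a0 <- if (length(above)) table$level[min(above)] else stats::median(table$level[table$level > 0])
  a0 <- min(max(a0, 1), 100)
  c(a0, exp(priors$beta_meanlog), g0, l0)
}

#' Fit the four-parameter Weibull psychometric function
#'
#' Constrained maximum a posteriori fit: the binomial log-likelihood of
#' [weibull_prob()] plus the log-priors of [default_priors()] is maximized by
#' bounded quasi-Newton optimization with multiple jittered restarts (the
#' penalized likelihood can be multimodal for sparse tables). The detection
#' threshold is the midpoint criterion `alpha * log(2)^(1/beta)`.
#'
#' @param table A [performance_table()] with at least 4 distinct levels.
#' @param priors A [default_priors()] specification.
#' @param n_restarts Number of jittered optimizer restarts.
#' @param start Optional starting values `c(alpha, beta, gamma, lambda)`
#'   (warm starts for bootstrap refits).
#' @param seed Integer seed for the restart jitter.
#' @param compute_se Compute the observed-information threshold standard
#'   error (skipped in bootstrap refit loops for speed).
#' @return An object of class `psychometric_fit`: list with `params`
#'   ([weibull_params()]), `threshold`, `threshold_se` (observed-information
#'   delta-method standard error; `NA` when the information matrix is
#'   singular), `loglik`, `log_posterior`, `deviance` (relative to the
#'   saturated model), `converged`, `boundary` (degenerate all-hit/all-miss
#'   table flag) and the input `table`.
#' @export
fit_psychometric <- function(table, priors = default_priors(), n_restarts = 5,
                             start = NULL, seed = 1, compute_se = TRUE) {
  stopifnot(inherits(table, "performance_table") || is.data.frame(table))
  if (length(unique(table$level)) < 4)
    stop("insufficient data: need >= 4 distinct levels for 4 free parameters")
  boundary <- all(table$n_hits == table$n_presented) || all(table$n_hits == 0)
  if (boundary)
    warning("degenerate table (all hits or all misses): boundary fit")

  lower <- c(0.5, 0.2, 1e-6, 1e-6)
  upper <- c(100, 20, priors$gamma_max - 1e-6, priors$lambda_max - 1e-6)
  neg_post <- function(theta) -(binom_loglik(theta, table) + log_prior(theta, priors))

  s0 <- if (is.null(start)) fit_start_values(table, priors) else start
  s0 <- pmin(pmax(s0, lower), upper)
  starts <- withr_seed(seed, {
    jit <- replicate(max(n_restarts - 1, 0), {
      s0 * exp(stats::rnorm(4, 0, 0.3))
    })
    cbind(s0, jit)
  })
  best <- NULL
  for (j in seq_len(ncol(starts))) {
    th0 <- pmin(pmax(starts[, j], lower), upper)
    opt <- tryCatch(
      stats::optim(th0, neg_post, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best))
    stop("fit failure: optimizer did not converge from any start")

  th <- best$par
  # observed-information delta-method SE of the midpoint threshold
  threshold_se <- if (!compute_se) NA_real_ else tryCatch({
    H <- stats::optimHess(th, neg_post)
    V <- solve(H)
    gr <- c(log(2)^(1 / th[2]),
            -th[1] * log(2)^(1 / th[2]) * log(log(2)) / th[2]^2, 0, 0)
    se <- sqrt(drop(t(gr) %*% V %*% gr))
    if (is.finite(se)) se else NA_real_
  }, error = function(e) NA_real_)
  params <- weibull_params(th[1], th[2], th[3], th[4])
  ll <- binom_loglik(th, table)
  prop <- table$n_hits / table$n_presented
  p_sat <- pmin(pmax(prop, 1e-10), 1 - 1e-10)
  ll_sat <- sum(table$n_hits * log(p_sat) +
                  (table$n_presented - table$n_hits) * log(1 - p_sat))
  structure(
    list(params = params, threshold = weibull_threshold(params),
         threshold_se = threshold_se,
         loglik = ll, log_posterior = -best$value,
         deviance = 2 * (ll_sat - ll),
         converged = best$convergence == 0, boundary = boundary,
         table = table, priors = priors),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> alpha = %.2f, beta = %.2f, gamma = %.3f, lambda = %.3f | threshold = %.2f%%, deviance = %.2f\n",
    x$params$alpha, x$params$beta, x$params$gamma, x$params$lambda,
    x$threshold, x$deviance
  ))
  invisible(x)
}

#' Midpoint threshold from a fitted psychometric function
#'
#' @param fit A [fit_psychometric()] result.
#' @return Threshold in percent modulation depth.
#' @export
threshold_from_fit <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  weibull_threshold(fit$params)
}

#' Monte Carlo deviance goodness of fit
#'
#' Deviance is twice the log-likelihood difference between the saturated
#' model and the fitted model. Its null distribution is obtained by
#' parametric bootstrap: datasets simulated from the fitted curve are refit
#' and their deviances collected; the Monte Carlo p value is the fraction of
#' simulated deviances at least as large as the observed one. The upper-tail
#' probability of a chi-square reference with `n_levels - 4` degrees of
#' freedom is reported alongside as a diagnostic.
#'
#' @param fit A [fit_psychometric()] result.
#' @param n_sims Number of parametric-bootstrap simulations (>= 100 for a
#'   stable p value).
#' @param seed Integer seed.
#' @param n_restarts Restarts per refit (warm-started from the original fit).
#' @return List with `deviance`, `p` (Monte Carlo), `p_chisq` (reference
#'   diagnostic), and the simulated `null_deviances`.
#' @export
deviance_gof <- function(fit, n_sims = 1000, seed = 1, n_restarts = 2) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (n_sims < 100) warning("n_sims < 100: Monte Carlo p value is unstable")
  tab <- fit$table
  p_fit <- weibull_prob(fit$params, tab$level)
  warm <- unlist(fit$params, use.names = FALSE)
  devs <- withr_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      k <- stats::rbinom(nrow(tab), tab$n_presented, p_fit)
      tb <- performance_table(tab$level, tab$n_presented, k)
      f <- tryCatch(
        suppressWarnings(fit_psychometric(tb, fit$priors,
                                          n_restarts = n_restarts,
                                          start = warm, seed = s,
                                          compute_se = FALSE)),
        error = function(e) NULL
      )
      if (is.null(f)) NA_real_ else f$deviance
    }, numeric(1))
  })
  devs <- devs[is.finite(devs)]
  df <- nrow(tab) - 4
  list(deviance = fit$deviance,
       p = mean(devs >= fit$deviance),
       p_chisq = if (df > 0) stats::pchisq(fit$deviance, df, lower.tail = FALSE) else NA_real_,
       null_deviances = devs)
}

#' Bootstrap confidence interval for the detection threshold
#'
#' Nonparametric bootstrap: per-level binomial resampling of the performance
#' table, refitting, and a bias-corrected percentile interval over the
#' resampled thresholds.
#'
#' @param table A [performance_table()].
#' @param n_boot Number of bootstrap resamples (>= 100 recommended).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @param priors Prior specification for the refits.
#' @param n_restarts Restarts per refit (warm-started).
#' @return List with `ci_low`, `ci_high`, `threshold` (point estimate),
#'   `boot_thresholds`, `n_failed` refits, and `degenerate` flag (set when
#'   the table is deterministic and the interval collapses).
#' @export
bootstrap_threshold_ci <- function(table, n_boot = 1000, conf = 0.95, seed = 1,
                                   priors = default_priors(), n_restarts = 2) {
  fit0 <- suppressWarnings(fit_psychometric(table, priors))
  warm <- unlist(fit0$params, use.names = FALSE)
  prop <- table$n_hits / table$n_presented
  degenerate <- all(prop %in% c(0, 1))
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      k <- stats::rbinom(nrow(table), table$n_presented, prop)
      tb <- performance_table(table$level, table$n_presented, k)
      f <- tryCatch(
        suppressWarnings(fit_psychometric(tb, priors, n_restarts = n_restarts,
                                          start = warm, seed = b,
                                          compute_se = FALSE)),
        error = function(e) NULL
      )
      if (is.null(f)) NA_real_ else f$threshold
    }, numeric(1))
  })
  n_failed <- sum(!is.finite(boots))
  if (n_failed > 0.1 * n_boot)
    warning("more than 10% of bootstrap refits failed; CI may be unreliable")
  boots <- boots[is.finite(boots)]
  if (degenerate)
    warning("deterministic table: degenerate bootstrap interval")
  ci <- bc_percentile_ci(boots, fit0$threshold, conf)
  list(ci_low = ci[1], ci_high = ci[2], threshold = fit0$threshold,
       boot_thresholds = boots, n_failed = n_failed, degenerate = degenerate)
}

#' Screen blocks for attention lapses
#'
#' Reproducible replacement for by-eye block exclusion: a block (subset of
#' trials) is discarded when its pooled hit rate at depths above
#' `depth_cutoff` falls below `hit_cutoff`. A block whose hit rate at those
#' depths is 1 is always retained.
#'
#' @param trials Trial data frame with columns `block`, `depth`, `outcome`.
#' @param depth_cutoff Depth (percent) above which hits are pooled.
#' @param hit_cutoff Minimal pooled hit rate to retain a block.
#' @return List with `keep` (logical per block), `hit_rates`, and the
#'   filtered `trials`.
#' @export
screen_lapse_blocks <- function(trials, depth_cutoff = 80, hit_cutoff = 0.90) {
  blocks <- sort(unique(trials$block))
  rates <- vapply(blocks, function(b) {
    sel <- trials$block == b & trials$depth > depth_cutoff &
      trials$outcome %in% c("hit", "miss")
    if (!any(sel)) return(NA_real_)
    mean(trials$outcome[sel] == "hit")
  }, numeric(1))
  keep <- is.na(rates) | rates >= hit_cutoff
  names(keep) <- names(rates) <- blocks
  list(keep = keep, hit_rates = rates,
       trials = trials[trials$block %in% blocks[keep], , drop = FALSE])
}
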