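#' Singular value decomposition of an MTF matrix
#'
#' Expresses the velocity-by-density matrix as the product of a temporal
#' orthogonal matrix, a diagonal matrix of singular values (non-increasing),
#' and a spectral orthogonal matrix. The decomposition conserves energy: the
#' sum of squared singular values equals the squared Frobenius norm of the
#' input.
#'
#' @param mtf An `mtf_matrix` (or plain numeric matrix) with finite entries.
#' @return An object of class `mtf_svd`: list with `u` (temporal singular
#'   vectors, one per velocity), `d` (singular values), `v` (spectral
#'   singular vectors, one per density), and the input `mtf`.
#' @export
svd_decompose <- function(mtf) {
  m <- unclass(mtf)
  if (!is.matrix(m) || !all(is.finite(m)))
    stop("input must be a complete finite matrix")
  s <- svd(m)
  structure(list(u = s$u, d = s$d, v = s$v, mtf = mtf), class = "mtf_svd")
}

#' @export
print.mtf_svd <- function(x, ...) {
  cat("<mtf_svd> singular values:", format(x$d, digits = 4), "\n")
  invisible(x)
}

#' Inseparability index from singular values
#'
#' `alpha_SVD = 1 - lambda_1^2 / sum(lambda_i^2)`: the proportion of total
#' power in the matrix not carried by its best rank-1 (separable)
#' approximation. Zero for a fully separable (rank-1) matrix; bounded above
#' by `1 - 1/min(dim)` when all singular values are equal.
#'
#' @param x An `mtf_svd` (or an `mtf_matrix`, decomposed on the fly).
#' @return The dimensionless index in `[0, 1)`.
#' @export
inseparability_index <- function(x) {
  if (!inherits(x, "mtf_svd")) x <- svd_decompose(x)
  tot <- sum(x$d^2)
  if (tot == 0) stop("undefined: all-zero matrix")
  1 - x$d[1]^2 / tot
}

#' Truncated-rank reconstruction of an MTF
#'
#' Reconstruction keeping the first `k` singular values; the Frobenius
#' reconstruction error is non-increasing in `k`, and `k = min(dim)`
#' reproduces the input.
#'
#' @param x An `mtf_svd`.
#' @param k Rank, `1 <= k <= length(x$d)`.
#' @return An `mtf_matrix` (same grid as the input) of the reconstruction.
#' @export
reconstruct_mtf <- function(x, k) {
  stopifnot(inherits(x, "mtf_svd"))
  if (k < 1 || k > length(x$d)) stop("'k' out of range")
  idx <- seq_len(k)
  rec <- x$u[, idx, drop = FALSE] %*%
    (x$d[idx] * t(x$v[, idx, drop = FALSE]))
  if (inherits(x$mtf, "mtf_matrix")) mtf_like(x$mtf, rec) else rec
}

#' Rank-correlation agreement between an MTF and its reconstruction
#'
#' Squared Spearman rank correlation (average ranks for ties) across all
#' paired cells of the original and reconstructed matrices.
#'
#' @param original,reconstructed Matrices of identical shape.
#' @return Squared Spearman correlation in `[0, 1]`.
#' @export
r2_svd <- function(original, reconstructed) {
  a <- as.vector(unclass(original)); b <- as.vector(unclass(reconstructed))
  if (length(a) != length(b)) stop("shape mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant input")
  stats::cor(a, b, method = "spearman")^2
}

#' Marginal spectral and temporal modulation transfer functions
#'
#' The first temporal and spectral singular vectors, sign-fixed so each has a
#' positive mean; for a separable matrix these are proportional to the
#' underlying temporal and spectral profiles.
#'
#' @param x An `mtf_svd`.
#' @return List with `temporal` (one value per velocity; the TMTF) and
#'   `spectral` (one value per density; the SMTF), plus the grids.
#' @export
marginal_mtfs <- function(x) {
  stopifnot(inherits(x, "mtf_svd"))
  if (x$d[1] <= 0) stop("undefined: zero leading singular value")
  g <- x$u[, 1]; h <- x$v[, 1]
  if (mean(g) < 0) g <- -g
  if (mean(h) < 0) h <- -h
  list(temporal = g, spectral = h,
       velocities = attr(x$mtf, "velocities"),
       densities = attr(x$mtf, "densities"))
}

#' Up/down symmetry of an MTF
#'
#' Splits the moving-ripple part of the matrix (velocity > 0 rows) into the
#' upward half (density < 0) and the downward half (density > 0), mirrors
#' the downward half so columns align by absolute density, and quantifies
#' symmetry by (i) the squared Pearson correlation over the paired cells,
#' (ii) the gain `g` of the no-intercept regression
#' `M(density < 0) = g * M(density > 0)`, and (iii) the mutual information
#' between the halves.
#'
#' @param mtf An `mtf_matrix` whose density grid is symmetric about 0.
#' @param n_bins Bins for the mutual-information term.
#' @return An object of class `updown_symmetry`: list with `r2_updown`,
#'   `gain`, `mi_updown`, and the paired half-matrices `up`, `down`.
#' @export
updown_symmetry <- function(mtf, n_bins = 3) {
  dens <- attr(mtf, "densities")
  vel <- attr(mtf, "velocities")
  neg <- sort(dens[dens < 0]); pos <- sort(dens[dens > 0])
  if (!isTRUE(all.equal(-rev(neg), pos)))
    stop("density grid is not symmetric about 0")
  if (!any(vel > 0)) stop("need at least one positive-velocity row")
  rows <- which(vel > 0)
  v <- unclass(mtf)
  up <- v[rows, match(neg, dens), drop = FALSE]            # density < 0
  down <- v[rows, match(pos, dens), drop = FALSE]          # density > 0
  down <- down[, rev(seq_len(ncol(down))), drop = FALSE]   # mirror: |density| aligns
  a <- as.vector(up); b <- as.vector(down)
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
  else stats::cor(a, b)^2
  gain <- sum(a * b) / sum(b^2)
  mi <- mutual_information(up, down, n_bins = n_bins)
  structure(list(r2_updown = r2, gain = gain, mi_updown = mi,
                 up = up, down = down),
            class = "updown_symmetry")
}

#' @export
print.updown_symmetry <- function(x, ...) {
  cat(sprintf("<updown_symmetry> r2 = %.3f, gain = %.3f, MI = %.3f bits\n",
              x$r2_updown, x$gain, x$mi_updown))
  invisible(x)
}

mtf_statistic_fn <- function(statistic) {
  switch(statistic,
    alpha_svd = function(m) inseparability_index(m),
    r2_svd = function(m) {
      s <- svd_decompose(m)
      r2_svd(m, reconstruct_mtf(s, 1))
    },
    r2_updown = function(m) updown_symmetry(m)$r2_updown,
    gain_updown = function(m) updown_symmetry(m)$gain,
    mi_updown = function(m) updown_symmetry(m)$mi_updown,
    stop("unknown statistic: ", statistic)
  )
}

#' Permutation null distribution of an MTF statistic
#'
#' Recomputes a named statistic on matrices whose cells have been randomly
#' reshuffled (all cells jointly by default; row- or column-wise restricted
#' reshuffles optional) and returns the null sample with a bias-corrected
#' percentile interval.
#'
#' @param mtf An `mtf_matrix`.
#' @param statistic One of `"alpha_svd"`, `"r2_svd"`, `"r2_updown"`,
#'   `"gain_updown"`, `"mi_updown"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param scope `"all"` (full reshuffle), `"rows"` or `"columns"`.
#' @param conf Confidence level of the null interval.
#' @return List with `observed`, `samples`, `ci`, and `quantile_999` (the
#'   99.9th percentile of the null sample).
#' @export
permutation_null <- function(mtf, statistic = "alpha_svd", n_perm = 1000,
                             seed = 1, scope = c("all", "rows", "columns"),
                             conf = 0.95) {
  if (n_perm < 100) stop("'n_perm' must be >= 100")
  scope <- match.arg(scope)
  fn <- mtf_statistic_fn(statistic)
  observed <- fn(mtf)
  v <- unclass(mtf)
  samples <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- switch(scope,
        all = matrix(sample(v), nrow(v), ncol(v)),
        rows = t(apply(v, 1, sample)),
        columns = apply(v, 2, sample)
      )
      fn(mtf_like(mtf, p))
    }, numeric(1))
  })
  list(observed = observed, samples = samples,
       ci = bc_percentile_ci(samples, mean(samples), conf),
       quantile_999 = unname(stats::quantile(samples, 0.999, type = 6)))
}

#' Cell-noise resampler for MTF bootstrap
#'
#' Parametric cell-level resampling: each cell is perturbed by independent
#' Gaussian noise with a per-cell (or common) standard error, emulating the
#' sampling variability of the per-cell threshold estimates. Use together
#' with [bootstrap_statistic()]. Trial-level resampling (resample trials,
#' refit, rebuild) is available through [simulate_trial_table()] +
#' [fit_mtf_cells()] at higher cost.
#'
#' @param mtf An `mtf_matrix`.
#' @param se Scalar or matrix of per-cell standard errors.
#' @return A resampler function of the replicate index.
#' @export
mtf_cell_resampler <- function(mtf, se) {
  v <- unclass(mtf)
  se_m <- if (length(se) == 1) matrix(se, nrow(v), ncol(v)) else unclass(se)
  function(b) mtf_like(mtf, v + stats::rnorm(length(v)) * se_m)
}

#' Ratio of iso-depth to threshold inseparability
#'
#' Normalizes an iso-depth MTF's inseparability index by the index of the
#' threshold MTF: unity means the iso-depth surface mirrors the threshold
#' surface in its degree of inseparability.
#'
#' @param iso_alpha Inseparability index (or `mtf_svd`/`mtf_matrix`) of the
#'   iso-depth MTF.
#' @param threshold_alpha Inseparability index (or object) of the threshold
#'   MTF; must be positive.
#' @return The dimensionless ratio.
#' @export
alpha_svd_ratio <- function(iso_alpha, threshold_alpha) {
  if (!is.numeric(iso_alpha)) iso_alpha <- inseparability_index(iso_alpha)
  if (!is.numeric(threshold_alpha))
    threshold_alpha <- inseparability_index(threshold_alpha)
  if (threshold_alpha <= 0) stop("undefined: zero threshold inseparability")
  iso_alpha / threshold_alpha
}
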