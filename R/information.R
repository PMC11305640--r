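#' Shannon entropy of a discrete distribution
#'
#' `H = -sum(p * log2(p))` in bits, with `0 * log(0) := 0`.
#'
#' @param p Probability vector: non-negative, summing to 1 within tolerance.
#' @return Entropy in bits, >= 0.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# equal-frequency (rank) binning of a numeric vector into n_bins codes
rank_bin <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  codes <- ceiling(r / length(x) * n_bins)
  pmin(pmax(codes, 1L), n_bins)
}

#' Plug-in mutual information between two matrices
#'
#' Paired cell values are discretized by equal-frequency (rank) binning into
#' `n_bins` codes per variable; the mutual information is the plug-in
#' estimate `I = H(A) + H(B) - H(A, B)` in bits. Rank binning makes the
#' estimate invariant to monotone rescaling of either input. No analytic
#' bias correction is applied by default: permutation nulls absorb the
#' estimator bias. A Miller--Madow correction is available.
#'
#' @param a,b Numeric matrices (or vectors) of identical length.
#' @param n_bins Number of bins per variable (>= 2); few bins are advisable
#'   for the 88-cell matrices.
#' @param correction `"none"` or `"miller-madow"`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b, n_bins = 4, correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  a <- as.vector(unclass(a)); b <- as.vector(unclass(b))
  if (length(a) != length(b)) stop("shape mismatch")
  if (n_bins < 2) stop("'n_bins' must be >= 2")
  ca <- rank_bin(a, n_bins); cb <- rank_bin(b, n_bins)
  joint <- table(factor(ca, levels = seq_len(n_bins)),
                 factor(cb, levels = seq_len(n_bins))) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- shannon_entropy(pa) + shannon_entropy(pb) -
    shannon_entropy(as.vector(joint))
  if (correction == "miller-madow") {
    n <- length(a)
    mm <- function(counts) (sum(counts > 0) - 1) / (2 * n)
    mi <- mi + mm(pa) + mm(pb) - mm(as.vector(joint))
  }
  mi
}

#' Per-slice mutual information profile between two MTFs
#'
#' Mutual information computed per velocity row (or per density column)
#' between corresponding slices of two matrices on the same grid, with
#' bias-corrected percentile bootstrap intervals from paired resampling of
#' the slice cells.
#'
#' @param a,b `mtf_matrix` objects on identical grids.
#' @param axis `"velocity"` (per row) or `"density"` (per column).
#' @param n_bins Bins per slice (slices are short: default 3).
#' @param n_boot Bootstrap resamples per slice.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Data frame with `coord`, `mi`, `ci_low`, `ci_high`; slices too
#'   short to bin are `NA`.
#' @export
mi_profile <- function(a, b, axis = c("velocity", "density"), n_bins = 3,
                       n_boot = 1000, conf = 0.95, seed = 1) {
  axis <- match.arg(axis)
  if (!identical(dim(unclass(a)), dim(unclass(b)))) stop("mismatched grids")
  va <- unclass(a); vb <- unclass(b)
  coords <- if (axis == "velocity") attr(a, "velocities") else attr(a, "densities")
  n_slice <- if (axis == "velocity") nrow(va) else ncol(va)
  rows <- lapply(seq_len(n_slice), function(i) {
    xa <- if (axis == "velocity") va[i, ] else va[, i]
    xb <- if (axis == "velocity") vb[i, ] else vb[, i]
    if (length(xa) < n_bins)
      return(data.frame(coord = coords[i], mi = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    est <- mutual_information(xa, xb, n_bins)
    boots <- withr_seed(seed + i, {
      vapply(seq_len(n_boot), function(bb) {
        idx <- sample(length(xa), replace = TRUE)
        mutual_information(xa[idx], xb[idx], n_bins)
      }, numeric(1))
    })
    ci <- bc_percentile_ci(boots, est, conf)
    data.frame(coord = coords[i], mi = est, ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}

#' Mutual information normalized by the reference self-information
#'
#' `I(a; ref) / I(ref; ref)`: the maximal obtainable value is the reference
#' matrix's self-information, so the ratio is 1 when `a` equals the
#' reference and near 0 when they are independent.
#'
#' @param a Comparison matrix.
#' @param ref Reference matrix (e.g. the threshold MTF).
#' @param n_bins Bins per variable.
#' @return Dimensionless ratio in approximately `[0, 1]`.
#' @export
normalized_mi <- function(a, ref, n_bins = 4) {
  self_mi <- mutual_information(ref, ref, n_bins)
  if (self_mi <= 0) stop("undefined: zero reference self-information")
  mutual_information(a, ref, n_bins) / self_mi
}
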