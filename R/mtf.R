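#' Classify a trial response by its latency
#'
#' Release latencies (seconds from ripple onset) inside the hit window are
#' hits; latencies beyond the window (or absent, `NA`: no release) are
#' misses; latencies below the window are early releases, which are
#' discarded from analysis.
#'
#' @param latency Numeric vector of latencies in seconds; `NA` for no
#'   release.
#' @param window Hit window `c(low, high)` in seconds (default 0.220--0.800).
#' @return Character vector with values `"hit"`, `"miss"`, `"early"`.
#' @export
classify_response <- function(latency, window = c(0.220, 0.800)) {
  if (window[1] >= window[2]) stop("'window' must satisfy low < high")
  if (any(latency < 0, na.rm = TRUE)) stop("negative latency")
  out <- rep("miss", length(latency))
  out[!is.na(latency) & latency < window[1]] <- "early"
  out[!is.na(latency) & latency >= window[1] & latency <= window[2]] <- "hit"
  out
}

#' Density-by-velocity MTF matrix
#'
#' Container for a modulation transfer function on the velocity (rows) by
#' density (columns) grid. Values may be detection thresholds (percent
#' depth), iso-depth performance (probability), or normalized arbitrary
#' units.
#'
#' @param values Numeric matrix, `length(velocities)` rows by
#'   `length(densities)` columns.
#' @param velocities Row coordinate: ripple velocities (Hz), ascending.
#' @param densities Column coordinate: ripple densities (c/o), ascending.
#' @param value_kind One of `"threshold"`, `"iso-dm performance"`,
#'   `"normalized"`, `"sensitivity"`.
#' @param origin_interpolated Was the (0, 0) cell filled by interpolation?
#' @return An object of class `mtf_matrix` (a numeric matrix with
#'   coordinate attributes).
#' @export
mtf_matrix <- function(values, velocities, densities,
                       value_kind = "threshold", origin_interpolated = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != length(velocities) || ncol(values) != length(densities))
    stop("matrix dimensions must match the velocity/density grids")
  if (is.unsorted(velocities) || is.unsorted(densities))
    stop("grids must be ascending")
  dimnames(values) <- list(velocity = as.character(velocities),
                           density = as.character(densities))
  structure(values,
            velocities = velocities, densities = densities,
            value_kind = value_kind, origin_interpolated = origin_interpolated,
            class = c("mtf_matrix", "matrix", "array"))
}

#' @export
print.mtf_matrix <- function(x, ...) {
  cat(sprintf("<mtf_matrix> %d x %d (%s)%s\n", nrow(x), ncol(x),
              attr(x, "value_kind"),
              if (isTRUE(attr(x, "origin_interpolated"))) ", origin interpolated" else ""))
  print(unclass(structure(x, velocities = NULL, densities = NULL,
                          value_kind = NULL, origin_interpolated = NULL)), ...)
  invisible(x)
}

mtf_like <- function(template, values, value_kind = attr(template, "value_kind"),
                     origin_interpolated = attr(template, "origin_interpolated")) {
  mtf_matrix(values, attr(template, "velocities"), attr(template, "densities"),
             value_kind, origin_interpolated)
}

#' Fit psychometric functions for every modulated grid cell
#'
#' Groups a trial table by (density, velocity), tabulates per-depth
#' performance (catch trials are pooled into every cell's zero-depth level as
#' the guess-rate anchor) and fits [fit_psychometric()] per cell.
#'
#' @param trials Trial data frame with columns `density`, `velocity`,
#'   `depth`, `outcome`.
#' @param priors,n_restarts Passed to [fit_psychometric()].
#' @param seed Integer seed.
#' @return Data frame of class `mtf_fits`: one row per modulated cell with
#'   `density`, `velocity`, `alpha`, `beta`, `gamma`, `lambda`, `threshold`,
#'   `threshold_se`, `deviance`, `n_trials`.
#' @export
fit_mtf_cells <- function(trials, priors = default_priors(), n_restarts = 5,
                          seed = 1) {
  is_catch <- trials$density == 0 & trials$velocity == 0
  catch <- trials[is_catch & trials$outcome %in% c("hit", "miss"), , drop = FALSE]
  mod <- trials[!is_catch, , drop = FALSE]
  cells <- unique(mod[, c("density", "velocity")])
  cells <- cells[order(cells$velocity, cells$density), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- mod$density == cells$density[i] & mod$velocity == cells$velocity[i]
    sub <- mod[sel, , drop = FALSE]
    if (nrow(catch)) {
      sub <- rbind(sub[, c("depth", "outcome")],
                   data.frame(depth = 0, outcome = catch$outcome))
    } else sub <- sub[, c("depth", "outcome")]
    tab <- tabulate_performance(sub)
    fit <- suppressWarnings(
      fit_psychometric(tab, priors, n_restarts = n_restarts, seed = seed + i)
    )
    data.frame(density = cells$density[i], velocity = cells$velocity[i],
               alpha = fit$params$alpha, beta = fit$params$beta,
               gamma = fit$params$gamma, lambda = fit$params$lambda,
               threshold = fit$threshold, threshold_se = fit$threshold_se,
               deviance = fit$deviance,
               n_trials = sum(tab$n_presented))
  })
  structure(do.call(rbind, rows), class = c("mtf_fits", "data.frame"))
}

#' Assemble the threshold MTF matrix from per-cell fits
#'
#' Places the midpoint detection threshold of every modulated cell on the
#' velocity-by-density grid. The origin (0, 0) cell, where no threshold is
#' defined, is left `NA` and marked for [interpolate_origin()].
#'
#' @param fits An `mtf_fits` data frame (or any data frame with `density`,
#'   `velocity`, `threshold`).
#' @param velocities,densities Full grid coordinates; defaults to the grids
#'   present in `fits` plus the zero rows/columns.
#' @return An `mtf_matrix` of kind `"threshold"` with an `NA` origin.
#' @export
build_threshold_mtf <- function(fits, velocities = NULL, densities = NULL) {
  if (is.null(velocities)) velocities <- sort(unique(c(0, fits$velocity)))
  if (is.null(densities)) densities <- sort(unique(c(0, fits$density)))
  n_cells <- length(velocities) * length(densities) - 1L
  if (nrow(fits) < n_cells) {
    full <- expand.grid(density = densities, velocity = velocities)
    full <- full[!(full$density == 0 & full$velocity == 0), ]
    have <- paste(fits$density, fits$velocity)
    missing <- full[!(paste(full$density, full$velocity) %in% have), ]
    stop("incomplete grid: missing (density, velocity) cells: ",
         paste(sprintf("(%g, %g)", missing$density, missing$velocity),
               collapse = ", "))
  }
  values <- matrix(NA_real_, length(velocities), length(densities))
  ri <- match(fits$velocity, velocities)
  ci <- match(fits$density, densities)
  values[cbind(ri, ci)] <- fits$threshold
  mtf_matrix(values, velocities, densities, value_kind = "threshold")
}

# pseudo-log coordinate for the velocity axis: octaves, with the zero row
# placed one octave below the lowest nonzero velocity
velocity_pseudo_log <- function(velocities) {
  nz <- velocities[velocities > 0]
  u <- log2(pmax(velocities, min(nz) / 2))
  u
}

#' Interpolate the undefined origin cell of an MTF
#'
#' The static-noise (0, 0) stimulus has no measurable threshold; its cell is
#' filled from the 87 surrounding cells by least-squares bicubic polynomial
#' surface fit on (density, pseudo-log velocity) coordinates (exact on
#' constant and low-order polynomial surfaces), or by averaging the two
#' adjacent grid neighbors.
#'
#' @param mtf An `mtf_matrix` whose only `NA` is the origin cell.
#' @param method `"spline"` (smooth surface fit) or `"bilinear"` (adjacent
#'   neighbors).
#' @return The completed `mtf_matrix` with `origin_interpolated = TRUE`.
#' @export
interpolate_origin <- function(mtf, method = c("spline", "bilinear")) {
  method <- match.arg(method)
  velocities <- attr(mtf, "velocities")
  densities <- attr(mtf, "densities")
  miss <- which(is.na(mtf), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(mtf)
  if (nrow(miss) > 1L) stop("unsupported: more than one missing cell")
  r0 <- miss[1, 1]; c0 <- miss[1, 2]
  if (velocities[r0] != 0 || densities[c0] != 0)
    stop("unsupported: the missing cell is not the (0, 0) origin")
  u <- velocity_pseudo_log(velocities)
  grid <- expand.grid(row = seq_along(velocities), col = seq_along(densities))
  grid$u <- u[grid$row]
  grid$d <- densities[grid$col]
  grid$z <- as.vector(unclass(mtf)[cbind(grid$row, grid$col)])
  known <- !is.na(grid$z)
  if (method == "spline") {
    # full bicubic tensor basis; 16 coefficients against 87 known cells
    X <- stats::model.matrix(~ poly(d, 3, raw = TRUE) * poly(u, 3, raw = TRUE),
                             data = grid)
    fit <- stats::lm.fit(X[known, , drop = FALSE], grid$z[known])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- drop(X[!known, , drop = FALSE] %*% beta)
  } else {
    vals <- unclass(mtf)
    nbrs <- c(if (r0 < nrow(mtf)) vals[r0 + 1, c0],
              if (r0 > 1) vals[r0 - 1, c0],
              if (c0 < ncol(mtf)) vals[r0, c0 + 1],
              if (c0 > 1) vals[r0, c0 - 1])
    pred <- mean(nbrs, na.rm = TRUE)
  }
  out <- unclass(mtf)
  out[r0, c0] <- pred
  mtf_matrix(out, velocities, densities, attr(mtf, "value_kind"),
             origin_interpolated = TRUE)
}

#' Build an iso-depth (suprathreshold) MTF
#'
#' The value at each modulated cell is the fitted detection probability
#' evaluated at a fixed modulation depth `dm0` (the stimulus scale as the
#' independent measure). The origin cell takes the pooled guess rate (its
#' fitted performance at any depth is the guess rate, since the catch
#' stimulus is unmodulated).
#'
#' @param fits An `mtf_fits` data frame with full Weibull parameters.
#' @param dm0 Iso-depth level in percent, in `[0, 100]`.
#' @param velocities,densities Full grid coordinates (defaults as in
#'   [build_threshold_mtf()]).
#' @return An `mtf_matrix` of kind `"iso-dm performance"`.
#' @export
build_iso_dm_mtf <- function(fits, dm0, velocities = NULL, densities = NULL) {
  if (dm0 < 0 || dm0 > 100) stop("'dm0' must be in [0, 100] percent")
  if (is.null(velocities)) velocities <- sort(unique(c(0, fits$velocity)))
  if (is.null(densities)) densities <- sort(unique(c(0, fits$density)))
  values <- matrix(NA_real_, length(velocities), length(densities))
  p <- vapply(seq_len(nrow(fits)), function(i)
    weibull_prob(weibull_params(fits$alpha[i], fits$beta[i],
                                fits$gamma[i], fits$lambda[i]), dm0),
    numeric(1))
  values[cbind(match(fits$velocity, velocities),
               match(fits$density, densities))] <- p
  values[velocities == 0, densities == 0] <- mean(fits$gamma)
  mtf_matrix(values, velocities, densities,
             value_kind = "iso-dm performance",
             origin_interpolated = TRUE)
}

#' Scale an MTF onto the unit interval
#'
#' `(M - min) / (max - min)`: the minimum cell maps to 0 and the maximum to
#' 1. Idempotent and rank-preserving.
#'
#' @param mtf An `mtf_matrix` with finite values.
#' @return An `mtf_matrix` of kind `"normalized"`.
#' @export
normalize_mtf <- function(mtf) {
  v <- unclass(mtf)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("undefined normalization: constant matrix")
  mtf_like(mtf, (v - rng[1]) / diff(rng), value_kind = "normalized")
}

#' Pool normalized MTFs across subjects
#'
#' Inputs are normalized individually, averaged cell-wise, and the average is
#' re-normalized.
#'
#' @param mtfs List of `mtf_matrix` objects on identical grids with identical
#'   value kinds.
#' @return The pooled, normalized `mtf_matrix`.
#' @export
pool_mtfs <- function(mtfs) {
  stopifnot(length(mtfs) >= 1)
  ref <- mtfs[[1]]
  for (m in mtfs[-1]) {
    if (!identical(attr(m, "velocities"), attr(ref, "velocities")) ||
        !identical(attr(m, "densities"), attr(ref, "densities")))
      stop("mismatched grids")
    if (!identical(attr(m, "value_kind"), attr(ref, "value_kind")))
      stop("mismatched value kinds")
  }
  normed <- lapply(mtfs, function(m) unclass(normalize_mtf(m)))
  avg <- Reduce(`+`, normed) / length(normed)
  normalize_mtf(mtf_like(ref, avg, value_kind = "normalized"))
}

#' Write / read an MTF matrix as delimited text
#'
#' The matrix is stored as CSV with velocity row names and density column
#' names; metadata (`value_kind`, `origin_interpolated`) goes to a JSON
#' sidecar `<path>.json`.
#'
#' @param mtf An `mtf_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly (`write_mtf`); the `mtf_matrix` (`read_mtf`).
#' @export
write_mtf <- function(mtf, path) {
  utils::write.csv(as.data.frame(unclass(mtf)), path, row.names = TRUE)
  meta <- list(velocities = attr(mtf, "velocities"),
               densities = attr(mtf, "densities"),
               value_kind = attr(mtf, "value_kind"),
               origin_interpolated = attr(mtf, "origin_interpolated"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mtf
#' @export
read_mtf <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mtf_matrix(as.matrix(df), meta$velocities, meta$densities,
             meta$value_kind, isTRUE(meta$origin_interpolated))
}
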