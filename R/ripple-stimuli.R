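#' Logarithmically spaced tone-complex frequency grid
#'
#' Builds the carrier grid for rippled-noise synthesis: `n_components` tones
#' spaced `tones_per_octave` per octave above the base frequency `f0`, so that
#' component `n` sits at `f0 * 2^((n - 1) / tones_per_octave)`.
#'
#' @param f0 Base frequency in Hz (component 1).
#' @param tones_per_octave Number of components per octave.
#' @param n_components Total number of components.
#'
#' @return An object of class `frequency_grid`: a list with `f0`,
#'   `tones_per_octave`, `n_components`, the component `frequencies` (Hz),
#'   the octave positions `x` of each component above `f0`, and the total
#'   `span_octaves`.
#'
#' @examples
#' g <- frequency_grid(250, 20, 126)
#' round(max(g$frequencies))   # ~19 kHz
#' g$span_octaves              # 6.25 octaves
#' @export
frequency_grid <- function(f0, tones_per_octave, n_components) {
  stopifnot(is.numeric(f0), length(f0) == 1L)
  if (!is.finite(f0) || f0 <= 0) stop("'f0' must be a positive frequency in Hz")
  if (tones_per_octave < 1 || n_components < 1)
    stop("'tones_per_octave' and 'n_components' must be >= 1")
  tones_per_octave <- as.integer(tones_per_octave)
  n_components <- as.integer(n_components)
  x <- (seq_len(n_components) - 1) / tones_per_octave
  structure(
    list(
      f0 = f0,
      tones_per_octave = tones_per_octave,
      n_components = n_components,
      frequencies = f0 * 2^x,
      x = x,
      span_octaves = (n_components - 1) / tones_per_octave
    ),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf(
    "<frequency_grid> %d tones, %d/octave, %.4g Hz .. %.4g Hz (%.2f octaves)\n",
    x$n_components, x$tones_per_octave, min(x$frequencies),
    max(x$frequencies), x$span_octaves
  ))
  invisible(x)
}

#' Dynamic ripple stimulus parameters
#'
#' One ripple specification: spectral density (cycles/octave, signed -- the
#' sign together with a positive velocity sets the direction of spectral
#' motion), temporal velocity (Hz), modulation depth (percent, linear scale),
#' and the durations of the leading static-noise segment and the modulated
#' ripple segment.
#'
#' @param density Ripple density Omega in cycles/octave (signed).
#' @param velocity Ripple velocity omega in Hz (>= 0).
#' @param depth Modulation depth in percent, in `[0, 100]`.
#' @param static_duration Duration D of the unmodulated leading noise (s).
#' @param ripple_duration Duration of the modulated segment (s).
#' @param rms_target Digital RMS each segment is normalized to. Absolute
#'   playback level (dB SPL) is a hardware property and out of scope.
#'
#' @return An object of class `ripple_params`.
#' @export
ripple_params <- function(density, velocity, depth,
                          static_duration = 1, ripple_duration = 1,
                          rms_target = 0.05) {
  if (!is.finite(depth) || depth < 0 || depth > 100)
    stop("'depth' must be in [0, 100] percent")
  if (velocity < 0) stop("'velocity' must be >= 0 Hz")
  if (static_duration <= 0 || ripple_duration <= 0)
    stop("durations must be positive")
  if (rms_target <= 0) stop("'rms_target' must be positive")
  structure(
    list(
      density = density, velocity = velocity, depth = depth,
      static_duration = static_duration, ripple_duration = ripple_duration,
      rms_target = rms_target
    ),
    class = "ripple_params"
  )
}

#' @export
print.ripple_params <- function(x, ...) {
  cat(sprintf(
    "<ripple_params> Omega = %g c/o, omega = %g Hz, dM = %g%%, D = %g s + %g s ripple\n",
    x$density, x$velocity, x$depth, x$static_duration, x$ripple_duration
  ))
  invisible(x)
}

#' Is a ripple specification audibly modulated?
#'
#' A stimulus is unmodulated (indistinguishable from the static-noise catch
#' stimulus) when its depth is zero or both density and velocity are zero.
#'
#' @param params A [ripple_params()] object.
#' @return Logical scalar.
#' @export
is_modulated <- function(params) {
  params$depth > 0 && !(params$density == 0 && params$velocity == 0)
}

#' Sinusoidal ripple amplitude envelope
#'
#' The single-envelope amplitude factor applied to each carrier: 1 during the
#' static segment (`t < D`) and
#' `1 + depth/100 * sin(2*pi*(velocity*t + density*x))` afterwards, where `x`
#' is the component position in octaves above the base frequency. Depth is
#' stored in percent and converted to a linear factor here.
#'
#' @param params A [ripple_params()] object.
#' @param t Time in seconds, `0 <= t < D + ripple_duration` (vectorized).
#' @param x Octaves above the base frequency (vectorized; recycled against `t`).
#' @return Amplitude factor(s) in `[1 - depth/100, 1 + depth/100]`.
#' @export
ripple_envelope <- function(params, t, x) {
  total <- params$static_duration + params$ripple_duration
  if (any(t < 0 | t >= total))
    stop("'t' out of range [0, D + ripple_duration)")
  m <- params$depth / 100
  out <- 1 + m * sin(2 * pi * (params$velocity * t + params$density * x))
  out[t < params$static_duration] <- 1
  out
}

#' Synthesize a dynamic rippled-noise waveform
#'
#' Sums the tone complex `sum_n R(t, x_n) * sin(2*pi*f_n*t + phi_n)` where the
#' envelope `R` is [ripple_envelope()]. The base component's phase is fixed at
#' maximum amplitude (`pi/2`); the remaining phases are drawn uniformly on
#' `(-pi, pi)` from the seeded generator. Carrier phases are identical before
#' and after the static-to-ripple transition (the envelope switch is seamless;
#' no ramp is applied there). The static and modulated segments are each
#' scaled to the requested digital RMS, so total power is matched across the
#' transition.
#'
#' @param params A [ripple_params()] object.
#' @param grid A [frequency_grid()] object.
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   component frequency.
#' @param seed Integer seed for the component phases.
#' @param ramp_duration Optional raised-cosine on/off ramp at stimulus start
#'   and end, in seconds (0 disables; the static-to-ripple transition is never
#'   ramped).
#'
#' @return An object of class `ripple_waveform`: list with `samples`,
#'   `sample_rate`, `params`, `grid`, `seed`, `phases`, and `n_static` (number
#'   of samples in the static segment).
#' @export
synthesize_ripple <- function(params, grid, sample_rate = 50000, seed,
                              ramp_duration = 0) {
  stopifnot(inherits(params, "ripple_params"), inherits(grid, "frequency_grid"))
  if (sample_rate <= 2 * max(grid$frequencies))
    stop("'sample_rate' violates the Nyquist criterion for the tone complex")
  if (missing(seed)) stop("'seed' must be supplied for reproducible phases")

  n_total <- round((params$static_duration + params$ripple_duration) * sample_rate)
  n_static <- round(params$static_duration * sample_rate)
  t <- (seq_len(n_total) - 1) / sample_rate
  t_mod <- t[(n_static + 1):n_total]

  phases <- withr_seed(seed, {
    c(pi / 2, stats::runif(grid$n_components - 1, -pi, pi))
  })

  m <- params$depth / 100
  # envelope sinusoid shares one temporal frequency across components:
  # sin(wt + 2*pi*Omega*x_n) expanded once via angle addition
  swt <- sin(2 * pi * params$velocity * t_mod)
  cwt <- cos(2 * pi * params$velocity * t_mod)

  samples <- numeric(n_total)
  for (n in seq_len(grid$n_components)) {
    carrier <- sin(2 * pi * grid$frequencies[n] * t + phases[n])
    if (m > 0) {
      px <- 2 * pi * params$density * grid$x[n]
      env <- 1 + m * (swt * cos(px) + cwt * sin(px))
      carrier[(n_static + 1):n_total] <- carrier[(n_static + 1):n_total] * env
    }
    samples <- samples + carrier
  }

  # per-segment RMS normalization (equal total power across the transition)
  idx_static <- seq_len(n_static)
  rms_static <- sqrt(mean(samples[idx_static]^2))
  rms_mod <- sqrt(mean(samples[-idx_static]^2))
  samples[idx_static] <- samples[idx_static] * (params$rms_target / rms_static)
  samples[-idx_static] <- samples[-idx_static] * (params$rms_target / rms_mod)

  if (ramp_duration > 0) {
    n_ramp <- min(round(ramp_duration * sample_rate), n_total %/% 2)
    if (n_ramp > 1) {
      w <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / (n_ramp - 1)))
      samples[seq_len(n_ramp)] <- samples[seq_len(n_ramp)] * w
      samples[n_total - seq_len(n_ramp) + 1] <-
        samples[n_total - seq_len(n_ramp) + 1] * w
    }
  }

  structure(
    list(samples = samples, sample_rate = sample_rate, params = params,
         grid = grid, seed = seed, phases = phases, n_static = n_static),
    class = "ripple_waveform"
  )
}

#' @export
print.ripple_waveform <- function(x, ...) {
  cat(sprintf(
    "<ripple_waveform> %d samples @ %g Hz (Omega = %g c/o, omega = %g Hz, dM = %g%%), seed %d\n",
    length(x$samples), x$sample_rate, x$params$density, x$params$velocity,
    x$params$depth, x$seed
  ))
  invisible(x)
}

#' Enumerate the ripple stimulus grid
#'
#' All Cartesian combinations of densities, velocities and depths, with every
#' unmodulated combination (zero depth, or density and velocity both zero)
#' collapsed into a single static-noise catch entry. For the canonical grids
#' (11 densities, 8 velocities, 11 depths including 0) this yields 88
#' density-velocity combinations and 871 distinct audible stimuli.
#'
#' @param densities Numeric vector of ripple densities (c/o), distinct values.
#' @param velocities Numeric vector of ripple velocities (Hz), distinct values.
#' @param depths Numeric vector of modulation depths (percent), distinct values.
#'
#' @return An object of class `stimulus_set`: list with `entries` (data frame
#'   of modulated `density`, `velocity`, `depth` rows), `catch_entry` (one-row
#'   data frame with depth 0), `n_combinations` (distinct density-velocity
#'   pairs including the catch pair), and `n_distinct_audible` (modulated
#'   entries plus the single catch entry).
#' @export
enumerate_stimulus_grid <- function(densities, velocities, depths) {
  if (!length(densities) || !length(velocities) || !length(depths))
    stop("grid value lists must be non-empty")
  if (anyDuplicated(densities) || anyDuplicated(velocities) || anyDuplicated(depths))
    stop("duplicate grid values are not allowed")
  full <- expand.grid(depth = depths, density = densities,
                      velocity = velocities, KEEP.OUT.ATTRS = FALSE)
  unmod <- full$depth == 0 | (full$density == 0 & full$velocity == 0)
  entries <- full[!unmod, c("density", "velocity", "depth")]
  rownames(entries) <- NULL
  catch <- data.frame(density = 0, velocity = 0, depth = 0)
  n_comb <- nrow(unique(entries[, c("density", "velocity")])) + 1L
  structure(
    list(entries = entries, catch_entry = catch,
         n_combinations = n_comb,
         n_distinct_audible = nrow(entries) + 1L),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "<stimulus_set> %d modulated entries over %d (density, velocity) combinations (+1 catch); %d distinct audible stimuli\n",
    nrow(x$entries), x$n_combinations - 1L, x$n_distinct_audible
  ))
  invisible(x)
}

#' The canonical ripple stimulus grids
#'
#' Densities -3.0 to +3.0 c/o in 0.6 steps, velocities 0/4/8/16/32/64/128/256
#' Hz, and 11 depth levels (0, 5, 7.5, 10, 15, 20, 30, 40, 50, 70, 100
#' percent).
#'
#' @return A list with `densities`, `velocities`, `depths`.
#' @export
default_ripple_grid <- function() {
  list(
    densities = seq(-3, 3, by = 0.6),
    velocities = c(0, 4, 8, 16, 32, 64, 128, 256),
    depths = c(0, 5, 7.5, 10, 15, 20, 30, 40, 50, 70, 100)
  )
}

#' Normalized fourth moment of a waveform segment
#'
#' `M4 = mean(S^4) / mean(S^2)^2` after removing the sample mean; an index of
#' instantaneous amplitude fluctuation that equals 3 for Gaussian noise, 1.5
#' for a pure sinusoid, and approximately `3 - 1.5/N` for an `N`-component
#' equal-amplitude random-phase complex.
#'
#' @param x Numeric vector of samples (a waveform segment), or a
#'   `ripple_waveform` whose modulated segment is used.
#' @param remove_mean Subtract the sample mean first (default `TRUE`).
#' @return The dimensionless M4 value.
#' @export
m4_statistic <- function(x, remove_mean = TRUE) {
  if (inherits(x, "ripple_waveform"))
    x <- x$samples[(x$n_static + 1):length(x$samples)]
  if (!length(x)) stop("empty segment")
  if (remove_mean) x <- x - mean(x)
  p2 <- mean(x^2)
  if (p2 == 0) stop("undefined statistic: all-zero segment")
  mean(x^4) / p2^2
}

#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float,
#' mono. Samples are expected within `[-1, 1]` after peak-safe scaling.
#'
#' @param waveform A `ripple_waveform`, or a numeric vector (then
#'   `sample_rate` must be given).
#' @param path Output file path.
#' @param format `"float32"` (lossless round trip) or `"pcm16"`.
#' @param sample_rate Sampling rate in Hz when `waveform` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, format = c("float32", "pcm16"),
                      sample_rate = NULL) {
  format <- match.arg(format)
  if (inherits(waveform, "ripple_waveform")) {
    samples <- waveform$samples
    sample_rate <- waveform$sample_rate
  } else {
    samples <- as.numeric(waveform)
    if (is.null(sample_rate)) stop("'sample_rate' required for bare samples")
  }
  if (max(abs(samples)) > 1 + 1e-12)
    stop("samples exceed [-1, 1]; apply peak-safe scaling before writing")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  fmt_code <- if (format == "pcm16") 1L else 3L
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(samples * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric, scaled to `[-1, 1]` for PCM16),
#'   `sample_rate`, and `format`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt_code <- NA_integer_; sample_rate <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (fmt_code == 1L) {
        raw_s <- readBin(con, "integer", size %/% 2, size = 2,
                         signed = TRUE, endian = "little")
        samples <- raw_s / 32767
      } else if (fmt_code == 3L) {
        samples <- readBin(con, "numeric", size %/% 4, size = 4,
                           endian = "little")
      } else stop("unsupported WAV format code: ", fmt_code)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples, sample_rate = sample_rate,
       format = if (fmt_code == 1L) "pcm16" else "float32")
}

#' Write a stimulus manifest CSV
#'
#' One row per stimulus: filename, density, velocity, depth, static duration,
#' and seed; companion to batch WAV export.
#'
#' @param set A [enumerate_stimulus_grid()] result.
#' @param path Output CSV path.
#' @param seeds Optional integer vector of per-stimulus seeds (recycled).
#' @param static_duration Static-noise duration recorded per stimulus (s).
#' @return The manifest data frame, invisibly.
#' @export
write_stimulus_manifest <- function(set, path, seeds = seq_len(nrow(set$entries) + 1L),
                                    static_duration = 1) {
  all_entries <- rbind(set$catch_entry, set$entries)
  manifest <- data.frame(
    filename = sprintf("ripple_%04d.wav", seq_len(nrow(all_entries))),
    density = all_entries$density,
    velocity = all_entries$velocity,
    depth = all_entries$depth,
    static_duration = static_duration,
    seed = rep_len(seeds, nrow(all_entries))
  )
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}

# Evaluate `expr` under a local RNG seed without touching the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
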