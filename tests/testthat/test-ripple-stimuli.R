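test_that("frequency grid follows the log-spaced construction", {
  g <- frequency_grid(250, 20, 126)
  expect_equal(g$frequencies[1], 250)
  expect_equal(g$frequencies[126], 250 * 2^(125 / 20))
  expect_equal(round(g$frequencies[126] / 1000), 19)  # printed as 19 kHz
  expect_equal(g$span_octaves, 6.25)
  expect_true(all(diff(g$frequencies) > 0))

  g1 <- frequency_grid(250, 20, 21)
  expect_equal(g1$frequencies[21], 500)  # exactly one octave above f0

  expect_error(frequency_grid(-1, 20, 126), "positive")
  expect_error(frequency_grid(250, 0, 126), ">= 1")
})

test_that("ripple envelope is 1 before ripple onset and sinusoidal after", {
  p <- ripple_params(2, 8, 50, static_duration = 1, ripple_duration = 1)
  expect_equal(ripple_envelope(p, t = 0.5, x = 0.3), 1)
  t <- 1.25; x <- 0.4
  expect_equal(ripple_envelope(p, t, x),
               1 + 0.5 * sin(2 * pi * (8 * t + 2 * x)))
  # zero depth
  p0 <- ripple_params(2, 8, 0)
  expect_equal(ripple_envelope(p0, c(0.2, 1.2, 1.9), 0.5), rep(1, 3))
  # catch stimulus: (0, 0) with full depth is unmodulated
  pc <- ripple_params(0, 0, 100)
  expect_equal(ripple_envelope(pc, 1.5, 0.7), 1)
  expect_false(is_modulated(pc))
  # envelope bound
  tt <- seq(1, 1.999, by = 0.001)
  env <- ripple_envelope(p, tt, 0.33)
  expect_true(all(env >= 0.5 - 1e-12 & env <= 1.5 + 1e-12))
  expect_error(ripple_envelope(p, 2.5, 0), "out of range")
})

test_that("synthesis is seed-deterministic with per-segment RMS equalization", {
  g <- small_grid()
  p <- ripple_params(1, 8, 100, static_duration = 0.3, ripple_duration = 0.5,
                     rms_target = 0.05)
  w1 <- synthesize_ripple(p, g, sample_rate = 4000, seed = 7)
  w2 <- synthesize_ripple(p, g, sample_rate = 4000, seed = 7)
  expect_identical(w1$samples, w2$samples)
  w3 <- synthesize_ripple(p, g, sample_rate = 4000, seed = 8)
  expect_false(identical(w1$samples, w3$samples))

  expect_length(w1$samples, round(0.8 * 4000))
  rms_static <- sqrt(mean(w1$samples[1:w1$n_static]^2))
  rms_mod <- sqrt(mean(w1$samples[-(1:w1$n_static)]^2))
  expect_equal(rms_static, 0.05, tolerance = 0.01)
  expect_equal(rms_mod, 0.05, tolerance = 0.01)

  expect_error(synthesize_ripple(p, g, sample_rate = 1500, seed = 1),
               "Nyquist")
})

test_that("static ripple imprints the sinusoidal per-component power profile", {
  # omega = 0, Omega = 2, full depth: component n carries envelope
  # 1 + sin(2*pi*Omega*x_n), so its time-averaged power is proportional to
  # that envelope squared; checked against an FFT-based power estimate
  g <- small_grid()
  p <- ripple_params(2, 0, 100, static_duration = 0.25, ripple_duration = 1)
  w <- synthesize_ripple(p, g, sample_rate = 4000, seed = 3)
  seg <- w$samples[-(1:w$n_static)]
  n <- length(seg)
  spec <- Mod(stats::fft(seg))^2 / n
  freq <- (seq_len(n) - 1) / n * 4000
  comp_power <- vapply(g$frequencies, function(f) {
    sum(spec[freq >= f - 2 & freq <= f + 2])
  }, numeric(1))
  expected <- (1 + sin(2 * pi * 2 * g$x))^2
  expect_gt(cor(comp_power, expected), 0.99)
})

test_that("unmodulated complex has a flat component spectrum", {
  g <- small_grid()
  p <- ripple_params(0, 0, 0, static_duration = 0.25, ripple_duration = 1)
  w <- synthesize_ripple(p, g, sample_rate = 4000, seed = 5)
  seg <- w$samples[-(1:w$n_static)]
  n <- length(seg)
  spec <- Mod(stats::fft(seg))^2 / n
  freq <- (seq_len(n) - 1) / n * 4000
  comp_power <- vapply(g$frequencies, function(f) {
    sum(spec[freq >= f - 2 & freq <= f + 2])
  }, numeric(1))
  # spectral leakage from the non-integer period count spreads a little
  # energy between neighbouring bins; flatness is asserted within that error
  expect_lt(max(comp_power) / min(comp_power), 1.4)
  expect_lt(stats::sd(comp_power) / mean(comp_power), 0.1)
})

test_that("positive density with positive velocity sweeps downward in frequency", {
  # peak of the spectrogram envelope sits at x = (1/4 - omega*t)/Omega mod
  # 1/Omega: the fitted phase of the power profile across x advances with t
  g <- small_grid()
  env_phase_slope <- function(density) {
    p <- ripple_params(density, 4, 100, static_duration = 0.25,
                       ripple_duration = 1)
    w <- synthesize_ripple(p, g, sample_rate = 4000, seed = 9)
    seg <- w$samples[-(1:w$n_static)]
    frame_len <- 100  # 25 ms
    n_frames <- floor(length(seg) / frame_len)
    # basis uses |density| so the fitted phase velocity carries the sign of
    # the spectral sweep direction
    theta <- 2 * pi * abs(density) * g$x
    phases <- vapply(seq_len(n_frames), function(k) {
      fr <- seg[((k - 1) * frame_len + 1):(k * frame_len)]
      spec <- Mod(stats::fft(fr))^2
      freq <- (seq_len(frame_len) - 1) / frame_len * 4000
      pw <- vapply(g$frequencies, function(f) {
        sum(spec[abs(freq - f) <= 40])
      }, numeric(1))
      # power profile across x is A + B * sin(theta + phi(t)) with
      # phi = 2*pi*omega*t; projections give sin/cos of phi
      atan2(sum(pw * cos(theta)), sum(pw * sin(theta)))
    }, numeric(1))
    unwrapped <- phases + 2 * pi * cumsum(c(0, diff(phases) < -pi)) -
      2 * pi * cumsum(c(0, diff(phases) > pi))
    unname(coef(lm(unwrapped ~ seq_along(unwrapped)))[2])
  }
  # envelope phase advances 2*pi*omega per second: with omega = 4 Hz and
  # 25 ms frames, +0.63 rad/frame for downward (density > 0) motion
  expect_gt(env_phase_slope(1), 0.3)
  # mirrored density reverses the sweep direction (upward)
  expect_lt(env_phase_slope(-1), -0.3)
})

test_that("stimulus grid enumeration collapses unmodulated entries", {
  grid <- paper_grid()
  ss <- enumerate_stimulus_grid(grid$densities, grid$velocities, grid$depths)
  expect_equal(ss$n_combinations, 88)
  expect_equal(ss$n_distinct_audible, 871)
  expect_equal(nrow(ss$entries), 870)
  expect_true(all(ss$entries$depth > 0))
  expect_false(any(ss$entries$density == 0 & ss$entries$velocity == 0))

  ss0 <- enumerate_stimulus_grid(0, 0, c(0, 50))
  expect_equal(ss0$n_distinct_audible, 1)

  expect_error(enumerate_stimulus_grid(c(1, 1), 0, 50), "duplicate")
})

test_that("M4 matches closed forms for sinusoid, constant, and flat complex", {
  t <- seq(0, 1, length.out = 4000)[-4000]
  expect_equal(m4_statistic(sin(2 * pi * 8 * t)), 1.5, tolerance = 1e-6)
  expect_equal(m4_statistic(rep(3, 100), remove_mean = FALSE), 1)
  expect_error(m4_statistic(rep(0, 10)), "all-zero")
  expect_error(m4_statistic(numeric(0)), "empty")

  # Gaussian-limit oracle: mean M4 of the flat 126-tone complex over many
  # seeded realizations approaches 3 - 1.5/126 = 2.988
  g <- frequency_grid(250, 20, 126)
  p <- ripple_params(0, 0, 0, static_duration = 0.1, ripple_duration = 1)
  m4s <- vapply(1:25, function(s) {
    m4_statistic(synthesize_ripple(p, g, 50000, seed = s))
  }, numeric(1))
  expect_gt(mean(m4s), 2.9)
  expect_lt(mean(m4s), 3.05)
})

test_that("WAV round trip preserves samples within format precision", {
  g <- small_grid()
  p <- ripple_params(1, 8, 50, static_duration = 0.1, ripple_duration = 0.2)
  w <- synthesize_ripple(p, g, sample_rate = 4000, seed = 2)
  w$samples <- w$samples / max(abs(w$samples))

  f32 <- tempfile(fileext = ".wav")
  write_wav(w, f32, "float32")
  r <- read_wav(f32)
  expect_equal(r$sample_rate, 4000)
  expect_lt(max(abs(r$samples - w$samples)), 1e-7)  # float32 rounding

  p16 <- tempfile(fileext = ".wav")
  write_wav(w, p16, "pcm16")
  r16 <- read_wav(p16)
  expect_lt(max(abs(r16$samples - w$samples)), 2^-15 + 1e-9)

  # header sample count: duration x rate
  w2 <- synthesize_ripple(ripple_params(0, 0, 0, 1.5, 1), g, 4000, seed = 1)
  f2 <- tempfile(fileext = ".wav")
  write_wav(w2$samples / max(abs(w2$samples)), f2, "float32", sample_rate = 4000)
  expect_length(read_wav(f2)$samples, 2.5 * 4000)
  unlink(c(f32, p16, f2))
})

test_that("stimulus manifest lists every stimulus with its parameters", {
  ss <- mini_stimuli()
  path <- tempfile(fileext = ".csv")
  man <- write_stimulus_manifest(ss, path)
  expect_true(file.exists(path))
  expect_equal(nrow(man), ss$n_distinct_audible)
  expect_equal(man$depth[1], 0)  # catch entry first
  unlink(path)
})
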