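random_mtf <- function(seed, nr = 8, nc = 11) {
  set.seed(seed)
  mtf_matrix(matrix(runif(nr * nc, 5, 100), nr, nc),
             c(0, 4, 8, 16, 32, 64, 128, 256)[seq_len(nr)],
             seq(-3, 3, length.out = nc))
}

test_that("SVD conserves energy and reconstructs exactly at full rank", {
  for (s in 1:20) {
    m <- random_mtf(s)
    sv <- svd_decompose(m)
    expect_true(all(diff(sv$d) <= 1e-12))
    expect_equal(sum(sv$d^2), sum(unclass(m)^2), tolerance = 1e-10)
    rec <- reconstruct_mtf(sv, length(sv$d))
    expect_lt(norm(unclass(m) - unclass(rec), "F") / norm(unclass(m), "F"),
              1e-10)
  }
  bad <- unclass(random_mtf(1)); bad[2, 2] <- NA
  expect_error(svd_decompose(bad), "finite")
})

test_that("rank-1 structure gives zero inseparability and unit rank correlation", {
  # sqrt-of-prime factors: all 88 products distinct (no rank ties)
  g <- sqrt(c(2, 3, 5, 7, 11, 13, 17, 19))
  h <- sqrt(c(23, 29, 31, 37, 41, 43, 47, 53, 59, 61, 67))
  m <- mtf_matrix(outer(g, h), c(0, 4, 8, 16, 32, 64, 128, 256),
                  seq(-3, 3, by = 0.6))
  sv <- svd_decompose(m)
  expect_lt(sv$d[2], 1e-10 * sv$d[1])
  expect_equal(inseparability_index(sv), 0, tolerance = 1e-12)
  expect_equal(r2_svd(m, reconstruct_mtf(sv, 1)), 1, tolerance = 1e-10)
  expect_equal(unclass(reconstruct_mtf(sv, 1)), unclass(m),
               tolerance = 1e-10)
})

test_that("inseparability arithmetic matches hand-computed spectra", {
  fake_svd <- function(d) structure(list(d = d), class = "mtf_svd")
  expect_equal(inseparability_index(fake_svd(c(2, 1, 0, 0))), 0.2)
  expect_equal(inseparability_index(fake_svd(rep(1, 8))), 1 - 1 / 8)
  expect_error(inseparability_index(fake_svd(rep(0, 8))), "all-zero")
  # embedded identity block: all singular values equal 1
  m <- diag(8)
  sv <- svd(cbind(m, matrix(0, 8, 3)))
  expect_equal(sv$d, rep(1, 8))
})

test_that("Frobenius identity oracle holds across random matrices", {
  # alpha from singular values must equal 1 - lambda1^2 / ||M||_F^2
  for (s in 1:1000) {
    nr <- sample(3:8, 1); nc <- sample(3:11, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    sv <- svd(m)
    a1 <- 1 - sv$d[1]^2 / sum(sv$d^2)
    a2 <- 1 - sv$d[1]^2 / sum(m^2)
    expect_equal(a1, a2, tolerance = 1e-10)
  }
})

test_that("reconstruction error is monotone non-increasing in rank", {
  for (s in 1:10) {
    m <- random_mtf(s + 100)
    sv <- svd_decompose(m)
    errs <- vapply(1:8, function(k)
      norm(unclass(m) - unclass(reconstruct_mtf(sv, k)), "F"), numeric(1))
    expect_true(all(diff(errs) <= 1e-10))
  }
  sv <- svd_decompose(random_mtf(1))
  expect_error(reconstruct_mtf(sv, 0), "out of range")
  expect_error(reconstruct_mtf(sv, 9), "out of range")
})

test_that("rank correlation is invariant to monotone transforms", {
  m <- random_mtf(7)
  mono <- mtf_matrix(exp(unclass(m) / 30), attr(m, "velocities"),
                     attr(m, "densities"))
  expect_equal(r2_svd(m, mono), 1, tolerance = 1e-12)
  expect_error(r2_svd(m, mtf_matrix(matrix(1, 8, 11),
                                    attr(m, "velocities"),
                                    attr(m, "densities"))),
               "constant")
})

test_that("second singular value improves reconstruction of inseparable MTFs", {
  m <- attr(smooth_mtf(ratio = 0.10), "sensitivity")
  sv <- svd_decompose(m)
  expect_lt(r2_svd(m, reconstruct_mtf(sv, 1)), r2_svd(m, reconstruct_mtf(sv, 2)))
  # near-separable surface: rank-1 already explains almost everything
  m2 <- smooth_mtf(ratio = 0.07)
  sv2 <- svd_decompose(m2)
  expect_gt(r2_svd(m2, reconstruct_mtf(sv2, 1)), 0.93)
})

test_that("marginal profiles recover the generating separable factors", {
  g <- c(0.5, 2, 4, 5, 3, 1.5, 0.7, 0.3)
  h <- c(0.3, 0.8, 1.5, 2.5, 3.2, 3.5, 3.2, 2.5, 1.5, 0.8, 0.3)
  m <- mtf_matrix(outer(g, h), c(0, 4, 8, 16, 32, 64, 128, 256),
                  seq(-3, 3, by = 0.6))
  prof <- marginal_mtfs(svd_decompose(m))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(prof$temporal, g), 0.999)
  expect_gt(cosine(prof$spectral, h), 0.999)
  expect_gt(mean(prof$temporal), 0)
  expect_gt(mean(prof$spectral), 0)
  # band-pass temporal truth: recovered peak at the true peak row
  expect_equal(which.max(prof$temporal), which.max(g))
})

test_that("up/down symmetry statistics behave on mirrored and scaled halves", {
  base <- smooth_mtf()
  ud <- updown_symmetry(base)
  expect_equal(ud$r2_updown, 1, tolerance = 1e-10)
  expect_equal(ud$gain, 1, tolerance = 1e-10)
  expect_equal(dim(ud$up), c(7, 5))

  # scaled upward half: exact gain recovery (on the sensitivity surface,
  # where the gain acts multiplicatively)
  sens <- attr(make_ground_truth_mtf(
    ground_truth_spec(inseparable_ratio = 0, updown_gain = 2.5)
  ), "sensitivity")
  ud2 <- updown_symmetry(sens)
  expect_equal(ud2$gain, 2.5, tolerance = 1e-10)
  expect_equal(ud2$r2_updown, 1, tolerance = 1e-10)

  asym <- mtf_matrix(matrix(1:8, 2, 4), c(0, 4), c(-2, -1, 1, 3))
  expect_error(updown_symmetry(asym), "symmetric")
})

test_that("permuted smooth MTFs rarely show strong up/down symmetry", {
  null <- permutation_null(smooth_mtf(), "r2_updown", n_perm = 2000, seed = 8)
  expect_lte(null$quantile_999, 0.8)
  expect_gt(null$observed, 0.99)
})

test_that("permutation null separates measured from shuffled inseparability", {
  m <- smooth_mtf(ratio = 0.07)
  null <- permutation_null(m, "alpha_svd", n_perm = 500, seed = 3)
  # a smooth near-separable surface has far lower alpha than its shuffles
  expect_lt(null$observed, quantile(null$samples, 0.001))

  # permuting a constant matrix leaves any statistic unchanged
  mc <- mtf_matrix(matrix(2, 8, 11), c(0, 4, 8, 16, 32, 64, 128, 256),
                   seq(-3, 3, by = 0.6))
  null_c <- permutation_null(mc, "alpha_svd", n_perm = 100, seed = 1)
  expect_equal(var(null_c$samples), 0)

  # Monte Carlo convergence: null CI width shrinks with more permutations
  w <- vapply(c(200, 5000), function(np) {
    nn <- permutation_null(m, "alpha_svd", n_perm = np, seed = 5)
    diff(quantile(nn$samples, c(0.025, 0.975))) /
      sqrt(length(nn$samples)) * 0 + diff(nn$ci)
  }, numeric(1))
  expect_lte(abs(w[2] - w[1]), w[1])  # stabilizes rather than diverging
  expect_error(permutation_null(m, "nonsense"), "unknown statistic")
  expect_error(permutation_null(m, "alpha_svd", n_perm = 10), ">= 100")
})

test_that("generic bootstrap achieves nominal coverage on a known mean", {
  # standard calibration: 95% BC interval for the mean of normal draws
  n <- 40
  cover <- vapply(1:200, function(r) {
    set.seed(r + 4000)
    x <- rnorm(n, mean = 3, sd = 2)
    bs <- bootstrap_statistic(
      x, function(b) sample(x, replace = TRUE), mean,
      n_boot = 400, seed = r
    )
    bs$ci[1] <= 3 && 3 <= bs$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("bootstrap machinery flags degenerate and failing resamples", {
  x <- c(1, 1, 1)
  bs <- bootstrap_statistic(x, function(b) x, mean, n_boot = 10, seed = 1)
  expect_true(bs$degenerate)
  expect_equal(bs$ci, c(1, 1))
  bs2 <- bootstrap_statistic(x, function(b) stop("boom"), mean,
                             n_boot = 10, seed = 1)
  expect_equal(bs2$n_skipped, 10)
})

test_that("bootstrap cloud of a near-separable MTF hugs the separable corner", {
  m <- smooth_mtf(ratio = 0.07)
  rs <- mtf_cell_resampler(m, se = 1.5)
  stat2 <- function(mm) {
    sv <- svd_decompose(mm)
    c(r2 = r2_svd(mm, reconstruct_mtf(sv, 1)), a = inseparability_index(sv))
  }
  set.seed(12)
  cloud <- t(replicate(300, stat2(rs(1))))
  expect_gt(min(cloud[, "r2"]), 0.8)
  expect_lt(max(cloud[, "a"]), 0.2)
  # permuted matrices live far away: clouds disjoint on both axes
  perm <- t(replicate(300, {
    p <- mtf_matrix(matrix(sample(unclass(m)), 8, 11),
                    attr(m, "velocities"), attr(m, "densities"))
    stat2(p)
  }))
  expect_lt(max(cloud[, "a"]), min(perm[, "a"]))
  expect_gt(min(cloud[, "r2"]), max(perm[, "r2"]))
})

test_that("iso-to-threshold inseparability ratio behaves at its anchors", {
  m <- smooth_mtf(ratio = 0.10)
  a <- inseparability_index(svd_decompose(m))
  expect_equal(alpha_svd_ratio(a, a), 1)
  expect_equal(alpha_svd_ratio(0, a), 0)
  expect_error(alpha_svd_ratio(a, 0), "zero")
  # a family whose inseparable part shrinks: ratio decreases
  ratios <- vapply(c(0.12, 0.08, 0.04), function(r) {
    alpha_svd_ratio(
      inseparability_index(svd_decompose(attr(smooth_mtf(r), "sensitivity"))),
      inseparability_index(svd_decompose(attr(m, "sensitivity")))
    )
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})
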