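test_that("crossing counts on a deterministic wave follow the half-open root
           convention", {
  # z = exp(2 pi i x): projection at theta0 = 0 is cos(2 pi x), with roots
  # at 0.25, 0.75, 1.25, 1.75 on [0, 2.25)
  t <- seq(0, 2.25, by = 0.005); t <- t[t < 2.25]
  sampled <- list(z = exp(2i * pi * t), t = t, theta0 = 0)
  n <- count_crossings(sampled)
  expect_equal(as.integer(n), 4L)
  expect_equal(attr(n, "positions"), c(0.25, 0.75, 1.25, 1.75),
               tolerance = 1e-4)
  # translation by one period leaves the count unchanged
  sampled2 <- list(z = exp(2i * pi * (t + 1)), t = t, theta0 = 0)
  expect_equal(as.integer(count_crossings(sampled2)), 4L)
  # the strict single-orientation convention keeps every other root
  expect_equal(as.integer(count_crossings(sampled, convention = "strict")), 2L)
  expect_error(count_crossings(list(z = rep(1i, 5), t = 1:5, theta0 = 0)),
               "identically zero")
})

test_that("exact-zero samples are attributed to the following interval", {
  # piecewise values engineered to hit the tie-break branches:
  # zero at the start followed by a positive value counts as a root;
  # zero at the end after a negative value does not
  s <- list(z = c(0, 1, -1, 0) + 1i, t = 0:3, theta0 = 0)
  expect_equal(as.integer(count_crossings(s)), 2L)
  s2 <- list(z = c(1, -1, 0) + 1i, t = 0:2, theta0 = 0)
  expect_equal(as.integer(count_crossings(s2)), 1L)
})

test_that("winding-number detection finds linear vortices with the right
           charge", {
  h <- 0.05
  xs <- seq(0, 1, by = h); ys <- seq(0, 1, by = h)
  zz <- outer(ys - 0.525, rep(1, length(xs))) * 1i +
        outer(rep(1, length(ys)), xs - 0.475)
  fs <- field_sample(zz, spacing = h)
  det <- detect_pinwheels(fs)
  expect_equal(nrow(det$detections), 1L)
  expect_equal(det$detections$charge, 1L)
  expect_lt(abs(det$detections$x - 0.475), h)
  expect_lt(abs(det$detections$y - 0.525), h)
  det2 <- detect_pinwheels(field_sample(Conj(zz), spacing = h))
  expect_equal(det2$detections$charge, -1L)
  # window filtering is half-open
  det3 <- detect_pinwheels(fs, window = c(0, 0.4, 0, 0.4))
  expect_equal(nrow(det3$detections), 0L)
})

test_that("plaquette detections survive grid refinement and balance their
           charges", {
  P <- atomic_spectrum(2 * pi)
  total_c <- 0; total_f <- 0; signed <- 0; matched <- 0; n_coarse <- 0
  for (i in 1:10) {
    fc <- sample_field(P, 64, width = 6, spacing = 1 / 12, seed = 50 + i)
    ff <- sample_field(P, 64, width = 6, spacing = 1 / 24, seed = 50 + i)
    win <- c(0.5, 5.5, 0.5, 5.5)
    dc <- detect_pinwheels(fc, win)$detections
    df <- detect_pinwheels(ff, win)$detections
    dist <- vapply(seq_len(nrow(dc)), function(k) {
      min(sqrt((df$x - dc$x[k])^2 + (df$y - dc$y[k])^2))
    }, numeric(1))
    matched <- matched + sum(dist < sqrt(2) / 12)
    n_coarse <- n_coarse + nrow(dc)
    total_c <- total_c + nrow(dc)
    total_f <- total_f + nrow(df)
    signed <- signed + sum(dc$charge)
  }
  # twofold refinement changes the ensemble count by < 2 % ...
  expect_lt(abs(total_c - total_f) / total_f, 0.02)
  # ... and nearly all detections persist within a coarse plaquette diameter
  # (the rest are tight +/- dipoles resolved differently by the two grids)
  expect_gt(matched / n_coarse, 0.95)
  expect_gt(total_c, 500)                   # ~ pi * 25 per field
  expect_lt(abs(signed) / total_c, 0.15)    # near charge balance
})

test_that("empirical pinwheel density is stable under window doubling", {
  P <- atomic_spectrum(2 * pi)
  d1 <- numeric(8); d2 <- numeric(8)
  for (i in 1:8) {
    fs <- sample_field(P, 128, width = 13, spacing = 1 / 12, seed = 600 + i)
    d1[i] <- empirical_pinwheel_density(
      detect_pinwheels(fs, c(1, 6, 1, 6)), 1)
    d2[i] <- empirical_pinwheel_density(
      detect_pinwheels(fs, c(1, 11, 1, 11)), 1)
  }
  se <- sqrt(stats::var(d1) / 8 + stats::var(d2) / 8)
  expect_lt(abs(mean(d1) - mean(d2)), 3 * se)
  expect_error(
    empirical_pinwheel_density(detect_pinwheels(
      sample_field(P, 64, width = 6, spacing = 1 / 12, seed = 1),
      c(0, 2, 0, 2)), 1),
    "edge-effect guard")
})

test_that("Monte Carlo ensembles are seed-deterministic and ergodic", {
  P <- atomic_spectrum(2 * pi)
  e1 <- mc_crossing_moments(P, 2, n_realizations = 100, seed = 12,
                            n_waves = 64)
  e2 <- mc_crossing_moments(P, 2, n_realizations = 100, seed = 12,
                            n_waves = 64)
  expect_identical(e1$values, e2$values)
  # long-segment single-realization rate vs ensemble rate
  long <- sample_on_segment(P, 256, segment_query(300), seed = 1234)
  rate_one <- as.integer(count_crossings(long)) / 300
  ens <- mc_crossing_moments(P, 5, n_realizations = 400, seed = 77,
                             n_waves = 64)
  rate_ens <- ens$mean / 5
  se <- ens$se_mean / 5
  # the single long segment has correlated increments; allow a generous
  # multiple of the ensemble standard error
  expect_lt(abs(rate_one - rate_ens), 6 * se + 0.05 * rate_ens)
})

test_that("small-interval crossing counts are Bernoulli", {
  P <- atomic_spectrum(2 * pi)
  ens <- mc_crossing_moments(P, 0.05, n_realizations = 400, seed = 8,
                             n_waves = 64)
  expect_true(all(ens$values %in% 0:1))
  p <- ens$mean
  expect_equal(ens$variance, p * (1 - p), tolerance = 0.05)
})
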