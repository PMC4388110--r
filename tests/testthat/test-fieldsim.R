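test_that("plane-wave synthesis is deterministic given the seed and honors
           guards", {
  P <- atomic_spectrum(2 * pi)
  w1 <- plane_waves(P, 64, seed = 5)
  w2 <- plane_waves(P, 64, seed = 5)
  expect_identical(w1$amp, w2$amp)
  expect_identical(w1$kx, w2$kx)
  w3 <- plane_waves(P, 64, seed = 6)
  expect_false(identical(w1$amp, w3$amp))
  # all wave vectors lie exactly on the ring
  expect_equal(sqrt(w1$kx^2 + w1$ky^2), rep(2 * pi, 64))
  expect_error(plane_waves(P, 8), "at least 16")
  P37 <- multicircle_spectrum(10.95, 0.95, 18)
  expect_error(plane_waves(P37, 20), "atoms")
  # atomic stratification: wave counts proportional to weights
  Pw <- atomic_spectrum(c(1, 2), c(0.25, 0.75))
  ww <- plane_waves(Pw, 64, seed = 1)
  expect_equal(sum(ww$radii == 1), 16L)
  expect_equal(sum(ww$radii == 2), 48L)
})

test_that("sampled fields are standardized: E|z|^2 = 1, Re/Im balanced and
           uncorrelated", {
  P <- atomic_spectrum(2 * pi)    # lambda_sq = 1
  stats <- t(vapply(1:20, function(i) {
    fs <- sample_field(P, n_waves = 64, width = 10, spacing = 1 / 12,
                       seed = 100 + i)
    z <- as.vector(fs$z)
    c(m2 = mean(Mod(z)^2), vr = stats::var(Re(z)), vi = stats::var(Im(z)),
      cor = stats::cor(Re(z), Im(z)))
  }, numeric(4)))
  se <- apply(stats, 2, stats::sd) / sqrt(nrow(stats))
  expect_lt(abs(mean(stats[, "m2"]) - 1), 5 * se["m2"])
  expect_lt(abs(mean(stats[, "vr"]) - 0.5), 5 * se["vr"])
  expect_lt(abs(mean(stats[, "vi"]) - 0.5), 5 * se["vi"])
  expect_lt(abs(mean(stats[, "cor"])), 5 * se["cor"])
})

test_that("grid rows and segment samples agree for the same seed and recipe", {
  P <- uniform_annulus(2 * pi * 0.9, 2 * pi * 1.1)
  lsq <- lambda_sq(P)
  h <- lsq / 60
  fs <- sample_field(P, n_waves = 64, width = 2, height = 2, spacing = h,
                     seed = 9)
  iy <- 13L
  seg <- segment_query(fs$x[length(fs$x)] - fs$x[1],
                       anchor = c(fs$x[1], fs$y[iy]), angle = 0)
  ss <- sample_on_segment(P, n_waves = 64, segment = seg,
                          samples_per_wavelength = 60, seed = 9)
  # same wave set, same points -> identical values
  expect_equal(length(ss$z), ncol(fs$z))
  expect_lt(max(Mod(ss$z - fs$z[iy, ])), 1e-12)
  expect_error(sample_on_segment(P, 64, seg, samples_per_wavelength = 10),
               "at least 50")
  expect_error(sample_field(P, 64, width = 2, spacing = lsq / 4),
               "resolution guard")
})

test_that("zero-length segments reduce to a standard complex Gaussian point
           value", {
  P <- atomic_spectrum(2 * pi)
  vals <- vapply(1:500, function(i) {
    sample_on_segment(P, 32, segment_query(0), seed = i)$z
  }, complex(1))
  expect_lt(abs(mean(Mod(vals)^2) - 1), 5 * stats::sd(Mod(vals)^2) / sqrt(500))
  expect_lt(abs(mean(Re(vals))), 5 * stats::sd(Re(vals)) / sqrt(500))
})

test_that("segment autocovariance of the real part matches the line
           covariance", {
  P <- atomic_spectrum(2 * pi)
  lsq <- 1
  lags <- c(0, 0.25, 0.5, 1)
  nrep <- 200L
  acc <- matrix(0, nrep, length(lags))
  for (i in seq_len(nrep)) {
    ss <- sample_on_segment(P, 64, segment_query(4), seed = 400 + i,
                            samples_per_wavelength = 60)
    x <- Re(ss$z)
    dt <- ss$t[2] - ss$t[1]
    for (j in seq_along(lags)) {
      k <- round(lags[j] / dt)
      acc[i, j] <- mean(x[seq_len(length(x) - k)] * x[seq_len(length(x) - k) + k])
    }
  }
  est <- colMeans(acc)
  se <- apply(acc, 2, stats::sd) / sqrt(nrep)
  theo <- line_covariance(P, lags, "half")
  expect_true(all(abs(est - theo) < 4 * se))
})

test_that("monochromatic fields satisfy the Helmholtz equation discretely at
           second order", {
  R0 <- 2 * pi
  P <- atomic_spectrum(R0)
  resid_for <- function(h) {
    fs <- sample_field(P, 64, width = 3, spacing = h, seed = 77)
    z <- fs$z
    ny <- nrow(z); nx <- ncol(z)
    lap <- (z[2:(ny - 1), 1:(nx - 2)] + z[2:(ny - 1), 3:nx] +
            z[1:(ny - 2), 2:(nx - 1)] + z[3:ny, 2:(nx - 1)] -
            4 * z[2:(ny - 1), 2:(nx - 1)]) / h^2
    core <- z[2:(ny - 1), 2:(nx - 1)]
    mean(Mod(lap + R0^2 * core)) / mean(Mod(R0^2 * core))
  }
  r1 <- resid_for(1 / 24)
  r2 <- resid_for(1 / 48)
  expect_lt(r1, 0.01)
  expect_equal(r1 / r2, 4, tolerance = 0.15)   # O(h^2)
})

test_that("crossing rates are isotropic: rotated probes agree within Monte
           Carlo error", {
  P <- atomic_spectrum(2 * pi)
  nrep <- 200L
  ang <- 37 * pi / 180
  cx <- integer(nrep); cr <- integer(nrep)
  for (i in seq_len(nrep)) {
    sx <- sample_on_segment(P, 64, segment_query(5, angle = 0), seed = 900 + i)
    sr <- sample_on_segment(P, 64, segment_query(5, angle = ang),
                            seed = 2900 + i)
    cx[i] <- count_crossings(sx)
    cr[i] <- count_crossings(sr)
  }
  se <- sqrt(stats::var(cx) / nrep + stats::var(cr) / nrep)
  expect_lt(abs(mean(cx) - mean(cr)), 3 * se)
})

test_that("grid containers round-trip through the binary writer", {
  P <- atomic_spectrum(2 * pi)
  fs <- sample_field(P, 32, width = 1.5, spacing = 1 / 16, seed = 4)
  path <- tempfile(fileext = ".f64")
  write_field(fs, path)
  back <- read_field(path)
  expect_equal(back$z, fs$z)
  expect_equal(back$spacing, fs$spacing)
  png_path <- tempfile(fileext = ".png")
  save_orientation_png(fs, png_path)
  expect_gt(file.size(png_path), 0)
  unlink(c(path, paste0(path, ".json"), png_path))
})
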