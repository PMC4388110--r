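#' Plane-wave synthesis recipe
#'
#' Draws the deterministic-given-seed ingredients of a plane-wave
#' superposition \eqn{z(x) = \sum_j a_j e^{i k_j \cdot x}}:
#' \itemize{
#'   \item radii: stratified by the spectral measure — atoms receive blocks
#'     of waves proportional to their weight (largest-remainder rounding),
#'     annuli receive the quantiles \eqn{(j - 1/2)/n} of the uniform
#'     density — so the realized spectrum is exact at finite `n`;
#'   \item angles: the vertices of a regular `n`-gon plus one uniform random
#'     global rotation (restoring isotropy in distribution), with radii
#'     randomly permuted across the vertices so multi-ring spectra stay
#'     isotropic;
#'   \item amplitudes: independent circular complex Gaussians of variance
#'     `1/n`, making the field centered with \eqn{E|z|^2 = 1} by
#'     construction.
#' }
#'
#' @param P a [spectral_measure].
#' @param n_waves number of plane waves (>= 16; >= number of atoms).
#' @param seed RNG seed (integer).
#' @return A `plane_waves` list: `kx`, `ky`, `amp`, `radii`, `rotation`,
#'   `n_waves`, `seed`, `spectrum`.
#' @export
plane_waves <- function(P, n_waves = 256L, seed = 1L) {
  stopifnot(inherits(P, "spectral_measure"))
  n_waves <- as.integer(n_waves)
  if (n_waves < 16L) stop("'n_waves' must be at least 16")
  if (P$kind == "atomic" && n_waves < length(P$radii))
    stop("'n_waves' is smaller than the number of spectral atoms")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (P$kind == "atomic") {
    # largest-remainder apportionment of waves to atoms
    exact <- n_waves * P$weights
    cnt <- floor(exact)
    rem <- n_waves - sum(cnt)
    if (rem > 0) {
      idx <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[idx] <- cnt[idx] + 1
    }
    radii <- rep(P$radii, times = cnt)
  } else {
    q <- (seq_len(n_waves) - 0.5) / n_waves
    radii <- P$r_lo + q * (P$r_hi - P$r_lo)
  }
  rot <- stats::runif(1, 0, 2 * pi)
  radii <- radii[sample.int(n_waves)]
  ang <- 2 * pi * (seq_len(n_waves) - 1L) / n_waves + rot
  amp <- (stats::rnorm(n_waves) + 1i * stats::rnorm(n_waves)) / sqrt(2 * n_waves)
  out <- list(kx = radii * cos(ang), ky = radii * sin(ang),
              amp = amp, radii = radii, rotation = rot,
              n_waves = n_waves, seed = seed, spectrum = P)
  class(out) <- "plane_waves"
  out
}

# evaluate a plane-wave superposition at arbitrary points (vectors x, y),
# chunked to bound the points x waves phase matrix
eval_waves <- function(waves, x, y, chunk = 262144L) {
  n <- length(x)
  z <- complex(n)
  k <- cbind(waves$kx, waves$ky)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk %/% waves$n_waves * 4L)
    ph <- cbind(x[i:j], y[i:j]) %*% t(k)
    z[i:j] <- exp(1i * ph) %*% waves$amp
    i <- j + 1L
  }
  z
}

#' Segment geometry for crossing statistics
#'
#' @param length segment length, > 0 (or 0 for a single point).
#' @param theta0 iso-orientation angle in `[0, pi)` used when counting
#'   crossings on the segment (irrelevant to the theory by invariance).
#' @param anchor segment start point `c(x, y)`.
#' @param angle direction of the segment (radians from the x-axis).
#' @export
segment_query <- function(length, theta0 = 0, anchor = c(0, 0), angle = 0) {
  if (!is.finite(length) || length < 0) stop("'length' must be nonnegative")
  out <- list(length = length, theta0 = theta0 %% pi,
              anchor = anchor, angle = angle,
              direction = c(cos(angle), sin(angle)))
  class(out) <- "segment_query"
  out
}

#' Sample an invariant Gaussian random field on a grid
#'
#' Generates one realization of the complex field by plane-wave
#' superposition on a rectangular grid (x increasing rightward, y increasing
#' upward). The grid spacing must resolve the column spacing:
#' `spacing <= lambda_sq(P) / 12`.
#'
#' @param P a [spectral_measure].
#' @param n_waves number of plane waves.
#' @param width,height grid extent in map units.
#' @param spacing grid spacing in map units.
#' @param origin lower-left corner `c(x, y)`.
#' @param seed RNG seed.
#' @return A `field_sample` of kind `"grid"`: `z` is an `ny x nx` complex
#'   matrix, `z[iy, ix]` at `(origin[1] + (ix-1)*spacing,
#'   origin[2] + (iy-1)*spacing)`, plus full provenance.
#' @export
sample_field <- function(P, n_waves = 256L, width, height = width,
                         spacing = lambda_sq(P) / 12, origin = c(0, 0),
                         seed = 1L) {
  lsq <- lambda_sq(P)
  if (spacing > lsq / 12 + 1e-12)
    stop(sprintf("grid spacing %.4g exceeds lambda_sq/12 = %.4g (resolution guard)",
                 spacing, lsq / 12))
  waves <- plane_waves(P, n_waves, seed)
  xs <- origin[1] + spacing * (seq_len(max(2L, floor(width / spacing) + 1L)) - 1L)
  ys <- origin[2] + spacing * (seq_len(max(2L, floor(height / spacing) + 1L)) - 1L)
  g <- expand.grid(x = xs, y = ys)
  z <- matrix(eval_waves(waves, g$x, g$y), nrow = length(ys),
              ncol = length(xs), byrow = TRUE)
  out <- list(kind = "grid", z = z, x = xs, y = ys, spacing = spacing,
              origin = origin, waves = waves, spectrum = P,
              n_waves = n_waves, seed = seed)
  class(out) <- "field_sample"
  out
}

#' Sample an invariant Gaussian random field along a segment
#'
#' Same synthesis recipe (and, for the same seed, bit-identical wave set) as
#' [sample_field], evaluated on an evenly sampled segment.
#'
#' @param P a [spectral_measure].
#' @param n_waves number of plane waves.
#' @param segment a [segment_query].
#' @param samples_per_wavelength sampling density relative to
#'   `lambda_sq(P)` (>= 50).
#' @param seed RNG seed.
#' @return A `field_sample` of kind `"segment"`: `z` complex vector, `t`
#'   arc-length positions, `theta0` from the query, plus provenance.
#' @export
sample_on_segment <- function(P, n_waves = 256L, segment,
                              samples_per_wavelength = 60, seed = 1L) {
  stopifnot(inherits(segment, "segment_query"))
  if (samples_per_wavelength < 50)
    stop("'samples_per_wavelength' must be at least 50 (sampling guard)")
  lsq <- lambda_sq(P)
  waves <- plane_waves(P, n_waves, seed)
  L <- segment$length
  n <- max(1L, ceiling(L / lsq * samples_per_wavelength) + 1L)
  t <- if (L == 0) 0 else seq(0, L, length.out = n)
  x <- segment$anchor[1] + t * segment$direction[1]
  y <- segment$anchor[2] + t * segment$direction[2]
  z <- eval_waves(waves, x, y)
  out <- list(kind = "segment", z = z, t = t, segment = segment,
              theta0 = segment$theta0, waves = waves, spectrum = P,
              n_waves = n_waves, seed = seed)
  class(out) <- "field_sample"
  out
}

#' Wrap a user-supplied gridded map as a field sample
#'
#' For empirical statistics on maps not generated by this package. `z` is a
#' complex matrix laid out as in [sample_field] (rows = y, columns = x).
#'
#' @param z complex matrix.
#' @param spacing grid spacing in map units.
#' @param origin lower-left corner.
#' @export
field_sample <- function(z, spacing, origin = c(0, 0)) {
  z <- as.matrix(z)
  if (!is.complex(z)) z <- z + 0i
  out <- list(kind = "grid", z = z,
              x = origin[1] + spacing * (seq_len(ncol(z)) - 1L),
              y = origin[2] + spacing * (seq_len(nrow(z)) - 1L),
              spacing = spacing, origin = origin,
              waves = NULL, spectrum = NULL, n_waves = NA_integer_,
              seed = NA_integer_)
  class(out) <- "field_sample"
  out
}

#' @export
print.field_sample <- function(x, ...) {
  if (x$kind == "grid") {
    cat(sprintf("Field sample: %d x %d grid, spacing %.4g\n",
                ncol(x$z), nrow(x$z), x$spacing))
  } else {
    cat(sprintf("Field sample: segment of length %.4g (%d samples)\n",
                max(x$t), length(x$t)))
  }
  if (!is.null(x$waves))
    cat(sprintf("  synthesized from %d plane waves, seed %d\n",
                x$n_waves, x$seed))
  invisible(x)
}

#' Write / read a gridded field sample (flat binary + JSON sidecar)
#'
#' The values go to `<path>` as little-endian doubles (real then imaginary,
#' column-major) and the metadata (shape, spacing, origin, spectrum, seed)
#' to `<path>.json`.
#'
#' @param sample a grid `field_sample`.
#' @param path output path.
#' @export
write_field <- function(sample, path) {
  stopifnot(inherits(sample, "field_sample"), sample$kind == "grid")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.numeric(Re(sample$z)), as.numeric(Im(sample$z))), con,
           size = 8, endian = "little")
  meta <- list(nrow = nrow(sample$z), ncol = ncol(sample$z),
               spacing = sample$spacing, origin = sample$origin,
               seed = sample$seed, n_waves = sample$n_waves,
               spectrum = if (!is.null(sample$spectrum))
                 jsonlite::fromJSON(spectrum_to_json(sample$spectrum)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- meta$nrow * meta$ncol
  v <- readBin(path, "numeric", 2 * n, size = 8, endian = "little")
  z <- matrix(complex(real = v[seq_len(n)], imaginary = v[n + seq_len(n)]),
              meta$nrow, meta$ncol)
  field_sample(z, meta$spacing, as.numeric(meta$origin))
}

#' Export an orientation map as a PNG image
#'
#' Hue encodes the preferred orientation (half the argument of z), and
#' brightness encodes the modulus |z| (dark at pinwheel centers).
#'
#' @param sample a grid `field_sample`.
#' @param path output PNG path.
#' @export
save_orientation_png <- function(sample, path) {
  stopifnot(inherits(sample, "field_sample"), sample$kind == "grid")
  z <- sample$z[rev(seq_len(nrow(sample$z))), , drop = FALSE]  # y up -> row 1 top
  hue <- (Arg(z) / (2 * pi)) %% 1            # half-argument mod pi, scaled
  val <- Mod(z) / max(Mod(z), 1e-12)
  col <- grDevices::hsv(h = hue, s = 1, v = pmin(val, 1))
  arr <- grDevices::col2rgb(col) / 255
  img <- array(0, dim = c(nrow(z), ncol(z), 3))
  img[, , 1] <- matrix(arr[1, ], nrow(z)); img[, , 2] <- matrix(arr[2, ], nrow(z))
  img[, , 3] <- matrix(arr[3, ], nrow(z))
  png::writePNG(img, path)
  invisible(path)
}
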