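#' Count iso-orientation crossings along a sampled segment
#'
#' Counts the zeros of the projection \eqn{Re(e^{-2 i \theta_0} z)} along a
#' segment sample by sign changes with linear-interpolation root
#' localization. The endpoint convention is half-open: a root at the start
#' of the segment counts, a root at the end does not; a sampled value that
#' is exactly zero is attributed to the following interval.
#'
#' `convention = "projection"` counts every zero of the projection; these
#' include two orientations a quarter-turn apart (the projection vanishes
#' when half the argument of z is \eqn{\theta_0 \pm \pi/4}).
#' `convention = "strict"` keeps only the roots whose conjugate component
#' \eqn{Im(e^{-2 i \theta_0} z)} is positive (one of the two branches;
#' exactly half of the roots on average). Neither is asserted to be the
#' uniquely correct reading; the two differ by an exact factor of 2 in
#' expectation.
#'
#' @param sample a segment `field_sample` (see [sample_on_segment]), or any
#'   list with complex `$z` and positions `$t`.
#' @param theta0 orientation angle; defaults to the segment query's.
#' @param convention `"projection"` (default) or `"strict"`.
#' @return Integer count, with attribute `"positions"` (interpolated root
#'   locations along the segment).
#' @export
count_crossings <- function(sample, theta0 = NULL,
                            convention = c("projection", "strict")) {
  convention <- match.arg(convention)
  if (is.null(theta0)) theta0 <- if (!is.null(sample$theta0)) sample$theta0 else 0
  z <- as.vector(sample$z)
  t <- sample$t
  n <- length(z)
  if (n < 2L) stop("segment sample too short to count crossings")
  w <- exp(-2i * theta0) * z
  s <- Re(w)
  if (all(s == 0)) stop("degenerate input: projection is identically zero")
  b <- s < 0
  hit <- which(b[-n] != b[-1L])
  # exact-zero tie-breaks under the half-open convention
  if (s[1L] == 0 && n >= 2L && s[2L] > 0) hit <- sort(c(hit, 1L))
  if (s[n] == 0 && s[n - 1L] < 0) hit <- hit[hit != n - 1L]
  frac <- s[hit] / (s[hit] - s[hit + 1L])
  frac[!is.finite(frac)] <- 0
  pos <- t[hit] + frac * (t[hit + 1L] - t[hit])
  if (convention == "strict") {
    u <- Im(w)
    uval <- u[hit] + frac * (u[hit + 1L] - u[hit])
    keep <- uval > 0
    hit <- hit[keep]; pos <- pos[keep]
  }
  out <- length(hit)
  attr(out, "positions") <- pos
  out
}

wrap_pi <- function(x) x - 2 * pi * ceiling(x / (2 * pi) - 0.5)  # (-pi, pi]

#' Detect pinwheels (phase singularities) by plaquette winding numbers
#'
#' For every grid plaquette, the four phase increments of `Arg(z)` around
#' the plaquette, each wrapped to \eqn{(-\pi, \pi]}, are summed; a total of
#' \eqn{\pm 2\pi} records a singularity of charge \eqn{\pm 1} at the
#' plaquette center. Only plaquette centers inside the (half-open) counting
#' window are kept.
#'
#' A phase increment within `1e-9` of \eqn{\pm\pi} is ambiguous; for
#' synthesized samples the plaquette is re-evaluated on a locally refined
#' (midpoint) stencil, otherwise an error is raised.
#'
#' @param sample a grid `field_sample`.
#' @param window counting window `c(x0, x1, y0, y1)`, half-open
#'   `[x0,x1) x [y0,y1)`; default: whole grid.
#' @return A `pinwheel_detection` list: `detections` (data.frame `x`, `y`,
#'   `charge`), `window`, `spacing`.
#' @export
detect_pinwheels <- function(sample, window = NULL) {
  stopifnot(inherits(sample, "field_sample"), sample$kind == "grid")
  z <- sample$z
  ph <- Arg(z)
  ny <- nrow(z); nx <- ncol(z)
  # oriented increments around plaquette (iy, ix)-(iy, ix+1)-(iy+1, ix+1)-(iy+1, ix)
  a1 <- wrap_pi(ph[-ny, -1L] - ph[-ny, -nx])   # bottom edge, rightward
  a2 <- wrap_pi(ph[-1L, -1L] - ph[-ny, -1L])   # right edge, upward
  a3 <- wrap_pi(ph[-1L, -nx] - ph[-1L, -1L])   # top edge, leftward
  a4 <- wrap_pi(ph[-ny, -nx] - ph[-1L, -nx])   # left edge, downward
  tot <- a1 + a2 + a3 + a4
  amb <- (abs(abs(a1) - pi) < 1e-9) | (abs(abs(a2) - pi) < 1e-9) |
         (abs(abs(a3) - pi) < 1e-9) | (abs(abs(a4) - pi) < 1e-9)
  charge <- round(tot / (2 * pi))
  if (any(amb)) {
    idx <- which(amb, arr.ind = TRUE)
    if (is.null(sample$waves))
      stop("ambiguous phase increment (exactly pi) and no synthesis recipe to refine with")
    for (k in seq_len(nrow(idx))) {
      iy <- idx[k, 1L]; ix <- idx[k, 2L]
      charge[iy, ix] <- refine_plaquette(sample, ix, iy)
    }
  }
  h <- sample$spacing
  hits <- which(charge != 0, arr.ind = TRUE)
  cx <- sample$x[hits[, 2L]] + h / 2
  cy <- sample$y[hits[, 1L]] + h / 2
  q <- charge[hits]
  if (is.null(window))
    window <- c(sample$x[1L], sample$x[nx], sample$y[1L], sample$y[ny])
  keep <- cx >= window[1L] & cx < window[2L] & cy >= window[3L] & cy < window[4L]
  out <- list(detections = data.frame(x = cx[keep], y = cy[keep],
                                      charge = as.integer(q[keep])),
              window = window, spacing = h)
  class(out) <- "pinwheel_detection"
  out
}

# winding of one plaquette on a 2x-refined (8-point) contour, using the
# synthesis recipe
refine_plaquette <- function(sample, ix, iy) {
  h <- sample$spacing
  x0 <- sample$x[ix]; y0 <- sample$y[iy]
  px <- x0 + c(0, 0.5, 1, 1, 1, 0.5, 0, 0) * h
  py <- y0 + c(0, 0, 0, 0.5, 1, 1, 1, 0.5) * h
  zz <- eval_waves(sample$waves, px, py)
  ph <- Arg(zz)
  inc <- wrap_pi(diff(c(ph, ph[1L])))
  if (any(abs(abs(inc) - pi) < 1e-9))
    stop("ambiguous phase increment persists after plaquette refinement")
  round(sum(inc) / (2 * pi))
}

#' @export
print.pinwheel_detection <- function(x, ...) {
  cat(sprintf("Pinwheel detection: %d singularities (charge +1: %d, -1: %d)\n",
              nrow(x$detections), sum(x$detections$charge > 0),
              sum(x$detections$charge < 0)))
  cat(sprintf("  window [%g, %g) x [%g, %g)\n",
              x$window[1], x$window[2], x$window[3], x$window[4]))
  invisible(x)
}

#' Empirical pinwheel density scaled by a wavelength
#'
#' Count per unit area times `scale_wavelength^2`: the number of pinwheels
#' per area `scale_wavelength^2`. For fields sampled from invariant
#' Gaussian random fields the theoretical value at
#' `scale_wavelength = lambda_sq` is exactly \eqn{\pi}.
#'
#' @param detection a `pinwheel_detection`.
#' @param scale_wavelength the wavelength defining the unit of area.
#' @export
empirical_pinwheel_density <- function(detection, scale_wavelength) {
  stopifnot(inherits(detection, "pinwheel_detection"))
  w <- detection$window
  area <- (w[2] - w[1]) * (w[4] - w[3])
  if (area < (4 * scale_wavelength)^2)
    stop("counting window smaller than (4 * scale_wavelength)^2 (edge-effect guard)")
  nrow(detection$detections) / area * scale_wavelength^2
}

new_ensemble_summary <- function(values, config) {
  n <- length(values)
  m <- mean(values)
  v <- stats::var(values)
  m4 <- mean((values - m)^4)
  out <- list(values = values, n = n, mean = m, variance = v,
              se_mean = stats::sd(values) / sqrt(n),
              # large-sample SE of the sample variance via the 4th moment
              se_variance = sqrt(max(m4 - v^2, 0) / n),
              normalized_variance = v / m^2,
              config = config)
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble of %d realizations\n", x$n))
  cat(sprintf("  mean = %.5g (se %.3g), variance = %.5g (se %.3g)\n",
              x$mean, x$se_mean, x$variance, x$se_variance))
  cat(sprintf("  normalized variance = %.5g\n", x$normalized_variance))
  invisible(x)
}

#' Monte Carlo crossing-count moments
#'
#' Counts iso-orientation crossings on segments of length `ell` drawn on
#' independent field realizations, and summarizes the ensemble (mean,
#' variance, standard errors). This is the oracle against which the
#' closed-form expectation ([expected_crossings]) and the exact variance
#' quadrature ([variance_crossings]) are arbitrated.
#'
#' @param P a [spectral_measure].
#' @param ell segment length.
#' @param theta0 orientation angle.
#' @param n_realizations number of independent fields (>= 100).
#' @param seed base seed; realization `i` uses `seed + i - 1`.
#' @param n_waves waves per realization.
#' @param samples_per_wavelength segment sampling density.
#' @param convention crossing convention, see [count_crossings].
#' @return An `ensemble_summary`.
#' @export
mc_crossing_moments <- function(P, ell, theta0 = 0, n_realizations = 1000L,
                                seed = 1L, n_waves = 256L,
                                samples_per_wavelength = 60,
                                convention = "projection") {
  if (n_realizations < 100L) stop("'n_realizations' must be at least 100")
  lsq <- lambda_sq(P)
  seg <- segment_query(ell, theta0 = theta0)
  # synthesis ingredients drawn directly per realization (same recipe as
  # sample_on_segment, inlined to keep large ensembles affordable)
  n <- max(2L, ceiling(ell / lsq * samples_per_wavelength) + 1L)
  t <- seq(0, ell, length.out = n)
  counts <- integer(n_realizations)
  for (i in seq_len(n_realizations)) {
    waves <- plane_waves(P, n_waves, seed = seed + i - 1L)
    p <- waves$kx   # segment along the x-axis; isotropy makes this generic
    z <- exp(1i * outer(t, p)) %*% waves$amp
    counts[i] <- count_crossings(list(z = z, t = t, theta0 = theta0),
                                 convention = convention)
  }
  new_ensemble_summary(counts, list(
    spectrum = spectrum_to_json(P), ell = ell, ell_over_lambda_sq = ell / lsq,
    theta0 = theta0, n_waves = n_waves, seed = seed,
    convention = convention, samples_per_wavelength = samples_per_wavelength))
}

#' Monte Carlo pinwheel density ensemble
#'
#' Simulates independent fields on a square grid, detects pinwheels by
#' winding number inside an interior window (a margin of `margin` map units
#' is discarded on all sides to suppress boundary bias), and summarizes the
#' per-field counts and the density scaled by `lambda_sq(P)`.
#'
#' @param P a [spectral_measure].
#' @param n_fields number of independent fields.
#' @param window_size side of the interior counting window, in units of
#'   `lambda_sq(P)` (>= 10 recommended).
#' @param margin boundary margin in units of `lambda_sq(P)`.
#' @param n_waves waves per field.
#' @param spacing grid spacing (defaults to the resolution guard limit).
#' @param seed base seed; field `i` uses `seed + i - 1`.
#' @return An `ensemble_summary` of per-field counts, with extra fields
#'   `density_mean` (mean count per `lambda_sq^2` of window area),
#'   `density_se`, and `window_area` (in map units).
#' @export
mc_pinwheel_density <- function(P, n_fields = 50L, window_size = 10,
                                margin = 1, n_waves = 256L,
                                spacing = lambda_sq(P) / 12, seed = 1L) {
  lsq <- lambda_sq(P)
  side <- (window_size + 2 * margin) * lsq
  counts <- integer(n_fields)
  win <- c(margin * lsq, (margin + window_size) * lsq,
           margin * lsq, (margin + window_size) * lsq)
  for (i in seq_len(n_fields)) {
    fs <- sample_field(P, n_waves = n_waves, width = side, height = side,
                       spacing = spacing, seed = seed + i - 1L)
    det <- detect_pinwheels(fs, window = win)
    counts[i] <- nrow(det$detections)
  }
  out <- new_ensemble_summary(counts, list(
    spectrum = spectrum_to_json(P), window_size = window_size,
    margin = margin, n_waves = n_waves, spacing = spacing, seed = seed))
  area_units <- (window_size * lsq / lsq)^2   # window area in lambda_sq^2
  out$density_mean <- out$mean / area_units
  out$density_se <- out$se_mean / area_units
  out$window_area <- (window_size * lsq)^2
  out
}
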