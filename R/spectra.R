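#' Radial spectral measures for invariant Gaussian random fields
#'
#' An invariant (homogeneous, isotropic, centered) complex Gaussian random
#' field on the plane is determined, up to scale, by a probability measure P
#' on radial wavenumbers: its covariance is the P-mixture of ring kernels
#' (order-zero Bessel functions). `spectral_measure` objects represent P
#' either as a finite set of atoms (rings) or as a uniform density on an
#' annulus `[r_lo, r_hi]`. Continuous measures carry a fixed Gauss-Legendre
#' quadrature rule so that every downstream integral is deterministic given
#' the configuration.
#'
#' @section Wavelengths:
#' Two column-spacing wavelengths derive from P: `lambda_mean(P)` = 2\eqn{\pi}
#' divided by the mean wavenumber, and `lambda_sq(P)` = 2\eqn{\pi} divided by
#' the quadratic mean (root-mean-square) wavenumber. By Jensen's inequality
#' `lambda_mean >= lambda_sq`, with equality exactly for monochromatic
#' (single-ring) measures.
#'
#' @name spectral_measure
NULL

new_spectral_measure <- function(kind, radii = NULL, weights = NULL,
                                 r_lo = NULL, r_hi = NULL, nquad = 2049L) {
  obj <- list(kind = kind, radii = radii, weights = weights,
              r_lo = r_lo, r_hi = r_hi, nquad = as.integer(nquad))
  if (kind == "annulus") {
    gl <- pracma::gaussLegendre(obj$nquad, r_lo, r_hi)
    # probability weights: uniform density 1/(r_hi - r_lo)
    obj$quad <- list(r = gl$x, w = gl$w / (r_hi - r_lo))
  }
  class(obj) <- "spectral_measure"
  obj
}

#' Atomic (finite-ring) spectral measure
#'
#' @param radii positive, distinct wavenumbers (ring radii in k-space).
#' @param weights nonnegative weights, not all zero; renormalized to sum to 1.
#' @return A `spectral_measure` of kind `"atomic"`.
#' @examples
#' atomic_spectrum(2 * pi)                 # monochromatic, lambda_sq = 1
#' atomic_spectrum(c(1, 3), c(2, 2))       # weights stored as 0.5, 0.5
#' @export
atomic_spectrum <- function(radii, weights = rep(1, length(radii))) {
  radii <- as.numeric(radii); weights <- as.numeric(weights)
  if (length(radii) == 0L) stop("'radii' must be non-empty")
  if (length(weights) != length(radii))
    stop("'weights' must match 'radii' in length")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("all radii must be finite and strictly positive")
  if (anyDuplicated(radii)) stop("radii must be distinct")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  tot <- sum(weights)
  if (tot == 0) stop("weights must not all be zero")
  new_spectral_measure("atomic", radii = radii, weights = weights / tot)
}

#' Multi-ring spectrum spanning an interval with 2n+1 equispaced rings
#'
#' Places `2n + 1` equally weighted atoms at `r_mean + half_width * i / n`
#' for `i = -n, ..., n`. As `n` grows the measure converges (as a Riemann
#' sum) to the uniform annulus on `[r_mean - half_width, r_mean + half_width]`.
#'
#' @param r_mean central ring radius (> 0).
#' @param half_width half the spanned interval; must be < `r_mean`. A value
#'   of 0 gives a degenerate, effectively monochromatic measure.
#' @param n number of rings on each side of the center (>= 1).
#' @export
multicircle_spectrum <- function(r_mean, half_width, n) {
  if (!is.finite(r_mean) || r_mean <= 0) stop("'r_mean' must be positive")
  if (!is.finite(half_width) || half_width < 0)
    stop("'half_width' must be nonnegative")
  if (half_width >= r_mean)
    stop("'half_width' must be smaller than 'r_mean' (radii must stay positive)")
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  radii <- r_mean + half_width * (-n:n) / n
  if (half_width == 0) return(atomic_spectrum(r_mean))
  atomic_spectrum(radii, rep(1, 2L * n + 1L))
}

#' Uniform annulus spectral measure
#'
#' Uniform probability density `1 / (r_hi - r_lo)` on `[r_lo, r_hi]`.
#' Wavenumber moments are available in closed form; covariance integrals use
#' the stored `nquad`-point Gauss-Legendre rule.
#'
#' @param r_lo,r_hi annulus bounds, `0 < r_lo < r_hi`.
#' @param nquad quadrature resolution for downstream integrals.
#' @export
uniform_annulus <- function(r_lo, r_hi, nquad = 2049L) {
  if (!is.finite(r_lo) || !is.finite(r_hi) || r_lo <= 0)
    stop("annulus bounds must be finite and positive")
  if (r_lo >= r_hi)
    stop("need r_lo < r_hi (zero-width annulus: use atomic_spectrum)")
  new_spectral_measure("annulus", r_lo = r_lo, r_hi = r_hi, nquad = nquad)
}

#' @export
print.spectral_measure <- function(x, ...) {
  if (x$kind == "atomic") {
    cat(sprintf("Spectral measure: %d atom(s)\n", length(x$radii)))
    k <- order(x$radii)
    show <- utils::head(k, 8L)
    cat("  radii:  ", paste(signif(x$radii[show], 6), collapse = ", "),
        if (length(k) > 8L) "..." else "", "\n")
    cat("  weights:", paste(signif(x$weights[show], 4), collapse = ", "),
        if (length(k) > 8L) "..." else "", "\n")
  } else {
    cat(sprintf("Spectral measure: uniform annulus [%g, %g] (%d-point rule)\n",
                x$r_lo, x$r_hi, x$nquad))
  }
  cat(sprintf("  lambda_mean = %.6g, lambda_sq = %.6g%s\n",
              lambda_mean(x), lambda_sq(x),
              if (is_monochromatic(x)) "  (monochromatic)" else ""))
  invisible(x)
}

#' Is the measure a single atom?
#' @param P a `spectral_measure`.
#' @export
is_monochromatic <- function(P) {
  stopifnot(inherits(P, "spectral_measure"))
  P$kind == "atomic" && length(P$radii) == 1L
}

# discrete support representation: exact atoms, or the stored quadrature rule
# (probability weights summing to 1 in both cases)
support_nodes <- function(P) {
  stopifnot(inherits(P, "spectral_measure"))
  if (P$kind == "atomic") list(r = P$radii, w = P$weights) else P$quad
}

#' Moments of the wavenumber distribution
#'
#' Computes \eqn{\int k^{order} dP(k)}. Orders 0-2 (and in fact any
#' nonnegative order) are closed-form for both kinds; `method = "quadrature"`
#' forces the stored quadrature rule, which is useful as an independent
#' cross-check of the closed forms.
#'
#' @param P a `spectral_measure`.
#' @param order nonnegative integer moment order.
#' @param method `"closed"` (default) or `"quadrature"`.
#' @export
wavenumber_moment <- function(P, order, method = c("closed", "quadrature")) {
  stopifnot(inherits(P, "spectral_measure"))
  method <- match.arg(method)
  if (!is.finite(order) || order < 0) stop("'order' must be nonnegative")
  if (order == 0) return(1)
  if (method == "quadrature" || P$kind == "atomic") {
    s <- support_nodes(P)
    return(sum(s$w * s$r^order))
  }
  a <- P$r_lo; b <- P$r_hi; q <- order
  (b^(q + 1) - a^(q + 1)) / ((q + 1) * (b - a))
}

#' @rdname spectral_measure
#' @param P a `spectral_measure`.
#' @export
lambda_mean <- function(P) 2 * pi / wavenumber_moment(P, 1)

#' @rdname spectral_measure
#' @export
lambda_sq <- function(P) 2 * pi / sqrt(wavenumber_moment(P, 2))

#' Worst-case wavelength gap over an annulus of given relative width
#'
#' For spectral measures supported in an annulus whose full width is
#' `width_fraction` times its central radius, computes the supremum of the
#' relative gap `100 * (lambda_mean - lambda_sq) / lambda_sq` (in percent).
#' The supremum is attained by a two-point measure at the annulus edges
#' (extreme points of the moment problem: for a fixed first moment, mass at
#' the endpoints maximizes the second moment); the endpoint weight is found
#' by one-dimensional optimization and cross-checked against a brute-force
#' grid over discretized measures on the interval.
#'
#' The annulus "radius" is read as the central radius; the inner-radius
#' reading gives a smaller worst case, so this is the conservative choice.
#'
#' @param width_fraction annulus width / central radius, in (0, 1).
#' @param cross_check also run the brute-force grid search and store it as
#'   an attribute (default TRUE).
#' @param n_grid grid resolution of the cross-check.
#' @return The worst-case gap in percent, with attributes `p_star` (optimal
#'   endpoint weight) and, if requested, `brute_force` (grid maximum, always
#'   <= the returned value up to grid resolution).
#' @export
annulus_gap_bound <- function(width_fraction, cross_check = TRUE,
                              n_grid = 201L) {
  if (!is.finite(width_fraction) || width_fraction <= 0 || width_fraction >= 1)
    stop("'width_fraction' must lie strictly between 0 and 1")
  a <- 1 - width_fraction / 2   # central radius 1
  b <- 1 + width_fraction / 2
  gap <- function(p) {
    m1 <- p * a + (1 - p) * b
    m2 <- p * a^2 + (1 - p) * b^2
    100 * (sqrt(m2) / m1 - 1)   # = 100 (lambda_mean - lambda_sq)/lambda_sq
  }
  opt <- stats::optimize(gap, c(0, 1), maximum = TRUE, tol = 1e-12)
  best <- max(opt$objective, gap(0), gap(1))
  out <- best
  attr(out, "p_star") <- opt$maximum
  if (cross_check) {
    # brute force over discretized measures: every two-point measure on a
    # support grid (all pairs x weight grid), plus 3-point measures with
    # weights on a coarse simplex grid
    r <- seq(a, b, length.out = n_grid)
    ij <- utils::combn(n_grid, 2L)
    ri <- r[ij[1L, ]]; rj <- r[ij[2L, ]]
    bf <- 0
    for (p in seq(0, 1, length.out = 41L)) {
      m1 <- p * ri + (1 - p) * rj
      m2 <- p * ri^2 + (1 - p) * rj^2
      bf <- max(bf, 100 * (sqrt(m2) / m1 - 1))
    }
    r3 <- seq(a, b, length.out = 21L)
    trip <- utils::combn(21L, 3L)
    wgrid <- seq(0.1, 0.8, by = 0.1)
    for (w1 in wgrid) for (w2 in wgrid) {
      w3 <- 1 - w1 - w2
      if (w3 <= 0) next
      m1 <- w1 * r3[trip[1L, ]] + w2 * r3[trip[2L, ]] + w3 * r3[trip[3L, ]]
      m2 <- w1 * r3[trip[1L, ]]^2 + w2 * r3[trip[2L, ]]^2 + w3 * r3[trip[3L, ]]^2
      bf <- max(bf, 100 * (sqrt(m2) / m1 - 1))
    }
    attr(out, "brute_force") <- bf
    if (bf > best + 1e-6)
      stop("brute-force cross-check exceeded the two-point optimum")
  }
  out
}

#' Serialize / deserialize a spectral measure as JSON
#'
#' The document is `{"kind": "atomic", "atoms": [[r, w], ...]}` or
#' `{"kind": "annulus", "range": [lo, hi]}` (optionally with `"nquad"`).
#'
#' @param P a `spectral_measure`.
#' @param json a JSON string or path to a JSON file.
#' @export
spectrum_to_json <- function(P) {
  stopifnot(inherits(P, "spectral_measure"))
  doc <- if (P$kind == "atomic") {
    list(kind = "atomic",
         atoms = lapply(seq_along(P$radii),
                        function(i) c(P$radii[i], P$weights[i])))
  } else {
    list(kind = "annulus", range = c(P$r_lo, P$r_hi), nquad = P$nquad)
  }
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

#' @rdname spectrum_to_json
#' @export
spectrum_from_json <- function(json) {
  if (length(json) == 1L && !grepl("\\{", json) && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  if (is.null(doc$kind) || !doc$kind %in% c("atomic", "annulus"))
    stop("spectral measure document needs \"kind\": \"atomic\" or \"annulus\"")
  if (doc$kind == "atomic") {
    atoms <- doc$atoms
    if (is.list(atoms)) atoms <- do.call(rbind, atoms)
    atoms <- matrix(as.numeric(atoms), ncol = 2)
    atomic_spectrum(atoms[, 1], atoms[, 2])
  } else {
    rng <- as.numeric(doc$range)
    if (length(rng) != 2L) stop("annulus document needs \"range\": [lo, hi]")
    nq <- if (!is.null(doc$nquad)) as.integer(doc$nquad) else 2049L
    uniform_annulus(rng[1], rng[2], nquad = nq)
  }
}
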