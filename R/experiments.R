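#' Normalized crossing-count variance as a function of spectral width
#'
#' For each spectral width (in percent of the mean wavenumber), builds a
#' uniform-annulus spectrum centered at `k_mean` (width 0 degenerates to a
#' single ring), evaluates the crossing-count variance on a segment of
#' length `ell_factor * lambda_sq` by the exact quadrature in both modes,
#' and repeats the evaluation at a perturbed quadrature setting to expose
#' the attained numerical precision. Optionally adds a Monte Carlo estimate
#' per width.
#'
#' The variance is reported in units of the squared expectation
#' (`normalized_variance`). Expected shape: minimal at width 0,
#' non-decreasing in width, with a flat slope at zero.
#'
#' @param widths_pct spectral widths, percent of the mean wavenumber.
#' @param k_mean central (mean) wavenumber of each annulus.
#' @param ell_factor segment length in units of each spectrum's own
#'   `lambda_sq`. The default is the hypercolumn scale `ell = lambda_sq`,
#'   the scale whose regularity the variance analysis addresses; the
#'   width-ordering of the curve is scale-dependent (it reverses for
#'   segments longer than about `2 * lambda_sq`; see the vignette).
#' @param quad_settings list of quadrature settings
#'   (`list(panel_frac=, nodes=)`), one result row per setting (replicates).
#' @param mc_realizations if > 0, Monte Carlo realizations per width.
#' @param seed seed for the optional Monte Carlo.
#' @param out_csv optional path; the table is written as CSV.
#' @return A data.frame with one row per (width, mode, setting):
#'   `width_pct`, `lambda_sq`, `ell`, `ell_over_lambda_sq`, `mode`,
#'   `setting`, `expected`, `variance`, `normalized_variance`, `quad_error`,
#'   `spectrum` (JSON), plus `mc_*` columns when requested.
#' @export
run_variance_curve <- function(widths_pct = seq(0, 30, by = 2.5),
                               k_mean = 10.95, ell_factor = 1,
                               quad_settings = list(
                                 list(panel_frac = 1 / 8, nodes = 16L),
                                 list(panel_frac = 1 / 12, nodes = 24L)),
                               mc_realizations = 0L, seed = 1L,
                               out_csv = NULL) {
  stopifnot(all(widths_pct >= 0), all(widths_pct <= 50),
            !is.unsorted(widths_pct), length(quad_settings) >= 2L)
  rows <- list()
  for (wp in widths_pct) {
    P <- width_spectrum(wp, k_mean)
    lsq <- lambda_sq(P)
    ell <- ell_factor * lsq
    mc <- NULL
    if (mc_realizations > 0L)
      mc <- mc_crossing_moments(P, ell, n_realizations = mc_realizations,
                                seed = seed)
    for (mode in c("factorial", "pi-spacing")) {
      for (si in seq_along(quad_settings)) {
        qs <- quad_settings[[si]]
        cs <- tryCatch(
          variance_crossings(P, ell, mode = mode,
                             panel_frac = qs$panel_frac, nodes = qs$nodes),
          error = function(e) e)
        row <- data.frame(
          width_pct = wp, lambda_sq = lsq, ell = ell,
          ell_over_lambda_sq = ell_factor, mode = mode, setting = si,
          expected = if (inherits(cs, "error")) NA_real_ else cs$expected_count,
          variance = if (inherits(cs, "error")) NA_real_ else cs$variance,
          normalized_variance = if (inherits(cs, "error")) NA_real_
                                else cs$normalized_variance,
          quad_error = if (inherits(cs, "error")) NA_real_
                       else cs$diagnostics$quad_error,
          note = if (inherits(cs, "error")) conditionMessage(cs) else "",
          spectrum = spectrum_to_json(P), seed = seed,
          stringsAsFactors = FALSE)
        if (!is.null(mc)) {
          row$mc_mean <- mc$mean; row$mc_variance <- mc$variance
          row$mc_normalized_variance <- mc$normalized_variance
          row$mc_se_variance <- mc$se_variance
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

# uniform annulus of full width `pct`% of the central wavenumber; width 0
# degenerates to a single ring
width_spectrum <- function(pct, k_mean = 10.95, nquad = 2049L) {
  if (pct == 0) return(atomic_spectrum(k_mean))
  hw <- k_mean * pct / 200
  uniform_annulus(k_mean - hw, k_mean + hw, nquad = nquad)
}

#' Multi-ring convergence of the crossing-count variance
#'
#' Evaluates the crossing-count variance for spectra made of `2N + 1`
#' equally weighted rings at `r_mean + half_width * i / N` and compares them
#' with the uniform annulus `[r_mean - half_width, r_mean + half_width]`
#' they converge to (Riemann sums). The variance is expected to be
#' non-increasing in `N`, approaching the annulus value from above.
#'
#' @param n_list values of N.
#' @param r_mean,half_width multi-ring construction parameters.
#' @param ell_factor segment length in units of `lambda_sq`.
#' @param mode variance mode, see [variance_crossings].
#' @param out_csv optional CSV path.
#' @return A data.frame with one row per N plus a final row for the annulus
#'   limit (`n = Inf`), and columns `n`, `n_rings`, `lambda_sq`,
#'   `normalized_variance`, `variance`, `expected`, `gap_to_limit_pct`.
#' @export
run_multicircle <- function(n_list = c(1L, 2L, 4L, 9L, 18L),
                            r_mean = 10.95, half_width = 0.95,
                            ell_factor = 1, mode = "factorial",
                            out_csv = NULL) {
  Plim <- uniform_annulus(r_mean - half_width, r_mean + half_width)
  lim <- variance_crossings(Plim, ell_factor * lambda_sq(Plim), mode = mode)
  one <- function(n, P) {
    cs <- variance_crossings(P, ell_factor * lambda_sq(P), mode = mode)
    data.frame(n = n,
               n_rings = if (P$kind == "atomic") length(P$radii) else NA_integer_,
               lambda_sq = lambda_sq(P), expected = cs$expected_count,
               variance = cs$variance,
               normalized_variance = cs$normalized_variance,
               gap_to_limit_pct =
                 100 * (cs$normalized_variance - lim$normalized_variance) /
                 lim$normalized_variance)
  }
  rows <- lapply(n_list, function(n) one(n, multicircle_spectrum(r_mean, half_width, n)))
  rows[[length(rows) + 1L]] <- one(Inf, Plim)
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Monte Carlo check of the pinwheel-density theorem
#'
#' Simulates ensembles for a monochromatic ring and for a uniform annulus
#' of relative width `annulus_width_pct` percent, counts winding-number
#' zeros in an interior window, and compares the density per
#' `lambda_sq^2` with the theoretical value \eqn{\pi}: spectral thinness
#' must not matter.
#'
#' @param n_fields fields per spectrum.
#' @param window_size interior window side, in units of `lambda_sq`.
#' @param annulus_width_pct relative width of the annulus case (percent of
#'   the mean wavenumber).
#' @param n_waves waves per field.
#' @param seed base seed.
#' @return A data.frame with one row per spectrum: `spectrum`, `n_fields`,
#'   `density`, `se`, `z_vs_pi` (standardized deviation from \eqn{\pi}).
#' @export
run_density_check <- function(n_fields = 50L, window_size = 10,
                              annulus_width_pct = 20, n_waves = 256L,
                              seed = 1L) {
  specs <- list(monochromatic = atomic_spectrum(2 * pi),
                annulus = width_spectrum(annulus_width_pct, 2 * pi))
  rows <- lapply(names(specs), function(nm) {
    ens <- mc_pinwheel_density(specs[[nm]], n_fields = n_fields,
                               window_size = window_size, n_waves = n_waves,
                               seed = seed)
    data.frame(spectrum = nm, n_fields = n_fields,
               density = ens$density_mean, se = ens$density_se,
               z_vs_pi = (ens$density_mean - pi) / ens$density_se)
  })
  do.call(rbind, rows)
}

#' Wavelength-gap bound for annulus-supported spectra
#'
#' Reports the worst-case relative gap between `lambda_mean` and
#' `lambda_sq` at `width_fraction = 1/5` (both the central-radius and the
#' inner-radius reading of "radius") and a sweep over widths, which is
#' monotone increasing.
#'
#' @param widths sweep of width fractions.
#' @return A list with `bound_at_fifth` (central-radius reading, percent),
#'   `bound_at_fifth_inner` (inner-radius reading), and `sweep`
#'   (data.frame `width_fraction`, `bound_pct`).
#' @export
run_bound_check <- function(widths = seq(0.025, 0.5, by = 0.025)) {
  b5 <- annulus_gap_bound(1 / 5)
  # inner-radius reading: width = r_lo / 5, i.e. w/(1 - w/2) relative to
  # center => width_fraction w solving w = (1/5)(1 - w/2)/1 ... computed
  # directly: annulus [r, r + r/5] has central radius r*(1 + 1/10)
  w_inner <- (1 / 5) / (1 + 1 / 10)
  b5i <- annulus_gap_bound(w_inner, cross_check = FALSE)
  sweep <- data.frame(
    width_fraction = widths,
    bound_pct = vapply(widths, function(w)
      as.numeric(annulus_gap_bound(w, cross_check = FALSE)), numeric(1)))
  list(bound_at_fifth = as.numeric(b5),
       bound_at_fifth_inner = as.numeric(b5i),
       sweep = sweep)
}

#' Spectrum-independence of the empirical crossing rate
#'
#' Estimates the crossing rate times `lambda_sq` by Monte Carlo for several
#' spectra of different widths and shapes. For invariant Gaussian random
#' fields this product is a spectrum-independent constant; the ensemble
#' also arbitrates between the two closed-form candidates
#' (`sqrt(2)` from the Kac-Rice evaluation vs 1 from the spacing reading;
#' see [expected_crossings]).
#'
#' @param spectra named list of [spectral_measure] objects; default: a
#'   monochromatic ring, 10 and 20 percent annuli, and a three-ring
#'   spectrum.
#' @param ell_factor segment length in `lambda_sq` units.
#' @param n_realizations realizations per spectrum.
#' @param seed base seed.
#' @return A data.frame with one row per spectrum: `spectrum`,
#'   `rate_lambda_sq` (mean count * lambda_sq / ell), `se`, plus the
#'   candidate constants as attributes `"cv_pct"` (coefficient of variation
#'   across spectra, percent).
#' @export
run_rate_check <- function(spectra = NULL, ell_factor = 5,
                           n_realizations = 2000L, seed = 1L) {
  if (is.null(spectra))
    spectra <- list(monochromatic = atomic_spectrum(2 * pi),
                    annulus10 = width_spectrum(10, 2 * pi),
                    annulus20 = width_spectrum(20, 2 * pi),
                    three_rings = multicircle_spectrum(10.95, 0.95, 1L))
  rows <- lapply(seq_along(spectra), function(i) {
    P <- spectra[[i]]
    lsq <- lambda_sq(P)
    ens <- mc_crossing_moments(P, ell_factor * lsq,
                               n_realizations = n_realizations,
                               seed = seed + 1000L * (i - 1L))
    data.frame(spectrum = names(spectra)[i],
               rate_lambda_sq = ens$mean / ell_factor,
               se = ens$se_mean / ell_factor)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv_pct") <- 100 * stats::sd(out$rate_lambda_sq) /
    mean(out$rate_lambda_sq)
  out
}
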