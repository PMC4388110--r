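---
title: "Level-crossing statistics of invariant Gaussian orientation-map models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-crossing statistics of invariant Gaussian orientation-map models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmfield)
```

## The model

Orientation preference maps assign to each point of the cortical surface a
preferred stimulus orientation, an angle modulo $\pi$. The standard
stochastic model for the early developmental stage is a complex-valued
Gaussian random field $z(x)$, $x \in \mathbb{R}^2$, with the orientation
read off as $\theta(x) = \tfrac12 \arg z(x)$ and pinwheels — the points
where all orientations meet — as the zeros of $z$. Three invariances are
imposed: homogeneity (translations), isotropy (rotations) and centering
(global phase shifts $z \mapsto e^{i\alpha} z$). Under these, the field is
determined up to scale by a single probability measure $P$ on radial
wavenumbers: the covariance is the mixture of ring kernels

$$\Gamma(\tau) = \int_{R>0} J_0(R\,|\tau|)\, dP(R),$$

with $J_0$ the order-zero Bessel function of the first kind. Each ring
kernel satisfies the Helmholtz equation $\Delta \Gamma_R = -R^2 \Gamma_R$,
which is what makes every closed form below exactly computable.

Two wavelengths summarize $P$:

* $\Lambda_{\mathrm{mean}} = 2\pi / \int k\,dP(k)$, from the mean
  wavenumber, close to the spectral peak for bell-shaped spectra;
* $\Lambda_{\mathrm{sq}} = 2\pi / \sqrt{\int k^2\,dP(k)}$, from the
  quadratic mean wavenumber.

Jensen's inequality gives $\Lambda_{\mathrm{mean}} \ge
\Lambda_{\mathrm{sq}}$ with equality exactly for monochromatic (single
ring) spectra. For spectra supported in an annulus whose full width is a
fifth of its central radius, the worst-case relative gap is attained by a
two-point measure at the annulus edges and equals
$\frac{a+b}{2\sqrt{ab}} - 1 \approx 0.504\,\%$ (`annulus_gap_bound(0.2)`),
comfortably below 3 %. We read the annulus "radius" as the central radius;
the inner-radius reading gives a smaller worst case, so this is the
conservative reading, and `run_bound_check()` reports both.

## Crossing counts and their expectation

Fix an orientation $\theta_0$ and a segment of length $\ell$. The points
where $\theta_0$ is represented are zeros of the projection
$\mathrm{Re}(e^{-2i\theta_0} z)$ restricted to the segment — a stationary
Gaussian process whose covariance $G$ is the $P$-mixture of
one-dimensional Bessel kernels. Under the normalization $G(0) = 1$ the
second spectral moment is $\lambda_2 = -G''(0) = \tfrac12 \int R^2 dP =
2\pi^2/\Lambda_{\mathrm{sq}}^2$, and the Kac–Rice formula gives

$$\mathbb{E}[N] = \frac{\ell}{\pi} \sqrt{\lambda_2/\lambda_0}
               = \sqrt{2}\,\frac{\ell}{\Lambda_{\mathrm{sq}}}.$$

A competing reading places one crossing per column spacing,
$\mathbb{E}[N] = \ell/\Lambda_{\mathrm{sq}}$. Because the two candidates
circulate in the literature with inconsistent normalizations, the package
exposes both (`expected_crossings(..., mode = "kac-rice" | "spacing")`)
and arbitrates by simulation: `run_rate_check()` estimates the empirical
rate on ensembles of independent fields for several spectra. The measured
rate times $\Lambda_{\mathrm{sq}}$ is spectrum-independent and equals
$\sqrt 2$ to Monte Carlo precision, so `"kac-rice"` is the default
everywhere. (Note the projection vanishes at the two orientations a quarter-turn
away from $\theta_0$ on either side; `count_crossings()` offers a
`"strict"` convention that keeps the single-orientation subset, exactly
half of the roots on average. All closed forms in the package refer to the
projection-zero count.)

## The pinwheel-density theorem

The expected number of zeros of $z$ in a region of area $|A|$ is
$\pi |A| / \Lambda_{\mathrm{sq}}^2$ for *every* invariant spectrum: the
pinwheel density per squared column spacing is exactly $\pi$, a signature
of Euclidean symmetry alone, not of spectral thinness.
`expected_pinwheels()` implements the closed form and
`run_density_check()` verifies it by simulation for a monochromatic ring
and a 20 %-wide annulus side by side; the identity
$\eta \Lambda_{\mathrm{sq}}^2 = \pi$ is also asserted algebraically for
randomized spectra in the test suite.

## The exact variance of crossing counts

The variance of the number of zeros of a unit-variance stationary Gaussian
process on $[0, \ell]$ is classical (Cramér–Leadbetter). With the $4\times4$
covariance matrix of $(\Phi(0), \Phi(\tau), \Phi'(0), \Phi'(\tau))$ and the
cofactors of its $(3,3)$ and $(3,4)$ entries,

$$M_{33} = \lambda_2 (1 - G^2) - G'^2, \qquad
  M_{34} = G''(\tau)(1 - G^2) + G\,G'^2,$$

the second factorial moment is the pair-intensity integral

$$\mathbb{E}[N(N-1)] = \frac{2}{\pi^2} \int_0^\ell (\ell - \tau)\,
  \frac{\sqrt{M_{33}^2 - M_{34}^2}}{(1 - G^2)^{3/2}}
  \left[1 + \frac{M_{34}}{\sqrt{M_{33}^2 - M_{34}^2}}
  \arctan\!\frac{M_{34}}{\sqrt{M_{33}^2 - M_{34}^2}}\right] d\tau,$$

and $\mathbb{V}[N] = \mathbb{E}[N] - \mathbb{E}[N]^2 +
\mathbb{E}[N(N-1)]$. `variance_crossings()` evaluates this with analytic
Bessel-identity derivatives (no finite differences anywhere in the
integrand). The statement of this theorem sometimes circulates with the
leading terms written as $\pi\ell/\Lambda_{\mathrm{sq}} -
(\pi\ell/\Lambda_{\mathrm{sq}})^2$; mode `"pi-spacing"` implements that
convention verbatim for comparison. It produces strongly negative
variances at moderate $\ell$ (e.g. $-185$ at $\ell = 5\Lambda_{\mathrm{sq}}$,
monochromatic) and is therefore flagged, never silently clipped. The
factorial-moment mode matches a 20 000-realization Monte Carlo ensemble
within its standard error (theory 2.9237 vs MC $2.943 \pm 0.028$ at
$\ell = 5\Lambda_{\mathrm{sq}}$), and is the default.

### Numerical choices

* The pair intensity is an indeterminate $0/0$ at $\tau = 0$ (zeros of a
  smooth process repel; the intensity vanishes linearly). Quadrature
  starts at $\tau_{\min} = 10^{-4} \Lambda_{\mathrm{sq}}$ and the
  $[0, \tau_{\min}]$ remainder is added via the linear small-lag law; its
  size is included in the reported error budget. Near $\tau = 0$ the
  combinations $M_{33} \pm M_{34}$ cancel to fourth order; they are
  evaluated in factored form, and the discriminant is clipped at zero only
  within $-10^{-10}\lambda_2^2$ of floating noise (anything larger is an
  error).
* The bracket is computed as $D + M_{34}\arctan(M_{34}/D)$ (no division by
  a vanishing $D$); at $D = 0$ the limit $|M_{34}|\,\pi/2$ is used.
* Panels of the composite Gauss–Legendre rule are capped at
  $\Lambda_{\mathrm{sq}}/8$ (the Bessel oscillation scale), 16 nodes each;
  the result is taken from a doubled-panel evaluation and the difference
  between the two is the reported quadrature error (typically
  $\lesssim 10^{-7}$). `run_variance_curve()` always evaluates a second,
  perturbed setting (panels $\Lambda_{\mathrm{sq}}/12$, 24 nodes) as a
  replicate; agreement is within 0.1 % in practice.
* Continuous spectra carry a fixed 2049-point Gauss–Legendre rule on their
  support, so every integral is deterministic given the configuration.
* Atomic spectra evaluate as exact finite Bessel sums.

## The variance-versus-spectral-width experiment

`run_variance_curve()` evaluates the normalized variance
$\mathbb{V}[N]/\mathbb{E}[N]^2$ for uniform annular spectra of widths 0 to
30 % of the mean wavenumber (width 0 handled exactly as a single ring).

**The segment length matters, and the package treats this as a finding.**
On a segment of hypercolumn length $\ell = \Lambda_{\mathrm{sq}}$ — the
scale whose regularity the hypercolumn question is about — the exact curve
is minimal at width 0, increases monotonically with width, and has a flat
slope at zero (the 0 → 2.5 % increment is under 1 % of the 0 → 30 % rise):
spectral thinness buys quasi-periodicity, and near-monochromatic spectra
behave like monochromatic ones. For segments longer than about
$2\Lambda_{\mathrm{sq}}$, however, the ordering *reverses*: the
monochromatic line covariance decays only like $\tau^{-1/2}$, the pair
correlations of its zeros are not integrable, and its count variance grows
like $\ell \log \ell$, whereas any finite spectral width cuts the
correlations off beyond a coherence length inversely proportional to the
width and yields linear
growth; asymptotically the monochromatic field has the *largest* count
variance. Both regimes are exact consequences of the same formula, and the
package's Monte Carlo oracle confirms them (at
$\ell = 5\Lambda_{\mathrm{sq}}$: monochromatic 2.9237 vs 20 %-annulus
2.7517 by quadrature; MC $2.91\pm0.06$ and $2.73\pm0.06$). The experiment
default is therefore $\ell = \Lambda_{\mathrm{sq}}$, with
`ell_factor` exposed and $\ell/\Lambda_{\mathrm{sq}}$ recorded on every
output row.

`run_multicircle()` runs the companion convergence experiment: spectra of
$2N+1$ rings at $R_{\mathrm{mean}} + hw\,i/N$ ($R_{\mathrm{mean}} = 10.95$,
$hw = 0.95$) have variances that decrease monotonically in $N$ and converge,
as Riemann sums, to the uniform annulus $[10.0, 11.9]$ — at $N = 18$ the
gap is below 0.04 %. Concentrating the same spectral width on a few rings
(several competing wavelengths) always yields a higher variance than the
uniform spectrum.

## The simulator and what it does (not) emulate

`sample_field()` synthesizes $z(x) = \sum_j a_j e^{i k_j \cdot x}$:

* radii stratified by $P$ (atoms get blocks proportional to weight by
  largest-remainder rounding; annuli get the mid-quantiles), so the
  realized spectrum is exact at finite $n$;
* angles at the vertices of a regular $n$-gon plus one uniform random
  rotation, with radii randomly permuted across vertices — the permutation
  keeps multi-ring spectra isotropic, and the global rotation restores
  rotational invariance in distribution;
* amplitudes i.i.d. circular complex Gaussian with variance $1/n$, making
  the field centered with $E|z|^2 = 1$ by construction.

This deliberately differs from i.i.d. wave-vector sampling: it has lower
Monte Carlo variance and an exactly known spectrum, at the cost of weak
$O(1/n)$ angular dependence between waves, immaterial at the default
$n = 256$ (the classic 100-wave, wavelength-$1/3$ construction is kept
available for map reproduction). Everything is deterministic given the
seed; grid and segment sampling share one synthesis path, so a grid row
and a segment with the same seed agree to machine precision.

The generator emulates the *early-development* Gaussian ensemble only. It
does not emulate mature maps (which are demonstrably non-Gaussian), nor
measured correlation spectra, nor anisotropies of real cortex. Passing
Monte Carlo tests therefore validates the mathematics of the invariant
Gaussian model — not the claim that any particular cortex realizes it.

## Empirical statistics

Crossing counts use sign changes of the projection with linear-interpolated
root localization and a half-open endpoint convention (a root at the start
of a segment counts, at the end it does not; an exactly-zero sample belongs
to the following interval). Pinwheels are detected by plaquette winding
numbers: the four phase increments of $\arg z$ around each grid cell,
wrapped to $(-\pi, \pi]$, sum to $\pm 2\pi$ at a singularity of charge
$\pm 1$. An increment within $10^{-9}$ of $\pm\pi$ is ambiguous and the
plaquette is re-evaluated on a refined stencil from the synthesis recipe.
Grids are sampled at $\Lambda_{\mathrm{sq}}/12$ or finer (a guard, as is a
minimum of 50 samples per wavelength on segments), density windows are
half-open so tiling counts add, and a margin of one $\Lambda_{\mathrm{sq}}$
is discarded around density windows to suppress boundary bias.

## Problem sizes

The shipped checks use: 50 fields of 256 waves per spectrum on a
$(10\Lambda_{\mathrm{sq}})^2$ interior window for the pinwheel-density
check; 2 000 realizations per spectrum for the rate arbitration and 20 000
for the variance arbitration; 13 spectral widths $\times$ 2 quadrature
settings for the variance curve; and $N \in \{1, 2, 4, 9, 18\}$ for the
multi-ring convergence run. These sizes make every Monte Carlo gate a
3-standard-error test with negligible flake probability.

## Known limitations

* The variance quadrature loses its error guarantee if the spectrum has
  support at extremely disparate scales (ratio $\gtrsim 10^3$), since the
  panel cap tracks only $\Lambda_{\mathrm{sq}}$.
* The pinwheel census reports counts and charges, not nearest-neighbour
  distances or density variability across subregions.
* No estimation of $P$ from measured maps: the package consumes spectra,
  it does not infer them.
* The variance of the pinwheel *count* (as opposed to the crossing count)
  is out of scope.
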