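# Independent oracles, deliberately sharing no code with the package paths
# they check.

# order-zero Bessel function of the first kind by its power series
# (adequate to ~1e-12 for |x| <= 20)
j0_series <- function(x) {
  vapply(x, function(xi) {
    term <- 1
    s <- 1
    m <- 0
    repeat {
      m <- m + 1
      term <- -term * (xi / 2)^2 / m^2
      s <- s + term
      if (abs(term) < 1e-18 || m > 200) break
    }
    s
  }, numeric(1))
}

# signed cofactor of entry (i, j) by generic determinant on the minor
cofactor_bruteforce <- function(m, i, j) {
  (-1)^(i + j) * det(m[-i, -j, drop = FALSE])
}

# central finite differences
fd1 <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
fd2 <- function(f, x, h) (f(x + h) - 2 * f(x) + f(x - h)) / h^2

# random spectral measure: atomic with 1-5 well-separated atoms, or an
# annulus; deterministic under the caller's seed
random_spectrum <- function() {
  if (stats::runif(1) < 0.7) {
    n <- sample(1:5, 1)
    radii <- sort(exp(stats::runif(n, log(0.5), log(30))))
    # enforce separation so "equality iff single atom" is numerically crisp
    radii <- radii * (1 + 0.05 * (seq_len(n) - 1))
    atomic_spectrum(radii, stats::runif(n, 0.1, 1))
  } else {
    lo <- exp(stats::runif(1, log(0.5), log(20)))
    uniform_annulus(lo, lo * stats::runif(1, 1.05, 1.8), nquad = 513L)
  }
}
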