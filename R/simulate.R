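#' Exact fractional Gaussian noise by circulant embedding
#'
#' Generates stationary fractional Gaussian noise (fGn) with unit-lag
#' autocovariance `gamma(k) = 0.5 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`
#' through the circulant-embedding (Davies-Harte) construction, which is
#' exact whenever the embedding is non-negative definite. Embedding
#' eigenvalues whose negative magnitude is below `1e-3` of the maximum are
#' clamped to zero (this occurs only for `H` above about 0.93); a larger
#' violation raises an error.
#'
#' @param n Number of samples (a power of two).
#' @param H Hurst exponent in (0, 1).
#' @param seed Integer seed; the draw is deterministic given `(n, H, seed)`.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @export
simulate_fgn <- function(n, H, seed) {
  check_H(H)
  if (!is_power_of_two(n)) mf_abort("`n` must be a power of two.", "input")
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row1 <- c(g, 0, rev(g[-1]))
  lam <- Re(fft(row1))
  if (min(lam) < -1e-3 * max(lam)) {
    mf_abort(sprintf("Circulant embedding not non-negative definite for H = %.4g.", H),
             "estimation")
  }
  lam[lam < 0] <- 0
  m <- length(row1)
  with_seed(seed, {
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    sqrt(2) * Re(fft(sqrt(lam / (2 * m)) * z))[seq_len(n)]
  })
}

check_H <- function(H) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1) {
    mf_abort("`H` must lie strictly inside (0, 1).", "input")
  }
}

#' Fractional Brownian motion trace
#'
#' Cumulates exact fractional Gaussian noise into a fractional Brownian
#' motion (fBm) trace, the canonical monofractal process: its multifractal
#' spectrum collapses to the point `(H, 0)`.
#'
#' @inheritParams simulate_fgn
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_fbm(4096, H = 1 / 3, seed = 1)
#' @export
simulate_fbm <- function(n, H, seed) {
  cumsum(simulate_fgn(n, H, seed))
}

#' Binomial multiplicative cascade signal
#'
#' Builds a binomial multiplicative cascade measure of depth
#' `log2(n)`: mass 1 is split recursively into fractions `p` and `1 - p`,
#' the assignment to the left/right child randomized independently at every
#' node. The returned signal is the cell density (mass times `n`), a
#' genuinely multifractal signal with box partition exponents
#' `-log2(p^q + (1-p)^q)`.
#'
#' @param n Signal length, `2^depth`.
#' @param p Small weight in (0, 0.5]; `p = 0.5` gives the uniform
#'   (degenerate, monofractal) limit.
#' @param seed Integer seed for the branch randomization.
#' @return Numeric vector of length `n` summing to `n`.
#' @export
simulate_cascade <- function(n, p, seed) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 0.5) {
    mf_abort("`p` must lie in (0, 0.5].", "input")
  }
  if (!is_power_of_two(n) || n < 2) {
    mf_abort("`n` must be a power of two (at least 2).", "input")
  }
  depth <- as.integer(round(log2(n)))
  with_seed(seed, {
    mass <- 1
    for (m in seq_len(depth)) {
      flip <- runif(length(mass)) < 0.5
      w_left <- ifelse(flip, p, 1 - p)
      mass <- as.vector(rbind(mass * w_left, mass * (1 - w_left)))
    }
    mass * n
  })
}
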