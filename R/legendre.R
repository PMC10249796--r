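#' Multifractal spectrum by the Legendre step
#'
#' Differentiates the estimated partition function by finite differences
#' (central in the interior, one-sided at the endpoints) to obtain the
#' singularity strength `alpha(q) = T'(q)`, then evaluates the spectrum
#' parametrically as `f(alpha(q)) = q * alpha(q) - T(q)`. The resolution of
#' the spectrum is set by the q grid. If the numerical `alpha(q)` is not
#' monotone non-increasing (estimated `T` not concave), a warning condition is
#' signalled and the points are kept unaltered.
#'
#' @param pf An `mf_pf` object from [estimate_partition_function()], with at
#'   least 3 q points.
#' @return A tibble of class `mf_spectrum` with columns `q`, `alpha`, `f`,
#'   carrying a logical attribute `non_concave`.
#' @examples
#' x <- simulate_fbm(1024, 0.5, seed = 1)
#' sp <- legendre_transform(
#'   estimate_partition_function(empirical_moments(dwt_normalized(x))))
#' spectral_mode(sp)
#' @export
legendre_transform <- function(pf) {
  if (!inherits(pf, "mf_pf")) {
    mf_abort("`pf` must be an `mf_pf` object.", "input")
  }
  q <- pf$table$q
  Tq <- pf$table$T
  n <- length(q)
  if (n < 3L) mf_abort("T(q) must be defined on at least 3 q points.", "input")
  alpha <- numeric(n)
  alpha[2:(n - 1)] <- (Tq[3:n] - Tq[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)])
  alpha[1] <- (Tq[2] - Tq[1]) / (q[2] - q[1])
  alpha[n] <- (Tq[n] - Tq[n - 1]) / (q[n] - q[n - 1])
  f <- q * alpha - Tq
  non_concave <- any(diff(alpha) > 1e-9)
  if (non_concave) {
    warn("alpha(q) is not monotone: estimated T(q) is not numerically concave; points kept.",
         class = "mfspectra_warning_nonconcave")
  }
  new_mf_spectrum(q, alpha, f, non_concave = non_concave)
}

new_mf_spectrum <- function(q, alpha, f, non_concave = FALSE) {
  out <- tibble(q = q, alpha = unname(alpha), f = unname(f))
  structure(out, class = c("mf_spectrum", class(tibble())),
            non_concave = non_concave)
}

#' Legendre transform by direct grid minimization (oracle route)
#'
#' Evaluates `f_L(alpha) = inf_q { q * alpha - T(q) }` over the estimated q
#' grid for each probe singularity strength. This is the direct definition of
#' the Legendre transform and serves as an independent check of the
#' parametric evaluation in [legendre_transform()]: for a concave `T` the two
#' agree at `alpha = alpha(q)`.
#'
#' @param pf An `mf_pf` object.
#' @param alpha_probe Numeric vector of singularity strengths to evaluate.
#' @return Numeric vector, one spectrum value per probe.
#' @export
legendre_bruteforce <- function(pf, alpha_probe) {
  if (!inherits(pf, "mf_pf")) {
    mf_abort("`pf` must be an `mf_pf` object.", "input")
  }
  q <- pf$table$q
  Tq <- pf$table$T
  vapply(alpha_probe, function(a) min(q * a - Tq), numeric(1))
}

#' One-call multifractal spectrum of a signal
#'
#' Convenience wrapper chaining [dwt_normalized()], [empirical_moments()],
#' [estimate_partition_function()] and [legendre_transform()].
#'
#' @inheritParams dwt_normalized
#' @inheritParams empirical_moments
#' @inheritParams estimate_partition_function
#' @return An `mf_spectrum` tibble; the partition function is attached as
#'   attribute `pf`.
#' @examples
#' sp <- multifractal_spectrum(simulate_fbm(1024, 0.7, seed = 2))
#' mf_descriptors(sp, auto_relax = TRUE)
#' @export
multifractal_spectrum <- function(x, wavelet = "db6",
                                  pad_mode = c("reflect", "none"),
                                  q_grid = seq(-5, 5, by = 0.1),
                                  eps_floor = 1e-12, scale_range = NULL) {
  pf <- estimate_partition_function(
    empirical_moments(dwt_normalized(x, wavelet, pad_mode),
                      q_grid = q_grid, eps_floor = eps_floor),
    scale_range = scale_range)
  sp <- withCallingHandlers(
    legendre_transform(pf),
    mfspectra_warning_nonconcave = function(w) {
      invokeRestart("muffleWarning")
    })
  attr(sp, "pf") <- pf
  sp
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat("<mf_spectrum> ", nrow(x), " points, alpha in [",
      signif(min(x$alpha), 4), ", ", signif(max(x$alpha), 4),
      "], apex f = ", signif(max(x$f), 4),
      if (isTRUE(attr(x, "non_concave"))) " (non-concave stretches flagged)",
      "\n", sep = "")
  invisible(x)
}

#' @describeIn legendre_transform Return the spectrum as a plain tibble.
#' @param x,... An `mf_spectrum`; further arguments ignored.
#' @method tidy mf_spectrum
#' @export
tidy.mf_spectrum <- function(x, ...) {
  tibble(q = x$q, alpha = x$alpha, f = x$f)
}
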