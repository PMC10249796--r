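#' Empirical log2 moments of normalized wavelet coefficients
#'
#' For each level `j` and moment order `q`, computes
#' `S_j(q) = 2^(-j) * sum_k |d_jk|^q` from the normalized detail coefficients
#' and returns `log2 S_j(q)`. For negative `q`, coefficients with magnitude
#' below `eps_floor` are excluded to guard against blow-up; at `q = 0` no
#' exclusion is applied, so `S_j(0) = 1` exactly and the fitted partition
#' function satisfies `T(0) = 0`.
#'
#' @param coeffs An [dwt_normalized()] result (`mf_dwt`).
#' @param q_grid Ordered numeric vector of moment orders; must contain 0.
#'   Default `seq(-5, 5, by = 0.1)`.
#' @param eps_floor Non-negative magnitude floor for negative moments
#'   (default `1e-12`).
#' @return A tibble of class `mf_moments` with columns `level`, `q`, `log2_S`
#'   and `n_retained`; cells where no coefficient survives the floor carry
#'   `NA` and are excluded from the later regression.
#' @examples
#' m <- empirical_moments(dwt_normalized(cumsum(rnorm(512))))
#' dplyr::filter(m, q == 0)  # identically zero
#' @export
empirical_moments <- function(coeffs, q_grid = seq(-5, 5, by = 0.1),
                              eps_floor = 1e-12) {
  if (!inherits(coeffs, "mf_dwt")) {
    mf_abort("`coeffs` must be an `mf_dwt` object from dwt_normalized().", "input")
  }
  if (is.unsorted(q_grid, strictly = TRUE)) {
    mf_abort("`q_grid` must be strictly increasing.", "input")
  }
  if (!any(abs(q_grid) < 1e-12)) {
    mf_abort("`q_grid` must contain 0.", "input")
  }
  if (!is.numeric(eps_floor) || length(eps_floor) != 1L || eps_floor < 0) {
    mf_abort("`eps_floor` must be a single non-negative number.", "input")
  }

  nq <- length(q_grid)
  neg <- q_grid < 0
  zero <- abs(q_grid) < 1e-12
  rows <- purrr::map_dfr(coeffs$levels, function(lv) {
    j <- lv$level
    dn <- abs(lv$detail_norm)
    lg <- log2(dn)                               # -Inf where dn == 0
    log2_S <- rep(NA_real_, nq)
    n_ret <- integer(nq)
    # positive q: all coefficients retained; 2^(q * -Inf) -> 0 contributes 0
    pos <- !neg & !zero
    if (any(pos)) {
      s <- colSums(2^outer(lg, q_grid[pos]))
      log2_S[pos] <- ifelse(s > 0, log2(s) - j, NA_real_)
      n_ret[pos] <- length(dn)
    }
    if (any(neg)) {
      keep <- dn >= eps_floor
      n_ret[neg] <- sum(keep)
      if (any(keep)) {
        M <- matrix(2^outer(lg[keep], q_grid[neg]), ncol = sum(neg))
        s <- colSums(M)
        log2_S[neg] <- ifelse(is.finite(s) & s > 0, log2(s) - j, NA_real_)
      }
    }
    # no exclusions at q = 0: S_j(0) = 2^-j * 2^j = 1 exactly
    log2_S[zero] <- 0
    n_ret[zero] <- length(dn)
    tibble(level = j, q = q_grid, log2_S = log2_S, n_retained = n_ret)
  })
  structure(rows,
            class = c("mf_moments", class(tibble())),
            q_grid = q_grid, J = coeffs$J, eps_floor = eps_floor,
            wavelet = coeffs$wavelet, n_orig = coeffs$n_orig)
}

default_scale_range <- function(J) c(3L, J - 3L)

#' Estimate the partition function T(q) by per-q log-scale regression
#'
#' For every moment order `q`, fits ordinary least squares of `log2 S_j(q)`
#' against the level index `j` over the chosen scale range; the partition
#' function is `T(q) = -slope`. The intercept (absorbing the `log2 C_q`
#' constant) and the per-q R-squared are retained as fit diagnostics.
#'
#' @param log_moments An `mf_moments` tibble from [empirical_moments()].
#' @param scale_range Integer pair `(j_min, j_max)` of levels used in the
#'   regression; default `c(3, J - 3)` excludes the coarsest and finest
#'   levels.
#' @return An object of class `mf_pf`: a list with a `table` tibble
#'   (`q`, `T`, `intercept`, `r2`, `n_scales`), the `scale_range`, and the
#'   `q_grid`.
#' @examples
#' x <- simulate_fbm(1024, 0.5, seed = 1)
#' pf <- estimate_partition_function(empirical_moments(dwt_normalized(x)))
#' glance(pf)
#' @export
estimate_partition_function <- function(log_moments, scale_range = NULL) {
  if (!inherits(log_moments, "mf_moments")) {
    mf_abort("`log_moments` must come from empirical_moments().", "input")
  }
  J <- attr(log_moments, "J")
  q_grid <- attr(log_moments, "q_grid")
  if (is.null(scale_range)) scale_range <- default_scale_range(J)
  if (length(scale_range) != 2L || scale_range[1] > scale_range[2]) {
    mf_abort("`scale_range` must be an increasing pair (j_min, j_max).", "input")
  }
  if (scale_range[2] > J - 1L || scale_range[1] < 0L) {
    mf_abort(paste0("`scale_range` must lie within available levels 0..",
                    J - 1L, "."), "input")
  }

  ## reshape to a levels x q matrix over the regression scales, then run the
  ## per-q least squares in closed form (columns with missing cells fall back
  ## to a masked fit)
  in_range <- log_moments$level >= scale_range[1] &
    log_moments$level <= scale_range[2]
  sub <- log_moments[in_range, ]
  js <- sort(unique(sub$level))
  qpos <- match(round(sub$q, 10), round(q_grid, 10))
  jpos <- match(sub$level, js)
  Y <- matrix(NA_real_, nrow = length(js), ncol = length(q_grid))
  Y[cbind(jpos, qpos)] <- sub$log2_S

  fit_col <- function(yv) {
    ok <- is.finite(yv)
    if (sum(ok) < 3L) return(NULL)
    j <- js[ok]; yv <- yv[ok]
    jm <- mean(j); ym <- mean(yv)
    sxx <- sum((j - jm)^2)
    slope <- sum((j - jm) * (yv - ym)) / sxx
    icpt <- ym - slope * jm
    rss <- sum((yv - icpt - slope * j)^2)
    tss <- sum((yv - ym)^2)
    c(T = -slope, intercept = icpt,
      r2 = if (tss > 1e-24) 1 - rss / tss else if (rss < 1e-20) 1 else NA_real_,
      n_scales = sum(ok))
  }
  cols <- lapply(seq_along(q_grid), function(i) fit_col(Y[, i]))
  bad <- vapply(cols, is.null, logical(1))
  if (any(bad)) {
    mf_abort(paste0("Fewer than 3 usable scales for q = ",
                    paste(signif(q_grid[bad], 4), collapse = ", "),
                    "; cannot estimate T(q)."), "estimation")
  }
  M <- do.call(rbind, cols)
  tab <- tibble(q = q_grid, T = M[, "T"], intercept = M[, "intercept"],
                r2 = M[, "r2"], n_scales = as.integer(M[, "n_scales"]))
  structure(list(table = tab, scale_range = as.integer(scale_range),
                 q_grid = q_grid, J = J,
                 wavelet = attr(log_moments, "wavelet"),
                 n_orig = attr(log_moments, "n_orig")),
            class = "mf_pf")
}

#' @export
print.mf_pf <- function(x, ...) {
  cat("<mf_pf> partition function on ", length(x$q_grid), " moment orders, ",
      "scales j = ", x$scale_range[1], "..", x$scale_range[2], "\n", sep = "")
  i2 <- which.min(abs(x$table$q - 2))
  cat("  T(2) = ", signif(x$table$T[i2], 4),
      ", mean R^2 = ", signif(mean(x$table$r2, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn estimate_partition_function Per-q tibble of `T`, intercept and
#'   R-squared.
#' @param x,... An `mf_pf` object; further arguments ignored.
#' @method tidy mf_pf
#' @export
tidy.mf_pf <- function(x, ...) x$table

#' @describeIn estimate_partition_function One-row summary (scale range, mean
#'   R-squared, `T(2)`).
#' @method glance mf_pf
#' @export
glance.mf_pf <- function(x, ...) {
  tibble(n_q = nrow(x$table),
         j_min = x$scale_range[1], j_max = x$scale_range[2],
         mean_r2 = mean(x$table$r2, na.rm = TRUE),
         T2 = x$table$T[which.min(abs(x$table$q - 2))])
}
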