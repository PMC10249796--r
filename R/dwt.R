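## Orthonormal Daubechies scaling filters (extremal phase), indexed by number
## of vanishing moments. Standard published constants; sum(h) = sqrt(2),
## sum(h^2) = 1. "db6" (6 vanishing moments) is the package default.
.db_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953)
)
.db_filters$db1 <- .db_filters$haar

wavelet_filter <- function(wavelet) {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !wavelet %in% names(.db_filters)) {
    mf_abort(
      paste0("Unsupported wavelet '", paste(wavelet, collapse = ","),
             "'. Available: ", paste(setdiff(names(.db_filters), "db1"),
                                     collapse = ", "), "."),
      "config")
  }
  .db_filters[[wavelet]]
}

## Quadrature mirror (high-pass) filter: g[n] = (-1)^n h[L-1-n].
qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1L)

#' Normalized discrete wavelet transform of a 1D spectrum
#'
#' Computes the periodized orthonormal DWT of an intensity trace and rescales
#' the detail coefficients to the L1-normalized convention used by the
#' multifractal partition function: at the level holding `2^j` coefficients the
#' orthonormal details are divided by `sqrt(N / 2^j)` (with `N` the analyzed
#' length), so that a signal of Holder regularity `H` has normalized details
#' scaling as `2^(-jH)`.
#'
#' @param x Numeric vector of intensities, length at least 64. All values must
#'   be finite.
#' @param wavelet Wavelet name: one of `"haar"`, `"db2"`, `"db4"`, `"db6"`
#'   (default), `"db8"`.
#' @param pad_mode `"reflect"` (default) appends the mirrored signal so the
#'   periodic extension is continuous (non-dyadic lengths are first
#'   reflection-padded to the next power of two); `"none"` requires a dyadic
#'   length and applies the plain periodized transform.
#' @return An object of class `mf_dwt`: a list with `levels` (per level `j`,
#'   holding the `2^j` orthonormal `detail` and normalized `detail_norm`
#'   coefficients), `J` (number of levels), `wavelet`, `n_orig`, `pad_mode`.
#' @examples
#' d <- dwt_normalized(sin(seq_len(256) / 8) + rnorm(256, sd = 0.1))
#' tidy(d)
#' @export
dwt_normalized <- function(x, wavelet = "db6", pad_mode = c("reflect", "none")) {
  pad_mode <- match.arg(pad_mode)
  if (!is.numeric(x)) mf_abort("`x` must be a numeric vector.", "input")
  if (anyNA(x) || any(!is.finite(x))) {
    mf_abort("`x` contains non-finite values.", "input")
  }
  n_orig <- length(x)
  min_len <- if (pad_mode == "reflect") 64L else 4L
  if (n_orig < min_len) {
    mf_abort(paste0("Signal length ", n_orig, " is below the minimum of ",
                    min_len, "."), "input")
  }
  h <- wavelet_filter(wavelet)

  y <- x
  if (pad_mode == "reflect") {
    p <- 2^ceiling(log2(n_orig))
    if (p > n_orig) y <- c(y, rev(y)[seq_len(p - n_orig)])
    y <- c(y, rev(y))
  } else if (!is_power_of_two(n_orig)) {
    mf_abort("pad_mode = \"none\" requires a power-of-two length.", "input")
  }

  g <- qmf(h)
  L <- length(h)
  J <- as.integer(round(log2(length(y))))
  levels <- vector("list", J)
  a <- y
  for (m in seq_len(J)) {                 # m: depth from the finest level
    n <- length(a)
    idx <- outer(2L * seq_len(n %/% 2L) - 1L, 0:(L - 1L), `+`)
    idx <- (idx - 1L) %% n + 1L
    A <- matrix(a[idx], ncol = L)
    d <- drop(A %*% g)
    a <- drop(A %*% h)
    j <- J - m                            # level j holds 2^j coefficients
    levels[[j + 1L]] <- list(level = j, detail = d,
                             detail_norm = d * 2^(-m / 2))
  }
  structure(
    list(levels = levels, J = J, wavelet = wavelet,
         n_orig = n_orig, n_analyzed = length(y), pad_mode = pad_mode),
    class = "mf_dwt")
}

## Internal constructor used by tests and the moment step: build an mf_dwt
## from explicit per-level normalized coefficients.
new_mf_dwt <- function(detail_norm_levels, wavelet = "manual") {
  J <- length(detail_norm_levels)
  levels <- lapply(seq_len(J), function(i) {
    list(level = i - 1L, detail = NULL,
         detail_norm = detail_norm_levels[[i]])
  })
  structure(list(levels = levels, J = J, wavelet = wavelet,
                 n_orig = NA_integer_, n_analyzed = 2^J, pad_mode = "none"),
            class = "mf_dwt")
}

#' @export
print.mf_dwt <- function(x, ...) {
  cat("<mf_dwt> ", x$J, " levels, wavelet ", x$wavelet,
      ", analyzed length ", x$n_analyzed,
      " (original ", x$n_orig, ", pad '", x$pad_mode, "')\n", sep = "")
  invisible(x)
}

#' @describeIn dwt_normalized Tidy the coefficients into a tibble with columns
#'   `level`, `k`, `detail`, `detail_norm`.
#' @param x,... An `mf_dwt` object (for `tidy`); further arguments ignored.
#' @method tidy mf_dwt
#' @export
tidy.mf_dwt <- function(x, ...) {
  purrr::map_dfr(x$levels, function(lv) {
    tibble(level = lv$level, k = seq_along(lv$detail_norm),
           detail = if (is.null(lv$detail)) NA_real_ else lv$detail,
           detail_norm = lv$detail_norm)
  })
}
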