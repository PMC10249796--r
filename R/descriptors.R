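#' Spectral mode (apex) of a multifractal spectrum
#'
#' The spectral mode `SM` is the singularity strength `alpha` at the maximum
#' of `f(alpha)`; for a monofractal signal it coincides with the Hurst
#' exponent. Exact ties are broken by the point with the smallest `|q|`.
#'
#' @param spec An `mf_spectrum` tibble.
#' @return The apex `alpha`, a single number.
#' @export
spectral_mode <- function(spec) {
  check_spectrum(spec)
  i <- apex_index(spec)
  spec$alpha[i]
}

check_spectrum <- function(spec) {
  if (!inherits(spec, "mf_spectrum") || nrow(spec) == 0L) {
    mf_abort("`spec` must be a non-empty `mf_spectrum`.", "input")
  }
  invisible(spec)
}

apex_index <- function(spec) {
  fmax <- max(spec$f)
  i <- which(spec$f >= fmax - 1e-12)
  i[which.min(abs(spec$q[i]))]
}

#' Broadness of a multifractal spectrum
#'
#' The broadness `B` is the width `alpha2 - alpha1` between the two crossings
#' of `f(alpha) = -threshold` (default threshold 0.2), one on each side of the
#' apex. On the discrete spectrum each crossing is located by scanning outward
#' from the apex for the first adjacent pair bracketing `-threshold` and
#' linearly interpolating. The threshold may be relaxed automatically
#' (halved, with a floor) when a side never reaches `-threshold`.
#'
#' @param spec An `mf_spectrum` tibble.
#' @param threshold Positive depth below the apex defining the crossings
#'   (default 0.2).
#' @param auto_relax If `TRUE`, halve the threshold until both crossings exist
#'   (floor `relax_floor`), recording the threshold actually used. Default
#'   `FALSE`: an undefined side raises a descriptor error naming the side.
#' @param relax_floor Smallest threshold tried under `auto_relax`
#'   (default 0.01).
#' @return A list with `B`, `alpha1`, `alpha2`, `threshold_used`, `relaxed`,
#'   and the bracketing pairs `left_bracket` / `right_bracket` (each a list
#'   with `alpha_l`, `f_l`, `alpha_u`, `f_u`) used for the tangents.
#' @export
broadness <- function(spec, threshold = 0.2, auto_relax = FALSE,
                      relax_floor = 0.01) {
  check_spectrum(spec)
  if (!is.numeric(threshold) || threshold <= 0) {
    mf_abort("`threshold` must be positive.", "input")
  }
  thr <- threshold
  repeat {
    res <- try_broadness(spec, thr)
    if (!is.character(res)) {
      res$threshold_used <- thr
      res$relaxed <- thr < threshold
      if (res$relaxed) {
        message(sprintf("broadness: threshold relaxed from %.3g to %.3g", threshold, thr))
      }
      return(res)
    }
    if (!auto_relax || thr / 2 < relax_floor) {
      mf_abort(
        paste0("Broadness undefined: no crossing of f = -", signif(thr, 4),
               " on the ", res, " side of the apex."),
        "descriptor", side = res)
    }
    thr <- thr / 2
  }
}

## Scan outward from the apex for the first bracketing pair on each side.
## alpha decreases with q, so indices above the apex (larger q) form the LEFT
## branch of the spectrum (alpha < SM) and indices below form the RIGHT one.
## Returns a result list, or the name of the failing side.
try_broadness <- function(spec, thr) {
  i <- apex_index(spec)
  n <- nrow(spec)
  scan_side <- function(side) {
    idx <- if (side == "left") {
      if (i >= n) integer(0) else seq(i + 1L, n)
    } else {
      if (i <= 1L) integer(0) else rev(seq_len(i - 1L))
    }
    prev <- i
    for (k in idx) {
      fk <- spec$f[k]
      fp <- spec$f[prev]
      if (!is.finite(fk)) break
      if (abs(fk + thr) < 1e-12) {
        return(list(alpha = spec$alpha[k],
                    bracket = list(alpha_l = spec$alpha[k], f_l = fk,
                                   alpha_u = spec$alpha[prev], f_u = fp)))
      }
      if (fk < -thr && fp > -thr) {
        a_out <- spec$alpha[k]; a_in <- spec$alpha[prev]
        cross <- a_out + ((-thr) - fk) * (a_in - a_out) / (fp - fk)
        return(list(alpha = cross,
                    bracket = list(alpha_l = a_out, f_l = fk,
                                   alpha_u = a_in, f_u = fp)))
      }
      prev <- k
    }
    NULL
  }
  left <- scan_side("left")
  if (is.null(left)) return("left")
  right <- scan_side("right")
  if (is.null(right)) return("right")
  list(B = right$alpha - left$alpha,
       alpha1 = left$alpha, alpha2 = right$alpha,
       left_bracket = left$bracket, right_bracket = right$bracket)
}

#' Slopes and tangents at the broadness crossings
#'
#' The left and right slopes are the secants from the apex to the threshold
#' crossings, `LS = threshold / (SM - alpha1)` and
#' `RS = -threshold / (alpha2 - SM)`; the left and right tangents `LT`, `RT`
#' are the secant slopes of the discrete bracketing pairs at each crossing.
#'
#' @param SM The spectral mode.
#' @param br A broadness result from [broadness()].
#' @return A list with `LS`, `RS`, `LT`, `RT`.
#' @export
slopes_tangents <- function(SM, br) {
  thr <- br$threshold_used
  if (abs(SM - br$alpha1) < 1e-12 || abs(br$alpha2 - SM) < 1e-12) {
    mf_abort("Degenerate spectrum: the apex coincides with a threshold crossing.",
             "descriptor")
  }
  lt <- with(br$left_bracket, (f_u - f_l) / (alpha_u - alpha_l))
  rt <- with(br$right_bracket, (f_u - f_l) / (alpha_u - alpha_l))
  list(LS = thr / (SM - br$alpha1),
       RS = -thr / (br$alpha2 - SM),
       LT = lt, RT = rt)
}

#' Six geometric descriptors of a multifractal spectrum
#'
#' Reduces an estimated spectrum to the descriptor set: spectral mode `SM`
#' (Hurst exponent of the apex), left/right slopes `LS`/`RS`, left/right
#' tangents `LT`/`RT`, and broadness `B` with its crossings `alpha1`,
#' `alpha2`.
#'
#' @inheritParams broadness
#' @return A one-row tibble with columns `SM`, `LS`, `LT`, `B`, `RS`, `RT`,
#'   `alpha1`, `alpha2`, `threshold_used`, `relaxed`.
#' @examples
#' sp <- multifractal_spectrum(simulate_cascade(2048, p = 0.3, seed = 3))
#' mf_descriptors(sp)
#' @export
mf_descriptors <- function(spec, threshold = 0.2, auto_relax = FALSE,
                           relax_floor = 0.01) {
  SM <- spectral_mode(spec)
  br <- broadness(spec, threshold = threshold, auto_relax = auto_relax,
                  relax_floor = relax_floor)
  st <- slopes_tangents(SM, br)
  tibble(SM = SM, LS = st$LS, LT = st$LT, B = br$B,
         RS = st$RS, RT = st$RT,
         alpha1 = br$alpha1, alpha2 = br$alpha2,
         threshold_used = br$threshold_used, relaxed = br$relaxed)
}

#' Descriptor table for a cohort of spectra
#'
#' Runs the full spectrum-to-descriptor pipeline over every sample of a
#' cohort tibble (as produced by [simulate_cohort()] or [read_spectra()]) and
#' binds the descriptors to the sample metadata.
#'
#' @param cohort A tibble with a `signal` list-column and metadata columns.
#' @param threshold Broadness threshold (default 0.2).
#' @param auto_relax Relax the threshold per sample when a side is undefined
#'   (default `TRUE` here: a cohort run should not abort on a single narrow
#'   spectrum; relaxations are counted and reported via a message).
#' @param relax_floor Smallest threshold tried when relaxing. The cohort
#'   default (1e-4) sits far below the single-spectrum default because a
#'   cohort run must survive the occasional near-monofractal sample whose
#'   spectrum hugs zero on one side.
#' @param on_undefined What to do when a sample's broadness is undefined even
#'   at the relax floor (a rare degenerate spectrum whose flagged non-concave
#'   branch never descends): `"na"` (default) records `SM` and sets the
#'   crossing-based descriptors to `NA`, `"error"` aborts.
#' @param ... Passed to [multifractal_spectrum()] (wavelet, q grid, scales).
#' @return The cohort metadata with descriptor columns appended.
#' @export
cohort_descriptors <- function(cohort, threshold = 0.2, auto_relax = TRUE,
                               relax_floor = 1e-4,
                               on_undefined = c("na", "error"), ...) {
  if (!is.data.frame(cohort) || !"signal" %in% names(cohort)) {
    mf_abort("`cohort` must be a tibble with a `signal` list-column.", "input")
  }
  on_undefined <- match.arg(on_undefined)
  meta <- dplyr::select(cohort, -"signal")
  desc <- purrr::map_dfr(seq_along(cohort$signal), function(i) {
    sp <- multifractal_spectrum(cohort$signal[[i]], ...)
    row <- tryCatch(
      suppressMessages(
        mf_descriptors(sp, threshold = threshold, auto_relax = auto_relax,
                       relax_floor = relax_floor)),
      mfspectra_error_descriptor = function(e) {
        if (on_undefined == "error") {
          mf_abort(paste0("Sample ", i, ": ", conditionMessage(e)), "descriptor")
        }
        tibble(SM = spectral_mode(sp), LS = NA_real_, LT = NA_real_,
               B = NA_real_, RS = NA_real_, RT = NA_real_,
               alpha1 = NA_real_, alpha2 = NA_real_,
               threshold_used = NA_real_, relaxed = NA)
      })
    row
  })
  n_rel <- sum(desc$relaxed, na.rm = TRUE)
  n_undef <- sum(is.na(desc$B))
  if (n_rel > 0) {
    message(sprintf("cohort_descriptors: broadness threshold relaxed for %d of %d samples",
                    n_rel, nrow(desc)))
  }
  if (n_undef > 0) {
    message(sprintf("cohort_descriptors: broadness undefined for %d of %d samples (descriptors set to NA)",
                    n_undef, nrow(desc)))
  }
  dplyr::bind_cols(meta, desc)
}
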