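#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   labs theme_minimal
NULL

#' Plot a multifractal spectrum
#'
#' The estimated `f(alpha)` curve with the broadness threshold line.
#'
#' @param object An `mf_spectrum`.
#' @param threshold Threshold line to draw (default 0.2).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mf_spectrum
#' @export
autoplot.mf_spectrum <- function(object, threshold = 0.2, ...) {
  ggplot(tidy(object), aes(x = .data$alpha, y = .data$f)) +
    geom_line() +
    geom_point(size = 0.6) +
    geom_hline(yintercept = -threshold, linetype = "dashed") +
    labs(x = expression(alpha), y = expression(f(alpha)),
         title = "Multifractal spectrum") +
    theme_minimal()
}

#' Plot an estimated partition function
#'
#' `T(q)` against the moment order; a monofractal signal gives a straight
#' line with slope equal to its Hurst exponent.
#'
#' @param object An `mf_pf`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mf_pf
#' @export
autoplot.mf_pf <- function(object, ...) {
  ggplot(object$table, aes(x = .data$q, y = .data$T)) +
    geom_line() +
    labs(x = "q", y = "T(q)", title = "Partition function") +
    theme_minimal()
}

#' Plot PCA scores of the descriptor triplets
#'
#' @param object An `mf_pca`.
#' @param colour Metadata column used for the point colour (default
#'   `"group"` when present).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mf_pca
#' @export
autoplot.mf_pca <- function(object, colour = NULL, ...) {
  sc <- object$scores
  if (is.null(colour) && "group" %in% names(sc)) colour <- "group"
  p <- if (is.null(colour)) {
    ggplot(sc, aes(x = .data$PC1, y = .data$PC2))
  } else {
    ggplot(sc, aes(x = .data$PC1, y = .data$PC2,
                   colour = .data[[colour]]))
  }
  p + geom_point() +
    labs(title = sprintf("PC scores (%.1f%% of variance)",
                         100 * object$variance_explained)) +
    theme_minimal()
}
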