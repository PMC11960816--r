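#' Spatially weighted dissimilarity between two map elements
#'
#' The building block of the saliency map: the absolute difference of two
#' z-scores, discounted by their separation in the matrix,
#' `|z[i,j] - z[p,q]| / (1 + sqrt((i-p)^2 + (j-q)^2))`. The farther apart two
#' bin pairs lie, the less their dissimilarity contributes. The absolute value
#' makes the measure non-negative, as a dissimilarity must be.
#'
#' @param Z A `normalized_matrix` (or a plain z-score matrix).
#' @param i,j,p,q 1-based matrix indices of the two elements.
#' @return A non-negative scalar.
#' @export
spatial_dissimilarity <- function(Z, i, j, p, q) {
  z <- if (is.matrix(Z)) Z else Z$z
  n <- nrow(z)
  m <- ncol(z)
  if (i < 1 || i > n || p < 1 || p > n || j < 1 || j > m || q < 1 || q > m) {
    stop("index out of bounds")
  }
  abs(z[i, j] - z[p, q]) / (1 + sqrt((i - p)^2 + (j - q)^2))
}

#' Saliency map of a normalized contact matrix
#'
#' Scores every bin pair by how much its z-score deviates from its local
#' spatial neighbourhood:
#' `b[i,j] = 1 - exp(-(1/(2k)^2) * sum_{p,q in window} d[(i,j),(p,q)])`,
#' where the sum runs over the `(2k+1) x (2k+1)` window centred on `(i, j)`
#' and `d` is [spatial_dissimilarity()]. Values lie in `[0, 1]`: a flat
#' background scores 0, an isolated block of elevated contacts scores near 1.
#'
#' At the default 50 kb bin size the window half-width `k = 10` spans about
#' 1 Mb, larger than most normal three-dimensional genome features (TADs,
#' loops), so ordinary chromatin structure does not register as salient.
#'
#' Windows are truncated at the matrix borders while the `(2k)^2` normalizer
#' is kept, which slightly attenuates edge cells but preserves the `[0, 1]`
#' range.
#'
#' @param Z A `normalized_matrix` from [distance_normalize()] or
#'   [trans_normalize()] (or a plain matrix of z-scores).
#' @param k Window half-width in bins (default 10).
#' @return An object of class `saliency_map` with fields `b` (the saliency
#'   matrix), `k` and the axis metadata of `Z`.
#' @export
saliency_map <- function(Z, k = 10) {
  z <- if (is.matrix(Z)) Z else Z$z
  if (any(!is.finite(z))) stop("normalized matrix must be finite")
  if (k >= nrow(z) || k >= ncol(z)) stop("window exceeds matrix")
  sym <- if (is.matrix(Z)) isSymmetric(unname(Z)) else isTRUE(Z$is_intra)
  b <- saliency_cpp(z, as.integer(k), sym)
  meta <- if (is.matrix(Z)) {
    list(chromA = "A", chromB = "B", binsA = NULL, binsB = NULL,
         binsize = NA_real_, is_intra = isSymmetric(unname(z)))
  } else {
    Z[c("chromA", "chromB", "binsA", "binsB", "binsize", "is_intra")]
  }
  structure(c(list(b = b, k = as.integer(k)), meta), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "<saliency_map> %s x %s  (%d x %d bins, k = %d, max b = %.4f)\n",
    x$chromA, x$chromB, nrow(x$b), ncol(x$b), x$k, max(x$b)
  ))
  invisible(x)
}

#' @export
dim.saliency_map <- function(x) dim(x$b)

#' Heatmap of a saliency or segmented map
#'
#' @param object A `saliency_map` or `tv_segmentation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, ...) {
  plot_map_matrix(object$b, "saliency")
}

plot_map_matrix <- function(b, fill_name) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(b)) - 1L,
    col = seq_len(ncol(b)) - 1L
  )
  df$value <- as.vector(t(b))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = fill_name) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin (columns)", y = "bin (rows)") +
    ggplot2::theme_minimal()
}
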