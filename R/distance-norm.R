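#' Per-distance mean and standard deviation of interaction counts
#'
#' Intra-chromosomal Hi-C counts fall off as a power law with genomic distance,
#' so detection statistics must be computed within distance strata. For every
#' distance class `d = |j - i|` (in bins) this returns the mean and the
#' population standard deviation (divide-by-N) of all counts at that distance.
#' Zero-count cells participate: at large distances "no contact" is real
#' signal, not missing data. Single-cell classes get `sigma = 0`.
#'
#' @param M An intra-chromosomal [contact_matrix()].
#' @return A tibble with columns `d` (bins), `mu`, `sigma` and `n_cells`.
#' @export
compute_distance_stats <- function(M) {
  stopifnot(inherits(M, "contact_matrix"))
  if (!M$is_intra) stop("distance stats are defined for intra-chromosomal matrices")
  a <- M$counts
  n <- nrow(a)
  d <- abs(.row(dim(a)) - .col(dim(a)))
  ## one representative per unordered pair: upper triangle incl. diagonal
  keep <- upper.tri(a, diag = TRUE)
  vals <- a[keep]
  dv <- d[keep]
  mu <- tapply(vals, dv, mean)
  m2 <- tapply(vals, dv, function(x) mean(x^2))
  nc <- tapply(vals, dv, length)
  tibble::tibble(
    d = as.integer(names(mu)),
    mu = as.numeric(mu),
    sigma = sqrt(pmax(as.numeric(m2) - as.numeric(mu)^2, 0)),
    n_cells = as.integer(nc)
  )
}

#' Distance-stratified z-score normalization
#'
#' Converts raw intra-chromosomal counts `a[i, j]` into z-scores
#' `z[i, j] = (a[i, j] - mu(d)) / sigma(d)` with `d = |j - i|`, removing the
#' distance decay so that rearrangement junctions — whose contacts rise far
#' above the expectation for their genomic separation — stand out. Classes
#' with `sigma(d) = 0` map to `z = 0`.
#'
#' @param M An intra-chromosomal [contact_matrix()].
#' @return An object of class `normalized_matrix`: fields `z` (matrix, same
#'   shape and axes as `M`), `stats` (the [compute_distance_stats()] table)
#'   plus the axis metadata of `M`.
#' @export
distance_normalize <- function(M) {
  stopifnot(inherits(M, "contact_matrix"))
  if (!M$is_intra) stop("inter-chromosomal matrix: use trans_normalize")
  stats <- compute_distance_stats(M)
  n <- nrow(M$counts)
  d <- abs(.row(c(n, n)) - .col(c(n, n)))
  mu <- stats$mu[d + 1L]
  sigma <- stats$sigma[d + 1L]
  z <- (M$counts - mu) / ifelse(sigma > 0, sigma, Inf)
  new_normalized(z, M, stats)
}

#' Global z-score normalization for inter-chromosomal matrices
#'
#' Genomic distance is undefined across chromosomes, so inter (trans) matrices
#' are normalized with a single global mean and population standard deviation
#' over all cells: `z[i, j] = (a[i, j] - mu) / sigma`, with `z = 0` everywhere
#' when `sigma = 0`.
#'
#' @param M An inter-chromosomal [contact_matrix()].
#' @return A `normalized_matrix` (see [distance_normalize()]); its `stats`
#'   table has a single row with `d = NA`.
#' @export
trans_normalize <- function(M) {
  stopifnot(inherits(M, "contact_matrix"))
  if (M$is_intra) stop("intra-chromosomal matrix: use distance_normalize")
  a <- M$counts
  mu <- mean(a)
  sigma <- sqrt(mean((a - mu)^2))
  z <- if (sigma > 0) (a - mu) / sigma else array(0, dim(a))
  stats <- tibble::tibble(
    d = NA_integer_, mu = mu, sigma = sigma,
    n_cells = length(a)
  )
  new_normalized(z, M, stats)
}

new_normalized <- function(z, M, stats) {
  structure(
    list(
      z = unname(z), stats = stats, chromA = M$chromA, chromB = M$chromB,
      binsA = M$binsA, binsB = M$binsB, binsize = M$binsize,
      is_intra = M$is_intra
    ),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "<normalized_matrix> %s x %s  (%d x %d bins, %s z-scores)\n",
    x$chromA, x$chromB, nrow(x$z), ncol(x$z),
    if (x$is_intra) "distance-stratified" else "global"
  ))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$z)
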