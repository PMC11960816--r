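#' Bin table for one chromosome
#'
#' Builds the table of fixed-width genomic bins that indexes one axis of a
#' contact matrix. Coordinates are 0-based, half-open: bin `i` covers
#' `[i * binsize, (i + 1) * binsize)`, and the terminal bin is truncated at the
#' chromosome end.
#'
#' @param chrom Chromosome label.
#' @param chrom_length Chromosome length in bp.
#' @param binsize Bin width in bp.
#' @return A tibble with columns `chrom`, `start`, `end`, `index` (dense from 0).
#' @export
#' @examples
#' bin_table("chr1", 1e6, 250e3)
bin_table <- function(chrom, chrom_length, binsize) {
  stopifnot(chrom_length > 0, binsize > 0)
  n <- ceiling(chrom_length / binsize)
  start <- (seq_len(n) - 1) * binsize
  tibble::tibble(
    chrom = chrom,
    start = start,
    end = pmin(start + binsize, chrom_length),
    index = seq_len(n) - 1L
  )
}

#' Contact matrix container
#'
#' Wraps a dense matrix of binned Hi-C interaction counts for one chromosome
#' pair together with the bin tables of both axes. Intra-chromosomal matrices
#' must be square and (within floating tolerance) symmetric.
#'
#' @param counts Numeric matrix of non-negative interaction counts, rows
#'   indexed by bins of `chromA`, columns by bins of `chromB`.
#' @param chromA,chromB Chromosome labels of the two axes.
#' @param binsize Bin width in bp.
#' @param binsA,binsB Optional bin tables (see [bin_table()]); derived from the
#'   matrix dimensions and `binsize` when omitted.
#' @return An object of class `contact_matrix` with fields `counts`, `chromA`,
#'   `chromB`, `binsA`, `binsB`, `binsize` and `is_intra`.
#' @export
contact_matrix <- function(counts, chromA, chromB = chromA, binsize,
                           binsA = NULL, binsB = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts))) {
    warning("non-finite cells in contact matrix replaced by 0", call. = FALSE)
    counts[!is.finite(counts)] <- 0
  }
  if (any(counts < 0)) stop("contact counts must be non-negative")
  is_intra <- identical(chromA, chromB)
  if (is_intra) {
    if (nrow(counts) != ncol(counts)) {
      stop("intra-chromosomal contact matrix must be square")
    }
    if (!isSymmetric(unname(counts), tol = 1e-8)) {
      stop("intra-chromosomal contact matrix must be symmetric")
    }
  }
  if (is.null(binsA)) binsA <- bin_table(chromA, nrow(counts) * binsize, binsize)
  if (is.null(binsB)) binsB <- bin_table(chromB, ncol(counts) * binsize, binsize)
  stopifnot(nrow(binsA) == nrow(counts), nrow(binsB) == ncol(counts))
  structure(
    list(
      counts = unname(counts), chromA = chromA, chromB = chromB,
      binsA = binsA, binsB = binsB, binsize = binsize, is_intra = is_intra
    ),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s x %s  (%d x %d bins @ %s bp, %s)\n  total counts: %.5g\n",
    x$chromA, x$chromB, nrow(x$counts), ncol(x$counts),
    format(x$binsize, big.mark = ","),
    if (x$is_intra) "intra" else "inter", sum(x$counts)
  ))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Total contact count of one or more matrices
#'
#' Sums counts over a list of contact matrices, counting each unordered bin
#' pair once (intra-chromosomal matrices are symmetric, so their off-diagonal
#' cells are halved). Used by the automatic segment-threshold rule, which is
#' keyed on sequencing depth.
#'
#' @param mats A `contact_matrix` or list of them.
#' @return Total number of contacts (scalar).
#' @export
total_contacts <- function(mats) {
  if (inherits(mats, "contact_matrix")) mats <- list(mats)
  sum(vapply(mats, function(m) {
    if (m$is_intra) {
      (sum(m$counts) + sum(diag(m$counts))) / 2
    } else {
      sum(m$counts)
    }
  }, numeric(1)))
}
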