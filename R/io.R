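#' Read a contact matrix from a dense TSV + bin table
#'
#' Reads binned Hi-C counts for one chromosome pair from a dense, headerless
#' tab-separated matrix covering all bins listed in a side-car bin table
#' (columns `chrom`, `start`, `end`). Rows of the matrix correspond to bin-table
#' rows in order. Cooler-style HDF5 containers (`.cool`/`.mcool`) are not
#' parsed here; convert them to text with `cooler dump` style exports first.
#'
#' Intra-chromosomal matrices stored upper-triangular are reflected onto the
#' lower triangle; asymmetric full storage is averaged with its transpose (with
#' a warning). Non-finite cells are zeroed with a warning.
#'
#' @param path Path to the dense matrix TSV.
#' @param resolution Bin size in bp; must match the bin-table bin width.
#' @param chromA,chromB Chromosome labels of the requested pair.
#' @param bins Either a bin-table data frame (`chrom`, `start`, `end`) or a
#'   path to a TSV holding one. Defaults to `<path>.bins.tsv`.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, resolution, chromA, chromB = chromA,
                                bins = paste0(path, ".bins.tsv")) {
  if (grepl("\\.(m?cool|hic)$", path, ignore.case = TRUE)) {
    stop(
      "unsupported container: ", basename(path),
      " (only dense TSV + bin table are read; export the matrix to text first)"
    )
  }
  bins <- read_bin_table(bins)
  widths <- bins$end - bins$start
  ## terminal bin of each chromosome may be short
  full <- widths[c(diff(match(bins$chrom, unique(bins$chrom))) == 0, FALSE)]
  if (!all(full == resolution)) {
    stop("resolution unavailable: bin table is at ", max(widths), " bp")
  }
  for (chrom in unique(c(chromA, chromB))) {
    if (!chrom %in% bins$chrom) stop("chromosome not found: ", chrom)
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (nrow(m) != nrow(bins) || ncol(m) != nrow(bins)) {
    stop(
      "matrix is ", nrow(m), " x ", ncol(m), " but bin table lists ",
      nrow(bins), " bins"
    )
  }
  ia <- which(bins$chrom == chromA)
  ib <- which(bins$chrom == chromB)
  counts <- m[ia, ib, drop = FALSE]
  if (anyNA(counts) || any(!is.finite(counts))) {
    warning("non-finite cells in ", basename(path), " replaced by 0", call. = FALSE)
    counts[!is.finite(counts)] <- 0
  }
  if (identical(chromA, chromB) && !isSymmetric(unname(counts), tol = 1e-8)) {
    lower <- counts[lower.tri(counts)]
    if (all(lower == 0)) {
      counts <- counts + t(counts) - diag(diag(counts))
    } else {
      warning("asymmetric intra matrix averaged with its transpose", call. = FALSE)
      counts <- (counts + t(counts)) / 2
    }
  }
  ba <- dplyr::mutate(bins[ia, ], index = dplyr::row_number() - 1L)
  bb <- dplyr::mutate(bins[ib, ], index = dplyr::row_number() - 1L)
  contact_matrix(counts, chromA, chromB,
    binsize = resolution,
    binsA = ba, binsB = bb
  )
}

read_bin_table <- function(bins) {
  if (is.character(bins)) {
    bins <- utils::read.table(bins,
      sep = "\t", header = FALSE,
      col.names = c("chrom", "start", "end"),
      colClasses = c("character", "numeric", "numeric")
    )
    ## tolerate a header line
    if (is.na(suppressWarnings(as.numeric(bins$start[1])))) bins <- bins[-1, ]
    bins$start <- as.numeric(bins$start)
    bins$end <- as.numeric(bins$end)
  }
  bins <- tibble::as_tibble(bins)[, c("chrom", "start", "end")]
  stopifnot(nrow(bins) > 0, all(bins$end > bins$start))
  bins
}

#' Write a dense matrix to TSV
#'
#' Debugging dump for contact, normalized or saliency matrices.
#'
#' @param m A matrix or a container with a matrix field (`counts`, `z`, `b` or
#'   `b_prime`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (!is.matrix(m)) {
    m <- m$counts %||% m$z %||% m$b %||% m$b_prime
  }
  utils::write.table(m, path,
    sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

sv_call_columns <- c(
  "chromA", "startA", "endA", "chromB", "startB", "endB",
  "name", "score", "sv_type"
)

sv_types <- c(
  "deletion", "duplication", "inversion", "balanced_translocation",
  "unbalanced_translocation", "inter_translocation", "unclassified"
)

#' Validate a table of SV calls
#'
#' Checks the invariants of the call format: positive-width intervals, interval
#' A not after interval B for intra-chromosomal calls, scores in `[0, 1]` and a
#' known SV type.
#'
#' @param calls A data frame of SV calls (see [write_sv_calls()] for columns).
#' @return The calls as a tibble, invisibly usable in a pipe.
#' @export
validate_sv_calls <- function(calls) {
  calls <- tibble::as_tibble(calls)
  missing <- setdiff(sv_call_columns, names(calls))
  if (length(missing) > 0) {
    stop("missing call columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(calls) == 0) return(calls)
  stopifnot(
    all(calls$startA < calls$endA), all(calls$startB < calls$endB),
    all(calls$score >= 0 & calls$score <= 1),
    all(calls$sv_type %in% sv_types)
  )
  intra <- calls$chromA == calls$chromB
  if (any(calls$startA[intra] > calls$startB[intra])) {
    stop("for intra-chromosomal calls interval A must precede interval B")
  }
  calls
}

#' Write SV calls to a BEDPE-compatible file
#'
#' Writes tab-delimited calls with the nine canonical columns (`chromA`,
#' `startA`, `endA`, `chromB`, `startB`, `endB`, `name`, `score`, `sv_type`)
#' followed by any extra columns present (e.g. breakpoint point estimates).
#' A header line is always written, so an empty call set round-trips.
#'
#' @param calls Data frame of SV calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_sv_calls()]
#' @export
write_sv_calls <- function(calls, path) {
  calls <- validate_sv_calls(calls)
  extra <- setdiff(names(calls), sv_call_columns)
  readr::write_tsv(calls[, c(sv_call_columns, extra)], path)
  invisible(path)
}

#' Read SV calls written by [write_sv_calls()]
#'
#' @param path Path to a tab-delimited call file with a header line.
#' @return A tibble of validated SV calls.
#' @export
read_sv_calls <- function(path) {
  calls <- readr::read_tsv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      chromA = "c", chromB = "c", name = "c", sv_type = "c",
      .default = readr::col_double()
    )
  )
  validate_sv_calls(calls)
}
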