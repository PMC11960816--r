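#' Per-bin coverage profile of an intra-chromosomal matrix
#'
#' The marginal contact count of each bin (`cov[i] = sum_j a[i, j]`) tracks
#' copy number: deleted regions lose contacts, duplicated regions gain them.
#' When a per-bin covariate table (GC content, mappability, restriction-site
#' count) is supplied, systematic coverage bias is removed with a generalized
#' additive model (one smooth term per covariate); the profile is divided by
#' the normalized fit. The genome-wide reference `c_prime` is the mean
#' coverage over bins with non-zero coverage.
#'
#' @param M An intra-chromosomal [contact_matrix()].
#' @param covariates Optional data frame with one row per bin and numeric
#'   covariate columns (e.g. `gc`, `mappability`, `re_sites`). Covariates
#'   without variation are ignored.
#' @return An object of class `coverage_profile`: a tibble field `profile`
#'   (`index`, `cov`, `cov_raw`), `c_prime`, `corrected` flag and `chrom`.
#' @export
coverage_profile <- function(M, covariates = NULL) {
  stopifnot(inherits(M, "contact_matrix"))
  if (!M$is_intra) stop("coverage profile is defined for intra-chromosomal matrices")
  cov_raw <- rowSums(M$counts)
  if (all(cov_raw == 0)) stop("all-zero matrix: average coverage undefined")
  cov <- cov_raw
  corrected <- FALSE
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    covariates <- covariates[vapply(covariates, is.numeric, logical(1))]
    stopifnot(nrow(covariates) == length(cov_raw))
    usable <- names(covariates)[vapply(
      covariates, function(x) length(unique(x)) >= 5, logical(1)
    )]
    if (length(usable) > 0) {
      terms <- paste0("s(", usable, ", k = ", pmin(
        10, vapply(covariates[usable], function(x) length(unique(x)), numeric(1)) - 1
      ), ")")
      fml <- stats::as.formula(paste("cov_raw ~", paste(terms, collapse = " + ")))
      fit <- mgcv::gam(fml, data = cbind(covariates, cov_raw = cov_raw))
      expected <- as.numeric(stats::fitted(fit))
      expected <- pmax(expected, 1e-8)
      cov <- cov_raw * mean(expected) / expected
      corrected <- TRUE
    }
  }
  structure(
    list(
      profile = tibble::tibble(
        index = seq_along(cov) - 1L,
        cov = as.numeric(cov), cov_raw = as.numeric(cov_raw)
      ),
      c_prime = mean(cov[cov > 0]),
      corrected = corrected,
      chrom = M$chromA,
      bin_width = M$binsize
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "<coverage_profile> %s  (%d bins, c' = %.4g%s)\n",
    x$chrom, nrow(x$profile), x$c_prime,
    if (x$corrected) ", covariate-corrected" else ""
  ))
  invisible(x)
}

#' Assign SV types to calls
#'
#' Classification proceeds in the order the signals are trusted:
#'
#' 1. Calls joining two chromosomes are `inter_translocation`.
#' 2. Copy-number change: the mean coverage over bins strictly between the two
#'    breakpoints is compared with the genome-wide reference `c_prime`; below
#'    `del_frac` (default 0.9) of it the call is a `deletion`, above
#'    `dup_frac` (default 1.1) a `duplication`. If no bin lies strictly
#'    between the breakpoints, the two breakpoint bins themselves are used.
#' 3. Copy-neutral calls are typed from the junction geometry of the
#'    normalized map: mean z-scores are taken in four `window`-sized quadrant
#'    blocks around the junction point. One dominant quadrant (or two
#'    adjacent ones, i.e. a one-sided strip) is the signature of an
#'    `unbalanced_translocation`; two dominant blocks on the diagonal
#'    quadrant pair (NW + SE) form the inversion butterfly; two blocks on the
#'    anti-diagonal pair (NE + SW) form the reciprocal (balanced)
#'    translocation butterfly. Anything else is `unclassified`.
#'
#' The quadrant-pair-to-type mapping follows the junction geometry implied by
#' a power-law contact model (and matches the field's usual reading of
#' butterfly orientations); it is exposed through `diag_type` and
#' `antidiag_type` for users who prefer the opposite convention.
#'
#' @param calls Tibble of calls (with `bpA`/`bpB` junction point columns, as
#'   produced by the pipeline; interval midpoints are used as a fallback).
#' @param profiles A [coverage_profile()] or named list of them (one per
#'   chromosome appearing in intra-chromosomal calls).
#' @param Z A `normalized_matrix` or named list of them, keyed like
#'   `"chromA|chromB"`; used for the orientation statistic.
#' @param del_frac,dup_frac Coverage thresholds relative to `c_prime`.
#' @param window Quadrant block size in bins; default `2 * k` with `k = 10`.
#' @param ratio Second-quadrant ratio above which a second block counts as
#'   part of a butterfly (default 0.5).
#' @param min_z Minimum dominant-quadrant mean z to attempt orientation
#'   typing (default 1).
#' @param diag_type,antidiag_type Types assigned to diagonal and
#'   anti-diagonal butterflies.
#' @return `calls` with `sv_type` filled in.
#' @export
classify_sv <- function(calls, profiles, Z = NULL,
                        del_frac = 0.9, dup_frac = 1.1,
                        window = 20, ratio = 0.5, min_z = 1,
                        diag_type = "inversion",
                        antidiag_type = "balanced_translocation") {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) return(calls)
  if (inherits(profiles, "coverage_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$chrom)
  }
  if (inherits(Z, "normalized_matrix")) {
    Z <- stats::setNames(list(Z), paste0(Z$chromA, "|", Z$chromB))
  }
  if (!"bpA" %in% names(calls)) calls$bpA <- (calls$startA + calls$endA) / 2
  if (!"bpB" %in% names(calls)) calls$bpB <- (calls$startB + calls$endB) / 2
  calls$sv_type <- vapply(seq_len(nrow(calls)), function(r) {
    call <- calls[r, ]
    if (!identical(call$chromA, call$chromB)) {
      return("inter_translocation")
    }
    prof <- profiles[[call$chromA]]
    if (is.null(prof)) stop("no coverage profile for ", call$chromA)
    cls <- classify_coverage(call, prof, del_frac, dup_frac)
    if (!is.na(cls)) return(cls)
    zmat <- (Z %||% list())[[paste0(call$chromA, "|", call$chromB)]]
    if (is.null(zmat)) return("unclassified")
    classify_orientation(
      call, zmat, window, ratio, min_z, diag_type, antidiag_type
    )
  }, character(1))
  calls
}

## coverage rule: deletion / duplication / NA (copy-neutral)
classify_coverage <- function(call, prof, del_frac, dup_frac) {
  n <- nrow(prof$profile)
  bs <- prof$bin_width
  lo <- ceiling(call$bpA / bs)
  hi <- floor(call$bpB / bs) - 1L
  idx <- seq.int(lo, hi)
  idx <- idx[idx >= 0 & idx < n]
  if (length(idx) == 0) {
    idx <- unique(pmax(0, pmin(n - 1, c(floor(call$bpA / bs), floor(call$bpB / bs)))))
  }
  mean_cov <- mean(prof$profile$cov[idx + 1L])
  if (mean_cov < del_frac * prof$c_prime) return("deletion")
  if (mean_cov > dup_frac * prof$c_prime) return("duplication")
  NA_character_
}

## quadrant-mean orientation rule on the normalized map
classify_orientation <- function(call, Z, window, ratio, min_z,
                                 diag_type, antidiag_type) {
  z <- Z$z
  bs <- Z$binsize
  n <- nrow(z)
  m <- ncol(z)
  x <- round(call$bpA / bs) # junction boundary: between bins x-1 and x (0-based)
  y <- round(call$bpB / bs)
  qmean <- function(rows, cols) {
    rows <- rows[rows >= 1 & rows <= n]
    cols <- cols[cols >= 1 & cols <= m]
    if (length(rows) == 0 || length(cols) == 0) return(NA_real_)
    mean(z[rows, cols, drop = FALSE])
  }
  w <- window
  q <- c(
    NW = qmean((x - w + 1):x, (y - w + 1):y),
    NE = qmean((x - w + 1):x, (y + 1):(y + w)),
    SW = qmean((x + 1):(x + w), (y - w + 1):y),
    SE = qmean((x + 1):(x + w), (y + 1):(y + w))
  )
  q[is.na(q)] <- -Inf
  ord <- order(q, decreasing = TRUE)
  m1 <- q[ord[1]]
  if (!is.finite(m1) || m1 < min_z) return("unclassified")
  hot <- names(q)[q > ratio * m1 & is.finite(q)]
  if (length(hot) == 1) return("unbalanced_translocation")
  if (length(hot) == 2) {
    if (setequal(hot, c("NW", "SE"))) return(diag_type)
    if (setequal(hot, c("NE", "SW"))) return(antidiag_type)
    return("unbalanced_translocation") # adjacent pair: one-sided strip
  }
  "unclassified"
}
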