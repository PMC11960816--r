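#' Pipeline configuration
#'
#' Collects the tunable parameters of the caller. Defaults correspond to a
#' 50 kb working bin size: the saliency window half-width `k = 10` spans
#' about 1 Mb, the TV regularization weight is 0.2, and the segment threshold
#' adapts to sequencing depth — 0.6 for deep maps (at least 1e8 total
#' contacts, where domain structure is crisp and a stricter cutoff pays off),
#' 0.5 otherwise. An explicit `t` always wins over the automatic rule.
#'
#' @param binsize Working bin size in bp.
#' @param k Saliency window half-width in bins.
#' @param lambda TV regularization weight.
#' @param t Segment-acceptance threshold in `(0, 1)`, or `NULL` for the
#'   depth-based automatic rule.
#' @param max_iter,tol TV solver controls.
#' @param min_cells Minimum segment size in cells.
#' @param merge_expand Segment-consolidation expansion fraction (see
#'   [merge_segments()]); 0 disables consolidation.
#' @param fine_binsize Fine bin size for breakpoint refinement, bp.
#' @param tol_intra,tol_inter Evaluation mismatch tolerances, bp.
#' @param del_frac,dup_frac Coverage-based typing thresholds.
#' @return A list of class `sv_config`.
#' @export
sv_config <- function(binsize = 50e3, k = 10, lambda = 0.2, t = NULL,
                      max_iter = 40, tol = 1e-6, min_cells = 2,
                      merge_expand = 0.5, fine_binsize = 10e3,
                      tol_intra = 100e3, tol_inter = 1e6,
                      del_frac = 0.9, dup_frac = 1.1) {
  stopifnot(k >= 1, lambda >= 0, is.null(t) || (t > 0 && t < 1))
  structure(
    list(
      binsize = binsize, k = k, lambda = lambda, t = t,
      max_iter = max_iter, tol = tol, min_cells = min_cells,
      merge_expand = merge_expand, fine_binsize = fine_binsize,
      tol_intra = tol_intra, tol_inter = tol_inter,
      del_frac = del_frac, dup_frac = dup_frac
    ),
    class = "sv_config"
  )
}

#' Call structural variants from contact matrices
#'
#' Runs the full detection pipeline on every supplied chromosome pair:
#' distance-stratified (intra) or global (inter) z-score normalization,
#' local-contrast saliency, total-variation segmentation, extraction of
#' above-threshold segments, and SV typing from coverage and junction
#' geometry. The result is one tidy tibble of calls.
#'
#' Each call reports the bounding box of its segment as the two breakpoint
#' regions (fragment A = rows, fragment B = columns) plus point breakpoint
#' estimates `bpA`/`bpB` taken at the segment's saliency peak — the edge of
#' the peak bin facing away from the bulk of the segment, which is where the
#' junction sits under a decaying contact model.
#'
#' @param x An `hic_simulation`, a single [contact_matrix()], or a (possibly
#'   named) list of contact matrices.
#' @param config An [sv_config()].
#' @param covariates Optional named list (by chromosome) of per-bin covariate
#'   tables for coverage bias correction.
#' @param verbose Log per-stage progress to stderr?
#' @return A tibble of SV calls (see [write_sv_calls()] for columns, plus
#'   `bpA`, `bpB`).
#' @export
call_svs <- function(x, config = sv_config(), covariates = NULL,
                     verbose = FALSE) {
  mats <- if (inherits(x, "hic_simulation")) {
    x$matrices
  } else if (inherits(x, "contact_matrix")) {
    list(x)
  } else {
    x
  }
  stopifnot(all(vapply(mats, inherits, logical(1), "contact_matrix")))
  t_use <- config$t %||% if (total_contacts(mats) >= 1e8) 0.6 else 0.5
  say <- function(...) if (verbose) message(sprintf(...))
  say("segment threshold t = %.2f", t_use)

  zs <- list()
  calls <- list()
  for (m in mats) {
    key <- paste0(m$chromA, "|", m$chromB)
    t0 <- proc.time()[["elapsed"]]
    Z <- if (m$is_intra) distance_normalize(m) else trans_normalize(m)
    B <- saliency_map(Z, k = config$k)
    S <- tv_denoise(B, config$lambda, config$max_iter, config$tol)
    segs <- extract_segments(S, t_use, config$min_cells)
    segs <- merge_segments(segs, config$merge_expand)
    zs[[key]] <- Z
    calls[[key]] <- segments_to_calls(segs, S)
    say(
      "%s: %d segment(s) [%.1f s]", key, nrow(segs),
      proc.time()[["elapsed"]] - t0
    )
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) {
    return(validate_sv_calls(tibble::tibble(
      chromA = character(), startA = numeric(), endA = numeric(),
      chromB = character(), startB = numeric(), endB = numeric(),
      name = character(), score = numeric(), sv_type = character(),
      bpA = numeric(), bpB = numeric()
    )))
  }
  profiles <- list()
  for (m in mats) {
    if (m$is_intra) {
      profiles[[m$chromA]] <- coverage_profile(m, covariates[[m$chromA]])
    }
  }
  calls <- classify_sv(
    calls, profiles, zs,
    del_frac = config$del_frac, dup_frac = config$dup_frac,
    window = 2 * config$k
  )
  calls$name <- sprintf("sv_%04d", seq_len(nrow(calls)))
  validate_sv_calls(calls[, c(sv_call_columns, "bpA", "bpB")])
}

#' Convert extracted segments to SV calls
#'
#' @param segments An [extract_segments()] tibble.
#' @param map The `tv_segmentation` (or `saliency_map`) the segments came
#'   from, providing axis metadata.
#' @return A tibble of calls with placeholder `sv_type = "unclassified"`.
#' @export
segments_to_calls <- function(segments, map) {
  if (nrow(segments) == 0) {
    return(tibble::tibble(
      chromA = character(), startA = numeric(), endA = numeric(),
      chromB = character(), startB = numeric(), endB = numeric(),
      name = character(), score = numeric(), sv_type = character(),
      bpA = numeric(), bpB = numeric()
    ))
  }
  bs <- map$binsize
  edge_bp <- function(peak, lo, hi, bins) {
    ## junction at the edge of the peak bin on the side where the segment
    ## does not extend (the signal decays away from the junction)
    left <- peak - lo
    right <- (hi - 1) - peak
    if (left <= right) bins$start[peak + 1] else bins$end[peak + 1]
  }
  tibble::tibble(
    chromA = map$chromA,
    startA = map$binsA$start[segments$row_lo + 1],
    endA = map$binsA$end[segments$row_hi],
    chromB = map$chromB,
    startB = map$binsB$start[segments$col_lo + 1],
    endB = map$binsB$end[segments$col_hi],
    name = sprintf("seg_%03d", segments$segment),
    score = segments$mean_saliency,
    sv_type = "unclassified",
    bpA = purrr::pmap_dbl(
      segments[, c("peak_row", "row_lo", "row_hi")],
      function(peak_row, row_lo, row_hi) {
        edge_bp(peak_row, row_lo, row_hi, map$binsA)
      }
    ),
    bpB = purrr::pmap_dbl(
      segments[, c("peak_col", "col_lo", "col_hi")],
      function(peak_col, col_lo, col_hi) {
        edge_bp(peak_col, col_lo, col_hi, map$binsB)
      }
    )
  )
}

#' Refine breakpoints of all calls
#'
#' Applies [refine_breakpoints()] to each call, fetching the fine-resolution
#' junction neighbourhood from `fine_provider`.
#'
#' @param calls Tibble of SV calls with `bpA`/`bpB` columns.
#' @param fine_provider Function of one call (one-row tibble) returning a
#'   fine [contact_matrix()] of its junction neighbourhood, e.g. a closure
#'   around [simulate_fine_submatrix()] or a finer-resolution file reader.
#' @param coarse_binsize Coarse bin size in bp.
#' @return The calls with refined `bpA`/`bpB`.
#' @export
refine_calls <- function(calls, fine_provider, coarse_binsize = 50e3) {
  if (nrow(calls) == 0) return(calls)
  dplyr::bind_rows(lapply(seq_len(nrow(calls)), function(i) {
    refine_breakpoints(calls[i, ], fine_provider(calls[i, ]), coarse_binsize)
  }))
}

#' One-call simulation-to-evaluation benchmark
#'
#' Simulates a sample (mixing in normal cells when `config$purity < 1`),
#' runs the caller, and evaluates against the simulation truth.
#'
#' @param sim_cfg A [sim_config()].
#' @param call_cfg An [sv_config()].
#' @param verbose Log progress?
#' @return A list: `sim`, `calls`, `eval` (an `sv_eval`).
#' @export
run_benchmark <- function(sim_cfg, call_cfg = sv_config(), verbose = FALSE) {
  sim <- if (sim_cfg$purity < 1) {
    simulate_mixture(sim_cfg)
  } else {
    simulate_contact_matrix(sim_cfg)
  }
  calls <- call_svs(sim, call_cfg, verbose = verbose)
  ev <- evaluate_calls(
    calls, sim$truth, call_cfg$tol_intra, call_cfg$tol_inter
  )
  list(sim = sim, calls = calls, eval = ev)
}

#' Write simulated matrices and truth to plain-text files
#'
#' Each chromosome-pair matrix goes to `<prefix>.<chromA>_<chromB>.tsv`, and
#' the truth junctions to `<prefix>.truth.tsv`.
#'
#' @param sim An `hic_simulation`.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- character()
  for (nm in names(sim$matrices)) {
    m <- sim$matrices[[nm]]
    p <- sprintf("%s.%s_%s.tsv", prefix, m$chromA, m$chromB)
    write_matrix_tsv(m, p)
    paths <- c(paths, p)
  }
  tp <- paste0(prefix, ".truth.tsv")
  readr::write_tsv(sim$truth, tp)
  invisible(c(paths, tp))
}
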