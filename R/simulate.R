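#' Simulation configuration
#'
#' Describes a synthetic Hi-C experiment: chromosome sizes, bin size, the
#' power-law distance-decay exponent, target sequencing depth (total contact
#' count), tumour purity, RNG seed and the list of rearrangements to embed.
#'
#' The generative model is deliberately simple but carries the
#' detection-relevant structure of real data: expected contacts between two
#' bins decay as `C * (1 + d)^(-alpha)` with `d` their distance *in the
#' rearranged (derived) genome*, so every embedded event rescales its
#' neighbourhood by the ratio of new to old expected interactions. Pairs on
#' different derived chromosomes receive a small constant trans rate.
#' Observed counts are Poisson draws around the expectation.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp (default two
#'   100 Mb chromosomes).
#' @param binsize Bin size in bp (default 50 kb).
#' @param alpha Distance-decay exponent (default 1, the canonical intra-
#'   chromosomal decay).
#' @param base_depth Target total contact count (default 6e6, the deepest
#'   simulated operating point; 2e6 and 4e6 are the shallow ones).
#' @param trans_frac Trans (cross-chromosome) contact rate as a fraction of
#'   the intra expectation at 1 Mb distance (default 0.01).
#' @param purity Tumour fraction in `[0, 1]` used by [simulate_mixture()].
#' @param seed RNG seed.
#' @param events Tibble of rearrangements (see [sv_events()] /
#'   [default_sv_events()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(simA = 100e6, simB = 100e6),
                       binsize = 50e3, alpha = 1, base_depth = 6e6,
                       trans_frac = 0.01, purity = 1, seed = 1,
                       events = default_sv_events()) {
  stopifnot(
    all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
    binsize > 0, alpha > 0, base_depth > 0,
    purity >= 0, purity <= 1, trans_frac >= 0
  )
  events <- validate_sv_events(events, chrom_lengths)
  structure(
    list(
      chrom_lengths = chrom_lengths, binsize = binsize, alpha = alpha,
      base_depth = base_depth, trans_frac = trans_frac, purity = purity,
      seed = as.integer(seed), events = events
    ),
    class = "sim_config"
  )
}

#' Build a table of SV events to embed
#'
#' Event types: `deletion`, `duplication` (tandem, `copy_gain` extra copies),
#' `inversion` (all three: interval `[posA, posA + span)` on `chromA`),
#' `translocation` (intra-chromosomal cut-and-paste: the interval is excised
#' and inserted before `posB` on the same chromosome) and
#' `inter_translocation` (reciprocal exchange of the tails at `posA` on
#' `chromA` and `posB` on `chromB`). Events sharing a `chain` label form one
#' complex SV and are applied sequentially.
#'
#' @param sv_type,chromA,posA,span,chromB,posB,copy_gain,chain Parallel
#'   vectors (recycled where sensible).
#' @return A tibble of events.
#' @export
sv_events <- function(sv_type, chromA, posA, span = NA_real_,
                      chromB = NA_character_, posB = NA_real_,
                      copy_gain = 1L, chain = NA_character_) {
  tibble::tibble(
    sv_type = sv_type, chromA = chromA, posA = posA, span = span,
    chromB = chromB, posB = posB, copy_gain = copy_gain, chain = chain
  )
}

#' Default embedded rearrangements
#'
#' Seven SVs on two 100 Mb chromosomes, spans 1-2 Mb: one each of deletion,
#' duplication, inversion, intra-chromosomal (cut-and-paste) translocation
#' and reciprocal inter-chromosomal translocation, plus two complex chains
#' (deletion+inversion, duplication+deletion). Events are spaced at least
#' 10 Mb apart so their junction neighbourhoods do not interact.
#'
#' @return A tibble of events.
#' @export
default_sv_events <- function() {
  dplyr::bind_rows(
    sv_events("deletion", "simA", 20e6, span = 1.5e6),
    sv_events("duplication", "simA", 35e6, span = 1.5e6),
    sv_events("inversion", "simA", 50e6, span = 1.5e6),
    sv_events("translocation", "simA", 65e6, span = 1.5e6,
              chromB = "simA", posB = 80e6),
    sv_events("inter_translocation", "simA", 92e6,
              chromB = "simB", posB = 30e6),
    sv_events(c("deletion", "inversion"), "simB", c(50e6, 51e6),
              span = c(1e6, 1.5e6), chain = "c1"),
    sv_events(c("duplication", "deletion"), "simB", c(70e6, 73e6),
              span = c(1.5e6, 1e6), chain = "c2")
  )
}

validate_sv_events <- function(events, chrom_lengths) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) return(events)
  needed <- c("sv_type", "chromA", "posA")
  stopifnot(all(needed %in% names(events)))
  if (!"span" %in% names(events)) events$span <- NA_real_
  if (!"chromB" %in% names(events)) events$chromB <- NA_character_
  if (!"posB" %in% names(events)) events$posB <- NA_real_
  if (!"copy_gain" %in% names(events)) events$copy_gain <- 1L
  if (!"chain" %in% names(events)) events$chain <- NA_character_
  known <- c("deletion", "duplication", "inversion", "translocation",
             "inter_translocation")
  if (!all(events$sv_type %in% known)) {
    stop("unknown event type(s): ",
         paste(setdiff(events$sv_type, known), collapse = ", "))
  }
  interval <- events$sv_type %in% c("deletion", "duplication", "inversion",
                                    "translocation")
  stopifnot(
    all(!is.na(events$span[interval])),
    all(events$chromA %in% names(chrom_lengths)),
    all(is.na(events$chromB) | events$chromB %in% names(chrom_lengths)),
    all(events$posA >= 0),
    all(is.na(events$span) |
          events$posA + events$span <= chrom_lengths[events$chromA])
  )
  ## simple (non-chained) event footprints must not overlap
  foot <- events |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::filter(is.na(.data$chain))
  if (nrow(foot) > 1) {
    ivals <- dplyr::bind_rows(
      dplyr::transmute(foot, .data$id, chrom = .data$chromA,
                       lo = .data$posA,
                       hi = ifelse(is.na(.data$span), .data$posA + 1,
                                   .data$posA + .data$span)),
      dplyr::transmute(
        dplyr::filter(foot, !is.na(.data$posB)), .data$id,
        chrom = .data$chromB, lo = .data$posB, hi = .data$posB + 1
      )
    ) |> dplyr::arrange(.data$chrom, .data$lo)
    by_chrom <- split(ivals, ivals$chrom)
    for (iv in by_chrom) {
      if (nrow(iv) > 1 &&
          any(iv$lo[-1] < iv$hi[-nrow(iv)] & iv$id[-1] != iv$id[-nrow(iv)])) {
        stop("overlapping simple events; mark them as a chain if intended")
      }
    }
  }
  events
}

#' Map from the rearranged (derived) genome back to reference bins
#'
#' Applies the configured events sequentially to the binned reference genome:
#' deletions remove bins, duplications insert repeated copies after the
#' original, inversions reverse bin order and flip strand, intra-chromosomal
#' translocations excise a block and splice it in before the acceptor bin,
#' and reciprocal inter-chromosomal translocations exchange chromosome tails.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per derived-genome bin: `derived_chrom`,
#'   `derived_pos` (0-based bin within the derived chromosome), `ref_chrom`,
#'   `ref_bin` (0-based bin in the reference), `strand` (`"+"`/`"-"`).
#' @export
build_rearranged_map <- function(config) {
  bs <- config$binsize
  chroms <- lapply(names(config$chrom_lengths), function(ch) {
    n <- ceiling(config$chrom_lengths[[ch]] / bs)
    tibble::tibble(ref_chrom = ch, ref_bin = seq_len(n) - 1L, strand = "+")
  })
  names(chroms) <- names(config$chrom_lengths)

  events <- config$events
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    if (ev$sv_type == "inter_translocation") {
      xa <- locate_point(chroms, ev$chromA, bin_of(ev$posA, bs))
      xb <- locate_point(chroms, ev$chromB, bin_of(ev$posB, bs))
      ta <- chroms[[xa$chrom]]
      tb <- chroms[[xb$chrom]]
      chroms[[xa$chrom]] <- dplyr::bind_rows(
        ta[seq_len(xa$idx - 1), ], tb[seq(xb$idx, nrow(tb)), ]
      )
      chroms[[xb$chrom]] <- dplyr::bind_rows(
        tb[seq_len(xb$idx - 1), ], ta[seq(xa$idx, nrow(ta)), ]
      )
      next
    }
    bins <- seq.int(bin_of(ev$posA, bs), bin_of(ev$posA + ev$span, bs) - 1L)
    run <- locate_run(chroms, ev$chromA, bins)
    t <- chroms[[run$chrom]]
    block <- t[run$idx, ]
    if (ev$sv_type == "deletion") {
      chroms[[run$chrom]] <- t[-run$idx, ]
    } else if (ev$sv_type == "duplication") {
      copies <- block[rep(seq_len(nrow(block)), ev$copy_gain), ]
      chroms[[run$chrom]] <- dplyr::bind_rows(
        t[seq_len(max(run$idx)), ], copies,
        if (max(run$idx) < nrow(t)) t[seq(max(run$idx) + 1, nrow(t)), ]
      )
    } else if (ev$sv_type == "inversion") {
      flipped <- block[rev(seq_len(nrow(block))), ]
      flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
      t[run$idx, ] <- flipped
      chroms[[run$chrom]] <- t
    } else if (ev$sv_type == "translocation") {
      rest <- t[-run$idx, ]
      chroms[[run$chrom]] <- rest
      x <- locate_point(chroms, ev$chromB, bin_of(ev$posB, bs))
      tt <- chroms[[x$chrom]]
      chroms[[x$chrom]] <- dplyr::bind_rows(
        tt[seq_len(x$idx - 1), ], block, tt[seq(x$idx, nrow(tt)), ]
      )
    }
  }
  purrr::imap_dfr(chroms, function(t, name) {
    dplyr::mutate(t,
      derived_chrom = name, derived_pos = dplyr::row_number() - 1L,
      .before = 1
    )
  })
}

bin_of <- function(pos, bs) {
  bin <- pos / bs
  if (abs(bin - round(bin)) > 1e-6) {
    stop("event coordinate ", pos, " is not a multiple of the bin size ", bs)
  }
  as.integer(round(bin))
}

locate_run <- function(chroms, chrom, bins) {
  for (name in names(chroms)) {
    t <- chroms[[name]]
    idx <- which(t$ref_chrom == chrom & t$strand == "+" &
                   t$ref_bin %in% bins)
    if (length(idx) == length(bins) && all(diff(idx) == 1) &&
        all(t$ref_bin[idx] == bins)) {
      return(list(chrom = name, idx = idx))
    }
  }
  stop("cannot locate contiguous block for bins ", bins[1], "..",
       bins[length(bins)], " of ", chrom)
}

locate_point <- function(chroms, chrom, bin) {
  for (name in names(chroms)) {
    t <- chroms[[name]]
    idx <- which(t$ref_chrom == chrom & t$ref_bin == bin & t$strand == "+")
    if (length(idx) >= 1) return(list(chrom = name, idx = idx[1]))
  }
  stop("cannot locate bin ", bin, " of ", chrom)
}

## --- ground truth ----------------------------------------------------------

#' Derive ground-truth junctions from a rearrangement map
#'
#' Scans the derived genome for non-canonical adjacencies (consecutive bins
#' that are not reference neighbours on the same strand). Each junction is
#' reported with its two reference breakpoints and a type computed the way an
#' ideal classifier would: chromosome change first, then the copy number of
#' the region between the breakpoints (from the derived bin copy counts),
#' then orientation — a *paired* strand-flip junction (both wings present at
#' the same coordinates) is an inversion, a solitary copy-neutral junction is
#' an unbalanced translocation.
#'
#' @param map A [build_rearranged_map()] result.
#' @param config The matching [sim_config()].
#' @return A tibble: `chromA`, `posA`, `chromB`, `posB`, `sv_type`,
#'   `n_junctions` (how many raw junctions collapsed into the record).
#' @export
derive_truth <- function(map, config) {
  bs <- config$binsize
  chrom_order <- names(config$chrom_lengths)
  copies <- dplyr::count(map, .data$ref_chrom, .data$ref_bin, name = "copies")
  jx <- list()
  for (dc in unique(map$derived_chrom)) {
    t <- map[map$derived_chrom == dc, ]
    n <- nrow(t)
    if (n < 2) next
    a <- t[-n, ]
    b <- t[-1, ]
    canonical <- a$ref_chrom == b$ref_chrom & a$strand == b$strand &
      ((a$strand == "+" & b$ref_bin == a$ref_bin + 1L) |
         (a$strand == "-" & b$ref_bin == a$ref_bin - 1L))
    bad <- which(!canonical)
    for (i in bad) {
      bp1 <- if (a$strand[i] == "+") (a$ref_bin[i] + 1) * bs else a$ref_bin[i] * bs
      s1 <- if (a$strand[i] == "+") "+" else "-"
      bp2 <- if (b$strand[i] == "+") b$ref_bin[i] * bs else (b$ref_bin[i] + 1) * bs
      s2 <- if (b$strand[i] == "+") "-" else "+"
      rec <- tibble::tibble(
        chromA = a$ref_chrom[i], posA = bp1, sideA = s1,
        chromB = b$ref_chrom[i], posB = bp2, sideB = s2
      )
      swap <- (rec$chromA == rec$chromB & rec$posA > rec$posB) |
        (rec$chromA != rec$chromB &
           match(rec$chromA, chrom_order) > match(rec$chromB, chrom_order))
      if (swap) {
        rec <- tibble::tibble(
          chromA = rec$chromB, posA = rec$posB, sideA = rec$sideB,
          chromB = rec$chromA, posB = rec$posA, sideB = rec$sideA
        )
      }
      jx[[length(jx) + 1]] <- rec
    }
  }
  if (length(jx) == 0) {
    return(tibble::tibble(
      chromA = character(), posA = numeric(), chromB = character(),
      posB = numeric(), sv_type = character(), n_junctions = integer()
    ))
  }
  jx <- dplyr::bind_rows(jx)
  jx |>
    dplyr::group_by(.data$chromA, .data$posA, .data$chromB, .data$posB) |>
    dplyr::summarise(
      sv_type = junction_type(
        .data$chromA[1], .data$posA[1], .data$chromB[1], .data$posB[1],
        .data$sideA, .data$sideB, copies, bs
      ),
      n_junctions = dplyr::n(),
      .groups = "drop"
    )
}

junction_type <- function(chromA, posA, chromB, posB, sideA, sideB,
                          copies, bs) {
  if (chromA != chromB) return("inter_translocation")
  lo <- round(posA / bs)
  hi <- round(posB / bs) - 1L
  if (hi >= lo) {
    idx <- tibble::tibble(ref_chrom = chromA, ref_bin = seq.int(lo, hi))
    idx <- dplyr::left_join(idx, copies, by = c("ref_chrom", "ref_bin"))
    cn <- mean(ifelse(is.na(idx$copies), 0, idx$copies))
    if (cn < 0.9) return("deletion")
    if (cn > 1.1) return("duplication")
  }
  flips <- sideA == sideB
  if (any(flips) && length(unique(paste(sideA, sideB)[flips])) >= 2) {
    return("inversion") # both wings present: ++ and --
  }
  "unbalanced_translocation"
}

## --- expected matrices and sampling ----------------------------------------

#' Simulate Hi-C contact matrices with embedded SVs
#'
#' Computes, for every chromosome pair, the expected contact matrix of the
#' rearranged genome under the power-law decay model (each reference bin pair
#' accumulates the expectation of all of its derived-copy pairs), scales the
#' genome-wide expectation to `base_depth` total contacts, and draws Poisson
#' counts. Intra-chromosomal matrices are sampled on the upper triangle and
#' mirrored, so they are exactly symmetric.
#'
#' @param config A [sim_config()].
#' @param keep_expected Keep the expected (noise-free) matrices in the result?
#' @return An object of class `hic_simulation`: `matrices` (named list of
#'   [contact_matrix()], names `"chrom1|chrom2"`), `truth` (see
#'   [derive_truth()]), `map`, `scale` (the depth-calibration constant `C`),
#'   and `config`. With `keep_expected`, also `expected`.
#' @export
simulate_contact_matrix <- function(config, keep_expected = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bs <- config$binsize
  chrom_names <- names(config$chrom_lengths)
  n_bins <- vapply(config$chrom_lengths, function(l) {
    as.integer(ceiling(l / bs))
  }, integer(1))
  offsets <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offsets) <- chrom_names
  n_ref <- sum(n_bins)

  map <- build_rearranged_map(config)
  trans_const <- config$trans_frac * (1 + 1e6 / bs)^(-config$alpha)

  ## expected matrix over derived bins, then fold back onto reference bins
  n_der <- nrow(map)
  der_chrom <- map$derived_chrom
  der_pos <- map$derived_pos
  D <- matrix(trans_const, n_der, n_der)
  for (dc in unique(der_chrom)) {
    sel <- which(der_chrom == dc)
    p <- der_pos[sel]
    D[sel, sel] <- (1 + abs(outer(p, p, "-")))^(-config$alpha)
  }
  ref_global <- offsets[map$ref_chrom] + map$ref_bin + 1L
  A <- Matrix::sparseMatrix(
    i = seq_len(n_der), j = ref_global, x = 1, dims = c(n_der, n_ref)
  )
  E <- as.matrix(Matrix::crossprod(A, D %*% A))
  rm(D)
  total_rel <- (sum(E) + sum(diag(E))) / 2
  C <- config$base_depth / total_rel
  E <- E * C

  matrices <- list()
  for (i in seq_along(chrom_names)) {
    for (j in seq(i, length(chrom_names))) {
      ca <- chrom_names[i]
      cb <- chrom_names[j]
      block <- E[offsets[ca] + seq_len(n_bins[ca]),
                 offsets[cb] + seq_len(n_bins[cb]), drop = FALSE]
      counts <- sample_counts(block, intra = i == j)
      m <- contact_matrix(counts, ca, cb, binsize = bs,
        binsA = bin_table(ca, config$chrom_lengths[[ca]], bs),
        binsB = bin_table(cb, config$chrom_lengths[[cb]], bs)
      )
      matrices[[paste0(ca, "|", cb)]] <- m
    }
  }
  out <- list(
    matrices = matrices, truth = derive_truth(map, config), map = map,
    scale = C, config = config
  )
  if (keep_expected) {
    out$expected <- list()
    for (i in seq_along(chrom_names)) {
      for (j in seq(i, length(chrom_names))) {
        ca <- chrom_names[i]
        cb <- chrom_names[j]
        out$expected[[paste0(ca, "|", cb)]] <-
          E[offsets[ca] + seq_len(n_bins[ca]),
            offsets[cb] + seq_len(n_bins[cb]), drop = FALSE]
      }
    }
  }
  structure(out, class = "hic_simulation")
}

sample_counts <- function(expected, intra) {
  n <- nrow(expected)
  m <- ncol(expected)
  if (intra) {
    counts <- matrix(0, n, m)
    up <- upper.tri(counts, diag = TRUE)
    counts[up] <- rpois(sum(up), expected[up])
    counts <- counts + t(counts) - diag(diag(counts))
  } else {
    counts <- matrix(rpois(n * m, expected), n, m)
  }
  counts
}

#' @export
print.hic_simulation <- function(x, ...) {
  cat(sprintf(
    "<hic_simulation> %d chromosome pair(s), %d truth junction(s), depth %.3g\n",
    length(x$matrices), nrow(x$truth), x$config$base_depth
  ))
  invisible(x)
}

#' Mix a tumour and a normal contact matrix at a given purity
#'
#' Emulates sample heterogeneity: each tumour count is binomially thinned at
#' rate `purity`, each normal count at `1 - purity`, and the thinned counts
#' are summed, so the expected mixture is
#' `purity * E[tumour] + (1 - purity) * E[normal]`. Intra-chromosomal
#' matrices are thinned on the upper triangle and mirrored.
#'
#' @param tumor,normal [contact_matrix()] objects of identical shape.
#' @param purity Tumour fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return A [contact_matrix()].
#' @export
mix_purity <- function(tumor, normal, purity, seed = 1) {
  stopifnot(
    inherits(tumor, "contact_matrix"), inherits(normal, "contact_matrix"),
    all(dim(tumor$counts) == dim(normal$counts)),
    purity >= 0, purity <= 1
  )
  if (purity == 1) return(tumor)
  if (purity == 0) return(normal)
  set.seed(seed)
  thin <- function(m, p) {
    x <- m$counts
    if (m$is_intra) {
      up <- upper.tri(x, diag = TRUE)
      v <- numeric(length(x))
      dim(v) <- dim(x)
      v[up] <- rbinom(sum(up), size = as.integer(round(x[up])), prob = p)
      v + t(v) - diag(diag(v))
    } else {
      matrix(rbinom(length(x), size = as.integer(round(x)), prob = p),
             nrow(x), ncol(x))
    }
  }
  mixed <- thin(tumor, purity) + thin(normal, 1 - purity)
  contact_matrix(mixed, tumor$chromA, tumor$chromB,
    binsize = tumor$binsize, binsA = tumor$binsA, binsB = tumor$binsB
  )
}

#' Simulate a purity-mixed sample
#'
#' Simulates the rearranged (tumour) sample and an event-free (normal) sample
#' at the same depth and mixes every chromosome pair at `config$purity`.
#' Ground truth is the tumour truth.
#'
#' @param config A [sim_config()] with `purity < 1`.
#' @return An `hic_simulation` whose matrices are the mixtures.
#' @export
simulate_mixture <- function(config) {
  tumor <- simulate_contact_matrix(config)
  normal_cfg <- config
  normal_cfg$events <- config$events[0, ]
  normal_cfg$seed <- config$seed + 999983L
  normal <- simulate_contact_matrix(normal_cfg)
  mixed <- tumor
  for (nm in names(tumor$matrices)) {
    mixed$matrices[[nm]] <- mix_purity(
      tumor$matrices[[nm]], normal$matrices[[nm]], config$purity,
      seed = config$seed + match(nm, names(tumor$matrices))
    )
  }
  mixed
}

#' Simulate a fine-resolution submatrix around a junction
#'
#' Regenerates the contact neighbourhood of one candidate junction at a
#' smaller bin size under the same derived-genome decay model, for breakpoint
#' refinement. The depth calibration is carried over from the coarse
#' simulation (`C_fine = C * r^(alpha - 2)` with `r` the bin-size ratio, so
#' coarse-bin sums are preserved for the default decay).
#'
#' @param sim An `hic_simulation`.
#' @param chromA,bpA,chromB,bpB Junction coordinates in bp.
#' @param fine_binsize Fine bin size in bp (default 10 kb).
#' @param pad Neighbourhood half-width in coarse bins (default 2, so a
#'   breakpoint estimate that is off by a full coarse bin still lies in the
#'   window interior).
#' @param fine_map Optional precomputed fine-resolution
#'   [build_rearranged_map()] (cached across calls for speed).
#' @param seed RNG seed; defaults to the simulation seed.
#' @return A [contact_matrix()] whose rows cover the `bpA` neighbourhood and
#'   columns the `bpB` neighbourhood at `fine_binsize`.
#' @export
simulate_fine_submatrix <- function(sim, chromA, bpA, chromB, bpB,
                                    fine_binsize = 10e3, pad = 2,
                                    fine_map = NULL, seed = NULL) {
  config <- sim$config
  bs <- config$binsize
  r <- bs / fine_binsize
  stopifnot(r >= 1)
  if (is.null(fine_map)) fine_map <- build_fine_map(sim, fine_binsize)
  set.seed(seed %||% (config$seed + 7919L))

  window_bins <- function(chrom, bp) {
    n_fine <- ceiling(config$chrom_lengths[[chrom]] / fine_binsize)
    lo <- floor((bp - pad * bs) / fine_binsize)
    hi <- ceiling((bp + pad * bs) / fine_binsize) - 1
    seq.int(max(0, lo), min(n_fine - 1, hi))
  }
  rows <- window_bins(chromA, bpA)
  cols <- window_bins(chromB, bpB)
  lookup <- function(chrom, bins) {
    lapply(bins, function(b) {
      sel <- fine_map$ref_chrom == chrom & fine_map$ref_bin == b
      list(chrom = fine_map$derived_chrom[sel], pos = fine_map$derived_pos[sel])
    })
  }
  pa <- lookup(chromA, rows)
  pb <- lookup(chromB, cols)
  trans_const <- config$trans_frac * (1 + 1e6 / fine_binsize)^(-config$alpha)
  Cf <- sim$scale * r^(config$alpha - 2)
  E <- matrix(0, length(rows), length(cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      ci <- pa[[i]]
      cj <- pb[[j]]
      if (length(ci$pos) == 0 || length(cj$pos) == 0) next
      e <- 0
      for (u in seq_along(ci$pos)) {
        same <- cj$chrom == ci$chrom[u]
        e <- e + sum((1 + abs(cj$pos[same] - ci$pos[u]))^(-config$alpha)) +
          sum(!same) * trans_const
      }
      E[i, j] <- e * Cf
    }
  }
  counts <- matrix(rpois(length(E), E), nrow(E), ncol(E))
  bins_of <- function(chrom, bins) {
    len <- config$chrom_lengths[[chrom]]
    tibble::tibble(
      chrom = chrom, start = bins * fine_binsize,
      end = pmin((bins + 1) * fine_binsize, len),
      index = seq_along(bins) - 1L
    )
  }
  structure(
    list(
      counts = counts, chromA = chromA, chromB = chromB,
      binsA = bins_of(chromA, rows), binsB = bins_of(chromB, cols),
      binsize = fine_binsize, is_intra = FALSE
    ),
    class = "contact_matrix"
  )
}

#' Precompute the fine-resolution rearrangement map
#'
#' @param sim An `hic_simulation`.
#' @param fine_binsize Fine bin size in bp.
#' @return A [build_rearranged_map()] tibble at the fine bin size.
#' @export
build_fine_map <- function(sim, fine_binsize = 10e3) {
  cfg <- sim$config
  fine_cfg <- cfg
  fine_cfg$binsize <- fine_binsize
  build_rearranged_map(fine_cfg)
}
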