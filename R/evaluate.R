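#' Match predicted SV calls against ground truth
#'
#' A prediction matches a truth junction when the chromosome pair agrees and
#' *both* breakpoints lie within the applicable tolerance: the gap on each
#' side is the distance from the truth breakpoint to the predicted breakpoint
#' interval (zero when the point falls inside it). Matching is one-to-one and
#' greedy by ascending total gap, so the closest pairs are assigned first.
#'
#' @param pred Tibble of calls (columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, and optionally `score`, `sv_type`).
#' @param truth Tibble of truth junctions (`chromA`, `posA`, `chromB`,
#'   `posB`, optionally `sv_type`).
#' @param tol_intra Allowed mismatch in bp for intra-chromosomal SVs
#'   (default 100 kb).
#' @param tol_inter Allowed mismatch for inter-chromosomal SVs (default 1 Mb).
#' @return A tibble with one row per match: `pred_id`, `truth_id`, `gapA`,
#'   `gapB`, `type_match`.
#' @export
match_calls <- function(pred, truth, tol_intra = 100e3, tol_inter = 1e6) {
  pred <- tibble::as_tibble(pred)
  truth <- tibble::as_tibble(truth)
  empty <- tibble::tibble(
    pred_id = integer(), truth_id = integer(),
    gapA = numeric(), gapB = numeric(), type_match = logical()
  )
  if (nrow(pred) == 0 || nrow(truth) == 0) return(empty)
  pred$pred_id <- seq_len(nrow(pred))
  truth$truth_id <- seq_len(nrow(truth))

  gap_point <- function(lo, hi, p) pmax(0, lo - p, p - hi)
  cand <- list()
  for (ti in seq_len(nrow(truth))) {
    tr <- truth[ti, ]
    tol <- if (tr$chromA == tr$chromB) tol_intra else tol_inter
    same <- pred$chromA == tr$chromA & pred$chromB == tr$chromB
    swapped <- pred$chromA == tr$chromB & pred$chromB == tr$chromA & !same
    for (set in list(
      list(sel = same, pa = "A", pb = "B"),
      list(sel = swapped, pa = "B", pb = "A")
    )) {
      if (!any(set$sel)) next
      p <- pred[set$sel, ]
      gA <- gap_point(p[[paste0("start", set$pa)]], p[[paste0("end", set$pa)]], tr$posA)
      gB <- gap_point(p[[paste0("start", set$pb)]], p[[paste0("end", set$pb)]], tr$posB)
      ok <- gA <= tol & gB <= tol
      if (any(ok)) {
        cand[[length(cand) + 1]] <- tibble::tibble(
          pred_id = p$pred_id[ok], truth_id = tr$truth_id,
          gapA = gA[ok], gapB = gB[ok],
          type_match = if ("sv_type" %in% names(p) && "sv_type" %in% names(tr)) {
            p$sv_type[ok] == tr$sv_type
          } else {
            NA
          }
        )
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- dplyr::arrange(dplyr::bind_rows(cand), .data$gapA + .data$gapB)
  used_p <- logical(nrow(pred))
  used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pi <- cand$pred_id[i]
    ti <- cand$truth_id[i]
    if (!used_p[pi] && !used_t[ti]) {
      used_p[pi] <- TRUE
      used_t[ti] <- TRUE
      keep[i] <- TRUE
    }
  }
  cand[keep, ]
}

#' Precision, recall and F1 from a matching
#'
#' `P = TP / n_pred` (0 when nothing was predicted), `R = TP / n_true`, and
#' F1 is their harmonic mean (0 when `P + R = 0`).
#'
#' @param matching A [match_calls()] result (its row count is TP).
#' @param n_pred,n_true Number of predictions and truth junctions.
#' @return A one-row tibble: `n_true`, `n_pred`, `n_tp`, `precision`,
#'   `recall`, `f1`.
#' @export
precision_recall_f1 <- function(matching, n_pred, n_true) {
  if (n_true == 0) stop("no ground truth events to evaluate against")
  tp <- nrow(matching)
  p <- if (n_pred > 0) tp / n_pred else 0
  r <- tp / n_true
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(
    n_true = n_true, n_pred = n_pred, n_tp = tp,
    precision = p, recall = r, f1 = f1
  )
}

#' Evaluate a callset against simulation truth
#'
#' Runs the mismatch-tolerant matching and reports precision/recall/F1
#' overall and split into intra- and inter-chromosomal SVs, plus the typing
#' accuracy over matched pairs and a per-type breakdown.
#'
#' @inheritParams match_calls
#' @return An object of class `sv_eval` with fields `metrics` (tibble, one
#'   row per class), `matching`, `typing_accuracy`, `by_type`,
#'   `tolerance_intra`, `tolerance_inter`.
#' @export
evaluate_calls <- function(pred, truth, tol_intra = 100e3, tol_inter = 1e6) {
  pred <- tibble::as_tibble(pred)
  truth <- tibble::as_tibble(truth)
  matching <- match_calls(pred, truth, tol_intra, tol_inter)
  intra_p <- pred$chromA == pred$chromB
  intra_t <- truth$chromA == truth$chromB
  class_of_match <- matching$truth_id %in% which(intra_t)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(
      precision_recall_f1(matching, nrow(pred), nrow(truth)),
      class = "all", .before = 1
    ),
    if (sum(intra_t) > 0) {
      dplyr::mutate(
        precision_recall_f1(
          matching[class_of_match, ], sum(intra_p), sum(intra_t)
        ),
        class = "intra", .before = 1
      )
    },
    if (sum(!intra_t) > 0) {
      dplyr::mutate(
        precision_recall_f1(
          matching[!class_of_match, ], sum(!intra_p), sum(!intra_t)
        ),
        class = "inter", .before = 1
      )
    }
  )
  typing <- NA_real_
  by_type <- NULL
  if (nrow(matching) > 0 && !all(is.na(matching$type_match))) {
    typing <- mean(matching$type_match)
    by_type <- matching |>
      dplyr::mutate(truth_type = truth$sv_type[.data$truth_id]) |>
      dplyr::group_by(.data$truth_type) |>
      dplyr::summarise(
        n_matched = dplyr::n(),
        type_accuracy = mean(.data$type_match),
        .groups = "drop"
      )
  }
  structure(
    list(
      metrics = metrics, matching = matching, typing_accuracy = typing,
      by_type = by_type, tolerance_intra = tol_intra,
      tolerance_inter = tol_inter
    ),
    class = "sv_eval"
  )
}

#' @export
print.sv_eval <- function(x, ...) {
  cat("<sv_eval>\n")
  print(x$metrics)
  if (!is.na(x$typing_accuracy)) {
    cat(sprintf("typing accuracy over matches: %.3f\n", x$typing_accuracy))
  }
  invisible(x)
}

#' @rdname evaluate_calls
#' @param x An `sv_eval` object.
#' @param ... Unused.
#' @method tidy sv_eval
#' @export
tidy.sv_eval <- function(x, ...) x$metrics

#' @rdname evaluate_calls
#' @method glance sv_eval
#' @export
glance.sv_eval <- function(x, ...) {
  overall <- x$metrics[x$metrics$class == "all", ]
  dplyr::mutate(
    overall[, c("n_true", "n_pred", "n_tp", "precision", "recall", "f1")],
    typing_accuracy = x$typing_accuracy,
    tolerance_intra = x$tolerance_intra,
    tolerance_inter = x$tolerance_inter
  )
}

#' Precision-recall curve over call-score thresholds
#'
#' Sweeps descending score thresholds, recomputing the matching and the
#' precision/recall point for the calls at or above each threshold, and
#' reports the trapezoidal area under the curve (over recall, anchored at
#' recall 0 with the precision of the strictest threshold).
#'
#' @inheritParams match_calls
#' @return An object of class `pr_curve`: `points` (tibble `threshold`,
#'   `precision`, `recall`) and `auprc`.
#' @export
pr_curve <- function(pred, truth, tol_intra = 100e3, tol_inter = 1e6) {
  pred <- tibble::as_tibble(pred)
  stopifnot("score" %in% names(pred))
  thresholds <- sort(unique(pred$score), decreasing = TRUE)
  points <- purrr::map_dfr(thresholds, function(s) {
    sub <- pred[pred$score >= s, ]
    m <- match_calls(sub, truth, tol_intra, tol_inter)
    dplyr::mutate(
      precision_recall_f1(m, nrow(sub), nrow(truth))[, c("precision", "recall")],
      threshold = s, .before = 1
    )
  })
  r <- c(0, points$recall)
  p <- c(points$precision[1], points$precision)
  auprc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  structure(list(points = points, auprc = auprc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUPR = %.4f\n", nrow(x$points), x$auprc))
  invisible(x)
}

#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "recall", y = "precision",
      subtitle = sprintf("AUPR = %.3f", object$auprc)
    ) +
    ggplot2::theme_minimal()
}
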