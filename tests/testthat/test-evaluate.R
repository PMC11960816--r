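truth_points <- function() {
  tibble::tibble(
    chromA = "chr1", posA = c(10e6, 30e6, 50e6),
    chromB = "chr1", posB = c(12e6, 33e6, 55e6),
    sv_type = c("deletion", "inversion", "duplication")
  )
}

pred_at <- function(posA, posB, width = 1e5, chromA = "chr1",
                    chromB = "chr1", score = 0.8, sv_type = "deletion") {
  tibble::tibble(
    chromA = chromA, startA = posA - width / 2, endA = posA + width / 2,
    chromB = chromB, startB = posB - width / 2, endB = posB + width / 2,
    name = sprintf("p%03d", seq_along(posA)), score = score,
    sv_type = sv_type
  )
}

test_that("exact predictions all match and tolerance gates marginal ones", {
  tr <- truth_points()
  exact <- pred_at(tr$posA, tr$posB,
                   sv_type = c("deletion", "inversion", "duplication"))
  m <- match_calls(exact, tr)
  expect_equal(nrow(m), 3)
  expect_true(all(m$type_match))

  # breakpoint 40 kb beyond the interval edge: in at 50 kb, out at 10 kb
  off <- pred_at(10e6 + 40e3 + 5e4, 12e6)
  expect_equal(nrow(match_calls(off, tr, tol_intra = 50e3)), 1)
  expect_equal(nrow(match_calls(off, tr, tol_intra = 10e3)), 0)

  # 3 truths, 2 predictions, exactly one within tolerance
  two <- pred_at(c(10e6, 41e6), c(12e6, 45e6))
  expect_equal(nrow(match_calls(two, tr, tol_intra = 50e3)), 1)
})

test_that("matching is one-to-one and greedy by total gap", {
  tr <- truth_points()[1, ]
  near <- pred_at(c(10e6, 10.06e6), c(12e6, 12.06e6))
  m <- match_calls(near, tr, tol_intra = 100e3)
  expect_equal(nrow(m), 1)
  expect_equal(m$pred_id, 1L) # the closer prediction wins
  # duplicate truths: one prediction cannot serve both
  tr2 <- dplyr::bind_rows(tr, tr)
  expect_equal(nrow(match_calls(near[1, ], tr2)), 1)
})

test_that("precision, recall and F1 follow their definitions", {
  perfect <- precision_recall_f1(tibble::tibble(x = 1:3), 3, 3)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  pr <- precision_recall_f1(tibble::tibble(x = 1), 2, 3)
  expect_equal(pr$precision, 0.5)
  expect_equal(round(pr$recall, 5), 0.33333)
  expect_equal(pr$f1, 0.4)

  none <- precision_recall_f1(tibble::tibble(), 0, 3)
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))
  expect_error(precision_recall_f1(tibble::tibble(), 2, 0), "ground truth")

  # harmonic-mean identity over random counts
  set.seed(12)
  for (i in 1:50) {
    n_true <- sample(1:20, 1)
    n_pred <- sample(0:20, 1)
    tp <- sample(0:min(n_true, n_pred), 1)
    r <- precision_recall_f1(tibble::tibble(x = seq_len(tp))[seq_len(tp), ],
                             n_pred, n_true)
    if (r$precision + r$recall > 0) {
      expect_equal(r$f1,
                   2 * r$precision * r$recall / (r$precision + r$recall))
    } else {
      expect_equal(r$f1, 0)
    }
  }
})

test_that("widening the tolerance never hurts any metric", {
  set.seed(6)
  tr <- truth_points()
  jitter <- runif(3, -150e3, 150e3)
  preds <- pred_at(tr$posA + jitter, tr$posB + rev(jitter))
  prev <- c(0, 0, 0)
  for (tol in c(10e3, 50e3, 100e3, 200e3)) {
    ev <- evaluate_calls(preds, tr, tol_intra = tol)
    cur <- unlist(ev$metrics[ev$metrics$class == "all",
                             c("precision", "recall", "f1")])
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("PR curves reward rankings that put true calls first", {
  tr <- truth_points()[1:2, ]
  good <- dplyr::bind_rows(
    pred_at(tr$posA, tr$posB, score = c(0.9, 0.8)),
    pred_at(c(70e6, 80e6), c(75e6, 88e6), score = c(0.3, 0.2))
  )
  curve <- pr_curve(good, tr)
  expect_equal(curve$auprc, 1)

  bad <- good
  bad$score <- rev(bad$score)
  expect_lt(pr_curve(bad, tr)$auprc, 1)

  single <- pr_curve(pred_at(tr$posA[1], tr$posB[1], score = 0.5), tr)
  expect_equal(nrow(single$points), 1)
  expect_equal(single$auprc, 1 * 0.5) # P = 1 over the recall 0.5 span

  one <- pr_curve(pred_at(tr$posA[1], tr$posB[1], score = 0.5), tr[1, ])
  expect_equal(one$auprc, 1)
})

test_that("evaluation objects split intra/inter and expose tidier views", {
  tr <- dplyr::bind_rows(
    truth_points(),
    tibble::tibble(chromA = "chr1", posA = 70e6, chromB = "chr5",
                   posB = 20e6, sv_type = "inter_translocation")
  )
  preds <- dplyr::bind_rows(
    pred_at(tr$posA[1:3], tr$posB[1:3],
            sv_type = c("deletion", "inversion", "inversion")),
    pred_at(70e6, 20e6, chromB = "chr5", sv_type = "inter_translocation")
  )
  ev <- evaluate_calls(preds, tr)
  td <- tidy(ev)
  expect_equal(td$class, c("all", "intra", "inter"))
  expect_equal(td$f1, c(1, 1, 1))
  expect_equal(ev$typing_accuracy, 3 / 4) # one mistyped duplication
  g <- glance(ev)
  expect_equal(g$n_tp, 4)
  expect_equal(g$tolerance_inter, 1e6)
})
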