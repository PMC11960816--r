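test_that("lambda = 0 returns the input and constant maps are fixed points", {
  set.seed(1)
  B <- matrix(runif(64), 8, 8)
  expect_equal(tv_denoise(B, lambda = 0)$b_prime, B, tolerance = 1e-8)
  const <- matrix(0.4, 6, 6)
  expect_equal(tv_denoise(const, lambda = 0.7)$b_prime, const,
               tolerance = 1e-10)
  expect_error(tv_denoise(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("solver matches a generic numeric minimizer of the same objective", {
  set.seed(42)
  for (rep in 1:3) {
    B <- matrix(runif(36), 6, 6)
    fit <- tv_denoise(B, lambda = 0.2, max_iter = 20000, tol = 0)
    ref <- tv_brute(B, lambda = 0.2)
    expect_lt(max(abs(fit$b_prime - ref)), 1e-4)
    expect_lte(fit$energy, tv_objective(B, ref, 0.2) + 1e-8)
  }
  B8 <- matrix(runif(64), 8, 8)
  fit8 <- tv_denoise(B8, lambda = 0.35, max_iter = 20000, tol = 0)
  expect_lt(max(abs(fit8$b_prime - tv_brute(B8, 0.35))), 1e-4)
})

test_that("objective trace is non-increasing and bounded by the initialization", {
  set.seed(8)
  B <- matrix(runif(400), 20, 20)
  fit <- tv_denoise(B, lambda = 0.3, max_iter = 300, tol = 0)
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_lte(fit$energy, fit$trace[1])
  expect_equal(fit$energy, tv_objective(B, fit$b_prime, 0.3),
               tolerance = 1e-10)
})

test_that("large lambda drives the estimate to the constant mean map", {
  set.seed(2)
  B <- matrix(runif(49), 7, 7)
  fit <- tv_denoise(B, lambda = 1e4, max_iter = 2000, tol = 0)
  expect_lt(max(abs(fit$b_prime - mean(B))), 1e-3)
})

test_that("segments are the 8-connected, size-filtered super-threshold set", {
  bp <- matrix(0, 10, 10)
  bp[3:4, 7:8] <- 0.8
  segs <- extract_segments(bp, t = 0.5, min_cells = 2, intra = FALSE)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$row_lo, 2L)
  expect_equal(segs$row_hi, 4L)
  expect_equal(segs$col_lo, 6L)
  expect_equal(segs$col_hi, 8L)
  expect_equal(segs$mean_saliency, 0.8)
  expect_equal(segs$n_cells, 4L)

  # strictly sub-threshold map -> empty
  expect_equal(nrow(extract_segments(bp, t = 0.8, intra = FALSE)), 0)
  bp2 <- matrix(0, 6, 6)
  bp2[2:3, 5] <- 0.55
  expect_equal(nrow(extract_segments(bp2, t = 0.6, intra = FALSE)), 0)

  # single-pixel noise dropped by min_cells
  bp3 <- matrix(0, 8, 8)
  bp3[2, 6] <- 0.9
  bp3[5:6, 2:3] <- 0.7
  segs3 <- extract_segments(bp3, t = 0.5, min_cells = 2, intra = FALSE)
  expect_equal(nrow(segs3), 1)
  expect_equal(segs3$peak_row, 4L)
})

test_that("segment cell sets are disjoint and cover the thresholded cells", {
  set.seed(31)
  bp <- matrix(runif(900, 0, 0.7), 30, 30)
  bp[5:8, 20:23] <- 0.95
  bp[15:16, 25:26] <- 0.9
  segs <- extract_segments(bp, t = 0.65, min_cells = 1, intra = FALSE)
  cells <- which(bp > 0.65, arr.ind = TRUE)
  inside <- rep(0, nrow(cells))
  for (s in seq_len(nrow(segs))) {
    inside <- inside + (cells[, 1] > segs$row_lo[s] &
                          cells[, 1] <= segs$row_hi[s] &
                          cells[, 2] > segs$col_lo[s] &
                          cells[, 2] <= segs$col_hi[s])
  }
  expect_true(all(inside >= 1)) # every cell in some bounding box
  expect_equal(sum(segs$n_cells), nrow(cells))
})

test_that("intra maps are scanned on the upper triangle only", {
  bp <- matrix(0, 12, 12)
  bp[2:3, 9:10] <- 0.9
  bp <- bp + t(bp)
  segs <- extract_segments(bp, t = 0.5, intra = TRUE)
  expect_equal(nrow(segs), 1)
  expect_lt(segs$row_hi, segs$col_hi)
})

test_that("consolidation merges satellite fragments but not distant junctions", {
  # one dominant block with a satellite fragment just outside it
  segs <- tibble::tibble(
    segment = 1:3,
    row_lo = c(10L, 52L, 200L), row_hi = c(50L, 55L, 204L),
    col_lo = c(100L, 145L, 300L), col_hi = c(140L, 148L, 304L),
    mean_saliency = c(0.7, 0.6, 0.65), max_saliency = c(0.95, 0.7, 0.8),
    n_cells = c(400L, 6L, 10L), peak_row = c(12L, 53L, 201L),
    peak_col = c(138L, 146L, 301L)
  )
  merged <- merge_segments(segs, expand = 0.5)
  expect_equal(nrow(merged), 2)
  big <- merged[merged$row_lo == 10, ]
  expect_equal(big$row_hi, 55L)
  expect_equal(big$peak_row, 12L) # peak of the strongest member
  expect_equal(big$n_cells, 406L)
  # distant small segments stay apart
  expect_true(any(merged$row_lo == 200))
  expect_equal(merge_segments(segs, expand = 0), segs)
})
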