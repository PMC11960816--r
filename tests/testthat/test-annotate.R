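fake_norm <- function(z, chrom = "chr1", binsize = 50e3) {
  structure(
    list(z = z, chromA = chrom, chromB = chrom, binsize = binsize,
         is_intra = TRUE),
    class = "normalized_matrix"
  )
}

neutral_profile <- function(n = 100, binsize = 50e3, chrom = "chr1") {
  m <- contact_matrix(matrix(1, n, n), chrom, binsize = binsize)
  coverage_profile(m)
}

call_at <- function(bpA, bpB, chromB = "chr1") {
  tibble::tibble(
    chromA = "chr1", startA = bpA - 1e5, endA = bpA + 1e5,
    chromB = chromB, startB = bpB - 1e5, endB = bpB + 1e5,
    name = "sv_0001", score = 0.7, sv_type = "unclassified",
    bpA = bpA, bpB = bpB
  )
}

test_that("coverage profile sums rows and averages non-empty bins", {
  prof <- coverage_profile(toy_matrix())
  expect_equal(prof$profile$cov, c(3, 6, 5))
  expect_equal(prof$c_prime, 14 / 3, tolerance = 1e-12)
  expect_equal(round(prof$c_prime, 4), 4.6667)
  expect_false(prof$corrected)
  expect_error(
    coverage_profile(contact_matrix(matrix(0, 3, 3), "c", binsize = 1e4)),
    "undefined"
  )
  expect_error(
    coverage_profile(contact_matrix(matrix(1, 2, 3), "a", "b", binsize = 1e4)),
    "intra"
  )
})

test_that("covariate correction is skipped for constant covariates and tames a smooth bias", {
  n <- 80
  m <- contact_matrix(matrix(2, n, n), "chr1", binsize = 50e3)
  covs <- tibble::tibble(gc = rep(0.5, n))
  prof <- coverage_profile(m, covs)
  expect_false(prof$corrected) # no usable variation: raw pass-through
  expect_equal(prof$profile$cov, prof$profile$cov_raw)

  # a GC-driven coverage gradient is flattened by the additive fit
  set.seed(4)
  gc <- seq(0.3, 0.6, length.out = n)
  cnt <- outer(1 + 2 * gc, 1 + 2 * gc)
  m2 <- contact_matrix(cnt, "chr1", binsize = 50e3)
  prof2 <- coverage_profile(m2, tibble::tibble(gc = gc))
  expect_true(prof2$corrected)
  raw_spread <- diff(range(prof2$profile$cov_raw)) / mean(prof2$profile$cov_raw)
  cor_spread <- diff(range(prof2$profile$cov)) / mean(prof2$profile$cov)
  expect_lt(cor_spread, raw_spread / 5)
})

test_that("copy-number rules classify deletions and duplications at 90%/110% of c-prime", {
  n <- 100
  base <- matrix(1, n, n)
  del <- base
  del[30:40, ] <- 0.2
  del[, 30:40] <- 0.2
  m <- contact_matrix((del + t(del)) / 2, "chr1", binsize = 50e3)
  prof <- coverage_profile(m)
  calls <- call_at(bpA = 29 * 50e3, bpB = 40 * 50e3)
  out <- classify_sv(calls, prof, Z = NULL)
  expect_equal(out$sv_type, "deletion")

  dup <- base
  dup[60:70, ] <- 2
  dup[, 60:70] <- 2
  m2 <- contact_matrix((dup + t(dup)) / 2, "chr1", binsize = 50e3)
  out2 <- classify_sv(call_at(59 * 50e3, 70 * 50e3), coverage_profile(m2),
                      Z = NULL)
  expect_equal(out2$sv_type, "duplication")

  # different chromosomes short-circuit to inter_translocation
  out3 <- classify_sv(call_at(1e6, 2e6, chromB = "chr9"), prof, Z = NULL)
  expect_equal(out3$sv_type, "inter_translocation")
})

test_that("junction geometry separates inversion, balanced and unbalanced patterns", {
  n <- 120
  bs <- 50e3
  x <- 50
  y <- 90 # junction between bins (x-1, x) and (y-1, y), 0-based
  prof <- neutral_profile(n)
  mk <- function(quads) {
    z <- matrix(0, n, n)
    w <- 15
    if ("NW" %in% quads) z[(x - w + 1):x, (y - w + 1):y] <- 3
    if ("NE" %in% quads) z[(x - w + 1):x, (y + 1):(y + w)] <- 3
    if ("SW" %in% quads) z[(x + 1):(x + w), (y - w + 1):y] <- 3
    if ("SE" %in% quads) z[(x + 1):(x + w), (y + 1):(y + w)] <- 3
    fake_norm(z)
  }
  cl <- call_at(x * bs, y * bs)
  classify1 <- function(quads) {
    classify_sv(cl, prof, mk(quads), window = 15)$sv_type
  }
  expect_equal(classify1(c("NW", "SE")), "inversion")
  expect_equal(classify1(c("NE", "SW")), "balanced_translocation")
  expect_equal(classify1("NE"), "unbalanced_translocation")
  expect_equal(classify1("SW"), "unbalanced_translocation")
  # one-sided strip (adjacent pair) is an unbalanced junction
  expect_equal(classify1(c("NW", "NE")), "unbalanced_translocation")
  # three hot quadrants or a flat neighbourhood are undecidable
  expect_equal(classify1(c("NW", "NE", "SE")), "unclassified")
  expect_equal(classify1(character(0)), "unclassified")
})

test_that("classification is total over a mixed callset", {
  sim <- simulate_contact_matrix(small_sim_config(seed = 5))
  calls <- call_svs(sim, sv_config())
  expect_true(all(calls$sv_type %in% c(
    "deletion", "duplication", "inversion", "balanced_translocation",
    "unbalanced_translocation", "inter_translocation", "unclassified"
  )))
  expect_false(any(is.na(calls$sv_type)))
})
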