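test_that("rearrangement maps implement the event semantics", {
  # no events: identity
  cfg0 <- sim_config(chrom_lengths = c(A = 1e6), binsize = 50e3,
                     events = sv_events(character(0), character(0), numeric(0)))
  map0 <- build_rearranged_map(cfg0)
  expect_equal(map0$ref_bin, 0:19)
  expect_true(all(map0$strand == "+"))

  # deletion of bins [5, 8): neighbours 4 and 8 become adjacent
  cfgd <- sim_config(chrom_lengths = c(A = 1e6), binsize = 50e3,
                     events = sv_events("deletion", "A", 250e3, span = 150e3))
  mapd <- build_rearranged_map(cfgd)
  expect_equal(nrow(mapd), 17)
  expect_equal(mapd$ref_bin[5:6], c(4L, 8L))

  # inversion of bins [5, 8): order ...4, 7, 6, 5, 8... with flipped strand
  cfgi <- sim_config(chrom_lengths = c(A = 1e6), binsize = 50e3,
                     events = sv_events("inversion", "A", 250e3, span = 150e3))
  mapi <- build_rearranged_map(cfgi)
  expect_equal(mapi$ref_bin[5:9], c(4L, 7L, 6L, 5L, 8L))
  expect_equal(mapi$strand[6:8], c("-", "-", "-"))

  # duplication inserts the copies right after the original block
  cfgu <- sim_config(chrom_lengths = c(A = 1e6), binsize = 50e3,
                     events = sv_events("duplication", "A", 250e3, span = 100e3))
  mapu <- build_rearranged_map(cfgu)
  expect_equal(nrow(mapu), 22)
  expect_equal(mapu$ref_bin[5:9], c(4L, 5L, 6L, 5L, 6L))

  # reciprocal inter-chromosomal translocation swaps the tails
  cfgt <- sim_config(
    chrom_lengths = c(A = 1e6, B = 1e6), binsize = 50e3,
    events = sv_events("inter_translocation", "A", 500e3,
                       chromB = "B", posB = 250e3)
  )
  mapt <- build_rearranged_map(cfgt)
  derA <- mapt[mapt$derived_chrom == "A", ]
  expect_equal(derA$ref_chrom, c(rep("A", 10), rep("B", 15)))
  expect_equal(derA$ref_bin, c(0:9, 5:19))
})

test_that("event validation rejects overlaps and off-grid coordinates", {
  expect_error(
    sim_config(events = dplyr::bind_rows(
      sv_events("deletion", "simA", 20e6, span = 2e6),
      sv_events("inversion", "simA", 21e6, span = 2e6)
    )),
    "overlapping"
  )
  cfg <- sim_config(chrom_lengths = c(A = 1e6), binsize = 50e3,
                    events = sv_events("deletion", "A", 260e3, span = 150e3))
  expect_error(build_rearranged_map(cfg), "multiple of the bin size")
})

test_that("derived truth labels junctions by chromosome, copy number and orientation", {
  one_event <- function(ev) {
    cfg <- sim_config(chrom_lengths = c(A = 10e6, B = 10e6), binsize = 50e3,
                      events = ev)
    derive_truth(build_rearranged_map(cfg), cfg)
  }
  del <- one_event(sv_events("deletion", "A", 3e6, span = 1e6))
  expect_equal(del$sv_type, "deletion")
  expect_equal(c(del$posA, del$posB), c(3e6, 4e6))

  dup <- one_event(sv_events("duplication", "A", 3e6, span = 1e6))
  expect_equal(dup$sv_type, "duplication")

  inv <- one_event(sv_events("inversion", "A", 3e6, span = 1e6))
  expect_equal(inv$sv_type, "inversion")
  expect_equal(inv$n_junctions, 2L) # both wings collapse onto (start, end)

  tl <- one_event(sv_events("translocation", "A", 3e6, span = 1e6,
                            chromB = "A", posB = 7e6))
  expect_equal(sort(tl$posB), c(4e6, 7e6, 7e6))
  expect_true(all(tl$sv_type == "unbalanced_translocation"))

  itl <- one_event(sv_events("inter_translocation", "A", 5e6,
                             chromB = "B", posB = 2e6))
  expect_equal(itl$sv_type, "inter_translocation")
  expect_equal(itl$n_junctions, 2L)
})

test_that("expected contacts follow the derived-genome power law", {
  # deletion shrinking a 2 Mb separation to 1 Mb: f2/f1 = 41/21
  ev <- sv_events("deletion", "A", 1e6, span = 1e6)
  cfg <- sim_config(chrom_lengths = c(A = 3e6), binsize = 50e3, alpha = 1,
                    base_depth = 1e5, events = ev)
  cfg0 <- cfg
  cfg0$events <- ev[0, ]
  st <- simulate_contact_matrix(cfg, keep_expected = TRUE)
  s0 <- simulate_contact_matrix(cfg0, keep_expected = TRUE)
  i <- 11
  j <- 51 # bins 10 and 50: distance 40 bins -> 20 bins after deletion
  f2 <- st$expected[["A|A"]][i, j] / st$scale
  f1 <- s0$expected[["A|A"]][i, j] / s0$scale
  expect_equal(f2 / f1, 41 / 21, tolerance = 1e-12)
  expect_equal(round(f2 / f1, 5), 1.95238)

  # event-free decay: log f vs log(1 + d) regression recovers -alpha
  E <- s0$expected[["A|A"]] / s0$scale
  d <- abs(row(E) - col(E))
  sel <- upper.tri(E) & d >= 1
  fit <- lm(log(E[sel]) ~ log(1 + d[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.05)

  # junction expectation rises far above the event-free rate at that distance
  bjx <- st$expected[["A|A"]][20, 41] / st$scale # flanks of the deleted block
  bg <- s0$expected[["A|A"]][1, 22] / s0$scale # same reference separation
  expect_gt(bjx, 3 * bg)
})

test_that("total counts hit the requested depth and draws are reproducible", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_contact_matrix(cfg)
  expect_equal(total_contacts(sim$matrices), cfg$base_depth,
               tolerance = 0.02)
  sim2 <- simulate_contact_matrix(cfg)
  for (nm in names(sim$matrices)) {
    expect_identical(sim$matrices[[nm]]$counts, sim2$matrices[[nm]]$counts)
  }
  # intra draws are exactly symmetric
  expect_true(isSymmetric(sim$matrices[["simA|simA"]]$counts))
})

test_that("purity mixing preserves the expected mixture", {
  n <- 40
  tum <- contact_matrix(matrix(100, n, n), "c1", "c2", binsize = 50e3)
  nor <- contact_matrix(matrix(100, n, n), "c1", "c2", binsize = 50e3)
  expect_identical(mix_purity(tum, nor, 1), tum)
  expect_identical(mix_purity(tum, nor, 0), nor)
  mixed <- mix_purity(tum, nor, 0.5, seed = 9)
  # each cell ~ Bin(100, .5) + Bin(100, .5): mean 100, sd sqrt(50)
  expect_lt(abs(mean(mixed$counts) - 100), 3 * sqrt(50) / sqrt(n * n))
  expect_error(
    mix_purity(tum, contact_matrix(matrix(1, 2, 2), "c1", "c2", binsize = 50e3),
               0.5),
    "dim"
  )
})
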