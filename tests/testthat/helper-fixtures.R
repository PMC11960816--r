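# Shared fixtures and independent oracles (brute-force implementations that
# deliberately avoid the package's optimized code paths).

toy_counts <- function() {
  matrix(c(
    0, 2, 1,
    2, 0, 4,
    1, 4, 0
  ), 3, 3, byrow = TRUE)
}

toy_matrix <- function(chrom = "chr1", binsize = 50e3) {
  contact_matrix(toy_counts(), chrom, binsize = binsize)
}

# small two-chromosome simulation: 20 Mb each at 50 kb bins (400 bins)
small_sim_config <- function(seed = 7, events = small_sim_events(), ...) {
  sim_config(
    chrom_lengths = c(simA = 20e6, simB = 20e6),
    binsize = 50e3, base_depth = 1.2e6, seed = seed, events = events, ...
  )
}

# deletion and duplication junctions carry the strongest signal at this
# small scale; weaker geometries (inversion wings, low purity) are exercised
# at full desk scale in the acceptance suite
small_sim_events <- function() {
  dplyr::bind_rows(
    sv_events("deletion", "simA", 5e6, span = 1.5e6),
    sv_events("duplication", "simA", 12e6, span = 1.5e6),
    sv_events("inter_translocation", "simA", 17e6,
              chromB = "simB", posB = 6e6)
  )
}

# brute-force saliency: literal double loop over the window
saliency_brute <- function(z, k) {
  n <- nrow(z)
  m <- ncol(z)
  b <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (p in max(1, i - k):min(n, i + k)) {
        for (q in max(1, j - k):min(m, j + k)) {
          s <- s + abs(z[i, j] - z[p, q]) /
            (1 + sqrt((i - p)^2 + (j - q)^2))
        }
      }
      b[i, j] <- min(1, max(0, 1 - exp(-s / (4 * k^2))))
    }
  }
  b
}

# generic numeric minimizer of the TV objective (smoothed, analytic gradient)
tv_brute <- function(B, lambda, eps = 1e-12) {
  n <- nrow(B)
  m <- ncol(B)
  obj <- function(v) {
    u <- matrix(v, n, m)
    dx <- rbind(u[-1, , drop = FALSE] - u[-n, , drop = FALSE], rep(0, m))
    dy <- cbind(u[, -1, drop = FALSE] - u[, -m, drop = FALSE], rep(0, n))
    sum((B - u)^2) + lambda * sum(sqrt(dx^2 + dy^2 + eps))
  }
  grad <- function(v) {
    u <- matrix(v, n, m)
    dx <- rbind(u[-1, , drop = FALSE] - u[-n, , drop = FALSE], rep(0, m))
    dy <- cbind(u[, -1, drop = FALSE] - u[, -m, drop = FALSE], rep(0, n))
    r <- sqrt(dx^2 + dy^2 + eps)
    gx <- dx / r
    gy <- dy / r
    g <- -2 * (B - u) +
      lambda * (rbind(rep(0, m), gx[-n, , drop = FALSE]) - gx +
                  cbind(rep(0, n), gy[, -m, drop = FALSE]) - gy)
    as.vector(g)
  }
  o <- stats::optim(as.vector(B), obj, grad, method = "L-BFGS-B",
                    control = list(maxit = 1e5, factr = 1))
  matrix(o$par, n, m)
}

random_calls <- function(n, seed = 1) {
  set.seed(seed)
  startA <- sort(sample.int(100, n)) * 1e5
  startB <- startA + 2e6 + sample.int(20, n) * 1e5
  tibble::tibble(
    chromA = "chr1", startA = startA, endA = startA + 1e5,
    chromB = "chr1", startB = startB, endB = startB + 1e5,
    name = sprintf("sv_%04d", seq_len(n)),
    score = round(stats::runif(n, 0.4, 1), 6),
    sv_type = sample(
      c("deletion", "duplication", "inversion", "unbalanced_translocation"),
      n, replace = TRUE
    )
  )
}
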