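test_that("TAD strength equals hand and brute-force oracles", {
  # block design yielding per-distance ratios {2, 3, 4} -> strength 3
  n <- 12
  v <- matrix(1, n, n)
  inside <- 5:8
  for (d in 1:3) {
    ratio <- c(2, 3, 4)[d]
    for (i in inside) {
      j <- i + d
      if (j %in% inside) { v[i, j] <- ratio; v[j, i] <- ratio }
    }
  }
  m <- contact_matrix(v, bin_grid("c", 2e4, n), norm = "KR",
                      mask = rep(TRUE, n))
  expect_equal(tad_strength(m, 5, 8), 3)
  # uniform matrix: every ratio 1
  u <- contact_matrix(matrix(2, n, n), bin_grid("c", 2e4, n), norm = "KR",
                      mask = rep(TRUE, n))
  expect_equal(tad_strength(u, 5, 8), 1)
  # random instances match the literal double-median oracle exactly
  for (seed in 1:4) {
    mr <- random_contact_matrix(30, seed = seed, lambda = 8)
    expect_equal(tad_strength(mr, 11, 18),
                 tad_strength_oracle(mr$values, 11, 18))
    expect_equal(tad_strength(mr, 2, 6),     # clipped left neighbor
                 tad_strength_oracle(mr$values, 2, 6))
  }
  # all-zero inter-TAD contacts are an error
  z <- matrix(0, n, n); z[inside, inside] <- 5
  mz <- contact_matrix(z, bin_grid("c", 2e4, n), norm = "KR",
                       mask = rep(TRUE, n))
  expect_error(tad_strength(mz, 5, 8), "inter-TAD")
  expect_error(tad_strength(m, 5, 6), "3 bins")
})

test_that("planted TAD enrichment is recovered by the strength statistic", {
  spec <- sim_spec(chrom_length = 1e7, depth = 1e5, beta = 0, gamma = 2,
                   seed = 9)
  sim <- simulate_species_set(spec, resolutions = 2e4)
  kr <- kr_balance(sim$species$human[["20000"]])
  bnd <- sim$truth$boundaries_bin
  tads <- data.frame(start_bin = bnd[-length(bnd)] + 1, end_bin = bnd[-1] - 1)
  st <- vapply(seq_len(nrow(tads)), function(k)
    tad_strength(kr, tads$start_bin[k], tads$end_bin[k]), numeric(1))
  expect_gt(median(st), 1.6)
  expect_lt(median(st), 2.4)
})

test_that("aggregate TAD maps recover the planted contrast", {
  spec <- sim_spec(chrom_length = 1e7, depth = 1e6, beta = 0, gamma = 2,
                   seed = 13)
  sim <- simulate_species_set(spec, resolutions = 2e4)
  kr <- kr_balance(sim$species$human[["20000"]])
  bnd <- sim$truth$boundaries_bin
  tads <- data.frame(start_bin = bnd[-length(bnd)] + 1, end_bin = bnd[-1] - 1)
  agg <- aggregate_tad_map(kr, tads)
  expect_gt(agg$n_used, 5)
  # center/flank contrast recovers the planted gamma = 2 within 15%
  expect_lt(abs(agg$ratio - 2) / 2, 0.15)
  # a single TAD on a uniform matrix gives a flat aggregate with ratio 1
  u <- contact_matrix(matrix(4, 60, 60), bin_grid("c", 2e4, 60),
                      norm = "KR", mask = rep(TRUE, 60))
  a1 <- aggregate_tad_map(u, data.frame(start_bin = 21, end_bin = 40),
                          expected = "none")
  expect_equal(a1$ratio, 1)
  expect_true(all(abs(a1$map - 4) < 1e-9))
  expect_equal(aggregate_tad_map(u, data.frame(start_bin = 21,
                                               end_bin = 40))$ratio, 1)
  # aggregating one TAD reproduces its own rescaled window
  mr <- random_contact_matrix(60, seed = 2)
  one <- data.frame(start_bin = 21, end_bin = 40)
  a2 <- aggregate_tad_map(mr, one, out_size = 60, expected = "none")
  expect_equal(a2$n_used, 1)
  expect_equal(a2$map, mr$values[1:60, 1:60], tolerance = 1e-9)
})

test_that("TAD composition statistics match exact hypergeometric enumeration", {
  tads <- data.frame(start = c(0, 2e6), end = c(1e6, 3e6),
                     class = c("Cons", "HS"))
  genes <- data.frame(
    gene = sprintf("g%02d", 1:20),
    pos = c(seq(1e5, 9e5, length.out = 10), seq(2.1e6, 2.9e6, length.out = 10)))
  # 8/10 Cons genes in the set vs 1/10 HS genes
  sets <- list(hk = c(sprintf("g%02d", 1:8), "g11"))
  st <- tad_composition_stats(tads, genes, sets)
  expect_equal(st$density$genes_per_mb, c(10, 10))
  ft <- st$fisher[1, ]
  # exact enumeration of the 2x2 table (8,2;1,9): two-sided Fisher p is the
  # total probability of tables no more likely than the observed one
  k <- 0:9
  dk <- dhyper(k, 10, 10, 9)
  p_oracle <- sum(dk[dk <= dhyper(8, 10, 10, 9) * (1 + 1e-7)])
  expect_equal(ft$p, fisher.test(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))$p.value)
  expect_equal(ft$p, p_oracle, tolerance = 1e-9)
})
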