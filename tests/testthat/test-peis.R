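test_that("promoter windows are strand-aware and 2700 bp long", {
  g <- bin_grid("chrS", 1e4, 100)
  tss <- data.frame(gene = c("gp", "gm"), pos = c(5e4, 2e5),
                    strand = c("+", "-"))
  pr <- make_promoters(tss, g)
  expect_equal(pr$win_end - pr$win_start, c(2700, 2700))
  expect_equal(pr$win_start[1], 5e4 - 2200)
  expect_equal(pr$win_end[2], 2e5 + 2200 + 1)
  expect_equal(pr$anchor_bin, c(6, 21))
})

test_that("PEI calling retains planted loops and applies its filters", {
  # deterministic world: decay background with two planted pixels
  n <- 150
  with_seed(77, {
    d <- abs(outer(1:n, 1:n, "-"))
    mu <- 600 / (1 + d)
    mu[40, 60] <- mu[40, 60] * 6; mu[60, 40] <- mu[40, 60]
    mu[40, 41] <- mu[40, 41] * 6; mu[41, 40] <- mu[40, 41]  # 10-kb loop
    counts <- matrix(0, n, n)
    ut <- upper.tri(mu, diag = TRUE)
    counts[ut] <- rpois(sum(ut), mu[ut])
    counts <- counts + t(counts); diag(counts) <- diag(counts) / 2
  })
  m <- contact_matrix(counts, bin_grid("chrS", 1e4, n))
  kr <- kr_balance(m)
  tss <- data.frame(gene = "g1", pos = 39.5 * 1e4, strand = "+")
  pr <- make_promoters(tss, kr$grid)
  peis <- call_peis(kr, pr)
  expect_true(any(peis$e_bin == 60))                       # 200-kb loop kept
  expect_false(any(peis$e_bin == 41))                      # < 20 kb dropped
  expect_true(all(peis$length >= 2e4))
  expect_true(all(peis$fdr <= 0.001))
})

test_that("promoter-promoter pairs are filtered out", {
  n <- 120
  with_seed(5, {
    d <- abs(outer(1:n, 1:n, "-"))
    mu <- 500 / (1 + d)
    mu[30, 70] <- mu[30, 70] * 8; mu[70, 30] <- mu[30, 70]
    counts <- matrix(0, n, n); ut <- upper.tri(mu, diag = TRUE)
    counts[ut] <- rpois(sum(ut), mu[ut])
    counts <- counts + t(counts); diag(counts) <- diag(counts) / 2
  })
  kr <- kr_balance(contact_matrix(counts, bin_grid("chrS", 1e4, n)))
  tss <- data.frame(gene = c("g1", "g2"), pos = c(29.5, 69.5) * 1e4,
                    strand = "+")
  peis <- call_peis(kr, make_promoters(tss, kr$grid))
  expect_false(any(peis$e_bin == 70 & peis$p_bin == 30))
})

test_that("a null decay matrix yields almost no PEIs", {
  hits <- 0; tests <- 0
  for (s in 1:5) {
    spec <- sim_spec(chrom_length = 2e6, resolution = 1e4, beta = 0,
                     gamma = 1, lambda = 1, depth = 1e5, n_loops = 0L,
                     seed = 400 + s)
    sim <- simulate_species_set(spec, resolutions = 1e4)
    m <- kr_balance(sim$species$human[["10000"]])
    peis <- call_peis(m, make_promoters(sim$truth$genes, m$grid))
    hits <- hits + nrow(peis)
    tests <- tests + nrow(attr(peis, "tests"))
  }
  expect_lt(hits / tests, 0.001)
})

test_that("enhancer annotation follows the 50%/5-kb overlap rule", {
  g <- bin_grid("chrS", 1e4, 50)
  peis <- data.frame(gene = "g", p_bin = 1, e_bin = c(10, 20, 30, 40))
  # bin 10: [90,100) kb
  se <- data.frame(start = 9.2e4, end = 9.8e4)            # 6 kb overlap
  re <- data.frame(start = c(1.92e5, 2.9e5), end = c(1.96e5, 2.950010e5))
  out <- annotate_enhancers(peis, g, re_peaks = re, se_peaks = se)
  expect_equal(out$enhancer_class, c("SE", "none", "RE", "none"))
  # bin 20 overlap is 4 kb (40%): both conditions fail
  # bin 30 overlap is 5001 bp: strict inequality passes
  # SE precedence when both overlap
  both <- annotate_enhancers(peis[1, ], g,
                             re_peaks = data.frame(start = 9e4, end = 1e5),
                             se_peaks = se)
  expect_equal(both$enhancer_class, "SE")
})

test_that("APA aggregates loop pixels and is ~1 on random pixels", {
  spec <- sim_spec(chrom_length = 2e6, resolution = 1e4, beta = 0,
                   gamma = 1, lambda = 1, depth = 4e5, n_loops = 0L,
                   seed = 55)
  sim <- simulate_species_set(spec, resolutions = 1e4)
  m <- sim$species$human[["10000"]]
  pix <- with_seed(6, data.frame(p_bin = sample(20:80, 30, TRUE)))
  pix$e_bin <- pix$p_bin + with_seed(7, sample(15:60, 30, TRUE))
  pix <- pix[pix$e_bin <= 180, ]
  a <- apa(m, pix)
  expect_gt(a$score, 0.8); expect_lt(a$score, 1.2)
  # single PEI: the aggregate is its own window
  one <- apa(m, pix[1, , drop = FALSE])
  expect_equal(one$n_used, 1)
  oe <- observed_over_expected(m, expected_by_distance(m, "mean"))
  i <- pix$p_bin[1]; j <- pix$e_bin[1]
  expect_equal(one$map, oe$values[(i - 5):(i + 5), (j - 5):(j + 5)])
  # planted loops score above one
  spec2 <- sim_spec(chrom_length = 2e6, resolution = 1e4, beta = 0,
                    gamma = 1, lambda = 3, depth = 4e5, n_loops = 10L,
                    loop_sep_range = c(1.5e5, 4e5), seed = 56)
  sim2 <- simulate_species_set(spec2, resolutions = 1e4)
  m2 <- sim2$species$human[["10000"]]
  lp <- data.frame(p_bin = bin_of(m2$grid, sim2$truth$loops$p_pos),
                   e_bin = bin_of(m2$grid, sim2$truth$loops$e_pos))
  expect_gt(apa(m2, lp)$score, 1)
  expect_error(apa(m2, lp[0, ]), "empty")
})

test_that("promoter valency histograms count PEIs per promoter", {
  peis <- data.frame(gene = c("p1", "p2", "p2", "p3", "p3", "p3", "p3"))
  v <- promoter_valency(peis)
  expect_equal(v$pct, c(100 / 3, 100 / 3, 0, 100 / 3), tolerance = 1e-9)
  one <- promoter_valency(data.frame(gene = c("a", "b")))
  expect_equal(one$pct, c(100, 0, 0, 0))
})
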