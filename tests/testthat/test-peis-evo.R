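test_that("anchor alignment enumerates its failure modes", {
  g <- bin_grid("chrS", 1e4, 100)
  pei <- data.frame(p_bin = 3, e_bin = 25)
  ok_map <- identity_map(1e6)
  al <- align_pei(pei, g, ok_map, homolog_tss = 2.4e4)
  expect_true(al$ok)
  expect_equal(al$q_p_mid, 2.5e4)
  expect_equal(al$q_e_mid, 24.5e4)

  # anchor mapping to a 30-kb region: size-out-of-range
  wide <- homology_map(data.frame(
    ref_chrom = "chrS", ref_start = c(0, 2.4e5, 2.46e5),
    ref_end = c(2.4e5, 2.46e5, 1e6),
    q_chrom = "chrS", q_start = c(0, 2.4e5, 2.66e5),
    q_end = c(2.4e5, 2.46e5, 1.02e6),
    strand = "+", reciprocal = TRUE))
  expect_equal(align_pei(pei, g, wide)$reason, "size-out-of-range")

  # anchors on different query chromosomes: trans-split
  trans <- homology_map(data.frame(
    ref_chrom = "chrS", ref_start = c(0, 1e5), ref_end = c(1e5, 1e6),
    q_chrom = c("chrS", "chrQ"), q_start = c(0, 1e5),
    q_end = c(1e5, 1e6), strand = "+", reciprocal = TRUE))
  expect_equal(align_pei(pei, g, trans)$reason, "trans-split")

  # gap under an anchor: unmapped
  gap <- homology_map(data.frame(
    ref_chrom = "chrS", ref_start = 1e5, ref_end = 1e6,
    q_chrom = "chrS", q_start = 1e5, q_end = 1e6,
    strand = "+", reciprocal = TRUE))
  expect_equal(align_pei(pei, g, gap)$reason, "unmapped")

  # mapped promoter >= 20 kb from the annotated homologous promoter
  expect_equal(align_pei(pei, g, ok_map, homolog_tss = 5e4)$reason,
               "promoter-displaced")
})

test_that("distance judgment applies d < min(r1*span, r2) and matches a scan", {
  # |i-j| = 200 kb: conservation threshold min(40, 20) kb = 20 kb
  qp <- data.frame(p_mid = 1e5, e_mid = 3e5)
  near <- data.frame(p_mid = 1e5 + 9e3, e_mid = 3e5 + 12e3)  # d = 15 kb
  dj <- distance_judgment(qp$p_mid, qp$e_mid, near, r1 = 0.2, r2 = 2e4)
  expect_equal(dj$threshold, 2e4)
  expect_equal(dj$d, 15000)
  expect_true(dj$pass)
  # d = 25 kb fails conservation but is not far under the 50-kb test either
  mid <- data.frame(p_mid = 1e5 + 15e3, e_mid = 3e5 + 2e4)
  expect_false(distance_judgment(qp$p_mid, qp$e_mid, mid, 0.2, 2e4)$pass)
  expect_true(distance_judgment(qp$p_mid, qp$e_mid, mid, 0.2, 5e4)$pass)
  # |i-j| = 50 kb: threshold min(10, 20) = 10 kb
  expect_equal(distance_judgment(1e5, 1.5e5, near, 0.2, 2e4)$threshold, 1e4)
  # no query PEIs: d infinite
  expect_false(distance_judgment(1e5, 3e5, near[0, ], 0.2, 2e4)$pass)

  # property: equals a brute-force nearest-neighbour scan
  with_seed(17, {
    for (rep in 1:20) {
      qpeis <- data.frame(p_mid = runif(8, 0, 1e6), e_mid = runif(8, 0, 1e6))
      p0 <- runif(1, 0, 1e6); e0 <- runif(1, 0, 1e6)
      d_scan <- min(sqrt((qpeis$p_mid - p0)^2 + (qpeis$e_mid - e0)^2))
      expect_equal(distance_judgment(p0, e0, qpeis, 0.2, 2e4)$d, d_scan)
    }
  })
})

test_that("enrichment judgment is a strict quantile exceedance", {
  m <- random_contact_matrix(50, seed = 23, lambda = 12, res = 1e4)
  bg <- expected_matrix(m)
  scores <- c(1, 2, 3, 4, 5)
  thr <- unname(quantile(scores, 0.2))
  pb <- 10; eb <- 30
  sc <- m$values[pb, eb] - bg$expected[pb, eb]
  en <- enrichment_judgment((pb - 0.5) * 1e4, (eb - 0.5) * 1e4, m, bg, scores)
  expect_equal(en$threshold, thr)
  expect_equal(en$score, sc)
  expect_equal(en$pass, sc > thr)
  # a score exactly at the threshold does not pass
  en2 <- enrichment_judgment((pb - 0.5) * 1e4, (eb - 0.5) * 1e4, m, bg,
                             rep(sc, 5))
  expect_false(en2$pass)
  # masked pixel: flagged missing, no pass
  m2 <- m; m2$mask[30] <- FALSE
  en3 <- enrichment_judgment((pb - 0.5) * 1e4, (eb - 0.5) * 1e4, m2, bg,
                             scores)
  expect_true(en3$missing); expect_false(en3$pass)
  expect_error(enrichment_judgment(1, 1, m, bg, numeric(0)), "empty")
})

test_that("PEI verdicts combine distance and enrichment votes", {
  j <- function(al, dc, ds, en)
    data.frame(aligned = al, dist_pass_cons = dc, dist_pass_spec = ds,
               enrich_pass = en)
  # enrichment alone conserves
  expect_equal(classify_pei(rbind(j(TRUE, FALSE, FALSE, TRUE),
                                  j(TRUE, FALSE, FALSE, TRUE)))$label,
               "species-conserved")
  # far and unenriched everywhere: human-specific
  expect_equal(classify_pei(rbind(j(TRUE, FALSE, FALSE, FALSE),
                                  j(TRUE, FALSE, FALSE, FALSE)))$label,
               "human-specific")
  # conserved vote in only one of two species: unclassified
  expect_equal(classify_pei(rbind(j(TRUE, TRUE, TRUE, FALSE),
                                  j(TRUE, FALSE, FALSE, FALSE)))$label,
               "unclassified")
  # any alignment failure: unclassified with reason
  out <- classify_pei(rbind(j(FALSE, FALSE, FALSE, FALSE),
                            j(TRUE, TRUE, TRUE, TRUE)))
  expect_equal(out$label, "unclassified")
  expect_equal(out$reason, "alignment-failure")
})

test_that("self-comparison classifies every alignable PEI as conserved", {
  spec <- sim_spec(chrom_length = 2e6, resolution = 1e4,
                   tad_bin_range = c(30L, 70L), beta = 0, depth = 1e5,
                   n_loops = 10L, loop_sep_range = c(1e5, 3e5),
                   gap_rate = 0, seed = 61)
  sim <- simulate_species_set(spec, resolutions = 1e4)
  m <- kr_balance(sim$species$human[["10000"]])
  tads <- tads_from_boundaries(call_boundaries(insulation_score(m)), m$grid)
  pr <- make_promoters(sim$truth$genes, m$grid)
  peis <- call_peis(m, pr, tads)
  expect_gt(nrow(peis), 0)
  self <- list(self = list(map = identity_map(2e6), m = m, tads = tads,
                           peis = peis, promoters = pr,
                           ortholog = setNames(sim$truth$genes$gene,
                                               sim$truth$genes$gene)))
  out <- classify_peis_across_species(peis, m$grid, self)
  expect_true(all(out$class == "species-conserved"))
})

test_that("planted loop classes are recovered across species", {
  pa <- run_pei_analysis(seed = 101)
  expect_gte(pa$classification_accuracy, 0.85)
  expect_gt(sum(!is.na(pa$classified$truth_class)), 10)
})
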