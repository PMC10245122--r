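test_that("TF preference applies the |delta| > 5 rule strictly", {
  enr <- data.frame(tf = c("a", "b", "c", "d"),
                    p_hs = c(1e-10, 1e-3, 1e-7, 0),
                    p_cons = c(1e-2, 1e-3, 1e-2, 1e-2))
  out <- tf_preference(enr)
  expect_equal(out$delta[1], 8)
  expect_equal(out$preference, c("HS", "neutral", "neutral", "HS"))
  # delta = 5 exactly stays neutral
  out2 <- tf_preference(data.frame(tf = "e", p_hs = 1e-7, p_cons = 1e-2))
  expect_equal(out2$delta, 5)
  expect_equal(out2$preference, "neutral")
  # Cons-preferring side is symmetric
  out3 <- tf_preference(data.frame(tf = "f", p_hs = 1e-2, p_cons = 1e-9))
  expect_equal(out3$preference, "Cons")
})

test_that("candidate TF pairs need occurrence, expression and PPI support", {
  hits <- rbind(
    data.frame(tf = "E1", role = "enhancer", region = paste0("r", 1:5)),
    data.frame(tf = "E2", role = "enhancer", region = paste0("r", 1:2)),
    data.frame(tf = "E3", role = "enhancer", region = paste0("r", 1:4)),
    data.frame(tf = "E4", role = "enhancer", region = paste0("r", 1:4)),
    data.frame(tf = "P1", role = "promoter", region = paste0("r", 1:5)),
    data.frame(tf = "P2", role = "promoter", region = paste0("r", 1:3)))
  expr <- c(E1 = 10, E2 = 10, E3 = 0.5, E4 = 10, P1 = 5, P2 = 8)
  # PPI: E1-P1 direct; E4-X-P2 indirect; E1..P2 distance 3 via chain
  ppi <- data.frame(a = c("E1", "E4", "X", "P1", "Z"),
                    b = c("P1", "X", "P2", "Z", "P2"))
  out <- suppressWarnings(candidate_tf_pairs(hits, expr, ppi))
  expect_true(any(out$enhancer_tf == "E1" & out$promoter_tf == "P1" &
                    out$ppi_mode == "direct"))
  expect_true(any(out$enhancer_tf == "E4" & out$promoter_tf == "P2" &
                    out$ppi_mode == "indirect"))
  expect_false(any(out$enhancer_tf == "E2"))   # 2 occurrences only
  expect_false(any(out$enhancer_tf == "E3"))   # TPM 0.5 <= 1
  # E1 to P2 is path length 3: excluded
  expect_false(any(out$enhancer_tf == "E1" & out$promoter_tf == "P2"))
})

test_that("pair preference test matches exact enumeration at small n", {
  hs <- c(1, 1, 1, 1, 0, 1, 1, 0)
  cons <- c(0, 0, 1, 0, 0, 0, 0, 1)
  p_pkg <- pair_preference_test(hs, cons)$p
  p_exact <- mw_exact_oracle(hs, cons)
  # normal approximation with continuity correction vs exact enumeration
  expect_lt(abs(p_pkg - p_exact), 0.02)
  # strong separation at n = 10 is kept
  out <- pair_preference_test(c(rep(1, 8), 0, 0), c(1, rep(0, 9)))
  expect_lt(out$p, 0.05)
  expect_true(out$keep)
  # identical distributions: one-sided p ~ 0.5, dropped
  same <- with_seed(2, rbinom(40, 1, 0.4))
  out2 <- pair_preference_test(same, same)
  expect_gt(out2$p, 0.4)
  expect_false(out2$keep)
  expect_true(is.na(pair_preference_test(numeric(0), cons)$p))
})

test_that("type-I error of the pair test is controlled under permutation", {
  rej <- with_seed(77, vapply(1:100, function(r) {
    x <- rbinom(90, 1, 0.3)
    idx <- sample(90, 30)
    isTRUE(pair_preference_test(x[idx], x[-idx])$keep)
  }, logical(1)))
  expect_lte(mean(rej), 0.10)
})

test_that("binding-site conservation contrasts phastCons by class", {
  with_seed(19, {
    hits <- rbind(
      data.frame(tf = "T1", class = "HS", phastcons = runif(20, 0.1, 0.4)),
      data.frame(tf = "T1", class = "Cons", phastcons = runif(20, 0.3, 0.6)),
      data.frame(tf = "T2", class = "HS", phastcons = rep(0.5, 10)),
      data.frame(tf = "T2", class = "Cons", phastcons = rep(0.5, 10)),
      data.frame(tf = "T3", class = "HS", phastcons = runif(2)),
      data.frame(tf = "T3", class = "Cons", phastcons = runif(5)))
  })
  out <- binding_site_conservation(hits)
  r1 <- out[out$tf == "T1", ]
  expect_equal(r1$direction, "lower-in-HS")
  expect_lt(r1$p, 0.05)
  expect_gt(out$p[out$tf == "T2"], 0.9)
  expect_true(is.na(out$p[out$tf == "T3"]))   # < 3 hits in one class
})

test_that("a planted co-occurring TF pair is recovered end to end", {
  spec <- sim_spec(chrom_length = 8e6, resolution = 1e4,
                   tad_bin_range = c(30L, 70L), beta = 0, depth = 2e5,
                   n_loops = 60L, hs_loop_frac = 0.3,
                   loop_sep_range = c(1e5, 3e5), seed = 71)
  sim <- simulate_species_set(spec, resolutions = 1e5)
  g <- bin_grid("chrS", 1e4, 800)
  fx <- simulate_fixtures(sim$truth, g, seed = 72)
  cand <- suppressWarnings(candidate_tf_pairs(fx$motif_hits, fx$tf_expr, fx$ppi))
  expect_true(any(cand$enhancer_tf == fx$planted_pair["enhancer_tf"] &
                    cand$promoter_tf == fx$planted_pair["promoter_tf"]))
  hs <- pair_cooccurrence(fx$motif_hits, fx$pei_ids[fx$pei_class == "HS"],
                          fx$planted_pair["enhancer_tf"],
                          fx$planted_pair["promoter_tf"])
  cons <- pair_cooccurrence(fx$motif_hits, fx$pei_ids[fx$pei_class == "Cons"],
                            fx$planted_pair["enhancer_tf"],
                            fx$planted_pair["promoter_tf"])
  expect_gt(length(hs), 2); expect_gt(length(cons), 2)
  expect_true(isTRUE(pair_preference_test(hs, cons)$keep))
})
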