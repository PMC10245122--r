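make_track <- function(values, grid) {
  structure(list(ab_index = values, grid = grid), class = "ab_index_track")
}

test_that("homologous bins require reciprocal mapping in every species", {
  g <- bin_grid("chrS", 2e4, 10)
  ref <- make_track(seq(-1, 1, length.out = 10), g)
  q1 <- make_track(rep(0.5, 10), g)
  q2 <- make_track(rep(-0.5, 10), g)
  # species 1 maps everything; species 2 has a gap over bins 3-4 and a
  # non-reciprocal block over bin 7
  map1 <- identity_map(2e5)
  map2 <- homology_map(data.frame(
    ref_chrom = "chrS",
    ref_start = c(0, 8e4, 12e4, 14e4),
    ref_end = c(4e4, 12e4, 14e4, 2e5),
    q_chrom = "chrS",
    q_start = c(0, 8e4, 12e4, 14e4),
    q_end = c(4e4, 12e4, 14e4, 2e5),
    strand = "+",
    reciprocal = c(TRUE, TRUE, FALSE, TRUE)))
  hb <- build_homologous_bins(ref, list(s1 = map1, s2 = map2),
                              list(s1 = q1, s2 = q2))
  # bins 3,4 (gap) and 7 (non-reciprocal) drop: 7 rows remain
  expect_equal(hb$bins, setdiff(1:10, c(3, 4, 7)))
  expect_equal(ncol(hb$ab), 3)
  expect_equal(unname(hb$ab[, "s1"]), rep(0.5, 7))
  expect_error(build_homologous_bins(ref, list(s1 = map1), list(s2 = q2)),
               "species")
})

test_that("the SSE elbow recovers a planted cluster count", {
  centers <- rbind(c(2, 2, 2), c(-2, -2, -2), c(2, -2, 2))
  ab <- with_seed(8, {
    idx <- sample(1:3, 300, replace = TRUE)
    centers[idx, ] + matrix(rnorm(900, 0, 0.2), 300)
  })
  ks <- choose_state_number(ab, 2:8, seed = 1)
  expect_equal(ks$k, 3)
  expect_false(ks$degenerate)

  # identical rows: SSE ~ 0 everywhere, degenerate flag
  ab0 <- matrix(1, 50, 3)
  ks0 <- choose_state_number(ab0, 2:5, seed = 1)
  expect_true(ks0$degenerate)
  expect_error(choose_state_number(ab, 2:3, seed = 1), "k_range")
})

test_that("state grouping applies the conservation fraction rules", {
  # three species; states built directly from planted fractions
  ab <- rbind(
    matrix(rep(c(1, 1, 1), 20), ncol = 3, byrow = TRUE),     # state 1: all A
    matrix(rep(c(-1, -1, -1), 20), ncol = 3, byrow = TRUE),  # state 2: all B
    matrix(rep(c(1, -1, -1), 20), ncol = 3, byrow = TRUE))   # state 3: ref A only
  colnames(ab) <- c("reference", "s1", "s2")
  states <- rep(1:3, each = 20)
  # dilute state 1 to 0.95 A and state 2 to 0.80 B per species
  flip <- function(rows, col, k) { ab[rows[seq_len(k)], col] <<- -ab[rows[seq_len(k)], col] }
  for (cc in 1:3) flip(which(states == 1), cc, 1)   # 19/20 = 0.95 A
  for (cc in 1:3) flip(which(states == 2), cc, 4)   # 16/20 = 0.80 B
  gr <- group_states(assign_states(ab, 3, states = states))
  expect_equal(gr$group[gr$state == 1], "CA")    # >0.90 A everywhere
  expect_equal(gr$group[gr$state == 2], "WCB")   # 0.70-0.90 B everywhere
  expect_equal(gr$group[gr$state == 3], "NC")
  expect_true(gr$hs_a[gr$state == 3])            # ref A-rich, queries A-poor
  # invariance to state relabeling
  relab <- c(3L, 1L, 2L)[states]
  gr2 <- group_states(assign_states(ab, 3, states = relab))
  expect_equal(sort(gr2$group), sort(gr$group))
  expect_equal(attr(gr2, "bin_group"), attr(gr, "bin_group"))
})

test_that("conserved compartmentalization is recovered within 5 points", {
  spec <- sim_spec(chrom_length = 4e7, depth = 8e6, seed = 2)
  sim <- simulate_species_set(spec, resolutions = c(2e4, 1e5))
  tracks <- lapply(sim$truth$species, function(sp) {
    mats <- sim$species[[sp]]
    kr100 <- kr_balance(mats[["1e+05"]])
    oe100 <- observed_over_expected(kr100,
                                    expected_by_distance(kr100, "mean"))
    lowres <- call_low_res_compartments(oe100, sim$truth$gene_density100)
    kr20 <- kr_balance(mats[["20000"]])
    oe20 <- observed_over_expected(kr20, expected_by_distance(kr20, "mean"))
    ab_index(oe20, lowres)
  })
  names(tracks) <- sim$truth$species
  hb <- build_homologous_bins(tracks$human, sim$maps, tracks[-1])
  st <- assign_states(hb$ab, k = 12, seed = 4)  # head-room over 2^3 patterns
  gr <- group_states(st)
  called <- mean(attr(gr, "bin_group") %in% c("CA", "WCA", "CB", "WCB"))
  sgn <- sapply(sim$truth$sign_per_species, identity)
  cons_block <- apply(sgn, 1, function(x) all(x == x[1]))
  b100 <- sim$truth$block_of_100[
    pmin(length(sim$truth$block_of_100),
         floor(bin_starts(tracks$human$grid) / 1e5) + 1)]
  planted <- mean(cons_block[b100[hb$bins]])
  expect_lt(abs(called - planted), 0.05)
})

test_that("exact boundary fractions stay below the open thresholds", {
  # exactly 0.90 A in every species is not CA (strict inequality)
  ab <- matrix(rep(1, 60), ncol = 3)
  ab[1:2, ] <- -1   # 18/20 = 0.90
  colnames(ab) <- c("reference", "s1", "s2")
  gr <- group_states(assign_states(ab, 1, states = rep(1L, 20)))
  expect_equal(gr$group, "WCA")
})
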