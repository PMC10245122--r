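test_that("triplet loading mirrors, sums duplicates and rejects bad input", {
  g <- bin_grid("chrT", 2e4, 3)
  f <- withr::local_tempfile()
  writeLines(c("0\t1\t5"), f)
  m <- load_contacts(f, g)
  expect_equal(m$values[1, 2], 5)
  expect_equal(m$values[2, 1], 5)
  expect_equal(sum(m$values), 10)

  writeLines(c("0\t1\t2", "1\t0\t3"), f)
  expect_equal(load_contacts(f, g)$values[1, 2], 5)

  file.create(f2 <- withr::local_tempfile())
  m0 <- load_contacts(f2, g)
  expect_equal(m0$total, 0)
  expect_true(all(m0$values == 0))

  writeLines(c("0\t5\t1"), f)
  expect_error(load_contacts(f, g), "index")
  writeLines(c("0\t1\t-2"), f)
  expect_error(load_contacts(f, g), "negative")
})

test_that("contact matrices round-trip through triplet files", {
  m <- random_contact_matrix(12, seed = 5)
  f <- withr::local_tempfile()
  write_contacts(m, f)
  m2 <- load_contacts(f, m$grid)
  expect_equal(m2$values, m$values)
})

test_that("KR balancing equalizes row sums and matches the equation oracle", {
  # 2x2 off-diagonal matrix balances exactly
  m2 <- contact_matrix(matrix(c(0, 4, 4, 0), 2), bin_grid("c", 1e4, 2))
  b2 <- kr_balance(m2)
  rs <- rowSums(b2$values)
  expect_equal(rs[1], rs[2])

  # diagonal matrix is already balanced, weights equal
  md <- contact_matrix(diag(3) * 2, bin_grid("c", 1e4, 3))
  bd <- kr_balance(md)
  expect_equal(max(bd$weights) / min(bd$weights), 1, tolerance = 1e-8)

  # random positive 20x20: row sums uniform, weights match the independent
  # fixed-point oracle for the balancing equations up to global scale
  a <- with_seed(42, {
    x <- matrix(rpois(400, 20) + 1, 20)
    round((x + t(x)) / 2)
  })
  m <- contact_matrix(a, bin_grid("c", 1e4, 20))
  b <- kr_balance(m, tol = 1e-12)
  rs <- rowSums(b$values)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-8)
  w_oracle <- balance_oracle(a)
  ratio <- b$weights / w_oracle
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-6)
})

test_that("masked all-zero bins survive balancing and propagate", {
  a <- with_seed(1, { x <- matrix(rpois(100, 10) + 1, 10); round((x + t(x)) / 2) })
  a[4, ] <- 0; a[, 4] <- 0
  m <- contact_matrix(a, bin_grid("c", 1e4, 10))
  expect_false(m$mask[4])
  b <- kr_balance(m)
  expect_true(is.na(b$weights[4]))
  expect_true(all(b$values[4, ] == 0))
})

test_that("distance decay estimation follows its estimator", {
  cm <- toy_matrix(5, function(k) rep(3, k))
  d <- expected_by_distance(cm, "median")
  expect_equal(d$expected, rep(3, 5))

  # off-diagonal values {1,3} at d=1 -> median 2
  v <- matrix(0, 3, 3); v[1, 2] <- v[2, 1] <- 1; v[2, 3] <- v[3, 2] <- 3
  diag(v) <- 5
  cm2 <- contact_matrix(v, bin_grid("c", 1e4, 3))
  expect_equal(expected_by_distance(cm2, "median")$expected[2], 2)
  expect_equal(expected_by_distance(cm2, "mean")$expected[2], 2)

  # strictly decaying matrix gives a monotone curve
  n <- 15
  v3 <- outer(1:n, 1:n, function(i, j) round(100 / (1 + abs(i - j))))
  cm3 <- contact_matrix(v3, bin_grid("c", 1e4, n))
  e <- expected_by_distance(cm3, "median")$expected
  expect_true(all(diff(e) <= 0))
})

test_that("observed/expected normalization matches the elementwise oracle", {
  m <- random_contact_matrix(15, seed = 9)
  dec <- expected_by_distance(m, "mean")
  oe <- observed_over_expected(m, dec)
  for (i in 1:15) for (j in 1:15) {
    e <- dec$expected[abs(i - j) + 1]
    expect_equal(oe$values[i, j], if (e > 0) m$values[i, j] / e else 0)
  }
  # per-stratum mean of O/E is exactly 1 under the mean estimator
  for (d in 0:10) {
    idx <- cbind(1:(15 - d), 1:(15 - d) + d)
    expect_equal(mean(oe$values[idx]), 1, tolerance = 1e-12)
  }
  # identity case: matrix equal to its own decay curve
  n <- 8
  v <- matrix(dec$expected[abs(outer(1:n, 1:n, "-")) + 1], n)
  cm <- contact_matrix(round(v), bin_grid("c", 1e4, n))
  dec2 <- expected_by_distance(cm, "mean")
  oe2 <- observed_over_expected(cm, dec2)
  expect_true(all(abs(oe2$values - 1) < 1e-12))
  # grid mismatch is a contract error
  expect_error(observed_over_expected(random_contact_matrix(10, 1), dec),
               "grid")
})

test_that("downsampling is a seeded binomial thinning", {
  m <- random_contact_matrix(20, seed = 3, lambda = 25)
  expect_equal(downsample(m, m$total, seed = 1)$values, m$values)
  expect_true(all(downsample(m, 0, seed = 1)$values == 0))
  half <- round(m$total / 2)
  d1 <- downsample(m, half, seed = 7)
  d2 <- downsample(m, half, seed = 7)
  expect_identical(d1$values, d2$values)              # seed reproducibility
  expect_equal(d1$values, t(d1$values))               # symmetry
  p <- half / m$total
  sd3 <- 3 * sqrt(m$total * p * (1 - p))
  expect_lt(abs(d1$total - half), sd3)
  expect_error(downsample(m, m$total + 1, seed = 1), "target")
})

test_that("quantile normalization equalizes sorted value vectors", {
  a <- random_contact_matrix(12, seed = 21)
  b <- random_contact_matrix(12, seed = 22)
  qn <- quantile_normalize(list(a, b))
  ut <- upper.tri(qn[[1]]$values, diag = TRUE)
  keep <- qn[[1]]$mask
  v1 <- sort(qn[[1]]$values[keep, keep][upper.tri(qn[[1]]$values[keep, keep], TRUE)])
  v2 <- sort(qn[[2]]$values[keep, keep][upper.tri(qn[[2]]$values[keep, keep], TRUE)])
  expect_equal(v1, v2)
  # B = 2A maps both to the elementwise mean 1.5A
  b2 <- contact_matrix(a$values * 2, a$grid)
  qn2 <- quantile_normalize(list(a, b2))
  expect_equal(qn2[[1]]$values, 1.5 * a$values, tolerance = 1e-12)
  expect_equal(qn2[[2]]$values, 1.5 * a$values, tolerance = 1e-12)
  expect_error(quantile_normalize(list(a)), "at least 2")
})
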