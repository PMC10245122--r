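# shared fixture builders; everything is generated in code

# symmetric integer contact matrix from an upper-triangle filler
toy_matrix <- function(n, fill, chrom = "chrT", res = 2e4) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- fill(sum(ut))
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  contact_matrix(m, bin_grid(chrom, res, n))
}

random_contact_matrix <- function(n, seed, lambda = 10, res = 2e4) {
  with_seed(seed, toy_matrix(n, function(k) stats::rpois(k, lambda),
                             res = res))
}

# identity homology map covering [0, len) in one block
identity_map <- function(len, chrom = "chrS", reciprocal = TRUE) {
  homology_map(data.frame(ref_chrom = chrom, ref_start = 0, ref_end = len,
                          q_chrom = chrom, q_start = 0, q_end = len,
                          strand = "+", reciprocal = reciprocal))
}

# independent Sinkhorn-equation oracle: solves x_i * (A x)_i = 1 exactly
# with a damped Jacobi fixed point unrelated to the package's iteration
balance_oracle <- function(a, iters = 10000, tol = 1e-13) {
  x <- rep(1, nrow(a))
  for (i in seq_len(iters)) {
    r <- x * as.vector(a %*% x)
    if (max(abs(r - 1)) < tol) break
    x <- (x / r + x) / 2  # half-step damping
  }
  x
}

# brute-force TAD strength: literal double-median over explicit pair lists
tad_strength_oracle <- function(values, start_bin, end_bin) {
  n <- nrow(values)
  len <- end_bin - start_bin + 1L
  inside <- start_bin:end_bin
  nb <- c(seq.int(max(1L, start_bin - len), start_bin - 1L),
          seq.int(end_bin + 1L, min(n, end_bin + len)))
  nb <- nb[nb >= 1L & nb <= n]
  ratios <- c()
  for (d in 1:(len - 1L)) {
    intra <- c(); inter <- c()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i != d) next
      if (i %in% inside && j %in% inside) intra <- c(intra, values[i, j])
      ins <- (i %in% inside) + (j %in% inside)
      nbc <- (i %in% nb) + (j %in% nb)
      if (ins == 1 && nbc == 1) inter <- c(inter, values[i, j])
    }
    if (length(inter) == 0) next
    med_inter <- stats::median(inter)
    if (med_inter > 0) ratios <- c(ratios, stats::median(intra) / med_inter)
  }
  stats::median(ratios)
}

# exact one-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_oracle <- function(x, y) {
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_along(x)])
  combs <- utils::combn(length(x) + length(y), length(x))
  stat <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mean(stat >= u_obs)
}
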