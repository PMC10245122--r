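#' Permutation test for HAR enrichment in a set of enhancer bins
#'
#' The statistic is the fraction of target enhancer bins containing at
#' least one HAR. The null draws same-size bin sets without replacement
#' from the enhancer universe; the p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param target Data frame of target enhancer bins (`start`, `end`, bp).
#' @param universe Data frame of all enhancer bins (superset of `target`).
#' @param hars Data frame of HAR intervals (`start`, `end`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `observed` (fraction), `null` (vector), `p`.
#' @export
har_permutation_test <- function(target, universe, hars, n_perm = 1000,
                                 seed = 1) {
  if (nrow(target) > nrow(universe))
    stop("contract error: target larger than universe")
  har_ir <- IRanges::reduce(IRanges::IRanges(start = hars$start + 1L,
                                             end = hars$end))
  hit <- function(bins) {
    ir <- IRanges::IRanges(start = bins$start + 1L, end = bins$end)
    IRanges::overlapsAny(ir, har_ir)
  }
  obs <- mean(hit(target))
  uhit <- hit(universe)
  nt <- nrow(target)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    mean(uhit[sample.int(length(uhit), nt)])
  }, numeric(1)))
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (1 + n_perm))
}

#' SNP density and enrichment in enhancer bins by PEI class
#'
#' @param class_bins Named list: per class, a data frame of enhancer bins
#'   (`start`, `end`, bp).
#' @param snps Data frame of SNP positions (`pos`, bp).
#' @return List with `density` (per class: SNPs per Mb) and `fisher`
#'   (pairwise 2x2 Fisher comparisons on SNP-containing vs empty bins).
#' @export
snp_enrichment <- function(class_bins, snps) {
  snp_ir <- IRanges::IRanges(start = snps$pos + 1L, width = 1L)
  stats_ <- lapply(class_bins, function(bins) {
    if (is.null(bins) || nrow(bins) == 0)
      return(list(n_snp = NA_real_, mb = NA_real_, with = NA_integer_,
                  without = NA_integer_))
    ir <- IRanges::IRanges(start = bins$start + 1L, end = bins$end)
    cov <- IRanges::countOverlaps(ir, snp_ir)
    list(n_snp = sum(cov), mb = sum(IRanges::width(ir)) / 1e6,
         with = sum(cov > 0), without = sum(cov == 0))
  })
  density <- data.frame(
    class = names(class_bins),
    snps_per_mb = vapply(stats_, function(s) s$n_snp / s$mb, numeric(1)))
  fisher <- NULL
  if (length(class_bins) >= 2) {
    combs <- utils::combn(names(class_bins), 2, simplify = FALSE)
    fisher <- do.call(rbind, lapply(combs, function(cc) {
      s1 <- stats_[[cc[1]]]; s2 <- stats_[[cc[2]]]
      if (is.na(s1$with) || is.na(s2$with))
        return(data.frame(class1 = cc[1], class2 = cc[2],
                          odds_ratio = NA_real_, p = NA_real_))
      ft <- stats::fisher.test(matrix(c(s1$with, s1$without,
                                        s2$with, s2$without), 2, byrow = TRUE))
      data.frame(class1 = cc[1], class2 = cc[2],
                 odds_ratio = unname(ft$estimate), p = ft$p.value)
    }))
  }
  list(density = density, fisher = fisher)
}
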