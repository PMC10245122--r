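#' TF binding preference between human-specific and conserved PEIs
#'
#' For each TF the preference statistic is
#' `delta = (-log10 p_HS) - (-log10 p_Cons)` over supplied motif-enrichment
#' p-values; `delta > delta_cut` marks an HS-preferring TF,
#' `delta < -delta_cut` a Cons-preferring one (strict inequalities),
#' anything else neutral. Zero p-values are capped at `p_floor` before the
#' log.
#'
#' @param enrichment Data frame with `tf`, `p_hs`, `p_cons`.
#' @param delta_cut Preference cut (5).
#' @param p_floor Floor for zero p-values (1e-300).
#' @return `enrichment` with `delta` and `preference` in
#'   `{HS, Cons, neutral}`.
#' @export
tf_preference <- function(enrichment, delta_cut = 5, p_floor = 1e-300) {
  p_hs <- pmax(enrichment$p_hs, p_floor)
  p_cons <- pmax(enrichment$p_cons, p_floor)
  delta <- -log10(p_hs) + log10(p_cons)
  enrichment$delta <- delta
  enrichment$preference <- ifelse(delta > delta_cut, "HS",
                                  ifelse(delta < -delta_cut, "Cons", "neutral"))
  enrichment
}

#' Candidate TF pairs for PEI formation
#'
#' A pair (enhancer-TF, promoter-TF) is a candidate when both TFs occur at
#' least `min_occ` times in ATAC peaks of their respective anchor role, both
#' are expressed above `min_tpm`, and the pair is connected in the PPI
#' network at path length 1 (direct) or 2 (indirect, one intermediate
#' protein).
#'
#' @param hits Motif hit data frame with `tf`, `role` (`"promoter"` or
#'   `"enhancer"`), `region` (region/PEI id).
#' @param expr Named numeric vector of TF TPM values; TFs absent from it
#'   are excluded with a warning.
#' @param ppi Data frame of undirected PPI edges (`a`, `b`).
#' @param min_occ Minimum motif occurrences (3).
#' @param min_tpm Expression cut, strict (1).
#' @return Data frame of pairs: `enhancer_tf`, `promoter_tf`, `ppi_mode`
#'   in `{direct, indirect}`.
#' @export
candidate_tf_pairs <- function(hits, expr, ppi, min_occ = 3, min_tpm = 1) {
  occ <- stats::aggregate(list(n = hits$region),
                          by = list(tf = hits$tf, role = hits$role), length)
  keep_occ <- function(role) occ$tf[occ$role == role & occ$n >= min_occ]
  e_tfs <- keep_occ("enhancer")
  p_tfs <- keep_occ("promoter")
  all_tf <- union(e_tfs, p_tfs)
  missing <- setdiff(all_tf, names(expr))
  if (length(missing)) {
    warning(sprintf("TFs absent from expression table excluded: %s",
                    paste(missing, collapse = ", ")))
  }
  expressed <- names(expr)[expr > min_tpm]
  e_tfs <- intersect(e_tfs, expressed)
  p_tfs <- intersect(p_tfs, expressed)
  if (length(e_tfs) == 0 || length(p_tfs) == 0)
    return(data.frame(enhancer_tf = character(0), promoter_tf = character(0),
                      ppi_mode = character(0)))
  gr <- igraph::graph_from_data_frame(ppi[, c("a", "b")], directed = FALSE)
  gr <- igraph::simplify(gr)
  verts <- igraph::V(gr)$name
  grid <- expand.grid(enhancer_tf = e_tfs, promoter_tf = p_tfs,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$enhancer_tf != grid$promoter_tf, , drop = FALSE]
  mode <- vapply(seq_len(nrow(grid)), function(k) {
    a <- grid$enhancer_tf[k]; b <- grid$promoter_tf[k]
    if (!(a %in% verts) || !(b %in% verts)) return("none")
    dpath <- igraph::distances(gr, v = a, to = b)[1, 1]
    if (dpath == 1) "direct" else if (dpath == 2) "indirect" else "none"
  }, character(1))
  grid$ppi_mode <- mode
  res <- grid[grid$ppi_mode != "none", , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-PEI co-occurrence indicator of a TF pair
#'
#' 1 iff the enhancer-TF hits the PEI's enhancer region AND the promoter-TF
#' hits its promoter region.
#'
#' @param hits Motif hit data frame (`tf`, `role`, `region` = PEI id).
#' @param pei_ids Character vector of PEI ids.
#' @param enhancer_tf,promoter_tf TF ids.
#' @return Integer 0/1 vector along `pei_ids`.
#' @export
pair_cooccurrence <- function(hits, pei_ids, enhancer_tf, promoter_tf) {
  e_hit <- unique(hits$region[hits$tf == enhancer_tf & hits$role == "enhancer"])
  p_hit <- unique(hits$region[hits$tf == promoter_tf & hits$role == "promoter"])
  as.integer(pei_ids %in% e_hit & pei_ids %in% p_hit)
}

#' Mann-Whitney preference test for one TF pair
#'
#' One-sided Mann-Whitney U test comparing the pair's per-PEI co-occurrence
#' indicators between human-specific and conserved PEI sets (HS greater);
#' the pair is kept when `p < alpha`. For small samples
#' (`n1 + n2 <= exact_max`) the p-value is exact over the permutation
#' distribution of the rank sum (ties handled by midranks, computed by
#' dynamic programming); larger samples use the normal approximation with
#' tie correction.
#'
#' @param hs_vec,cons_vec 0/1 co-occurrence vectors for the two PEI sets.
#' @param alpha Significance cut, strict (0.05).
#' @param exact_max Largest combined sample size for the exact p (30).
#' @return List with `p`, `keep`; `NA` when either set is empty.
#' @export
pair_preference_test <- function(hs_vec, cons_vec, alpha = 0.05,
                                 exact_max = 30L) {
  if (length(hs_vec) == 0 || length(cons_vec) == 0)
    return(list(p = NA_real_, keep = NA))
  n1 <- length(hs_vec); n2 <- length(cons_vec)
  p <- if (n1 + n2 <= exact_max) mw_exact_p(hs_vec, cons_vec)
    else suppressWarnings(
      stats::wilcox.test(hs_vec, cons_vec, alternative = "greater",
                         exact = FALSE, correct = TRUE)$p.value)
  list(p = p, keep = p < alpha)
}

# exact one-sided rank-sum p over the permutation distribution: counts the
# k-subsets whose (doubled mid-)rank sum reaches the observed one, via a
# subset-sum dynamic program
mw_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  w <- as.integer(round(2 * r))  # midranks are multiples of 1/2
  tot <- sum(w)
  dp <- matrix(0, n1 + 1L, tot + 1L)
  dp[1L, 1L] <- 1
  for (wi in w) {
    kmax <- n1
    for (k in kmax:1) {
      src <- dp[k, 1:(tot + 1L - wi)]
      dp[k + 1L, (wi + 1L):(tot + 1L)] <-
        dp[k + 1L, (wi + 1L):(tot + 1L)] + src
    }
  }
  obs <- sum(w[seq_len(n1)])
  sum(dp[n1 + 1L, (obs + 1L):(tot + 1L)]) / choose(n, n1)
}

#' Binding-site sequence conservation contrast per TF
#'
#' Per TF, a two-sided Wilcoxon rank-sum test between the phastCons scores
#' of its hits in human-specific vs conserved PEIs; the direction records
#' which class has the lower median.
#'
#' @param hits Data frame with `tf`, `class` (`"HS"`/`"Cons"`), `phastcons`.
#' @param min_hits Minimum hits per class (3); fewer gives `NA`.
#' @return Data frame per TF: `tf`, `median_hs`, `median_cons`, `direction`
#'   (`lower-in-HS`, `lower-in-Cons`, `none`), `p`.
#' @export
binding_site_conservation <- function(hits, min_hits = 3) {
  out <- lapply(unique(hits$tf), function(tf) {
    hs <- hits$phastcons[hits$tf == tf & hits$class == "HS"]
    cons <- hits$phastcons[hits$tf == tf & hits$class == "Cons"]
    if (length(hs) < min_hits || length(cons) < min_hits)
      return(data.frame(tf = tf, median_hs = NA_real_, median_cons = NA_real_,
                        direction = NA_character_, p = NA_real_))
    p <- if (length(unique(c(hs, cons))) == 1) 1  # fully tied scores
      else suppressWarnings(stats::wilcox.test(hs, cons)$p.value)
    mh <- stats::median(hs); mc <- stats::median(cons)
    dir <- if (mh < mc) "lower-in-HS" else if (mh > mc) "lower-in-Cons" else "none"
    data.frame(tf = tf, median_hs = mh, median_cons = mc, direction = dir,
               p = p)
  })
  do.call(rbind, out)
}
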