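#' TAD strength statistic
#'
#' For each genomic distance `d` from 1 bin to the TAD length minus 1, the
#' intra-TAD contact is the median matrix value over pairs at distance `d`
#' with both ends inside the TAD, and the inter-TAD contact is the median
#' over pairs at distance `d` with one end inside the TAD and the other in
#' the neighbor region (the TAD extended up- and downstream by its own
#' length, clipped to the chromosome). TAD strength is the median over
#' distances of the intra/inter ratio.
#'
#' @param m A `contact_matrix`.
#' @param start_bin,end_bin Inclusive 1-based bin range of the TAD
#'   (>= 3 bins).
#' @return Strength (numeric scalar).
#' @export
tad_strength <- function(m, start_bin, end_bin) {
  n <- m$grid$n_bins
  len <- end_bin - start_bin + 1L
  if (len < 3L) stop("TAD shorter than 3 bins")
  inside <- start_bin:end_bin
  nb <- c(seq.int(max(1L, start_bin - len), start_bin - 1L),
          seq.int(end_bin + 1L, min(n, end_bin + len)))
  nb <- nb[nb >= 1L & nb <= n]
  v <- m$values
  ratios <- rep(NA_real_, len - 1L)
  any_inter <- FALSE
  for (d in seq_len(len - 1L)) {
    i <- inside[seq_len(len - d)]
    intra <- stats::median(v[cbind(i, i + d)])
    pairs_lo <- nb[(nb + d) %in% inside]
    pairs_hi <- nb[(nb - d) %in% inside]
    inter_vals <- c(v[cbind(pairs_lo, pairs_lo + d)],
                    v[cbind(pairs_hi, pairs_hi - d)])
    if (length(inter_vals) == 0) next
    inter <- stats::median(inter_vals)
    if (inter > 0) {
      any_inter <- TRUE
      ratios[d] <- intra / inter
    }
  }
  if (!any_inter) stop("undefined strength: inter-TAD contacts all zero")
  stats::median(ratios, na.rm = TRUE)
}

#' Aggregate rescaled TAD contact map
#'
#' Each TAD window (the TAD extended by its own length on both sides) is
#' rescaled to `out_size x out_size` by interval-overlap-weighted averaging
#' and the windows are averaged elementwise. The aggregate strength is the
#' mean of the central third diagonal block divided by the mean of the two
#' adjacent center-vs-flank blocks. With `expected = "inter"` (default)
#' each window is first divided by a distance-decay curve estimated from
#' inter-domain pairs only, so that domain enrichment is preserved in the
#' numerator rather than absorbed into the expectation.
#'
#' @param m A `contact_matrix`.
#' @param tads Data frame with `start_bin`, `end_bin` (TADs whose 3x window
#'   leaves the chromosome are skipped).
#' @param out_size Output side length in pixels (multiple of 3; default 30).
#' @param expected `"inter"` normalizes by the inter-domain decay;
#'   `"none"` aggregates the matrix values as they are.
#' @return List with `map` (`out_size x out_size` mean matrix), `ratio`
#'   (aggregate strength), `n_used`.
#' @export
aggregate_tad_map <- function(m, tads, out_size = 30L,
                              expected = c("inter", "none")) {
  expected <- match.arg(expected)
  stopifnot(out_size %% 3L == 0L)
  n <- m$grid$n_bins
  vals <- m$values
  if (expected == "inter" && nrow(tads) > 0) {
    tid <- rep(0L, n)
    for (k in seq_len(nrow(tads)))
      tid[tads$start_bin[k]:tads$end_bin[k]] <- k
    # pairs with both ends outside annotated TADs are ambiguous background
    # and are excluded from the inter-domain decay estimate
    inter <- outer(tid, tid, "!=")
    dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
    sel <- which(inter)
    sums <- rowsum(m$values[sel], dmat[sel])
    cnts <- rowsum(rep(1, length(sel)), dmat[sel])
    e <- rep(NA_real_, n)
    e[as.integer(rownames(sums)) + 1L] <- sums[, 1] / cnts[, 1]
    # fill strata without inter-domain pairs from the global decay
    glob <- expected_by_distance(m, "mean")$expected
    bad <- is.na(e) | e == 0
    e[bad] <- glob[bad]
    emat <- matrix(e[dmat + 1L], n, n)
    vals <- m$values / emat
    vals[!is.finite(vals)] <- 0
  }
  acc <- matrix(0, out_size, out_size)
  used <- 0L
  for (k in seq_len(nrow(tads))) {
    len <- tads$end_bin[k] - tads$start_bin[k] + 1L
    lo <- tads$start_bin[k] - len
    hi <- tads$end_bin[k] + len
    if (lo < 1L || hi > n) next
    wmat <- rescale_weights(hi - lo + 1L, out_size)
    acc <- acc + wmat %*% vals[lo:hi, lo:hi] %*% t(wmat)
    used <- used + 1L
  }
  if (used == 0L)
    return(list(map = matrix(NA_real_, out_size, out_size), ratio = NA_real_,
                n_used = 0L))
  map <- acc / used
  third <- out_size / 3L
  mid <- (third + 1L):(2L * third)
  left <- 1:third
  right <- (2L * third + 1L):out_size
  center <- mean(map[mid, mid])
  flank <- mean(c(map[mid, left], map[mid, right]))
  list(map = map, ratio = center / flank, n_used = used)
}

# overlap-fraction weight matrix mapping n_src bins onto n_out pixels;
# rows sum to 1, so the rescaling is an exact overlap-weighted average
rescale_weights <- function(n_src, n_out) {
  edges <- seq(0, n_src, length.out = n_out + 1L)
  w <- matrix(0, n_out, n_src)
  for (r in seq_len(n_out)) {
    lo <- edges[r]; hi <- edges[r + 1L]
    cols <- seq.int(floor(lo) + 1L, ceiling(hi))
    cols <- cols[cols >= 1L & cols <= n_src]
    ov <- pmin(hi, cols) - pmax(lo, cols - 1L)
    w[r, cols] <- ov / (hi - lo)
  }
  w
}

#' Gene composition of TAD classes with Fisher enrichment
#'
#' Per TAD class: gene density (genes per Mb of TAD span) and, for each
#' named gene set, the count of genes falling inside the class's TADs.
#' Classes are compared pairwise by 2x2 Fisher's exact test on
#' set-membership among the genes they contain.
#'
#' @param tads Data frame with `start`, `end` (bp) and `class`.
#' @param genes Data frame with `pos` (TSS bp) and `gene` id.
#' @param gene_sets Named list of character vectors of gene ids.
#' @return List with `density` (per-class data frame) and `fisher` (data
#'   frame of pairwise class comparisons per set: odds ratio + p; `NA` for
#'   empty classes).
#' @export
tad_composition_stats <- function(tads, genes, gene_sets = list()) {
  classes <- unique(tads$class)
  gene_ir <- IRanges::IRanges(start = genes$pos + 1L, width = 1L)
  per_class <- lapply(classes, function(cl) {
    td <- tads[tads$class == cl, , drop = FALSE]
    if (nrow(td) == 0) return(list(genes = character(0), mb = 0))
    tir <- IRanges::reduce(IRanges::IRanges(start = td$start + 1L, end = td$end))
    hit <- IRanges::overlapsAny(gene_ir, tir)
    list(genes = genes$gene[hit], mb = sum(IRanges::width(tir)) / 1e6)
  })
  names(per_class) <- classes
  density <- data.frame(
    class = classes,
    n_genes = vapply(per_class, function(x) length(x$genes), integer(1)),
    mb = vapply(per_class, function(x) x$mb, numeric(1)))
  density$genes_per_mb <- ifelse(density$mb > 0,
                                 density$n_genes / density$mb, NA_real_)
  fisher <- list()
  if (length(classes) >= 2 && length(gene_sets) > 0) {
    combs <- utils::combn(as.character(classes), 2, simplify = FALSE)
    for (set_name in names(gene_sets)) {
      set <- gene_sets[[set_name]]
      for (cc in combs) {
        g1 <- per_class[[cc[1]]]$genes
        g2 <- per_class[[cc[2]]]$genes
        if (length(g1) == 0 || length(g2) == 0) {
          fisher[[length(fisher) + 1L]] <- data.frame(
            set = set_name, class1 = cc[1], class2 = cc[2],
            odds_ratio = NA_real_, p = NA_real_)
          next
        }
        tab <- matrix(c(sum(g1 %in% set), sum(!g1 %in% set),
                        sum(g2 %in% set), sum(!g2 %in% set)),
                      2, 2, byrow = TRUE)
        ft <- stats::fisher.test(tab)
        fisher[[length(fisher) + 1L]] <- data.frame(
          set = set_name, class1 = cc[1], class2 = cc[2],
          odds_ratio = unname(ft$estimate), p = ft$p.value)
      }
    }
  }
  list(density = density,
       fisher = if (length(fisher)) do.call(rbind, fisher) else NULL)
}
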