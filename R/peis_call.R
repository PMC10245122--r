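#' Build promoter anchors from TSS annotations
#'
#' The promoter window is 2200 bp upstream to 500 bp downstream of the TSS
#' (strand-aware); the anchor bin is the 10-kb bin containing the TSS.
#'
#' @param tss Data frame with `gene`, `pos` (TSS bp), `strand` (`"+"/"-"`).
#' @param grid The 10-kb `bin_grid`.
#' @return Data frame with `gene`, `tss`, `strand`, `win_start`, `win_end`
#'   (half-open), `anchor_bin`.
#' @export
make_promoters <- function(tss, grid) {
  up <- 2200; down <- 500
  plus <- tss$strand == "+"
  win_start <- ifelse(plus, tss$pos - up, tss$pos - down + 1)
  win_end <- win_start + up + down
  data.frame(gene = tss$gene, tss = tss$pos, strand = tss$strand,
             win_start = win_start, win_end = win_end,
             anchor_bin = bin_of(grid, tss$pos))
}

#' Domain-aware expected contact matrix
#'
#' Background model for PEI calling: the distance-decay expectation
#' `E(|i-j|)`, rescaled inside each TAD by a per-domain multiplicative
#' factor fitted as the median observed/expected ratio over the domain's
#' pairs. Pairs not inside a single TAD keep the global decay expectation.
#' This captures domain-specific elevation of contact frequency with one
#' parameter per domain.
#'
#' Per-bin coverage factors `c_i` (the mean observed/decay ratio of each
#' bin's row, normalized to mean 1) absorb residual bin-level biases such
#' as the inflation of chromosome-end bins by equal-row-sum balancing.
#'
#' @param m A `contact_matrix` (KR-balanced, count scale preserved).
#' @param tads Data frame with `start_bin`, `end_bin` (may be empty).
#' @param estimator Decay estimator (default `"mean"`, appropriate for a
#'   count expectation).
#' @return List with `expected` (n x n matrix), `decay`, `coverage`
#'   (per-bin factors), `tad_factor` (per-TAD fitted factors).
#' @export
expected_matrix <- function(m, tads = NULL, estimator = "mean") {
  decay <- expected_by_distance(m, estimator)
  n <- m$grid$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expd <- matrix(decay$expected[d + 1L], n, n)
  ratio <- m$values / expd
  ratio[!is.finite(ratio)] <- NA
  diag(ratio) <- NA
  cov_f <- rowMeans(ratio, na.rm = TRUE)
  cov_f[!m$mask | !is.finite(cov_f)] <- NA
  cov_f <- cov_f / mean(cov_f, na.rm = TRUE)
  cov_f[is.na(cov_f)] <- 1
  expd <- expd * outer(cov_f, cov_f)
  factors <- numeric(0)
  if (!is.null(tads) && nrow(tads) > 0) {
    factors <- rep(NA_real_, nrow(tads))
    for (k in seq_len(nrow(tads))) {
      idx <- tads$start_bin[k]:tads$end_bin[k]
      obs <- m$values[idx, idx]
      exp_ <- expd[idx, idx]
      off <- abs(outer(idx, idx, "-")) > 0
      ok <- off & exp_ > 0
      if (!any(ok)) next
      f <- stats::median(obs[ok] / exp_[ok])
      if (!is.finite(f) || f <= 0) next
      factors[k] <- f
      expd[idx, idx] <- expd[idx, idx] * f
    }
  }
  list(expected = expd, decay = decay, coverage = cov_f,
       tad_factor = factors)
}

#' Call promoter-enhancer interactions
#'
#' For every promoter anchor, each bin within `max_span` is tested for
#' contact enrichment over the domain-aware background: the p-value is the
#' Poisson upper tail at the observed count given the expected value, FDR is
#' Benjamini-Hochberg over all promoter-centered tests, and retained PEIs
#' satisfy FDR <= `fdr_cut`, interaction length >= `min_len`, and do not
#' link two promoters (candidate bins overlapping any promoter window are
#' dropped).
#'
#' @param m KR-balanced 10-kb `contact_matrix` (count scale).
#' @param promoters Data frame from [make_promoters()].
#' @param tads Optional TAD data frame for the background model.
#' @param max_span Maximum interaction span in bp (1e7).
#' @param fdr_cut FDR cutoff (0.001).
#' @param min_len Minimum interaction length in bp (20000).
#' @return Data frame of retained PEIs: `gene`, `p_bin`, `e_bin`, `observed`,
#'   `expected`, `enrichment` (observed - expected), `p`, `fdr`, `length`.
#'   The full test table is attached as attribute `tests`.
#' @export
call_peis <- function(m, promoters, tads = NULL, max_span = 1e7,
                      fdr_cut = 0.001, min_len = 20000) {
  g <- m$grid
  bg <- expected_matrix(m, tads)
  span_bins <- floor(max_span / g$resolution)
  min_bins <- ceiling(min_len / g$resolution)
  # bins whose interval intersects any promoter window are promoter bins
  prom_bins <- unique(unlist(lapply(seq_len(nrow(promoters)), function(k) {
    lo <- bin_of(g, max(0, promoters$win_start[k]))
    hi <- bin_of(g, min(g$n_bins * g$resolution - 1, promoters$win_end[k] - 1))
    if (is.na(lo) || is.na(hi)) return(integer(0))
    lo:hi
  })))
  rows <- list()
  for (k in seq_len(nrow(promoters))) {
    pb <- promoters$anchor_bin[k]
    if (is.na(pb)) next
    if (!m$mask[pb]) {
      warning(sprintf("promoter %s anchor bin is masked; skipped",
                      promoters$gene[k]))
      next
    }
    j <- seq.int(max(1L, pb - span_bins), min(g$n_bins, pb + span_bins))
    j <- j[abs(j - pb) >= min_bins & m$mask[j] & !(j %in% prom_bins)]
    if (length(j) == 0) next
    obs <- m$values[pb, j]
    expd <- bg$expected[pb, j]
    ok <- expd > 0
    j <- j[ok]; obs <- obs[ok]; expd <- expd[ok]
    if (length(j) == 0) next
    # the Poisson tail is evaluated on the raw count scale: balanced values
    # are w_i*w_j times a Poisson count, so testing them directly would
    # inflate apparent significance wherever the weights exceed one
    f <- if (!is.null(m$weights)) m$weights[pb] * m$weights[j] else 1
    f[!is.finite(f) | f <= 0] <- 1
    p <- stats::ppois(ceiling(obs / f) - 1, lambda = expd / f,
                      lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = promoters$gene[k], p_bin = pb, e_bin = j, observed = obs,
      expected = expd, enrichment = obs - expd, p = p,
      length = abs(j - pb) * g$resolution)
  }
  if (length(rows) == 0) {
    res <- data.frame(gene = character(0), p_bin = integer(0),
                      e_bin = integer(0), observed = numeric(0),
                      expected = numeric(0), enrichment = numeric(0),
                      p = numeric(0), fdr = numeric(0), length = numeric(0))
    attr(res, "tests") <- res
    return(res)
  }
  tests <- do.call(rbind, rows)
  tests$fdr <- stats::p.adjust(tests$p, method = "BH")
  res <- tests[tests$fdr <= fdr_cut, , drop = FALSE]
  rownames(res) <- NULL
  rownames(tests) <- NULL
  attr(res, "tests") <- tests
  res
}

#' Annotate PEI enhancer bins with regular/super-enhancer status
#'
#' An enhancer bin is annotated with a peak class when the peaks overlap
#' more than half the bin or more than 5 kb of it (strict inequalities);
#' super-enhancers take precedence over regular enhancers.
#'
#' @param peis PEI data frame from [call_peis()].
#' @param grid The 10-kb `bin_grid`.
#' @param re_peaks,se_peaks Data frames with `start`, `end` (bp, half-open);
#'   may be `NULL`.
#' @param min_bp Absolute overlap cut in bp (5000).
#' @return `peis` with an `enhancer_class` column in `{SE, RE, none}`.
#' @export
annotate_enhancers <- function(peis, grid, re_peaks = NULL, se_peaks = NULL,
                               min_bp = 5000) {
  res <- grid$resolution
  overlap_bp <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0) return(rep(0, nrow(peis)))
    pk <- IRanges::reduce(IRanges::IRanges(start = peaks$start + 1L,
                                           end = peaks$end))
    bins <- IRanges::IRanges(start = (peis$e_bin - 1L) * res + 1L,
                             width = res)
    ov <- IRanges::findOverlaps(bins, pk)
    w <- IRanges::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(ov)], pk[S4Vectors::subjectHits(ov)]))
    out <- rep(0, nrow(peis))
    agg <- rowsum(w, S4Vectors::queryHits(ov))
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }
  passes <- function(w) w > min_bp | w > res / 2
  w_se <- overlap_bp(se_peaks)
  w_re <- overlap_bp(re_peaks)
  peis$enhancer_class <- ifelse(passes(w_se), "SE",
                                ifelse(passes(w_re), "RE", "none"))
  peis
}

#' Aggregate peak analysis (APA)
#'
#' Averages the O/E submatrix of size `(2*half_window+1)^2` centered on each
#' PEI pixel; the APA score is the center value over the mean of the
#' `corner x corner` block in the lower-left (short-distance) quadrant.
#' Scores above one indicate an enrichment peak. Pixels closer than
#' `half_window + corner` bins to the matrix edge or diagonal are skipped.
#'
#' @param m A 10-kb `contact_matrix`.
#' @param peis PEI data frame with `p_bin`, `e_bin`.
#' @param half_window Half window in bins (default 5).
#' @param corner Corner block side in bins (default 3).
#' @return List with `map` (aggregate window), `score`, `n_used`.
#' @export
apa <- function(m, peis, half_window = 5L, corner = 3L) {
  oe <- observed_over_expected(m, expected_by_distance(m, "mean"))
  n <- m$grid$n_bins
  hw <- half_window
  size <- 2L * hw + 1L
  guard <- hw + corner
  acc <- matrix(0, size, size)
  used <- 0L
  for (k in seq_len(nrow(peis))) {
    i <- min(peis$p_bin[k], peis$e_bin[k])
    j <- max(peis$p_bin[k], peis$e_bin[k])
    if (i - hw < 1L || j + hw > n || (j - i) < guard) next
    acc <- acc + oe$values[(i - hw):(i + hw), (j - hw):(j + hw)]
    used <- used + 1L
  }
  if (used == 0L) stop("empty result: no PEI far enough from edge and diagonal")
  map <- acc / used
  center <- map[hw + 1L, hw + 1L]
  ll <- map[(size - corner + 1L):size, 1:corner]
  list(map = map, score = center / mean(ll), n_used = used)
}

#' Distribution of PEIs per promoter
#'
#' @param peis PEI data frame with `gene` and optionally `class`.
#' @return Data frame of percentages over the categories `1, 2, 3, >3`
#'   PEIs per promoter, one row per class (or a single `all` row).
#' @export
promoter_valency <- function(peis) {
  if (!"class" %in% names(peis)) peis$class <- "all"
  out <- lapply(unique(peis$class), function(cl) {
    counts <- table(peis$gene[peis$class == cl])
    cat_ <- cut(as.integer(counts), breaks = c(0, 1, 2, 3, Inf),
                labels = c("1", "2", "3", ">3"))
    pct <- 100 * as.numeric(table(cat_)) / length(counts)
    data.frame(class = cl, category = c("1", "2", "3", ">3"), pct = pct)
  })
  do.call(rbind, out)
}
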