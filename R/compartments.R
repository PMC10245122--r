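#' Call low-resolution A/B compartments from a 100-kb O/E matrix
#'
#' Two-step caller, step one: the first principal component of the O/E
#' matrix is oriented by its Pearson correlation with gene density, so that
#' gene-rich bins land in compartment A. With positive correlation,
#' positive-PC1 bins are A and negative-PC1 bins are B; with negative
#' correlation the signs flip.
#'
#' @param oe O/E `contact_matrix` (typically 100-kb resolution).
#' @param gene_density Per-bin gene counts on the same grid.
#' @param on `"oe"` (default) computes PC1 on the O/E matrix itself;
#'   `"cor"` on its correlation matrix.
#' @return Object of class `lowres_compartments`: list with `pc1` (length
#'   `n_bins`, `NA` on masked bins), `r` (orientation correlation), `label`
#'   (factor `"A"`/`"B"`, `NA` on masked bins), `grid`.
#' @export
call_low_res_compartments <- function(oe, gene_density, on = c("oe", "cor")) {
  on <- match.arg(on)
  stopifnot(inherits(oe, "contact_matrix"))
  if (length(gene_density) != oe$grid$n_bins)
    stop("gene density length does not match grid")
  keep <- oe$mask
  x <- oe$values[keep, keep, drop = FALSE]
  if (on == "cor") x <- suppressWarnings(stats::cor(x))
  if (any(!is.finite(x))) x[!is.finite(x)] <- 0
  sds <- apply(x, 2, stats::sd)
  if (all(sds < 1e-12)) stop("degenerate input: constant O/E matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pc1_sub <- pc$x[, 1]
  if (stats::sd(pc1_sub) < 1e-12) stop("degenerate input: constant PC1")
  r <- stats::cor(pc1_sub, gene_density[keep])
  if (is.na(r) || r == 0) stop("ambiguous orientation: zero gene-density correlation")
  oriented <- if (r > 0) pc1_sub else -pc1_sub
  n <- oe$grid$n_bins
  pc1 <- rep(NA_real_, n)
  pc1[keep] <- pc1_sub
  label <- rep(NA_character_, n)
  label[keep] <- ifelse(oriented > 0, "A", "B")
  structure(list(pc1 = pc1, r = r, label = factor(label, levels = c("A", "B")),
                 grid = oe$grid),
            class = "lowres_compartments")
}

#' Broadcast low-resolution compartment labels onto a finer grid
#'
#' Each fine bin takes the label of the coarse bin covering its start
#' (grids are assumed nested, e.g. 100-kb labels onto 20-kb bins).
#'
#' @param lowres A `lowres_compartments`.
#' @param grid Target (finer) `bin_grid`.
#' @return Character vector of labels on the fine grid (`NA` where the
#'   coarse bin is masked or beyond the coarse grid).
#' @export
broadcast_labels <- function(lowres, grid) {
  coarse <- lowres$grid
  idx <- floor(bin_starts(grid) / coarse$resolution) + 1L
  out <- rep(NA_character_, grid$n_bins)
  ok <- idx >= 1L & idx <= coarse$n_bins
  out[ok] <- as.character(lowres$label[idx[ok]])
  out
}

#' A-B index at fine (20-kb) resolution
#'
#' For each unmasked bin the A score is the median O/E contact between the
#' bin and every other bin lying in a low-resolution A region on the same
#' chromosome (self excluded); the B score likewise for B regions. The A-B
#' index is A score minus B score: the higher, the more A-like.
#'
#' @param oe_fine O/E `contact_matrix` at the fine resolution (20-kb).
#' @param lowres `lowres_compartments` from [call_low_res_compartments()].
#' @return Object of class `ab_index_track`: list with `a_score`, `b_score`,
#'   `ab_index` (numeric, `NA` on masked bins), `label` (the broadcast
#'   low-res label), `grid`.
#' @export
ab_index <- function(oe_fine, lowres) {
  lab <- broadcast_labels(lowres, oe_fine$grid)
  keep <- oe_fine$mask
  a_idx <- which(lab == "A" & keep)
  b_idx <- which(lab == "B" & keep)
  if (length(a_idx) == 0 || length(b_idx) == 0)
    stop("undefined score: chromosome lacks a low-resolution A or B region")
  v <- oe_fine$values
  diag(v) <- NA  # self excluded
  n <- oe_fine$grid$n_bins
  a_score <- rep(NA_real_, n)
  b_score <- rep(NA_real_, n)
  rows <- which(keep)
  a_score[rows] <- apply(v[rows, a_idx, drop = FALSE], 1, stats::median, na.rm = TRUE)
  b_score[rows] <- apply(v[rows, b_idx, drop = FALSE], 1, stats::median, na.rm = TRUE)
  structure(list(a_score = a_score, b_score = b_score,
                 ab_index = a_score - b_score, label = lab,
                 grid = oe_fine$grid),
            class = "ab_index_track")
}

#' Write an A-B index track as bedGraph
#' @param track An `ab_index_track`.
#' @param path Output path.
#' @export
write_ab_bedgraph <- function(track, path) {
  g <- track$grid
  ok <- !is.na(track$ab_index)
  df <- data.frame(chrom = g$chrom, start = bin_starts(g)[ok],
                   end = bin_starts(g)[ok] + g$resolution,
                   value = track$ab_index[ok])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
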