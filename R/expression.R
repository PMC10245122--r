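#' Conserved-rank scaling normalization of cross-species expression
#'
#' Single-copy ortholog TPM values are log2(TPM+1)-transformed; genes whose
#' transformed expression sits within the interquartile range of every
#' sample are eligible, and among them the `n_anchor` genes with the
#' lowest variance of within-sample ranks are the conserved-rank anchors.
#' Each sample is shifted so its anchor median equals the cross-sample mean
#' of anchor medians; the multiplicative factor on the TPM scale is
#' `2^shift`.
#'
#' @param tpm Genes x samples matrix of TPM values (rownames = ortholog ids).
#' @param n_anchor Number of anchor genes (1000).
#' @param pseudo Pseudo-count inside the log (1).
#' @return List with `normalized` (log2 scale, genes x samples),
#'   `normalized_tpm` (TPM scale, each sample multiplied by its factor),
#'   `shift` (per-sample additive log2 shift), `factor` (`2^shift`),
#'   `anchors` (gene ids). Re-normalizing `normalized_tpm` yields factors
#'   of ~1 (idempotence).
#' @export
scale_normalize <- function(tpm, n_anchor = 1000, pseudo = 1) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  L <- log2(tpm + pseudo)
  q <- apply(L, 2, stats::quantile, probs = c(0.25, 0.75))
  eligible <- rowSums(sweep(L, 2, q[1, ], ">=") &
                      sweep(L, 2, q[2, ], "<=")) == ncol(L)
  if (sum(eligible) < n_anchor) {
    warning(sprintf("only %d genes pass the interquartile filter; using all",
                    sum(eligible)))
    n_anchor <- sum(eligible)
  }
  if (n_anchor == 0) stop("no genes pass the interquartile filter")
  ranks <- apply(L[eligible, , drop = FALSE], 2, rank)
  rank_var <- apply(ranks, 1, stats::var)
  ord <- order(rank_var, rownames(L)[eligible])  # deterministic tie-break
  anchors <- rownames(L)[eligible][ord[seq_len(n_anchor)]]
  med <- apply(L[anchors, , drop = FALSE], 2, stats::median)
  shift <- mean(med) - med
  normalized <- sweep(L, 2, shift, "+")
  list(normalized = normalized,
       normalized_tpm = sweep(tpm, 2, 2^shift, "*"),
       shift = shift, factor = 2^shift, anchors = anchors)
}

#' Coefficient of variation of expression across species
#'
#' Per gene: species means over that species' replicate samples, then
#' CV = sd/mean over the species means. Genes with zero mean are flagged
#' undefined (`NA`).
#'
#' @param normalized Genes x samples matrix (e.g. from [scale_normalize()]).
#' @param species Character vector, one species id per sample column.
#' @return Numeric vector of per-gene CVs (named by gene).
#' @export
cross_species_cv <- function(normalized, species) {
  if (length(unique(species)) < 2)
    stop("contract error: need at least two species")
  sp <- unique(species)
  means <- vapply(sp, function(s)
    rowMeans(normalized[, species == s, drop = FALSE]), numeric(nrow(normalized)))
  mu <- rowMeans(means)
  cv <- apply(means, 1, stats::sd) / mu
  cv[mu == 0] <- NA_real_
  cv
}

#' Expression contrasts between structure classes
#'
#' Per class of genes: (i) the human-vs-other log2 fold summary with a
#' one-sample t test, and (ii) pairwise cross-species Spearman correlations
#' regressed on divergence time with an exponential-decay trend
#' `y = a * exp(-b * t) + c` fitted by nonlinear least squares.
#'
#' @param normalized Genes x samples matrix (log2 scale).
#' @param species Species id per sample; must contain `ref_species`.
#' @param gene_classes Named character vector: class per gene (subset of
#'   rownames).
#' @param divergence Symmetric species x species divergence-time matrix
#'   (e.g. Myr), dimnames = species ids.
#' @param ref_species Reference species id (default `"human"`).
#' @return Data-frame-per-class list with `fold` (mean log2 FC, t, p, n) and
#'   `decay` (fitted a, b, c or `NA` when the fit fails); classes with < 3
#'   genes give `NA` rows.
#' @export
class_expression_contrast <- function(normalized, species, gene_classes,
                                      divergence, ref_species = "human") {
  sp <- unique(species)
  sp_means <- vapply(sp, function(s)
    rowMeans(normalized[, species == s, drop = FALSE]),
    numeric(nrow(normalized)))
  out_fold <- list(); out_decay <- list()
  for (cl in unique(gene_classes)) {
    genes <- intersect(names(gene_classes)[gene_classes == cl],
                       rownames(normalized))
    if (length(genes) < 3) {
      warning(sprintf("class %s has < 3 genes; NA", cl))
      out_fold[[cl]] <- data.frame(class = cl, mean_lfc = NA_real_,
                                   t = NA_real_, p = NA_real_,
                                   n = length(genes))
      out_decay[[cl]] <- data.frame(class = cl, a = NA_real_, b = NA_real_,
                                    c = NA_real_)
      next
    }
    other <- setdiff(sp, ref_species)
    lfc <- sp_means[genes, ref_species] -
      rowMeans(sp_means[genes, other, drop = FALSE])
    tt <- stats::t.test(lfc)
    out_fold[[cl]] <- data.frame(class = cl, mean_lfc = mean(lfc),
                                 t = unname(tt$statistic), p = tt$p.value,
                                 n = length(genes))
    pairs <- utils::combn(sp, 2, simplify = FALSE)
    cor_df <- do.call(rbind, lapply(pairs, function(pp) {
      data.frame(t = divergence[pp[1], pp[2]],
                 rho = stats::cor(sp_means[genes, pp[1]],
                                  sp_means[genes, pp[2]],
                                  method = "spearman"))
    }))
    fit <- tryCatch(
      minpack.lm::nlsLM(rho ~ a * exp(-b * t) + c, data = cor_df,
                        start = list(a = 0.3, b = 0.02, c = 0.5),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    cf <- if (is.null(fit)) c(a = NA_real_, b = NA_real_, c = NA_real_)
      else stats::coef(fit)
    out_decay[[cl]] <- data.frame(class = cl, a = cf[["a"]], b = cf[["b"]],
                                  c = cf[["c"]])
  }
  list(fold = do.call(rbind, out_fold), decay = do.call(rbind, out_decay))
}
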