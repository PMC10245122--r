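#' Bin grid for a binned intra-chromosomal contact matrix
#'
#' Describes the fixed-width binning of one chromosome. Bin `i` (1-based in R)
#' covers the 0-based half-open interval `[(i-1)*resolution, i*resolution)`.
#'
#' @param chrom Chromosome name.
#' @param resolution Bin width in bp (> 0).
#' @param n_bins Number of bins (> 0).
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(chrom, resolution, n_bins) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  resolution <- as.numeric(resolution)
  n_bins <- as.integer(n_bins)
  if (!is.finite(resolution) || resolution <= 0) stop("resolution must be > 0")
  if (is.na(n_bins) || n_bins <= 0L) stop("n_bins must be > 0")
  structure(list(chrom = chrom, resolution = resolution, n_bins = n_bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %s: %d bins @ %g bp\n", x$chrom, x$n_bins, x$resolution))
  invisible(x)
}

#' Start coordinates (bp, 0-based) of every bin in a grid
#' @param grid A `bin_grid`.
#' @return Numeric vector of length `n_bins`.
#' @export
bin_starts <- function(grid) (seq_len(grid$n_bins) - 1) * grid$resolution

#' Midpoint coordinates (bp) of every bin in a grid
#' @param grid A `bin_grid`.
#' @return Numeric vector of length `n_bins`.
#' @export
bin_mids <- function(grid) bin_starts(grid) + grid$resolution / 2

#' 1-based bin index containing a bp position
#' @param grid A `bin_grid`.
#' @param pos bp positions (0-based coordinates).
#' @return Integer bin indices; `NA` outside the grid.
#' @export
bin_of <- function(grid, pos) {
  i <- floor(pos / grid$resolution) + 1L
  i[i < 1L | i > grid$n_bins] <- NA_integer_
  as.integer(i)
}

#' Construct a contact matrix object
#'
#' Symmetric intra-chromosomal contact matrix on a [bin_grid()]. Bins whose
#' raw marginal is zero are masked and stay masked through every
#' normalization.
#'
#' @param values Symmetric non-negative `n_bins x n_bins` matrix.
#' @param grid A `bin_grid`.
#' @param norm Normalization tag: one of `"raw"`, `"KR"`, `"OE"`, `"quantile"`.
#' @param weights Per-bin balancing weights (KR matrices only).
#' @param mask Logical vector, `TRUE` for usable bins. Default: bins with a
#'   positive marginal.
#' @return An object of class `contact_matrix` with fields `grid`, `values`,
#'   `norm`, `weights`, `mask`, `total` (upper-triangle sum incl. diagonal).
#' @export
contact_matrix <- function(values, grid, norm = "raw", weights = NULL,
                           mask = NULL) {
  stopifnot(inherits(grid, "bin_grid"), is.matrix(values))
  n <- grid$n_bins
  if (nrow(values) != n || ncol(values) != n)
    stop("values dimension does not match grid")
  if (any(values < 0, na.rm = TRUE)) stop("negative contact values")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("contact matrix must be symmetric")
  norm <- match.arg(norm, c("raw", "KR", "OE", "quantile"))
  if (norm == "raw" && any(abs(values - round(values)) > 1e-8, na.rm = TRUE))
    stop("raw contact matrices must be integer-valued")
  if (is.null(mask)) {
    marg <- rowSums(values, na.rm = TRUE)
    mask <- marg > 0
  }
  structure(list(grid = grid, values = values, norm = norm, weights = weights,
                 mask = mask,
                 total = sum(values[upper.tri(values, diag = TRUE)], na.rm = TRUE)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp, norm=%s, total=%g, masked=%d\n",
              x$grid$chrom, x$grid$n_bins, x$grid$resolution, x$norm,
              x$total, sum(!x$mask)))
  invisible(x)
}

#' Load a contact matrix from a sparse-triplet or dense text file
#'
#' Sparse triplet files carry three columns `bin_i bin_j count` with 0-based
#' bin indices (cooler convention); entries are mirrored onto both triangles
#' and duplicates are summed. Dense files carry an `n_bins x n_bins` matrix.
#'
#' @param path Path to a whitespace-delimited text file.
#' @param grid A `bin_grid` describing the binning.
#' @param format `"triplet"` or `"dense"`.
#' @return A raw `contact_matrix`.
#' @export
load_contacts <- function(path, grid, format = c("triplet", "dense")) {
  format <- match.arg(format)
  n <- grid$n_bins
  if (format == "dense") {
    vals <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(vals) <- NULL
    return(contact_matrix(vals, grid))
  }
  m <- matrix(0, n, n)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    tri <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "count"))
    if (nrow(tri) > 0) {
      if (any(tri$i < 0 | tri$j < 0 | tri$i >= n | tri$j >= n))
        stop("malformed input: bin index outside grid")
      if (any(tri$count < 0)) stop("malformed input: negative count")
      i <- pmin(tri$i, tri$j) + 1L
      j <- pmax(tri$i, tri$j) + 1L
      agg <- rowsum(tri$count, group = paste(i, j))
      ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
      m[cbind(ij[, 1], ij[, 2])] <- agg[, 1]
      m[cbind(ij[, 2], ij[, 1])] <- agg[, 1]
    }
  }
  contact_matrix(m, grid)
}

#' Write a contact matrix as sparse upper-triangle triplets
#' @param m A `contact_matrix`.
#' @param path Output path; columns `bin_i bin_j count`, 0-based indices.
#' @export
write_contacts <- function(m, path) {
  ut <- which(upper.tri(m$values, diag = TRUE) & m$values != 0, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                   count = m$values[ut])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
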