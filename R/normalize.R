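#' Knight-Ruiz style matrix balancing
#'
#' Finds per-bin weights `w` such that the balanced matrix
#' `w_i * values[i,j] * w_j` has equal row sums over unmasked bins. The
#' contract is the equal-row-sum property; the solver is a damped symmetric
#' Sinkhorn fixed point (`w <- w / sqrt(rowsums)`), which converges to the
#' unique symmetric scaling whenever one exists. Weights are rescaled so the
#' balanced matrix keeps the raw total contact count, preserving the count
#' scale for downstream count models.
#'
#' @param m Raw `contact_matrix`. All-zero rows are masked out first.
#' @param tol Relative row-sum tolerance (max |rowsum/mean - 1|).
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A `contact_matrix` with `norm = "KR"` and a `weights` field
#'   (`NA` on masked bins).
#' @export
kr_balance <- function(m, tol = 1e-10, max_iter = 5000L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$norm != "raw") stop("kr_balance expects a raw matrix")
  keep <- m$mask
  if (!any(keep)) stop("empty input: all bins masked")
  a <- m$values[keep, keep, drop = FALSE]
  nk <- nrow(a)
  w <- rep(1, nk)
  res <- Inf
  for (it in seq_len(max_iter)) {
    r <- as.vector(a %*% w) * w
    res <- max(abs(r - 1))
    if (res <= tol) break
    if (any(r <= 0)) stop("balancing failed: zero row sum on unmasked bin")
    w <- w / sqrt(r)
  }
  if (res > tol)
    stop(sprintf("KR balancing did not converge in %d iterations (residual %.3g)",
                 max_iter, res))
  bal <- a * outer(w, w)
  # restore count scale: total of balanced equals total of raw
  s <- sum(m$values[keep, keep][upper.tri(a, diag = TRUE)]) /
    sum(bal[upper.tri(bal, diag = TRUE)])
  bal <- bal * s
  w <- w * sqrt(s)
  n <- m$grid$n_bins
  out <- matrix(0, n, n)
  out[keep, keep] <- bal
  weights <- rep(NA_real_, n)
  weights[keep] <- w
  contact_matrix(out, m$grid, norm = "KR", weights = weights, mask = keep)
}

#' Expected contact frequency by genomic distance
#'
#' Distance-decay curve `E(d)` for `d = |i - j|` in bins, estimated over all
#' unmasked bin pairs in each distance stratum.
#'
#' @param m A `contact_matrix`.
#' @param estimator `"median"` or `"mean"`.
#' @return An object of class `decay_curve`: list with `expected` (length
#'   `n_bins`, `E(d)` at `d = 0 .. n_bins-1`), `estimator`, `grid`.
#' @export
expected_by_distance <- function(m, estimator = c("median", "mean")) {
  estimator <- match.arg(estimator)
  keep <- m$mask
  if (!any(keep)) stop("empty input: all bins masked")
  n <- m$grid$n_bins
  est <- if (estimator == "median") stats::median else mean
  e <- numeric(n)
  idx <- which(keep)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    ok <- keep[i] & keep[i + d]
    e[d + 1L] <- if (any(ok)) est(m$values[cbind(i[ok], i[ok] + d)]) else NA_real_
  }
  structure(list(expected = e, estimator = estimator, grid = m$grid),
            class = "decay_curve")
}

#' Observed/expected normalization
#'
#' Divides each entry by the expected value at its genomic distance. Strata
#' with `E(d) = 0` (or undefined) are set to 0 and flagged.
#'
#' @param m A `contact_matrix`.
#' @param decay A `decay_curve` from [expected_by_distance()] on the same grid.
#' @return A `contact_matrix` with `norm = "OE"` and attribute
#'   `zero_strata` (distances with no usable expected value).
#' @export
observed_over_expected <- function(m, decay) {
  stopifnot(inherits(decay, "decay_curve"))
  if (!identical(decay$grid$n_bins, m$grid$n_bins) ||
      !identical(decay$grid$resolution, m$grid$resolution))
    stop("contract error: decay curve computed on a different grid")
  n <- m$grid$n_bins
  e <- decay$expected
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  emat <- matrix(e[d + 1L], n, n)
  out <- m$values / emat
  bad <- !is.finite(out)
  out[bad] <- 0
  cm <- contact_matrix(out, m$grid, norm = "OE", mask = m$mask)
  zero_d <- which(e == 0 | is.na(e)) - 1L
  attr(cm, "zero_strata") <- zero_d
  cm
}

#' Binomially down-sample a raw contact matrix to a target depth
#'
#' Each upper-triangle contact is retained independently with probability
#' `target_total / total_contacts` (binomial thinning).
#'
#' @param m Raw integer `contact_matrix`.
#' @param target_total Target total contact count (<= current total).
#' @param seed Integer seed; runs with the same seed are identical.
#' @return A raw `contact_matrix` (mask recomputed from the thinned counts).
#' @export
downsample <- function(m, target_total, seed) {
  if (m$norm != "raw") stop("downsample expects a raw matrix")
  if (target_total > m$total) stop("contract error: target exceeds total")
  p <- target_total / m$total
  n <- m$grid$n_bins
  ut <- upper.tri(m$values, diag = TRUE)
  v <- m$values[ut]
  thinned <- with_seed(seed, stats::rbinom(length(v), size = as.integer(v), prob = p))
  out <- matrix(0, n, n)
  out[ut] <- thinned
  out <- out + t(out)
  diag(out) <- diag(out) / 2
  contact_matrix(out, m$grid)
}

#' Quantile-normalize a set of contact matrices
#'
#' Standard quantile normalization over the upper-triangle entries of bins
#' unmasked in every matrix: each value is replaced by the mean of the
#' equally-ranked values across matrices, so afterwards the sorted value
#' vectors are identical across matrices and within-matrix ranks are
#' preserved (ties broken by position, which keeps the sorted multisets
#' exactly equal even on heavily tied count data).
#'
#' @param ms List of >= 2 `contact_matrix` objects on the same grid.
#' @return List of `contact_matrix` objects, `norm = "quantile"`.
#' @export
quantile_normalize <- function(ms) {
  if (length(ms) < 2L) stop("contract error: need at least 2 matrices")
  g <- ms[[1]]$grid
  for (m in ms)
    if (!identical(m$grid$n_bins, g$n_bins) ||
        !identical(m$grid$resolution, g$resolution))
      stop("contract error: matrices on different grids")
  keep <- Reduce(`&`, lapply(ms, function(m) m$mask))
  n <- g$n_bins
  sub <- which(keep)
  ut <- upper.tri(matrix(0, length(sub), length(sub)), diag = TRUE)
  cols <- vapply(ms, function(m) m$values[sub, sub, drop = FALSE][ut],
                 numeric(sum(ut)))
  target <- rowMeans(apply(cols, 2, sort))
  qn <- apply(cols, 2, function(x) target[rank(x, ties.method = "first")])
  lapply(seq_along(ms), function(k) {
    out <- matrix(0, n, n)
    block <- matrix(0, length(sub), length(sub))
    block[ut] <- qn[, k]
    block <- block + t(block)
    diag(block) <- diag(block) / 2
    out[sub, sub] <- block
    contact_matrix(out, g, norm = "quantile", mask = keep)
  })
}

#' Evaluate a function with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state,
#' so seeded operations do not perturb the surrounding random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
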