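#' Insulation score track
#'
#' The raw insulation of bin `i` is the mean contact over the square window
#' `[i-w, i) x (i, i+w]` (w bins per side), i.e. the aggregate of contacts
#' passing across the bin. The normalized score is
#' `IS = log2(raw / mean(raw))` with the mean over all defined bins, and the
#' delta vector is the mean IS over the `delta_span` bins left of `i` minus
#' the mean over the `delta_span` bins right of `i`.
#'
#' @param m KR-normalized `contact_matrix` (20-kb in the standard run).
#' @param window Insulation square size in bp (default 260000, 13 bins at
#'   20-kb).
#' @param delta_span Delta window in bp (default 200000, 10 bins).
#' @return Object of class `insulation_track`: `raw`, `is`, `delta`
#'   (length `n_bins`, `NA` where undefined), `w`, `ds` (bins), `grid`.
#' @export
insulation_score <- function(m, window = 260000, delta_span = 200000) {
  g <- m$grid
  w <- as.integer(round(window / g$resolution))
  ds <- as.integer(round(delta_span / g$resolution))
  n <- g$n_bins
  if (n < 2L * w + 1L) stop("chromosome too short for the insulation window")
  v <- m$values
  v[!m$mask, ] <- NA
  v[, !m$mask] <- NA
  raw <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w)) {
    block <- v[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
    if (!all(is.na(block))) raw[i] <- mean(block, na.rm = TRUE)
  }
  mu <- mean(raw, na.rm = TRUE)
  is_ <- log2(raw / mu)
  is_[!is.finite(is_)] <- NA
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - ds; hi <- i + ds
    if (lo < 1L || hi > n) next
    left <- is_[(i - ds):(i - 1L)]
    right <- is_[(i + 1L):(i + ds)]
    if (all(is.na(left)) || all(is.na(right))) next
    delta[i] <- mean(left, na.rm = TRUE) - mean(right, na.rm = TRUE)
  }
  structure(list(raw = raw, is = is_, delta = delta, w = w, ds = ds, grid = g),
            class = "insulation_track")
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries sit where the delta vector crosses zero from positive to
#' negative. The boundary bin is the crossing bin with the lower insulation
#' score (margin of error 0: reported exactly); boundary strength is the
#' local delta maximum over the `delta_span` bins left of the crossing minus
#' the local delta minimum over the `delta_span` bins right of it, and only
#' boundaries with strength >= `noise_threshold` are emitted.
#'
#' @param track An `insulation_track`.
#' @param noise_threshold Minimum strength (default 0.5).
#' @return Data frame with `bin` (1-based), `pos` (bp midpoint of the bin),
#'   `strength`.
#' @export
call_boundaries <- function(track, noise_threshold = 0.5) {
  d <- track$delta
  n <- length(d)
  ds <- track$ds
  res <- track$grid$resolution
  out <- list()
  for (t in seq_len(n - 1L)) {
    if (is.na(d[t]) || is.na(d[t + 1L])) next
    if (!(d[t] > 0 && d[t + 1L] <= 0)) next
    left <- d[max(1L, t - ds + 1L):t]
    right <- d[(t + 1L):min(n, t + ds)]
    strength <- max(left, na.rm = TRUE) - min(right, na.rm = TRUE)
    if (!is.finite(strength) || strength < noise_threshold) next
    is_t <- track$is[t]; is_t1 <- track$is[t + 1L]
    b <- if (!is.na(is_t) && !is.na(is_t1) && is_t1 < is_t) t + 1L else t
    out[[length(out) + 1L]] <- data.frame(bin = b,
                                          pos = (b - 0.5) * res,
                                          strength = strength)
  }
  if (length(out) == 0)
    return(data.frame(bin = integer(0), pos = numeric(0), strength = numeric(0)))
  do.call(rbind, out)
}

#' Assemble TADs from consecutive boundaries
#'
#' TADs are the intervals between consecutive emitted boundaries (no nesting);
#' domains shorter than `min_bins` are dropped.
#'
#' @param boundaries Data frame from [call_boundaries()].
#' @param grid The `bin_grid`.
#' @param min_bins Minimum TAD size in bins (default 3).
#' @return Data frame with `start_bin`, `end_bin` (inclusive bin range of the
#'   domain body between the flanking boundary bins), `start`, `end` (bp,
#'   half-open), `left_boundary`, `right_boundary` (boundary bins).
#' @export
tads_from_boundaries <- function(boundaries, grid, min_bins = 3L) {
  b <- sort(unique(boundaries$bin))
  if (length(b) < 2L)
    return(data.frame(start_bin = integer(0), end_bin = integer(0),
                      start = numeric(0), end = numeric(0),
                      left_boundary = integer(0), right_boundary = integer(0)))
  res <- grid$resolution
  out <- data.frame(start_bin = b[-length(b)] + 1L, end_bin = b[-1] - 1L,
                    left_boundary = b[-length(b)], right_boundary = b[-1])
  out <- out[out$end_bin - out$start_bin + 1L >= min_bins, , drop = FALSE]
  out$start <- (out$start_bin - 1L) * res
  out$end <- out$end_bin * res
  rownames(out) <- NULL
  out[, c("start_bin", "end_bin", "start", "end",
          "left_boundary", "right_boundary")]
}
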