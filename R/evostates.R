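#' Build the homologous-bin A-B index matrix across species
#'
#' Retains the reference 20-kb bins that lift reciprocally through every
#' query species' homology map, and assembles the bins x species matrix of
#' A-B indices. A query bin's value is taken from the query bin containing
#' the midpoint of the mapped interval.
#'
#' @param ref_track Reference-species `ab_index_track`.
#' @param maps Named list of `homology_map`, one per query species.
#' @param query_tracks Named list of `ab_index_track`, same names as `maps`.
#' @return List with `bins` (retained reference bin indices) and `ab`
#'   (matrix, columns = reference then query species).
#' @export
build_homologous_bins <- function(ref_track, maps, query_tracks) {
  if (is.null(names(maps)) || !setequal(names(maps), names(query_tracks)))
    stop("contract error: maps and query_tracks must share species names")
  g <- ref_track$grid
  species <- names(maps)
  n <- g$n_bins
  starts <- bin_starts(g)
  vals <- matrix(NA_real_, n, length(species) + 1L,
                 dimnames = list(NULL, c("reference", species)))
  vals[, 1] <- ref_track$ab_index
  ok <- !is.na(ref_track$ab_index)
  for (sp in species) {
    map <- maps[[sp]]
    qt <- query_tracks[[sp]]
    for (b in which(ok)) {
      pieces <- lift_interval(map, g$chrom, starts[b], starts[b] + g$resolution)
      pieces <- pieces[pieces$reciprocal, , drop = FALSE]
      if (nrow(pieces) != 1L ||
          pieces$ref_covered[1] < g$resolution) next  # needs full reciprocal map
      mid <- (pieces$q_start[1] + pieces$q_end[1]) / 2
      qb <- bin_of(qt$grid, mid)
      if (!is.na(qb) && pieces$q_chrom[1] == qt$grid$chrom)
        vals[b, sp] <- qt$ab_index[qb]
    }
  }
  keep <- which(stats::complete.cases(vals))
  list(bins = keep, ab = vals[keep, , drop = FALSE])
}

#' Choose the number of evolutionary compartment states by the SSE elbow
#'
#' Runs K-means on the homologous-bin A-B matrix for each candidate `k`,
#' records the total within-cluster sum of squared error SSE(k), and takes
#' the elbow as the interior `k` maximizing the second difference
#' `SSE(k-1) - 2 SSE(k) + SSE(k+1)`.
#'
#' @param ab Bins x species numeric matrix.
#' @param k_range Candidate state counts (>= 3 values).
#' @param seed Integer seed for the K-means starts.
#' @param nstart Random starts per `k`.
#' @return List with `k` (chosen), `sse` (named vector), `degenerate`
#'   (`TRUE` when SSE is ~0 everywhere), `low_confidence` (`TRUE` when the
#'   elbow is weak: max second difference < 5% of SSE range).
#' @export
choose_state_number <- function(ab, k_range = 2:10, seed = 1, nstart = 10) {
  if (length(k_range) < 3L) stop("contract error: k_range needs >= 3 candidates")
  k_range <- sort(k_range)
  if (nrow(ab) < max(k_range)) stop("fewer rows than largest k")
  if (nrow(unique(ab)) < max(k_range)) {
    sse <- stats::setNames(rep(0, length(k_range)), k_range)
    return(list(k = k_range[1], sse = sse, degenerate = TRUE,
                low_confidence = TRUE))
  }
  sse <- with_seed(seed, vapply(k_range, function(k) {
    stats::kmeans(ab, centers = k, nstart = nstart, iter.max = 50)$tot.withinss
  }, numeric(1)))
  names(sse) <- k_range
  if (max(sse) < 1e-12)
    return(list(k = k_range[1], sse = sse, degenerate = TRUE,
                low_confidence = TRUE))
  interior <- 2:(length(k_range) - 1L)
  d2 <- sse[interior - 1L] - 2 * sse[interior] + sse[interior + 1L]
  best <- interior[which.max(d2)]
  list(k = k_range[best], sse = sse, degenerate = FALSE,
       low_confidence = max(d2) < 0.05 * (max(sse) - min(sse)))
}

#' Assign evolutionary states to homologous bins
#'
#' K-means state labels over the species A-B matrix (a stand-in for
#' externally fitted phylogenetic HMM states, which can be supplied instead
#' via `states`).
#'
#' @param ab Bins x species A-B matrix.
#' @param k Number of states.
#' @param seed Integer seed.
#' @param states Optional externally computed per-bin state vector
#'   (integers in `1..k`); when given, K-means is skipped.
#' @return List with `states` (per-bin integer) and `ab`.
#' @export
assign_states <- function(ab, k, seed = 1, states = NULL) {
  if (is.null(states)) {
    km <- with_seed(seed, stats::kmeans(ab, centers = k, nstart = 10,
                                        iter.max = 50))
    states <- km$cluster
  } else {
    states <- as.integer(states)
    if (length(states) != nrow(ab)) stop("states length mismatch")
  }
  list(states = states, ab = ab)
}

#' Group evolutionary states into conservation classes
#'
#' For each state and species, `p_A` is the fraction of its bins with A
#' status (A-B index > 0). A state is CA when `p_A > a_hi` in every species,
#' WCA when `p_A > a_lo` in every species (but not CA); CB/WCB use the
#' B-status fractions symmetrically; everything else is NC. An NC state is
#' flagged human-specific-A (HS-A) when the reference species' `p_A`
#' exceeds `hs_ref_min` while every query stays below `hs_query_max`.
#'
#' @param assign Output of [assign_states()].
#' @param a_hi,a_lo Conserved / weakly-conserved fraction cuts (0.90, 0.70;
#'   open boundaries, strict inequality).
#' @param hs_ref_min,hs_query_max HS-A rule cuts (0.70, 0.50).
#' @return Data frame, one row per state: `state`, per-species `pA_*`
#'   columns, `group` in `{CA, WCA, CB, WCB, NC}`, `hs_a` flag, `n_bins`;
#'   plus a `bin_group` attribute giving each bin its state's group.
#' @export
group_states <- function(assign, a_hi = 0.90, a_lo = 0.70,
                         hs_ref_min = 0.70, hs_query_max = 0.50) {
  st <- assign$states
  isA <- assign$ab > 0
  species <- colnames(assign$ab)
  out <- lapply(sort(unique(st)), function(s) {
    rows <- st == s
    if (!any(rows)) {
      warning(sprintf("state %d is empty; skipped", s))
      return(NULL)
    }
    pA <- colMeans(isA[rows, , drop = FALSE])
    pB <- 1 - pA
    group <- if (min(pA) > a_hi) "CA"
      else if (min(pA) > a_lo) "WCA"
      else if (min(pB) > a_hi) "CB"
      else if (min(pB) > a_lo) "WCB"
      else "NC"
    hs_a <- group == "NC" && pA[1] > hs_ref_min && all(pA[-1] < hs_query_max)
    row <- data.frame(state = s, t(pA), group = group, hs_a = hs_a,
                      n_bins = sum(rows))
    names(row)[2:(1 + length(species))] <- paste0("pA_", species)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin_group") <- res$group[match(st, res$state)]
  res
}
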