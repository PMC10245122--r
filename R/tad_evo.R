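#' Classify reference boundaries as conserved or species-specific
#'
#' Each reference boundary is lifted into every query species; the distance
#' from the lifted position to the nearest query boundary decides the
#' per-species verdict: within `flank` (40 kb) of a query boundary =
#' conserved; at least `specific_min` (100 kb) from every query boundary =
#' specific; in between = unclassified. A boundary that fails to lift is
#' unclassified for that species (absence of alignment is not evidence of
#' divergence). Overall: species-conserved iff conserved in all queries;
#' reference-specific (human-specific when the reference is human) iff
#' specific in all queries; otherwise other.
#'
#' @param ref_bounds Data frame from [call_boundaries()] (reference species).
#' @param query_bounds Named list of boundary data frames per query species.
#' @param maps Named list of `homology_map` per query species.
#' @param ref_chrom Reference chromosome name.
#' @param flank Conservation distance cut in bp (40000).
#' @param specific_min Specificity distance cut in bp (100000).
#' @return Data frame: one row per reference boundary with `bin`, `pos`,
#'   per-species distance (`dist_*`) and verdict (`verdict_*`), and
#'   `overall` in `{species-conserved, species-specific, other}`.
#' @export
classify_boundaries <- function(ref_bounds, query_bounds, maps, ref_chrom,
                                flank = 40000, specific_min = 100000) {
  species <- names(maps)
  if (is.null(species) || !setequal(species, names(query_bounds)))
    stop("contract error: maps and query_bounds must share species names")
  nb <- nrow(ref_bounds)
  out <- data.frame(bin = ref_bounds$bin, pos = ref_bounds$pos)
  verdicts <- matrix(NA_character_, nb, length(species),
                     dimnames = list(NULL, species))
  for (sp in species) {
    qpos <- query_bounds[[sp]]$pos
    dist <- rep(NA_real_, nb)
    verdict <- rep("unclassified", nb)
    for (k in seq_len(nb)) {
      lift <- lift_position(maps[[sp]], ref_chrom, ref_bounds$pos[k])
      if (lift$status != "ok" || !isTRUE(lift$reciprocal)) next
      if (length(qpos) == 0) { dist[k] <- Inf }
      else dist[k] <- min(abs(qpos - lift$q_pos))
      verdict[k] <- if (dist[k] <= flank) "conserved"
        else if (dist[k] >= specific_min) "specific"
        else "unclassified"
    }
    out[[paste0("dist_", sp)]] <- dist
    out[[paste0("verdict_", sp)]] <- verdict
    verdicts[, sp] <- verdict
  }
  out$overall <- apply(verdicts, 1, function(v) {
    if (all(v == "conserved")) "species-conserved"
    else if (all(v == "specific")) "species-specific"
    else "other"
  })
  out
}

#' Classify TADs from their flanking boundary labels
#'
#' A TAD is conserved (Cons) when both flanking boundaries are
#' species-conserved, and species-specific (HS when the reference is human)
#' when at least one flank is species-specific; otherwise other.
#'
#' @param tads Data frame from [tads_from_boundaries()].
#' @param boundary_labels Data frame from [classify_boundaries()].
#' @return `tads` with a `class` column in `{Cons, HS, other}`.
#' @export
classify_tads <- function(tads, boundary_labels) {
  lab <- boundary_labels$overall[match(tads$left_boundary, boundary_labels$bin)]
  rab <- boundary_labels$overall[match(tads$right_boundary, boundary_labels$bin)]
  tads$class <- ifelse(
    !is.na(lab) & !is.na(rab) & lab == "species-conserved" & rab == "species-conserved",
    "Cons",
    ifelse((!is.na(lab) & lab == "species-specific") |
           (!is.na(rab) & rab == "species-specific"), "HS", "other"))
  tads
}

#' Write boundaries or TADs as BED
#' @param df Data frame with `start`/`end` bp columns (TADs) or `pos`
#'   (boundaries, written as their bin interval).
#' @param grid The `bin_grid`.
#' @param path Output path.
#' @export
write_bed <- function(df, grid, path) {
  if ("start" %in% names(df)) {
    bed <- data.frame(chrom = grid$chrom, start = df$start, end = df$end)
  } else {
    s <- (df$bin - 1L) * grid$resolution
    bed <- data.frame(chrom = grid$chrom, start = s, end = s + grid$resolution)
  }
  extra <- intersect(c("class", "overall", "strength"), names(df))
  if (length(extra)) bed <- cbind(bed, df[, extra, drop = FALSE])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
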