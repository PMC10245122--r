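#' Construct / validate a homology map
#'
#' Interval correspondences between a reference genome and one query species
#' (a liftOver-chain stand-in). Intervals are 0-based half-open; `strand`
#' `"-"` means the query interval runs in reverse orientation; `reciprocal`
#' records whether the query-to-reference mapping returns the source.
#'
#' @param df Data frame with columns `ref_chrom, ref_start, ref_end,
#'   q_chrom, q_start, q_end, strand, reciprocal`.
#' @return The validated data frame, class `homology_map`.
#' @export
homology_map <- function(df) {
  need <- c("ref_chrom", "ref_start", "ref_end", "q_chrom", "q_start",
            "q_end", "strand", "reciprocal")
  if (!all(need %in% names(df))) stop("homology map missing columns")
  if (any(df$ref_end <= df$ref_start) || any(df$q_end <= df$q_start))
    stop("homology map has empty intervals")
  if (any((df$ref_end - df$ref_start) != (df$q_end - df$q_start)))
    stop("homology map blocks must preserve length")
  df <- df[order(df$ref_chrom, df$ref_start), ]
  class(df) <- c("homology_map", "data.frame")
  df
}

#' Read a homology map from TSV
#' @param path TSV with a header matching the [homology_map()] columns.
#' @return A `homology_map`.
#' @export
read_homology_map <- function(path) {
  homology_map(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Lift a reference interval through a homology map
#'
#' Maps every covered piece of `[start, end)` on `chrom` into query
#' coordinates and merges query-adjacent pieces.
#'
#' @param map A `homology_map`.
#' @param chrom,start,end Reference interval (0-based half-open).
#' @return Data frame of query pieces (`q_chrom, q_start, q_end, strand,
#'   reciprocal, ref_covered`); zero rows when the interval falls in a gap.
#' @export
lift_interval <- function(map, chrom, start, end) {
  hit <- map[map$ref_chrom == chrom & map$ref_start < end & map$ref_end > start, ,
             drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(q_chrom = character(0), q_start = numeric(0),
                      q_end = numeric(0), strand = character(0),
                      reciprocal = logical(0), ref_covered = numeric(0)))
  s <- pmax(hit$ref_start, start)
  e <- pmin(hit$ref_end, end)
  qs <- ifelse(hit$strand == "+", hit$q_start + (s - hit$ref_start),
               hit$q_start + (hit$ref_end - e))
  qe <- qs + (e - s)
  out <- data.frame(q_chrom = hit$q_chrom, q_start = qs, q_end = qe,
                    strand = hit$strand, reciprocal = hit$reciprocal,
                    ref_covered = e - s, stringsAsFactors = FALSE)
  out <- out[order(out$q_chrom, out$q_start), ]
  # merge book-ended pieces on the same chromosome/strand
  if (nrow(out) > 1) {
    merged <- out[1, ]
    for (k in 2:nrow(out)) {
      last <- nrow(merged)
      if (out$q_chrom[k] == merged$q_chrom[last] &&
          out$strand[k] == merged$strand[last] &&
          out$q_start[k] <= merged$q_end[last]) {
        merged$q_end[last] <- max(merged$q_end[last], out$q_end[k])
        merged$reciprocal[last] <- merged$reciprocal[last] && out$reciprocal[k]
        merged$ref_covered[last] <- merged$ref_covered[last] + out$ref_covered[k]
      } else merged <- rbind(merged, out[k, ])
    }
    out <- merged
  }
  rownames(out) <- NULL
  out
}

#' Lift a reference point position through a homology map
#'
#' @param map A `homology_map`.
#' @param chrom Reference chromosome.
#' @param pos Reference bp position.
#' @return List with `q_chrom`, `q_pos`, `reciprocal`, and `status` in
#'   `{"ok", "unmapped", "ambiguous"}`.
#' @export
lift_position <- function(map, chrom, pos) {
  hit <- map[map$ref_chrom == chrom & map$ref_start <= pos & map$ref_end > pos, ,
             drop = FALSE]
  if (nrow(hit) == 0)
    return(list(q_chrom = NA_character_, q_pos = NA_real_,
                reciprocal = NA, status = "unmapped"))
  if (nrow(hit) > 1)
    return(list(q_chrom = NA_character_, q_pos = NA_real_,
                reciprocal = NA, status = "ambiguous"))
  q <- if (hit$strand == "+") hit$q_start + (pos - hit$ref_start)
       else hit$q_start + (hit$ref_end - 1 - pos)
  list(q_chrom = hit$q_chrom, q_pos = q, reciprocal = hit$reciprocal,
       status = "ok")
}
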