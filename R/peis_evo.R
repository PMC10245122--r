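#' Align a PEI's anchors into a query species
#'
#' Both anchors must lift reciprocally to intervals of 5-20 kb on the same
#' query chromosome, and the mapped promoter anchor must land within 20 kb
#' of the annotated homologous promoter. Failures are data, not errors, and
#' carry an enumerated reason: `unmapped`, `size-out-of-range`,
#' `trans-split`, `promoter-displaced`.
#'
#' @param pei One PEI row (`p_bin`, `e_bin`).
#' @param grid Reference 10-kb `bin_grid`.
#' @param map A `homology_map` for the query species.
#' @param homolog_tss Query-species TSS (bp) of the orthologous gene
#'   (`NA` when no ortholog is annotated).
#' @param size_range Allowed mapped-anchor size in bp (5000-20000).
#' @param max_promoter_offset Promoter displacement cut in bp (20000).
#' @return List with `ok`, `reason`, and on success `q_chrom`, `q_p_mid`,
#'   `q_e_mid` (mapped anchor midpoints, bp).
#' @export
align_pei <- function(pei, grid, map, homolog_tss = NA,
                      size_range = c(5000, 20000),
                      max_promoter_offset = 20000) {
  lift_anchor <- function(bin) {
    s <- (bin - 1L) * grid$resolution
    pieces <- lift_interval(map, grid$chrom, s, s + grid$resolution)
    pieces <- pieces[pieces$reciprocal, , drop = FALSE]
    if (nrow(pieces) == 0) return(list(ok = FALSE, reason = "unmapped"))
    if (length(unique(pieces$q_chrom)) > 1)
      return(list(ok = FALSE, reason = "trans-split"))
    span <- max(pieces$q_end) - min(pieces$q_start)
    if (span < size_range[1] || span > size_range[2])
      return(list(ok = FALSE, reason = "size-out-of-range"))
    list(ok = TRUE, q_chrom = pieces$q_chrom[1],
         mid = (min(pieces$q_start) + max(pieces$q_end)) / 2)
  }
  pa <- lift_anchor(pei$p_bin)
  if (!pa$ok) return(list(ok = FALSE, reason = pa$reason))
  ea <- lift_anchor(pei$e_bin)
  if (!ea$ok) return(list(ok = FALSE, reason = ea$reason))
  if (pa$q_chrom != ea$q_chrom) return(list(ok = FALSE, reason = "trans-split"))
  if (!is.na(homolog_tss) && abs(pa$mid - homolog_tss) >= max_promoter_offset)
    return(list(ok = FALSE, reason = "promoter-displaced"))
  list(ok = TRUE, reason = NA_character_, q_chrom = pa$q_chrom,
       q_p_mid = pa$mid, q_e_mid = ea$mid)
}

#' Distance judgment for an aligned PEI
#'
#' `d` is the two-dimensional Euclidean distance (bp) between the aligned
#' anchor pair and its closest query PEI of the homologous promoter; the
#' judgment passes when `d < min(r1 * |i-j|, r2)`, with `|i-j|` the linear
#' anchor span of the aligned PEI in query coordinates. Use `r2 = 20000`
#' for the conservation test and `r2 = 50000` for the specificity test.
#'
#' @param q_p_mid,q_e_mid Aligned anchor midpoints (bp, query coordinates).
#' @param query_peis Data frame of the homologous promoter's query PEIs with
#'   `p_mid`, `e_mid` (bp); zero rows give `d = Inf`.
#' @param r1 Relative distance coefficient (0.2).
#' @param r2 Absolute distance threshold in bp.
#' @return List with `d`, `threshold`, `pass`.
#' @export
distance_judgment <- function(q_p_mid, q_e_mid, query_peis, r1 = 0.2, r2) {
  if (is.null(query_peis) || nrow(query_peis) == 0) {
    return(list(d = Inf, threshold = min(r1 * abs(q_e_mid - q_p_mid), r2),
                pass = FALSE))
  }
  d <- min(sqrt((query_peis$p_mid - q_p_mid)^2 +
                (query_peis$e_mid - q_e_mid)^2))
  thr <- min(r1 * abs(q_e_mid - q_p_mid), r2)
  list(d = d, threshold = thr, pass = d < thr)
}

#' Enrichment judgment for an aligned PEI
#'
#' The aligned pixel's enrichment score (observed minus expected under the
#' query background model) must strictly exceed the `q`-quantile (default
#' 20%) of the enrichment scores of all called PEIs in the query species.
#'
#' @param q_p_mid,q_e_mid Aligned anchor midpoints (bp).
#' @param query_m Query `contact_matrix` (10-kb, KR count scale).
#' @param query_expected Expected matrix for the query (from
#'   [expected_matrix()]).
#' @param query_scores Enrichment scores of all query PEIs (non-empty).
#' @param q Quantile (0.20).
#' @return List with `score`, `threshold`, `pass`, `missing` (`TRUE` when
#'   the pixel falls on a masked bin).
#' @export
enrichment_judgment <- function(q_p_mid, q_e_mid, query_m, query_expected,
                                query_scores, q = 0.20) {
  if (length(query_scores) == 0)
    stop("contract error: empty query enrichment-score distribution")
  thr <- stats::quantile(query_scores, q, names = FALSE)
  pb <- bin_of(query_m$grid, q_p_mid)
  eb <- bin_of(query_m$grid, q_e_mid)
  if (is.na(pb) || is.na(eb) || !query_m$mask[pb] || !query_m$mask[eb])
    return(list(score = NA_real_, threshold = thr, pass = FALSE,
                missing = TRUE))
  score <- query_m$values[pb, eb] - query_expected$expected[pb, eb]
  list(score = score, threshold = thr, pass = score > thr, missing = FALSE)
}

#' Combine per-species judgments into a PEI conservation label
#'
#' Per species: a conserved vote needs the conservation-distance judgment
#' (`r2` = 20 kb) OR the enrichment judgment to pass; a specific vote needs
#' the PEI to be far under the specificity test (`r2` = 50 kb) AND show no
#' enrichment. Overall: species-conserved iff conserved votes in all
#' species; human-specific iff specific votes in all species; otherwise
#' unclassified. An alignment failure in any species forces unclassified.
#'
#' @param judgments Data frame with one row per query species: `aligned`
#'   (logical), `dist_pass_cons`, `dist_pass_spec` (distance pass under the
#'   20-kb and 50-kb tests), `enrich_pass`.
#' @return List with `label` in `{species-conserved, human-specific,
#'   unclassified}` and `reason`.
#' @export
classify_pei <- function(judgments) {
  if (any(!judgments$aligned))
    return(list(label = "unclassified", reason = "alignment-failure"))
  conserved_vote <- judgments$dist_pass_cons | judgments$enrich_pass
  specific_vote <- !judgments$dist_pass_spec & !judgments$enrich_pass
  if (all(conserved_vote)) list(label = "species-conserved", reason = NA_character_)
  else if (all(specific_vote)) list(label = "human-specific", reason = NA_character_)
  else list(label = "unclassified", reason = "mixed-votes")
}

#' Classify reference PEIs across query species
#'
#' Driver running [align_pei()], both [distance_judgment()] tests and the
#' [enrichment_judgment()] for every reference PEI against every query
#' species, then combining them with [classify_pei()].
#'
#' @param ref_peis Reference PEI data frame (from [call_peis()]).
#' @param ref_grid Reference 10-kb `bin_grid`.
#' @param queries Named list, one entry per query species, each a list with
#'   `map` (`homology_map`), `m` (query `contact_matrix`), `tads`
#'   (query TADs or `NULL`), `peis` (query PEI data frame), `promoters`
#'   (query promoter data frame), `ortholog` (named vector mapping reference
#'   gene ids to query gene ids).
#' @param r1 Relative distance coefficient (0.2).
#' @param r2_cons,r2_spec Absolute cuts for the conservation / specificity
#'   distance tests (20 kb / 50 kb).
#' @param quantile_cut Enrichment-score quantile (0.20).
#' @return `ref_peis` with added `class` and `reason` columns.
#' @export
classify_peis_across_species <- function(ref_peis, ref_grid, queries,
                                         r1 = 0.2, r2_cons = 20000,
                                         r2_spec = 50000, quantile_cut = 0.20) {
  prep <- lapply(queries, function(qq) {
    bg <- expected_matrix(qq$m, qq$tads)
    qp <- qq$peis
    g <- qq$m$grid
    qp$p_mid <- (qp$p_bin - 0.5) * g$resolution
    qp$e_mid <- (qp$e_bin - 0.5) * g$resolution
    list(map = qq$map, m = qq$m, bg = bg, peis = qp,
         promoters = qq$promoters, ortholog = qq$ortholog,
         scores = qp$enrichment)
  })
  labels <- character(nrow(ref_peis))
  reasons <- character(nrow(ref_peis))
  for (k in seq_len(nrow(ref_peis))) {
    jd <- lapply(prep, function(qq) {
      ortho <- qq$ortholog[[as.character(ref_peis$gene[k])]]
      homolog_tss <- if (is.null(ortho) || is.na(ortho)) NA else {
        hit <- qq$promoters[qq$promoters$gene == ortho, , drop = FALSE]
        if (nrow(hit)) hit$tss[1] else NA
      }
      al <- align_pei(ref_peis[k, ], ref_grid, qq$map, homolog_tss)
      if (!al$ok)
        return(data.frame(aligned = FALSE, dist_pass_cons = FALSE,
                          dist_pass_spec = FALSE, enrich_pass = FALSE))
      qpeis <- if (is.null(ortho) || is.na(ortho)) qq$peis[0, ]
        else qq$peis[qq$peis$gene == ortho, , drop = FALSE]
      dc <- distance_judgment(al$q_p_mid, al$q_e_mid, qpeis, r1, r2_cons)
      dsp <- distance_judgment(al$q_p_mid, al$q_e_mid, qpeis, r1, r2_spec)
      # no called PEIs in the query at all: the enrichment-score
      # distribution is undefined, so there is no enrichment evidence
      en_pass <- if (length(qq$scores) == 0) FALSE else
        enrichment_judgment(al$q_p_mid, al$q_e_mid, qq$m, qq$bg,
                            qq$scores, quantile_cut)$pass
      data.frame(aligned = TRUE, dist_pass_cons = dc$pass,
                 dist_pass_spec = dsp$pass, enrich_pass = en_pass)
    })
    cl <- classify_pei(do.call(rbind, jd))
    labels[k] <- cl$label
    reasons[k] <- if (is.na(cl$reason)) "" else cl$reason
  }
  ref_peis$class <- labels
  ref_peis$reason <- reasons
  ref_peis
}
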