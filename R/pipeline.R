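#' Area under the ROC curve for a score separating two planted classes
#'
#' Rank-based (Mann-Whitney) AUC with ties counted half.
#'
#' @param score Numeric scores.
#' @param positive Logical, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, positive) {
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]; positive <- positive[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Boundary recovery metrics against planted truth
#'
#' @param called Called boundary bins.
#' @param planted Planted boundary bins.
#' @param tol Match tolerance in bins (1).
#' @return List with `recall`, `precision`.
#' @export
boundary_recovery <- function(called, planted, tol = 1L) {
  if (length(planted) == 0) return(list(recall = NA_real_, precision = NA_real_))
  hit_p <- vapply(planted, function(b) any(abs(called - b) <= tol), logical(1))
  hit_c <- if (length(called) == 0) logical(0)
    else vapply(called, function(b) any(abs(planted - b) <= tol), logical(1))
  list(recall = mean(hit_p),
       precision = if (length(called) == 0) NA_real_ else mean(hit_c))
}

#' Simulate and analyse a multi-chromosome PEI study
#'
#' Simulates `n_chrom` independent chromosomes with planted loops at the
#' study depth, runs the full per-chromosome PEI pipeline (KR balancing,
#' TAD calling for the domain-aware background, PEI calling, cross-species
#' classification) and pools the results. Several moderate chromosomes at
#' the per-chromosome depth give the fixture the contact density of deep
#' merged Hi-C libraries while keeping every planted loop measurable.
#'
#' @param seed Integer seed; per-chromosome seeds derive from it.
#' @param n_chrom Number of chromosomes (3).
#' @param chrom_length Length per chromosome in bp (2e6).
#' @param depth Contacts per chromosome (1e5).
#' @param n_loops Planted loops requested per chromosome (12).
#' @param fdr_cut,min_len,max_span,r1,r2_cons,r2_spec,quantile_cut
#'   Thresholds as in [run_config()].
#' @return List with `classified` (pooled PEI table with `chrom_id`,
#'   `class`, `truth_class` for calls matching a planted loop at <= 1 bin),
#'   `loop_recall`, `classification_accuracy` (over matched calls with a
#'   decided label), `apa_score` (pooled mean of per-chromosome scores
#'   weighted by pixels used), `n_planted`, and `first_chrom` (the first
#'   chromosome's simulation, for downstream fixtures).
#' @export
run_pei_analysis <- function(seed, n_chrom = 3L, chrom_length = 2e6,
                             depth = 1e5, n_loops = 12L, fdr_cut = 0.001,
                             min_len = 20000, max_span = 1e7, r1 = 0.2,
                             r2_cons = 20000, r2_spec = 50000,
                             quantile_cut = 0.20) {
  pooled <- list()
  apa_scores <- numeric(0); apa_n <- numeric(0)
  n_planted <- 0L; n_found <- 0L
  first_chrom <- NULL
  for (cc in seq_len(n_chrom)) {
    pspec <- sim_spec(chrom_length = chrom_length, resolution = 1e4,
                      tad_bin_range = c(30L, 70L), beta = 0, depth = depth,
                      n_loops = n_loops, loop_sep_range = c(1e5, 3e5),
                      gap_rate = 0.02, seed = seed + 1000L * cc)
    psim <- simulate_species_set(pspec, resolutions = 1e4)
    world <- lapply(psim$species, function(s) {
      m <- kr_balance(s[["10000"]])
      tads <- tads_from_boundaries(call_boundaries(insulation_score(m)),
                                   m$grid)
      list(m = m, tads = tads)
    })
    promoters <- make_promoters(psim$truth$genes, world$human$m$grid)
    peis <- lapply(names(world), function(sp)
      call_peis(world[[sp]]$m, promoters, world[[sp]]$tads,
                max_span = max_span, fdr_cut = fdr_cut, min_len = min_len))
    names(peis) <- names(world)
    queries <- lapply(setdiff(names(world), "human"), function(sp)
      list(map = psim$maps[[sp]], m = world[[sp]]$m,
           tads = world[[sp]]$tads, peis = peis[[sp]],
           promoters = promoters,
           ortholog = stats::setNames(psim$truth$genes$gene,
                                      psim$truth$genes$gene)))
    names(queries) <- setdiff(names(world), "human")
    classified <- classify_peis_across_species(
      peis$human, world$human$m$grid, queries, r1 = r1, r2_cons = r2_cons,
      r2_spec = r2_spec, quantile_cut = quantile_cut)
    g10 <- world$human$m$grid
    lp <- psim$truth$loops
    lp$p_bin <- bin_of(g10, lp$p_pos); lp$e_bin <- bin_of(g10, lp$e_pos)
    truth_cls <- rep(NA_character_, nrow(classified))
    for (k in seq_len(nrow(classified))) {
      d <- abs(lp$p_bin - classified$p_bin[k]) +
        abs(lp$e_bin - classified$e_bin[k])
      if (length(d) && min(d) <= 1) truth_cls[k] <- lp$class[which.min(d)]
    }
    classified$truth_class <- truth_cls
    classified$chrom_id <- cc
    pooled[[cc]] <- classified
    n_planted <- n_planted + nrow(lp)
    n_found <- n_found + sum(vapply(seq_len(nrow(lp)), function(k)
      any(abs(peis$human$p_bin - lp$p_bin[k]) +
            abs(peis$human$e_bin - lp$e_bin[k]) <= 1), logical(1)))
    ap <- tryCatch(apa(world$human$m, peis$human), error = function(e) NULL)
    if (!is.null(ap)) { apa_scores <- c(apa_scores, ap$score)
                        apa_n <- c(apa_n, ap$n_used) }
    if (is.null(first_chrom))
      first_chrom <- list(sim = psim, grid = g10, peis = peis$human)
  }
  classified <- do.call(rbind, pooled)
  decided <- !is.na(classified$truth_class) &
    classified$class != "unclassified"
  acc <- mean((classified$class[decided] == "human-specific") ==
                (classified$truth_class[decided] == "human-gained"))
  list(classified = classified,
       loop_recall = n_found / n_planted,
       classification_accuracy = acc,
       apa_score = sum(apa_scores * apa_n) / sum(apa_n),
       n_planted = n_planted, first_chrom = first_chrom)
}

#' Default run configuration
#'
#' Thresholds default to the pipeline's standard values: 40-kb boundary
#' conservation flank, 100-kb specificity distance, PEI FDR 0.001 and
#' minimum length 20 kb, distance coefficients r1 = 0.2 with r2 = 20/50 kb,
#' enrichment quantile 0.20, 1000 expression anchors, TF filters
#' (>= 3 motif occurrences, TPM > 1, |delta| > 5, p < 0.05).
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A named list of parameters, class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("hicevo_run_")) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    flank = 40000, specific_min = 100000,
    r1 = 0.2, r2_cons = 20000, r2_spec = 50000,
    fdr_cut = 0.001, min_len = 20000, max_span = 1e7,
    quantile_cut = 0.20, n_anchor = 1000,
    min_occ = 3, min_tpm = 1, delta_cut = 5, alpha_pair = 0.05,
    noise_threshold = 0.5, is_window = 260000, is_delta_span = 200000,
    comp_chrom_length = 4e7, comp_depth = 1e5,
    tad_chrom_length = 2e7, tad_depth = 1e5,
    pei_chrom_length = 2e6, pei_depth = 1e5, pei_n_loops = 12L,
    pei_n_chrom = 3L)
  if (cfg$r1 < 0) stop("validation error: r1 < 0")
  class(cfg) <- "run_config"
  cfg
}

#' Run the synthetic end-to-end analysis
#'
#' Simulates the multi-species study at the configured sizes and executes
#' the requested stages in dependency order: compartment calling and A-B
#' index recovery, TAD boundary calling with evolutionary classification,
#' PEI calling with cross-species classification, expression scaling, and
#' TF-pair inference. Writes stage outputs (BED/bedGraph/TSV) plus a
#' `manifest.json` recording seeds, thresholds, planted-truth recovery
#' metrics and content hashes of every written file.
#'
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("compartments", "tads", "peis", "expression", "tfpairs")`.
#' @return The manifest (invisibly written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("compartments", "tads", "peis",
                                    "expression", "tfpairs")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   thresholds = config[!(names(config) %in%
                                           c("seed", "out_dir"))],
                   metrics = list(), files = list())
  seed <- config$seed

  if ("compartments" %in% stages) {
    spec <- sim_spec(chrom_length = config$comp_chrom_length,
                     depth = config$comp_depth, seed = seed)
    sim <- simulate_species_set(spec, resolutions = c(2e4, 1e5))
    hum <- sim$species$human
    kr100 <- kr_balance(hum[["1e+05"]])
    oe100 <- observed_over_expected(kr100, expected_by_distance(kr100, "mean"))
    lowres <- call_low_res_compartments(oe100, sim$truth$gene_density100)
    kr20 <- kr_balance(hum[["20000"]])
    oe20 <- observed_over_expected(kr20, expected_by_distance(kr20, "mean"))
    track <- ab_index(oe20, lowres)
    truth_sign100 <- sim$truth$sign_per_species$human[sim$truth$block_of_100]
    ok <- !is.na(lowres$label)
    agree <- mean((lowres$label[ok] == "A") == (truth_sign100[ok] > 0))
    agree <- max(agree, 1 - agree)  # planted signs are label-symmetric
    bins20 <- pmin(length(truth_sign100), floor(bin_starts(track$grid) / 1e5) + 1)
    auc <- rank_auc(track$ab_index, truth_sign100[bins20] > 0)
    auc <- max(auc, 1 - auc)
    manifest$metrics$compartment_sign_agreement <- agree
    manifest$metrics$ab_index_auc <- auc
    f <- file.path(config$out_dir, "ab_index.bedgraph")
    write_ab_bedgraph(track, f)
    manifest$files <- c(manifest$files, f)
  }

  if (any(c("tads", "peis") %in% stages)) seed <- seed + 1L

  if ("tads" %in% stages) {
    spec <- sim_spec(chrom_length = config$tad_chrom_length,
                     depth = config$tad_depth, beta = 0, seed = seed)
    sim <- simulate_species_set(spec, resolutions = 2e4)
    kr <- lapply(sim$species, function(s) kr_balance(s[["20000"]]))
    tracks <- lapply(kr, insulation_score, window = config$is_window,
                     delta_span = config$is_delta_span)
    bounds <- lapply(tracks, call_boundaries,
                     noise_threshold = config$noise_threshold)
    rec <- boundary_recovery(bounds$human$bin, sim$truth$boundaries_bin)
    labels <- classify_boundaries(bounds$human, bounds[-1], sim$maps, "chrS",
                                  flank = config$flank,
                                  specific_min = config$specific_min)
    tads <- tads_from_boundaries(bounds$human, kr$human$grid)
    tads <- classify_tads(tads, labels)
    tads$strength <- vapply(seq_len(nrow(tads)), function(k)
      tad_strength(kr$human, tads$start_bin[k], tads$end_bin[k]), numeric(1))
    agg <- aggregate_tad_map(kr$human, tads)
    # accuracy of the evolutionary labels against the planted classes
    truth_bins <- sim$truth$boundaries_bin
    hs_truth <- sim$truth$boundary_hs
    match_idx <- vapply(labels$bin, function(b) {
      d <- abs(truth_bins - b)
      if (min(d) <= 1) which.min(d) else NA_integer_
    }, integer(1))
    matched <- !is.na(match_idx)
    pred_hs <- labels$overall == "species-specific"
    correct <- (pred_hs & hs_truth[match_idx]) |
      (labels$overall == "species-conserved" & !hs_truth[match_idx])
    manifest$metrics$boundary_recall <- rec$recall
    manifest$metrics$boundary_precision <- rec$precision
    manifest$metrics$boundary_evo_accuracy <-
      mean(correct[matched], na.rm = TRUE)
    manifest$metrics$median_tad_strength <-
      stats::median(tads$strength, na.rm = TRUE)
    manifest$metrics$aggregate_tad_ratio <- agg$ratio
    f1 <- file.path(config$out_dir, "boundaries.bed")
    write_bed(labels, kr$human$grid, f1)
    f2 <- file.path(config$out_dir, "tads.bed")
    write_bed(tads, kr$human$grid, f2)
    manifest$files <- c(manifest$files, f1, f2)
  }

  if ("peis" %in% stages || "tfpairs" %in% stages) {
    seed <- seed + 1L
    pa <- run_pei_analysis(seed, n_chrom = config$pei_n_chrom,
                           chrom_length = config$pei_chrom_length,
                           depth = config$pei_depth,
                           n_loops = config$pei_n_loops,
                           fdr_cut = config$fdr_cut,
                           min_len = config$min_len,
                           max_span = config$max_span, r1 = config$r1,
                           r2_cons = config$r2_cons,
                           r2_spec = config$r2_spec,
                           quantile_cut = config$quantile_cut)
    manifest$metrics$n_peis_human <- nrow(pa$classified)
    manifest$metrics$pei_loop_recall <- pa$loop_recall
    manifest$metrics$pei_classification_accuracy <-
      pa$classification_accuracy
    manifest$metrics$apa_score <- pa$apa_score
    f <- file.path(config$out_dir, "peis.tsv")
    utils::write.table(pa$classified, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$files <- c(manifest$files, f)

    if ("tfpairs" %in% stages) {
      psim <- pa$first_chrom$sim
      g10 <- pa$first_chrom$grid
      fx <- simulate_fixtures(psim$truth, g10, seed = seed + 1L)
      hp <- har_permutation_test(
        fx$enhancers[fx$enhancers$class == "HS", ],
        fx$enhancers, fx$hars, n_perm = 1000, seed = seed + 2L)
      cand <- candidate_tf_pairs(fx$motif_hits, fx$tf_expr, fx$ppi)
      hs_ids <- fx$pei_ids[fx$pei_class == "HS"]
      cons_ids <- fx$pei_ids[fx$pei_class == "Cons"]
      kept <- vapply(seq_len(nrow(cand)), function(k) {
        hs <- pair_cooccurrence(fx$motif_hits, hs_ids,
                                cand$enhancer_tf[k], cand$promoter_tf[k])
        cons <- pair_cooccurrence(fx$motif_hits, cons_ids,
                                  cand$enhancer_tf[k], cand$promoter_tf[k])
        isTRUE(pair_preference_test(hs, cons, config$alpha_pair)$keep)
      }, logical(1))
      planted_found <- any(
        cand$enhancer_tf[kept] == fx$planted_pair["enhancer_tf"] &
        cand$promoter_tf[kept] == fx$planted_pair["promoter_tf"])
      manifest$metrics$har_permutation_p <- hp$p
      manifest$metrics$planted_tf_pair_recovered <- planted_found
    }
  }

  if ("expression" %in% stages) {
    seed <- config$seed + 10L
    spec <- sim_spec(chrom_length = 1e7, depth = 1e4, n_genes = 1500L,
                     seed = seed)
    sim <- simulate_species_set(spec, resolutions = 1e5)
    expr <- simulate_expression(sim$truth, n_rep = 1L,
                                scale_factors = c(1, 2, 4), seed = seed)
    sn <- scale_normalize(expr$tpm, n_anchor = 400)
    rel <- (sn$factor / sn$factor[1]) * expr$scale_factors /
      expr$scale_factors[1]
    manifest$metrics$scale_factor_max_rel_error <- max(abs(rel - 1))
    cv <- cross_species_cv(sn$normalized, expr$species)
    manifest$metrics$median_cv <- stats::median(cv, na.rm = TRUE)
  }

  manifest$files <- as.character(unlist(manifest$files))
  if (length(manifest$files)) {
    h <- tools::md5sum(manifest$files)
    names(h) <- basename(names(h))
    manifest$hashes <- as.list(h)
  }
  # manifests must be byte-identical across output directories
  manifest$files <- basename(manifest$files)
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
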