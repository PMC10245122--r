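#' Specification for a synthetic multi-species Hi-C experiment
#'
#' Defines the generative model: contacts are Poisson counts around the
#' intensity
#' `mu(i,j) = C * (1+|i-j|)^(-alpha) * exp(beta*s_i*s_j) * gamma^[same TAD]
#'  * lambda^[loop pixel]`,
#' with `s = +/-1` compartment signs on a block checkerboard, TAD blocks
#' between planted boundaries, and loop pixels at planted
#' promoter-enhancer anchors. Query species derive from the reference by
#' flipping a fraction of variable compartment blocks, removing the planted
#' reference-specific boundaries, and omitting reference-gained loops;
#' homology maps are piecewise-identity with gaps.
#'
#' @param n_species Number of species incl. the reference (3).
#' @param chrom_length Chromosome length in bp (4e7).
#' @param resolution Base bin width in bp (2e4).
#' @param alpha Distance-decay exponent (1).
#' @param beta Compartment contrast; `exp(2*beta)` is the checkerboard
#'   contrast ratio (default `log(2)/2`, i.e. 2x).
#' @param gamma Intra-TAD enrichment (2).
#' @param lambda Loop pixel amplitude (5).
#' @param depth Total contacts per chromosome (1e5).
#' @param comp_block_range Compartment block length range in 100-kb units.
#' @param tad_bin_range TAD length range in base-resolution bins
#'   (15-35 bins = 300-700 kb at 20-kb, median 500 kb).
#' @param flip_frac Fraction of compartment blocks that vary across species.
#' @param hs_boundary_frac Fraction of boundaries planted reference-specific.
#' @param n_loops Number of planted loops (0 disables).
#' @param hs_loop_frac Fraction of loops gained in the reference only.
#' @param loop_sep_range Loop anchor separation range in bp.
#' @param gap_rate Per-segment probability of a homology gap.
#' @param n_genes Number of genes (default one per 100 kb).
#' @param seed Integer seed; everything derives from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_species = 3L, chrom_length = 4e7, resolution = 2e4,
                     alpha = 1, beta = log(2) / 2, gamma = 2, lambda = 5,
                     depth = 1e5, comp_block_range = c(5L, 15L),
                     tad_bin_range = c(15L, 35L), flip_frac = 0.2,
                     hs_boundary_frac = 0.2, n_loops = 0L,
                     hs_loop_frac = 0.2, loop_sep_range = c(1e5, 1e6),
                     gap_rate = 0.05, n_genes = NULL, seed = 1L) {
  if (is.null(n_genes)) n_genes <- max(20L, round(chrom_length / 1e5))
  spec <- list(n_species = n_species, chrom_length = chrom_length,
               resolution = resolution, alpha = alpha, beta = beta,
               gamma = gamma, lambda = lambda, depth = depth,
               comp_block_range = comp_block_range,
               tad_bin_range = tad_bin_range, flip_frac = flip_frac,
               hs_boundary_frac = hs_boundary_frac, n_loops = n_loops,
               hs_loop_frac = hs_loop_frac, loop_sep_range = loop_sep_range,
               gap_rate = gap_rate, n_genes = n_genes, seed = as.integer(seed))
  stopifnot(spec$depth > 0,
            spec$flip_frac >= 0, spec$flip_frac <= 1,
            spec$hs_boundary_frac >= 0, spec$hs_boundary_frac <= 1,
            spec$gap_rate >= 0, spec$gap_rate <= 1)
  if (spec$tad_bin_range[2] * spec$resolution > spec$chrom_length)
    stop("contract error: TAD longer than chromosome")
  class(spec) <- "sim_spec"
  spec
}

# Poisson count matrix around the planted intensity at one resolution.
# s: per-bin compartment sign; tid: per-bin TAD id (0 = outside);
# loops: data.frame(p, e) of bin pairs.
sim_count_matrix <- function(n, depth, alpha, beta, gamma, lambda,
                             s, tid, loops = NULL) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- (1 + d)^(-alpha)
  mu <- mu * exp(beta * outer(s, s))
  same <- outer(tid, tid, "==") & tid > 0
  mu[same] <- mu[same] * gamma
  if (!is.null(loops) && nrow(loops) > 0) {
    for (k in seq_len(nrow(loops))) {
      mu[loops$p[k], loops$e[k]] <- mu[loops$p[k], loops$e[k]] * lambda
      mu[loops$e[k], loops$p[k]] <- mu[loops$e[k], loops$p[k]] * lambda
    }
  }
  ut <- upper.tri(mu, diag = TRUE)
  mu <- mu * (depth / sum(mu[ut]))
  counts <- matrix(0, n, n)
  counts[ut] <- stats::rpois(sum(ut), mu[ut])
  counts <- counts + t(counts)
  diag(counts) <- diag(counts) / 2
  counts
}

#' Simulate a multi-species chromosome with planted ground truth
#'
#' @param spec A [sim_spec()].
#' @param resolutions Resolutions (bp) at which to emit count matrices
#'   (default: the base resolution and 100 kb).
#' @return List with `species` (named list; per species a list of
#'   `contact_matrix` objects keyed by resolution string), `maps` (named
#'   `homology_map` list for the query species), and `truth` (planted
#'   compartment signs per species and resolution, boundary tables with
#'   reference-specific flags, loop table with classes, gene table,
#'   per-100-kb-bin gene density).
#' @export
simulate_species_set <- function(spec,
                                 resolutions = unique(c(spec$resolution, 1e5))) {
  with_seed(spec$seed, {
    L <- spec$chrom_length
    species <- c("human", paste0("sp", seq_len(spec$n_species - 1L) + 1L))

    # compartment blocks in 100-kb units
    n100 <- floor(L / 1e5)
    lens <- integer(0)
    while (sum(lens) < n100)
      lens <- c(lens, sample(spec$comp_block_range[1]:spec$comp_block_range[2], 1))
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n100)
    nb <- length(lens)
    first <- sample(c(-1, 1), 1)
    block_sign <- first * (-1)^(seq_len(nb) - 1)
    variable <- stats::runif(nb) < spec$flip_frac
    sign_per_species <- lapply(species, function(sp) {
      s <- block_sign
      if (sp != "human") {
        flip <- variable & stats::runif(nb) < 0.5
        s[flip] <- -s[flip]
      }
      s
    })
    names(sign_per_species) <- species
    block_end100 <- cumsum(lens)
    block_of_100 <- rep(seq_len(nb), lens)

    # TADs in base-resolution bins
    nbin <- floor(L / spec$resolution)
    tlens <- integer(0)
    while (sum(tlens) < nbin)
      tlens <- c(tlens, sample(spec$tad_bin_range[1]:spec$tad_bin_range[2], 1))
    tlens[length(tlens)] <- tlens[length(tlens)] - (sum(tlens) - nbin)
    bnd_bins <- cumsum(tlens)
    bnd_bins <- bnd_bins[bnd_bins < nbin]  # internal boundaries
    n_hs <- round(spec$hs_boundary_frac * length(bnd_bins))
    hs_idx <- if (n_hs > 0) sort(sample(seq_along(bnd_bins), n_hs)) else integer(0)
    hs_flag <- seq_along(bnd_bins) %in% hs_idx
    bnd_per_species <- lapply(species, function(sp) {
      if (sp == "human") bnd_bins else bnd_bins[!hs_flag]
    })
    names(bnd_per_species) <- species

    # genes: density-weighted toward A compartment (reference signs)
    w100 <- ifelse(block_sign[block_of_100] > 0, 3, 1)
    gene_bin100 <- sample.int(n100, spec$n_genes, replace = TRUE, prob = w100)
    gene_pos <- (gene_bin100 - 1) * 1e5 + floor(stats::runif(spec$n_genes) * 1e5)
    genes <- data.frame(gene = sprintf("g%04d", seq_len(spec$n_genes)),
                        pos = sort(gene_pos),
                        strand = sample(c("+", "-"), spec$n_genes,
                                        replace = TRUE))
    genes$block <- block_of_100[pmin(n100, floor(genes$pos / 1e5) + 1)]
    genes$block_variable <- variable[genes$block]
    gene_density100 <- tabulate(floor(genes$pos / 1e5) + 1, nbins = n100)

    # loops between gene promoters and distal enhancer anchors (10-kb pixels)
    loops <- NULL
    if (spec$n_loops > 0) {
      cand <- sample(seq_len(nrow(genes)), nrow(genes))
      off <- stats::runif(length(cand), spec$loop_sep_range[1],
                          spec$loop_sep_range[2]) *
        sample(c(-1, 1), length(cand), replace = TRUE)
      e_pos <- genes$pos[cand] + off
      cls <- ifelse(stats::runif(length(cand)) < spec$hs_loop_frac,
                    "human-gained", "shared")
      loops <- data.frame(gene = genes$gene[cand], p_pos = genes$pos[cand],
                          e_pos = e_pos, class = cls,
                          stringsAsFactors = FALSE)
      loops <- loops[loops$e_pos >= 2e4 & loops$e_pos <= L - 3e4, ,
                     drop = FALSE]
      # keep loops long enough to survive the 20-kb length filter, and
      # enhancer anchors distal to every promoter (enhancers are distal
      # elements; promoter-promoter pairs are filtered by the PEI caller)
      loops <- loops[abs(loops$e_pos - loops$p_pos) >= 3e4, , drop = FALSE]
      near_tss <- vapply(loops$e_pos, function(p)
        any(abs(genes$pos - p) < 2.2e4), logical(1))
      loops <- loops[!near_tss, , drop = FALSE]
      loops <- utils::head(loops, spec$n_loops)
    }

    # homology maps: piecewise identity with gaps (per query species);
    # segment size scales with the chromosome so a gap stays local
    seg <- min(5e5, max(1e5, L / 20))
    starts <- seq(0, L - 1, by = seg)
    maps <- lapply(species[-1], function(sp) {
      gap <- stats::runif(length(starts)) < spec$gap_rate
      kept <- which(!gap)
      homology_map(data.frame(
        ref_chrom = "chrS", ref_start = starts[kept],
        ref_end = pmin(starts[kept] + seg, L),
        q_chrom = "chrS", q_start = starts[kept],
        q_end = pmin(starts[kept] + seg, L),
        strand = "+", reciprocal = TRUE, stringsAsFactors = FALSE))
    })
    names(maps) <- species[-1]

    # count matrices per species and resolution
    out_species <- lapply(species, function(sp) {
      s100 <- sign_per_species[[sp]][block_of_100]
      bnd <- bnd_per_species[[sp]]
      mats <- lapply(resolutions, function(res) {
        n <- floor(L / res)
        grid <- bin_grid("chrS", res, n)
        bin100 <- pmin(n100, floor(bin_starts(grid) / 1e5) + 1L)
        s <- s100[bin100]
        bnd_res <- unique(pmin(n, floor(((bnd * spec$resolution) - 1) / res) + 1L))
        tid <- findInterval(seq_len(n), c(0, bnd_res)) # domains between boundaries
        tid[bnd_res] <- 0L  # boundary bins separate domains
        lp <- NULL
        if (!is.null(loops) && nrow(loops) > 0) {
          keep <- if (sp == "human") rep(TRUE, nrow(loops))
            else loops$class == "shared"
          if (any(keep)) {
            lp <- data.frame(p = bin_of(grid, loops$p_pos[keep]),
                             e = bin_of(grid, loops$e_pos[keep]))
            lp <- lp[!is.na(lp$p) & !is.na(lp$e) & lp$p != lp$e, ]
          }
        }
        contact_matrix(
          sim_count_matrix(n, spec$depth, spec$alpha, spec$beta, spec$gamma,
                           spec$lambda, s, tid, lp),
          grid)
      })
      names(mats) <- as.character(resolutions)
      mats
    })
    names(out_species) <- species

    truth <- list(
      species = species,
      block_lengths_100kb = lens,
      block_variable = variable,
      sign_per_species = sign_per_species,
      block_of_100 = block_of_100,
      boundaries_bin = bnd_bins,
      boundary_hs = hs_flag,
      boundaries_per_species = bnd_per_species,
      loops = loops,
      genes = genes,
      gene_density100 = gene_density100)
    list(species = out_species, maps = maps, truth = truth)
  })
}

#' Simulate a cross-species expression table with planted structure effects
#'
#' Log-normal expression for the planted genes: each gene has a baseline,
#' per-species effects whose standard deviation is scaled by its structure
#' class multiplier (genes in variable compartment blocks diverge faster
#' when their multiplier exceeds the conserved one), replicate noise, and
#' planted per-sample multiplicative scale factors.
#'
#' @param truth Truth list from [simulate_species_set()].
#' @param class_multiplier Named vector: divergence s.d. multipliers for
#'   `conserved` and `variable` genes (default both 1).
#' @param n_rep Replicates per species (2).
#' @param scale_factors Optional per-sample multiplicative factors (recycled
#'   over samples); default 1.
#' @param base_sd Species-effect s.d. in log2 units (0.5).
#' @param rep_sd Replicate noise s.d. (0.1).
#' @param seed Integer seed.
#' @return List with `tpm` (genes x samples), `species` (per sample),
#'   `scale_factors` (per sample), `gene_class`.
#' @export
simulate_expression <- function(truth,
                                class_multiplier = c(conserved = 1,
                                                     variable = 1),
                                n_rep = 2L, scale_factors = NULL,
                                base_sd = 0.5, rep_sd = 0.1, seed = 1L) {
  with_seed(seed, {
    genes <- truth$genes
    species <- truth$species
    ng <- nrow(genes)
    samples <- paste(rep(species, each = n_rep), rep(seq_len(n_rep),
                                                     length(species)),
                     sep = "_r")
    sp_of <- rep(species, each = n_rep)
    if (is.null(scale_factors)) scale_factors <- rep(1, length(samples))
    scale_factors <- rep_len(scale_factors, length(samples))
    cls <- ifelse(genes$block_variable, "variable", "conserved")
    mult <- unname(class_multiplier[cls])
    base <- stats::rnorm(ng, mean = 5, sd = 1.5)
    spe <- matrix(stats::rnorm(ng * length(species), 0, base_sd * mult),
                  ng, length(species))
    log2e <- base + spe[, match(sp_of, species)] +
      matrix(stats::rnorm(ng * length(samples), 0, rep_sd), ng)
    tpm <- sweep(pmax(2^log2e - 1, 0), 2, scale_factors, "*")
    dimnames(tpm) <- list(genes$gene, samples)
    list(tpm = tpm, species = sp_of, scale_factors = scale_factors,
         gene_class = stats::setNames(cls, genes$gene))
  })
}

#' Simulate annotation fixtures: HARs, SNPs, motif hits and a PPI network
#'
#' HARs and SNPs are placed into loop enhancer bins with a configurable
#' density ratio between reference-gained (HS) and shared loop classes; a
#' decoy enhancer universe is added. Motif hits plant one TF pair with
#' elevated co-occurrence in HS loops; the PPI graph is random plus the
#' planted direct edge.
#'
#' @param truth Truth list from [simulate_species_set()] (needs loops).
#' @param grid The 10-kb reference `bin_grid`.
#' @param har_density Baseline probability that an enhancer bin carries a
#'   HAR (0.2).
#' @param har_ratio HS-over-shared density ratio (2).
#' @param snp_density,snp_ratio Same for SNPs (0.3, 2).
#' @param n_tf Number of TFs (12).
#' @param cooc_hs,cooc_cons Planted pair co-occurrence probabilities (0.8,
#'   0.1); background TFs hit at 0.3.
#' @param n_decoy Decoy enhancer bins added to the universe (200).
#' @param seed Integer seed.
#' @return List with `enhancers` (universe with `class`), `hars`, `snps`,
#'   `motif_hits`, `ppi`, `tf_expr`, `planted_pair`.
#' @export
simulate_fixtures <- function(truth, grid, har_density = 0.2, har_ratio = 2,
                              snp_density = 0.3, snp_ratio = 2, n_tf = 12L,
                              cooc_hs = 0.8, cooc_cons = 0.1, n_decoy = 200L,
                              seed = 1L) {
  if (is.null(truth$loops) || nrow(truth$loops) == 0)
    stop("truth has no planted loops")
  with_seed(seed, {
    res <- grid$resolution
    e_bin <- bin_of(grid, truth$loops$e_pos)
    loop_cls <- ifelse(truth$loops$class == "human-gained", "HS", "Cons")
    decoy_bin <- sample(setdiff(seq_len(grid$n_bins), e_bin),
                        min(n_decoy, grid$n_bins - length(e_bin)))
    enhancers <- data.frame(
      bin = c(e_bin, decoy_bin),
      start = (c(e_bin, decoy_bin) - 1) * res,
      end = c(e_bin, decoy_bin) * res,
      class = c(loop_cls, rep("decoy", length(decoy_bin))))
    place <- function(p0, ratio) {
      p <- ifelse(enhancers$class == "HS", pmin(1, p0 * ratio), p0)
      rows <- which(stats::runif(nrow(enhancers)) < p)
      data.frame(start = enhancers$start[rows] +
                   floor(stats::runif(length(rows)) * (res - 100)),
                 stringsAsFactors = FALSE)
    }
    hars <- place(har_density, har_ratio)
    hars$end <- hars$start + 100
    snps <- place(snp_density, snp_ratio)
    snps$pos <- snps$start; snps$start <- NULL
    tfs <- sprintf("TF%02d", seq_len(n_tf))
    planted <- c(enhancer_tf = tfs[1], promoter_tf = tfs[2])
    pei_ids <- paste0("pei", seq_len(nrow(truth$loops)))
    hit_rows <- list()
    for (k in seq_along(pei_ids)) {
      p_cooc <- if (loop_cls[k] == "HS") cooc_hs else cooc_cons
      if (stats::runif(1) < p_cooc) {
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(tf = c(tfs[1], tfs[2]), role = c("enhancer", "promoter"),
                     region = pei_ids[k])
      }
      for (tf in tfs[-(1:2)]) {
        for (role in c("enhancer", "promoter"))
          if (stats::runif(1) < 0.3)
            hit_rows[[length(hit_rows) + 1L]] <-
              data.frame(tf = tf, role = role, region = pei_ids[k])
      }
    }
    motif_hits <- do.call(rbind, hit_rows)
    extra <- t(utils::combn(tfs, 2))
    keep <- stats::runif(nrow(extra)) < 0.15
    ppi <- unique(rbind(data.frame(a = planted[1], b = planted[2],
                                   row.names = NULL),
                        data.frame(a = extra[keep, 1], b = extra[keep, 2])))
    tf_expr <- stats::setNames(stats::runif(n_tf, 2, 50), tfs)
    list(enhancers = enhancers, hars = hars, snps = snps,
         motif_hits = motif_hits, ppi = ppi, tf_expr = tf_expr,
         planted_pair = planted, pei_ids = pei_ids, pei_class = loop_cls)
  })
}
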