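#!/usr/bin/env Rscript
# Stage 6: HAR enrichment of human-specific PEI enhancers, SNP densities,
# TF binding preference and TF-pair inference with the Mann-Whitney
# preference test.

suppressPackageStartupMessages(library(hicevo))
seed <- 5L
dir.create("results", showWarnings = FALSE)

spec <- sim_spec(chrom_length = 4e7, resolution = 1e4,
                 tad_bin_range = c(30L, 70L), beta = 0, depth = 1e5,
                 n_loops = 250L, hs_loop_frac = 0.3,
                 loop_sep_range = c(1e5, 3e5), seed = seed)
sim <- simulate_species_set(spec, resolutions = 1e5)
fx <- simulate_fixtures(sim$truth, bin_grid("chrS", 1e4, 4000),
                        seed = seed + 1L)

hp <- har_permutation_test(fx$enhancers[fx$enhancers$class == "HS", ],
                           fx$enhancers, fx$hars, n_perm = 1000,
                           seed = seed + 2L)
cat(sprintf("HARs in HS-PEI enhancers: observed %.1f%%, permutation p = %.4g\n",
            100 * hp$observed, hp$p))

snp <- snp_enrichment(list(HS = fx$enhancers[fx$enhancers$class == "HS", ],
                           Cons = fx$enhancers[fx$enhancers$class == "Cons", ]),
                      fx$snps)
print(snp$density); print(snp$fisher)

cand <- suppressWarnings(candidate_tf_pairs(fx$motif_hits, fx$tf_expr,
                                            fx$ppi))
hs_ids <- fx$pei_ids[fx$pei_class == "HS"]
cons_ids <- fx$pei_ids[fx$pei_class == "Cons"]
res <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
  hs <- pair_cooccurrence(fx$motif_hits, hs_ids, cand$enhancer_tf[k],
                          cand$promoter_tf[k])
  cons <- pair_cooccurrence(fx$motif_hits, cons_ids, cand$enhancer_tf[k],
                            cand$promoter_tf[k])
  tt <- pair_preference_test(hs, cons)
  data.frame(cand[k, ], p = tt$p, keep = tt$keep)
}))
utils::write.table(res, "results/tf_pairs.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
kept <- res[which(res$keep), ]
cat(sprintf("candidate pairs: %d; kept at p < 0.05: %d\n",
            nrow(res), nrow(kept)))
cat(sprintf("planted pair (%s -> %s) p = %.3g, recovered: %s\n",
            fx$planted_pair["enhancer_tf"], fx$planted_pair["promoter_tf"],
            res$p[res$enhancer_tf == fx$planted_pair["enhancer_tf"] &
                    res$promoter_tf == fx$planted_pair["promoter_tf"]],
            any(kept$enhancer_tf == fx$planted_pair["enhancer_tf"] &
                  kept$promoter_tf == fx$planted_pair["promoter_tf"])))
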