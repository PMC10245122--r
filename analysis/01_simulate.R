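#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-species study and write the shared
# inputs. Three worlds are simulated, matching the three scales of the
# analysis: a 40-Mb chromosome for compartments (merged-library depth),
# a 20-Mb chromosome for TAD calling (depth 1e5) and pooled 2-Mb
# chromosomes at 10-kb for PEI calling. Downstream drivers regenerate the
# same worlds deterministically from the seeds recorded here; this stage
# writes example inputs (sparse triplets, gene TSS, homology maps, truth)
# so the on-disk formats are exercised and inspectable.

suppressPackageStartupMessages(library(hicevo))
seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- sim_spec(chrom_length = 4e7, depth = 8e6, seed = seed)
sim <- simulate_species_set(spec, resolutions = c(2e4, 1e5))

# write a depth-matched 100-kb excerpt of each species' map: full 20-kb
# matrices at merged depth are tens of MB and are regenerated on demand
for (sp in names(sim$species)) {
  m <- downsample(sim$species[[sp]][["1e+05"]], 5e5, seed = seed)
  write_contacts(m, file.path(out, paste0(sp, "_100kb.triplets.tsv")))
}
genes <- sim$truth$genes
utils::write.table(genes[, c("gene", "pos", "strand")],
                   file.path(out, "genes.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
for (sp in names(sim$maps)) {
  utils::write.table(as.data.frame(sim$maps[[sp]]),
                     file.path(out, paste0("homology_", sp, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(
  list(seed = seed,
       species = sim$truth$species,
       n_compartment_blocks = length(sim$truth$block_lengths_100kb),
       variable_block_fraction = mean(sim$truth$block_variable),
       n_boundaries = length(sim$truth$boundaries_bin),
       boundaries_bin = sim$truth$boundaries_bin,
       boundary_hs = sim$truth$boundary_hs),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "simulated %d species on a 40-Mb chromosome: %d compartment blocks (%.0f%% variable), %d TAD boundaries\n",
  length(sim$truth$species), length(sim$truth$block_lengths_100kb),
  100 * mean(sim$truth$block_variable), length(sim$truth$boundaries_bin)))
cat("inputs written under", out, "\n")
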