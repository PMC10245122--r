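#!/usr/bin/env Rscript
# Stage 4: promoter-enhancer interaction calling at 10-kb against the
# domain-aware background, APA, and cross-species conservation
# classification on the pooled multi-chromosome study.

suppressPackageStartupMessages(library(hicevo))
seed <- 3L
dir.create("results", showWarnings = FALSE)

pa <- run_pei_analysis(seed = seed)
utils::write.table(pa$classified, "results/peis_classified.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("planted loops: %d; called at the planted pixel: %.0f%%\n",
            pa$n_planted, 100 * pa$loop_recall))
cat("classification of calls matching a planted loop:\n")
print(table(pa$classified$class, pa$classified$truth_class,
            useNA = "ifany"))
cat(sprintf("classification accuracy (decided calls): %.1f%%\n",
            100 * pa$classification_accuracy))
cat(sprintf("APA score over called PEIs: %.2f\n", pa$apa_score))

valency <- promoter_valency(pa$classified)
utils::write.table(valency, "results/promoter_valency.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("PEIs per promoter (%):\n"); print(valency)
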