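# hicevo

Comparative evolutionary analysis of 3D genome organization from Hi-C.

Chromosomes fold at several scales — megabase A/B compartments,
sub-megabase topologically associating domains (TADs), and individual
promoter–enhancer interactions (PEIs) — and each layer evolves at its own
pace across mammals. hicevo implements a complete pipeline for asking,
from binned intra-chromosomal Hi-C contact matrices of several species,
which structures are conserved and which are lineage-specific (e.g.
human-specific), and how those classes relate to gene expression,
regulatory annotation and transcription-factor co-binding. It is aimed at
computational biologists doing cross-species chromatin-architecture
studies, and at method developers who need a fully synthetic,
ground-truthed test bed for such pipelines.

## What it implements

**Matrix layer** — Knight–Ruiz-style balancing (equal row sums via per-bin
weights `w_i m_ij w_j`, count scale preserved), distance-decay expected
values E(d), observed/expected normalization, seeded binomial
down-sampling, quantile normalization across samples.

**Compartments** — two-step A/B calling: PC1 of the 100-kb O/E matrix
oriented by gene density, then the 20-kb **A-B index**

    A-B index(bin) = median O/E(bin, A regions) − median O/E(bin, B regions)

(positive = A-like); homologous 20-kb bins (reciprocal liftOver-style
maps across all species) clustered into evolutionary states and grouped
as CA / WCA / CB / WCB / NC by per-species A-status fractions
(>0.90 / >0.70, open), with a human-specific-A flag.

**TADs** — insulation score (260-kb square, log2 ratio to the chromosome
mean), boundary calls at positive-to-negative zero crossings of the
200-kb delta vector (strength ≥ 0.5), TADs tiling between boundaries,

    TAD strength = median_d [ median intra-TAD(d) / median inter-TAD(d) ],

aggregate rescaled TAD maps, and conservation labels: conserved within
40 kb of a query boundary, species-specific at ≥ 100 kb from all of them,
unanimity across species for the overall label.

**PEIs** — promoter-centered (±10 Mb) Poisson tests at 10-kb against a
domain-aware background (decay × per-bin coverage × per-TAD factor),
BH-FDR ≤ 0.001, length ≥ 20 kb, promoter–promoter pairs removed; RE/SE
annotation (>50% or >5 kb overlap), APA scores; cross-species
classification combining a two-dimensional anchor-distance judgment
`d < min(0.2·|i−j|, r2)` (r2 = 20 kb conservation / 50 kb specificity)
with a 20th-percentile enrichment judgment.

**Expression & TFs** — conserved-rank scaling of single-copy-ortholog
TPM (1000 lowest-rank-variance anchors), cross-species CV, class
contrasts with exponential correlation-decay fits; TF binding preference
(|Δ(−log10 p)| > 5), TF-pair inference (≥3 motif occurrences, TPM > 1,
direct/indirect PPI) with an exact small-n Mann–Whitney preference test;
HAR permutation and SNP Fisher enrichment.

**Synthetic data** — a multi-species generator with planted truth:
Poisson counts around
`C·(1+|i−j|)^(−α) · exp(β·s_i·s_j) · γ^[same TAD] · λ^[loop]`,
species-specific compartment flips, deleted boundaries, gained loops,
piecewise-identity homology maps with gaps, plus matched expression,
HAR/SNP, motif-hit and PPI fixtures.

## Worked example

Call and classify TAD boundaries on a synthetic three-species study
(20-Mb chromosome, 1e5 contacts per species, 20% of boundaries planted
human-specific):

```r
library(hicevo)
spec <- sim_spec(chrom_length = 2e7, depth = 1e5, beta = 0,
                 hs_boundary_frac = 0.2, seed = 2)
sim    <- simulate_species_set(spec, resolutions = 2e4)
kr     <- lapply(sim$species, function(s) kr_balance(s[["20000"]]))
bounds <- lapply(kr, function(m) call_boundaries(insulation_score(m)))

unlist(boundary_recovery(bounds$human$bin, sim$truth$boundaries_bin))
#>    recall precision
#> 0.9473684 1.0000000

labels <- classify_boundaries(bounds$human, bounds[-1], sim$maps, "chrS")
table(labels$overall)
#>             other species-conserved  species-specific
#>                 3                24                 9

tads <- classify_tads(tads_from_boundaries(bounds$human, kr$human$grid),
                      labels)
tads$strength <- vapply(seq_len(nrow(tads)), function(k)
  tad_strength(kr$human, tads$start_bin[k], tads$end_bin[k]), numeric(1))
summary(tads$strength)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   1.095   1.615   1.750   1.756   1.899   2.221
table(tads$class)
#>  Cons    HS other
#>    17    13     5
```

36 of 38 planted boundaries are recovered within ±1 bin with no false
calls; 9 boundaries classify as species-specific (the planted fraction
is 20% of 38 ≈ 8), and the median TAD strength of 1.75 reflects the
planted two-fold intra-TAD enrichment measured against neighbor regions
at matched distances. The `analysis/` directory runs the full study —
`01_simulate.R` through `06_tf_pairs.R` — writing tables under
`results/`.

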