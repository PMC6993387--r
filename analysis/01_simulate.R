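#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screen.
#
# Emulates the full data-generating process of a pooled CBS complementation
# screen: a codon-randomized clone library (Poisson mutational load, mean
# 2.65 codon changes per clone), growth selection (5.5 doublings) at low
# (0 and 1 ng/ml) and high (400 ng/ml) vitamin B6, and TileSeq-style
# sequencing at 2 million reads with wildtype control libraries. Writes the
# count table and the ground truth that later stages are scored against.

suppressMessages(library(cbsmap))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(
  orf_length_codons = 200, n_clones = 2e4, depth = 2e6,
  error_rate = 1e-6, seed = 2026
)
sim <- simulate_screen(cfg)

# oligo design for the simulated ORF (one NNK oligo per non-initiator codon)
oligos <- design_popcode_oligos(sim$library$orf)
write_oligos_fasta(oligos, "results/popcode_oligos.fasta")

write_count_table(sim$counts, "results/counts.tsv")
write.table(sim$truth, "results/truth.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

k <- tabulate(sim$library$clone_variants$clone, nbins = cfg$n_clones)
cat(sprintf(
  paste0(
    "library: %d clones, %.2f codon changes/clone (lambda %.2f), ",
    "%d distinct protein variants reachable\n"
  ),
  cfg$n_clones, mean(k), cfg$mutation_load_lambda, nrow(sim$truth)
))
cat(sprintf(
  "oligos: %d designed, lengths %d-%d nt\n",
  nrow(oligos), min(nchar(oligos$oligo)), max(nchar(oligos$oligo))
))
cat(sprintf(
  "counts: %d rows over %d conditions x %d replicates -> results/counts.tsv\n",
  nrow(sim$counts), length(unique(sim$counts$condition)), cfg$replicates
))
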