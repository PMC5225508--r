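#!/usr/bin/env Rscript
# Step 1 — simulate the study genome.
#
# Builds a multi-scaffold genome carrying a family of full-length MULE-like
# elements (145-bp TIRs, 9-bp TSDs, 9 x 12-bp subterminal repeats, a 2-exon
# DDE transposase) plus truncated nonautonomous derivatives, with 64.3% of
# insertions in genic regions, and writes FASTA/GFF3 plus the truth table
# that later steps are scored against.

suppressMessages(library(mulescan))
dir.create("results", showWarnings = FALSE)

seed <- 7
sim <- generate_genome(n_scaffolds = 3, scaffold_len = 60000,
                       n_full_copies = 4, n_derivatives = 10, n_genes = 8,
                       genic_insert_frac = 0.643, seed = seed)

write_genome(sim$genome, "results/genome.fa")
write_annotation(sim$genes, "results/genes.gff3")
write.table(sim$truth, "results/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(sim$element$seq, "results/element.txt")

cat(sprintf("Simulated %d scaffolds (%s bp) with %d full elements, %d derivatives (%d perfect-TSD), %d genes.\n",
            length(sim$genome$scaffolds),
            format(sum(sim$genome$lengths), big.mark = ","),
            sum(sim$truth$kind == "full"),
            sum(sim$truth$kind == "derivative"),
            sum(sim$truth$kind == "derivative" & sim$truth$perfect_tsd),
            nrow(sim$genes)))
cat(sprintf("Genic insertion fraction: %.3f (requested 0.643)\n",
            mean(sim$truth$genic)))
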