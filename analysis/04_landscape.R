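#!/usr/bin/env Rscript
# Stage 4: genomic landscape of the candidate loci.
#
# Intersects loci with the gene annotation (150 kb up/downstream, 10 kb
# bins), profiles sense/antisense orientation relative to host genes, tests
# selective-sweep overlap of the significant loci against a binomial
# expectation, and exports per-pattern gene lists for external ontology
# searches.

suppressMessages(library(ervsegmap))

loci <- utils::read.table("results/loci_full.tsv", header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
results <- utils::read.table("results/difftest.tsv", header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
genes <- read_gene_annotation("results/fixtures/genes.bed")
sweeps <- read_bed3("results/fixtures/sweeps.bed")
genome_size <- sum(Biostrings::width(
  Biostrings::readDNAStringSet("results/fixtures/reference.fa")))

relations <- intersect_genes(loci, genes, flank = 150000, bin_width = 10000)
profile <- orientation_profile(relations, bin_width = 10000)
sig_loci <- loci[loci$locus_id %in% results$locus_id[results$significant], ]
sweep_res <- sweep_overlap_test(sig_loci, sweeps, genome_size)
summary <- pattern_summary(results, relations)

utils::write.table(relations, "results/gene_relations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(profile$intergenic, "results/orientation_profile.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(summary$table, "results/summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
list_paths <- export_gene_lists(relations, results, "results/gene_lists")

cat("locus-gene relations (<=150 kb):", nrow(relations), "\n")
cat("  intragenic / upstream / downstream:",
    paste(table(factor(relations$relation,
                       c("intragenic", "upstream", "downstream"))),
          collapse = " / "), "\n")
cat(sprintf("intragenic antisense fraction: %.3f (binomial p vs 0.5: %.3g)\n",
            profile$intragenic$antisense_fraction,
            profile$intragenic$p_value))
cat(sprintf("sweep overlap: %d of %d significant loci in %.1f%% of genome (p = %.3g)\n",
            sweep_res$k, sweep_res$n, 100 * sweep_res$sweep_fraction,
            sweep_res$p_value))
tot <- summary$totals
cat(sprintf("significant loci near genes: %d ERVs adjacent to %d genes\n",
            tot["ervs_adjacent_genes"], tot["genes_adjacent_ervs"]))
cat("gene lists for ontology tools written to results/gene_lists/\n")
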