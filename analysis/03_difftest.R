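#!/usr/bin/env Rscript
# Stage 3: per-locus differential presence testing.
#
# Each candidate locus's per-line read support is tested against the
# line-wide ERV-host pair totals (Freeman-Halton exact test below 15 reads,
# Pearson chi-square otherwise), Bonferroni-corrected at alpha = 0.05,
# classified into presence patterns, and polarized into gains/losses on the
# ((H,L),W) line tree with the reference assembly as outgroup.

suppressMessages(library(ervsegmap))

loci <- utils::read.table("results/loci_full.tsv", header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
records <- read_alignments(Sys.glob("results/fixtures/alignments_*.tsv"))
anchored <- records[records$erv_score >= 400 & records$mate_anchor_score >= 1, ]
line_totals <- c(H = sum(anchored$line_id == "H"),
                 L = sum(anchored$line_id == "L"),
                 W = sum(anchored$line_id == "W"))

# reference-assembly status from the simulated truth (known here; on real
# data this comes from the reference ERV annotation)
truth_bed <- utils::read.table("results/fixtures/truth.bed", sep = "\t")
truth <- data.frame(insertion_id = truth_bed$V4, chrom = truth_bed$V1,
                    position = truth_bed$V2, erv_span = truth_bed$V3 - truth_bed$V2,
                    in_reference = truth_bed$V3 - truth_bed$V2 > 1,
                    stringsAsFactors = FALSE)
loci <- match_truth(loci, truth)

tests <- test_loci(loci, line_totals, fisher_cutoff = 15)
results <- classify_results(tests, line_totals, in_reference = loci$in_reference)
summary <- pattern_summary(results)

utils::write.table(results, "results/difftest.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(summary$table, "results/summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(as.list(summary$venn), "results/venn.json",
                     auto_unbox = TRUE)

thr <- attr(results, "threshold")
cat("line-wide ERV-host pair totals:",
    paste(names(line_totals), line_totals, collapse = ", "), "\n")
cat(sprintf("loci tested: %d; Bonferroni threshold %.3g (reported %.0e)\n",
            nrow(results), as.numeric(thr), attr(thr, "rounded")))
cat("test dispatch:", sum(results$test == "fisher"), "exact,",
    sum(results$test == "chisq"), "chi-square\n")
cat("corrected-significant loci:", sum(results$significant), "\n")
cat("\nper-pattern summary (candidate / corrected):\n")
with(summary$table, cat(sprintf("  %s %5d %6s\n", pattern, candidate_loci,
                                ifelse(is.na(corrected_loci), "nd",
                                       corrected_loci)), sep = ""))
tot <- summary$totals
cat(sprintf("differential candidates: %d of %d (%.0f%%)\n",
            tot["differential_loci"], tot["candidate_loci"],
            100 * tot["nominal_difference_fraction"]))
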