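mk_loci <- function(start, end, chrom = "chr1", orientation = "+") {
  data.frame(locus_id = sprintf("L%03d", seq_along(start)), chrom = chrom,
             start = start, end = end, orientation = orientation,
             stringsAsFactors = FALSE)
}
mk_genes <- function(start, end, strand = "+", chrom = "chr1") {
  data.frame(gene_id = sprintf("G%03d", seq_along(start)), chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("gene intersection classifies position, strandedness and distance", {
  genes <- mk_genes(500000, 520000, strand = "+")
  # inside the transcript: intragenic, distance 0
  r <- intersect_genes(mk_loci(505000, 506000), genes)
  expect_equal(r$relation, "intragenic")
  expect_equal(r$distance, 0)
  expect_equal(r$relative_orientation, "sense")
  # left of a + gene: upstream; right: downstream
  r <- intersect_genes(mk_loci(c(400000, 600000), c(401000, 601000),
                               orientation = "-"), genes)
  expect_equal(r$relation, c("upstream", "downstream"))
  expect_equal(r$distance, c(99000, 80000))
  expect_equal(r$relative_orientation, c("antisense", "antisense"))
  expect_equal(r$distance_bin, c(9L, 8L))
  # same geometry against a - gene flips the sides
  r <- intersect_genes(mk_loci(c(400000, 600000), c(401000, 601000)),
                       mk_genes(500000, 520000, strand = "-"))
  expect_equal(r$relation, c("downstream", "upstream"))
})

test_that("the 150 kb flank boundary is inclusive at exactly 150,000", {
  genes <- mk_genes(1000000, 1010000)
  at <- intersect_genes(mk_loci(1000000 - 150000 - 1000, 1000000 - 150000),
                        genes)
  expect_equal(nrow(at), 1)
  expect_equal(at$distance, 150000)
  over <- intersect_genes(mk_loci(1000000 - 150001 - 1000, 1000000 - 150001),
                          genes)
  expect_equal(nrow(over), 0)
})

test_that("relations equal a quadratic all-pairs scan on random intervals", {
  set.seed(33)
  for (rep in 1:5) {
    nl <- sample(20:50, 1); ng <- sample(20:50, 1)
    loci <- mk_loci(start = sample.int(2e6, nl),
                    end = 0, chrom = sample(c("chr1", "chr2"), nl, TRUE),
                    orientation = sample(c("+", "-"), nl, TRUE))
    loci$end <- loci$start + sample(100:5000, nl, TRUE)
    genes <- mk_genes(start = sample.int(2e6, ng), end = 0,
                      strand = sample(c("+", "-"), ng, TRUE),
                      chrom = sample(c("chr1", "chr2"), ng, TRUE))
    genes$end <- genes$start + sample(1000:20000, ng, TRUE)
    got <- intersect_genes(loci, genes)
    want <- oracle_relations(loci, genes)
    key <- function(d) sort(paste(d$locus_id, d$gene_id, d$relation, d$distance))
    expect_equal(key(got), key(want))
  }
})

test_that("relations are invariant under a constant coordinate shift", {
  set.seed(34)
  loci <- mk_loci(start = sample.int(1e6, 20), end = 0)
  loci$end <- loci$start + 1000
  genes <- mk_genes(start = sample.int(1e6, 20), end = 0)
  genes$end <- genes$start + 5000
  r1 <- intersect_genes(loci, genes)
  shift <- 12345
  loci2 <- transform(loci, start = start + shift, end = end + shift)
  genes2 <- transform(genes, start = start + shift, end = end + shift)
  r2 <- intersect_genes(loci2, genes2)
  expect_equal(r1, r2)
})

test_that("orientation profile conserves bins and tests the intragenic bias", {
  rel <- data.frame(
    locus_id = sprintf("L%02d", 1:8), gene_id = sprintf("G%02d", 1:8),
    relation = c("intragenic", "intragenic", "intragenic", "upstream",
                 "upstream", "downstream", "downstream", "downstream"),
    distance = c(0, 0, 0, 5000, 15000, 2000, 2500, 149000),
    relative_orientation = c("antisense", "antisense", "sense", "sense",
                             "antisense", "sense", "sense", "antisense"),
    distance_bin = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 14L),
    stringsAsFactors = FALSE)
  prof <- orientation_profile(rel)
  expect_equal(sum(prof$intergenic$n_sense + prof$intergenic$n_antisense),
               sum(rel$relation != "intragenic"))
  expect_equal(prof$intragenic$n_antisense, 2L)
  expect_equal(prof$intragenic$antisense_fraction, 2 / 3)
  expect_equal(prof$intragenic$p_value,
               stats::binom.test(2, 3, 0.5)$p.value)
  # forced all-antisense intragenic set
  rel2 <- rel[rel$relation == "intragenic", ]
  rel2$relative_orientation <- "antisense"
  expect_equal(orientation_profile(rel2)$intragenic$antisense_fraction, 1)
  # empty relations -> empty profile
  p0 <- orientation_profile(rel[0, ])
  expect_equal(nrow(p0$intergenic), 0)
  expect_true(is.na(p0$intragenic$p_value))
})

test_that("unbiased intragenic orientations stay inside the binomial 99% CI", {
  # simulation with no orientation preference: antisense fraction ~ Bin(n, .5)
  cfg <- sim_config(seed = 41, n_chromosomes = 4, chromosome_length = 3e6,
                    n_insertions = 300, n_genes = 700,
                    allele_freq_model = list(type = "point",
                                             values = c(0.9, 0.9, 0.9)))
  sim <- simulate_truth(cfg)
  ann <- simulate_annotation(sim)
  loci <- data.frame(locus_id = sim$truth$insertion_id,
                     chrom = sim$truth$chrom, start = sim$truth$position,
                     end = sim$truth$position + 1L,
                     orientation = sim$truth$orientation,
                     stringsAsFactors = FALSE)
  prof <- orientation_profile(intersect_genes(loci, ann$genes))
  n <- prof$intragenic$n_sense + prof$intragenic$n_antisense
  expect_gte(n, 30)
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(prof$intragenic$antisense_fraction, ci[1])
  expect_lte(prof$intragenic$antisense_fraction, ci[2])
})

test_that("sweep overlap follows binomial moments and handles edge fractions", {
  genome <- 1e7
  sweeps <- data.frame(chrom = "chr1", start = 0, end = 1e6)  # 10%
  set.seed(51)
  n <- 369
  loci <- mk_loci(start = sample.int(genome - 1000, n), end = 0)
  loci$end <- loci$start + 1000
  res <- sweep_overlap_test(loci, sweeps, genome)
  expect_equal(res$n, n)
  expect_equal(res$expected, 36.9)
  expect_lt(abs(res$k - 36.9), 3 * sqrt(n * 0.1 * 0.9))
  expect_gt(res$p_value, 0.001)
  # degenerate sweep fractions
  none <- sweep_overlap_test(loci, sweeps[0, ], genome)
  expect_equal(none$k, 0L)
  expect_equal(none$p_value, 1)
  all_sw <- sweep_overlap_test(loci, data.frame(chrom = "chr1", start = 0,
                                                end = genome), genome)
  expect_equal(all_sw$k, n)
  expect_equal(all_sw$p_value, 1)
  expect_error(sweep_overlap_test(loci, sweeps, 0))
})

test_that("gene lists are de-duplicated per pattern and match the summary", {
  results <- data.frame(locus_id = c("L1", "L2", "L3"),
                        pattern = c("H--", "H--", "-L-"),
                        significant = c(TRUE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  relations <- data.frame(locus_id = c("L1", "L2", "L2", "L3"),
                          gene_id = c("gA", "gA", "gB", "gC"),
                          stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  paths <- export_gene_lists(relations, results, d)
  h <- readLines(paths[["H--"]])
  expect_equal(h, c("gene_id", "gA", "gB"))  # gA once despite two loci
  expect_equal(readLines(paths[["-L-"]]), "gene_id")  # not significant
  s <- pattern_summary(results, relations)
  expect_equal(s$table$genes_adjacent_ervs[s$table$pattern == "H--"],
               length(h) - 1L)
})

test_that("BED12 gene annotation round-trips through the reader", {
  cfg <- sim_config(seed = 43, n_insertions = 5, emit_sequences = TRUE,
                    n_genes = 25)
  sim <- simulate_truth(cfg)
  rec <- simulate_mate_pairs(sim)
  d <- withr::local_tempdir()
  paths <- write_fixtures(sim, rec, d)
  genes <- read_gene_annotation(paths[["genes"]])
  want <- simulate_annotation(sim)$genes
  expect_equal(genes[order(genes$gene_id), c("gene_id", "chrom", "start",
                                             "end", "strand")],
               want[order(want$gene_id), ], ignore_attr = TRUE)
  sw <- read_bed3(paths[["sweeps"]])
  expect_equal(names(sw), c("chrom", "start", "end"))
})
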