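#' Intersect candidate loci with gene annotation
#'
#' Emits every (locus, gene) pair whose nearest-edge distance is at most
#' `flank` bases (default 150 kb). A locus overlapping the transcript is
#' intragenic (distance 0); otherwise it is upstream or downstream relative
#' to the gene's strand. The relative orientation compares the insertion
#' orientation to the gene strand (sense = equal). Distances fall into
#' `bin_width` bins (`floor(distance / bin_width)`). One locus may relate to
#' several genes and vice versa. In `tss_mode`, the flank window and
#' distance are anchored at the transcription start site instead of the
#' transcript edges.
#'
#' @param loci candidate loci (`chrom, start, end, orientation`, 0-based
#'   half-open; `locus_id`).
#' @param genes gene annotation (`gene_id, chrom, start, end, strand`),
#'   e.g. from [read_gene_annotation()].
#' @param flank maximum nearest-edge distance, bases (inclusive).
#' @param bin_width distance bin width, bases.
#' @param tss_mode anchor distances at the TSS rather than transcript edges.
#' @return data frame of relations: `locus_id, gene_id, relation`
#'   (intragenic/upstream/downstream), `distance`, `relative_orientation`,
#'   `distance_bin`.
#' @export
intersect_genes <- function(loci, genes, flank = 150000, bin_width = 10000,
                            tss_mode = FALSE) {
  empty <- data.frame(locus_id = character(), gene_id = character(),
                      relation = character(), distance = numeric(),
                      relative_orientation = character(),
                      distance_bin = integer(), stringsAsFactors = FALSE)
  if (nrow(loci) == 0 || nrow(genes) == 0) return(empty)
  only <- setdiff(unique(loci$chrom), unique(genes$chrom))
  if (length(only)) {
    warning("loci on chromosomes absent from the gene annotation skipped: ",
            paste(only, collapse = ", "))
  }
  gstart <- genes$start
  gend <- genes$end
  if (tss_mode) {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    gstart <- tss
    gend <- tss + 1L
  }
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, loci$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(gstart + 1L, gend))
  hits <- GenomicRanges::findOverlaps(lgr, ggr, maxgap = flank,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  li <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(lgr[li], ggr[gi], ignore.strand = TRUE)
  dist[is.na(dist)] <- 0
  keep <- dist <= flank
  li <- li[keep]; gi <- gi[keep]; dist <- dist[keep]
  overlap <- loci$start[li] < gend[gi] & loci$end[li] > gstart[gi]
  before <- loci$end[li] <= gstart[gi]          # locus left of gene
  side <- ifelse(overlap, "intragenic",
          ifelse(before == (genes$strand[gi] == "+"), "upstream",
                 "downstream"))
  dist[overlap] <- 0
  data.frame(locus_id = loci$locus_id[li], gene_id = genes$gene_id[gi],
             relation = side, distance = dist,
             relative_orientation = ifelse(
               loci$orientation[li] == genes$strand[gi], "sense", "antisense"),
             distance_bin = as.integer(dist %/% bin_width),
             stringsAsFactors = FALSE)
}

#' Orientation and distance profile of locus-gene relations
#'
#' Bins intergenic relations by distance and counts them by flank side and
#' relative orientation; intragenic relations are kept separate, with the
#' antisense fraction and a two-sided exact binomial test against 0.5
#' (insertions inside transcripts are expected antisense-biased under
#' purifying selection against splice interference, while an unbiased
#' simulation should sit at 0.5). Per-bin mean distances accompany the
#' counts.
#'
#' @param relations output of [intersect_genes()].
#' @param bin_width bin width in bases (must match the binning used).
#' @return list with `intergenic` (data frame: relation, distance_bin,
#'   n_sense, n_antisense, mean_distance), `intragenic` (list: n_sense,
#'   n_antisense, antisense_fraction, p_value) and `bin_width`.
#' @export
orientation_profile <- function(relations, bin_width = 10000) {
  intra <- relations[relations$relation == "intragenic", , drop = FALSE]
  inter <- relations[relations$relation != "intragenic", , drop = FALSE]
  n_s <- sum(intra$relative_orientation == "sense")
  n_a <- sum(intra$relative_orientation == "antisense")
  pv <- if (n_s + n_a > 0) stats::binom.test(n_a, n_s + n_a, 0.5)$p.value
        else NA_real_
  if (nrow(inter)) {
    key <- interaction(inter$relation, inter$distance_bin, drop = TRUE)
    sp <- split(seq_len(nrow(inter)), key)
    prof <- data.frame(
      relation = vapply(sp, function(ix) inter$relation[ix[1]], ""),
      distance_bin = vapply(sp, function(ix) inter$distance_bin[ix[1]], 0L),
      n_sense = vapply(sp, function(ix)
        sum(inter$relative_orientation[ix] == "sense"), 0L),
      n_antisense = vapply(sp, function(ix)
        sum(inter$relative_orientation[ix] == "antisense"), 0L),
      mean_distance = vapply(sp, function(ix) mean(inter$distance[ix]), 0),
      stringsAsFactors = FALSE)
    prof <- prof[order(prof$relation, prof$distance_bin), , drop = FALSE]
    rownames(prof) <- NULL
  } else {
    prof <- data.frame(relation = character(), distance_bin = integer(),
                       n_sense = integer(), n_antisense = integer(),
                       mean_distance = numeric(), stringsAsFactors = FALSE)
  }
  list(intergenic = prof,
       intragenic = list(n_sense = n_s, n_antisense = n_a,
                         antisense_fraction =
                           if (n_s + n_a > 0) n_a / (n_s + n_a) else NA_real_,
                         p_value = pv),
       bin_width = bin_width)
}

#' Test candidate loci for selective-sweep overlap
#'
#' Merges the sweep intervals, counts loci whose span midpoint falls inside
#' a sweep, and compares the count to a binomial expectation: under random
#' placement each locus lands in a sweep with probability equal to the
#' merged sweep fraction of the genome. Two-sided exact binomial test.
#'
#' @param loci candidate loci (`chrom, start, end`).
#' @param sweeps sweep intervals (`chrom, start, end`, 0-based half-open).
#' @param genome_size total genome size in bases.
#' @return list: `n` loci, `k` overlapping, `sweep_fraction`, `expected`,
#'   `p_value`.
#' @export
sweep_overlap_test <- function(loci, sweeps, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  sgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sweeps$chrom, IRanges::IRanges(sweeps$start + 1L, sweeps$end)))
  p0 <- min(1, sum(GenomicRanges::width(sgr)) / genome_size)
  n <- nrow(loci)
  if (n == 0) {
    return(list(n = 0L, k = 0L, sweep_fraction = p0, expected = 0,
                p_value = NA_real_))
  }
  mid <- floor((loci$start + loci$end) / 2)
  mgr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  k <- sum(GenomicRanges::countOverlaps(mgr, sgr) > 0)
  pv <- if (p0 == 0) as.numeric(k == 0) else if (p0 == 1) as.numeric(k == n)
        else stats::binom.test(k, n, p0)$p.value
  list(n = n, k = k, sweep_fraction = p0, expected = n * p0, p_value = pv)
}

#' Export per-pattern gene lists for external ontology searches
#'
#' Writes one plain-text gene-id list per presence pattern, containing the
#' genes adjacent to that pattern's Bonferroni-significant loci
#' (de-duplicated, sorted). Gene-ontology enrichment itself is performed by
#' external services on these lists.
#'
#' @param relations locus-gene relations from [intersect_genes()].
#' @param results classified results from [classify_results()].
#' @param outdir output directory.
#' @return named character vector of file paths (one per pattern).
#' @export
export_gene_lists <- function(relations, results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (p in setdiff(pattern_levels, "HLW")) {
    sel <- !is.na(results$pattern) & results$pattern == p & results$significant
    genes <- sort(unique(
      relations$gene_id[relations$locus_id %in% results$locus_id[sel]]))
    path <- file.path(outdir, sprintf("genes_%s.txt", gsub("-", "x", p)))
    writeLines(c("gene_id", genes), path)
    paths[p] <- path
  }
  paths
}

#' Read a gene annotation from BED12 or GFF3
#'
#' Imports transcripts and collapses them to gene-level extremes (one
#' interval per gene id, outermost start/end). Coordinates are returned
#' 0-based half-open.
#'
#' @param path BED or GFF3 file.
#' @return data frame: gene_id, chrom, start, end, strand.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  id <- if (!is.null(gr$name)) gr$name
        else if (!is.null(gr$gene_id)) gr$gene_id
        else if (!is.null(gr$ID)) gr$ID
        else as.character(seq_along(gr))
  df <- data.frame(gene_id = id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  sp <- split(df, df$gene_id)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1],
               stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read BED3 intervals
#'
#' @param path BED3 file (0-based half-open, no header).
#' @return data frame: chrom, start, end.
#' @export
read_bed3 <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df
}
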