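#' Simulation configuration for pooled mate-pair ERV sequencing
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults emulate pooled sequencing of three chicken lines (high-growth H,
#' low-growth L, white leghorn W): pools of 11 individuals, 50 nt x 2
#' mate-pair reads with ~3,500 nt inserts, per-line fold coverages
#' 5.53/5.19/3.37, ERV consensus lengths of 7-11 kb, and a locus composition
#' in which solo-LTRs dominate (full-length proviruses are ~1/20 of loci).
#'
#' @param seed integer seed; all downstream generation is deterministic in it.
#' @param n_chromosomes,chromosome_length number and length (bases) of host
#'   chromosomes.
#' @param n_erv_families number of ERV consensus sequences in the reference
#'   library.
#' @param erv_length_range length-2 range (bases) of full-length ERV consensi.
#' @param ltr_length LTR length in bases; solo-LTR insertions occupy this much
#'   host sequence.
#' @param n_insertions number of segregating insertions to plant.
#' @param solo_ltr_fraction,full_fraction proportions of solo-LTR and
#'   full-length forms among insertions (the remainder is truncated).
#'   Defaults keep the total:full ratio at about 20:1.
#' @param pool_size_per_line diploid individuals per pooled library.
#' @param coverage_per_line named numeric of per-line fold sequence coverage.
#' @param read_length read length in bases (each mate).
#' @param insert_mean,insert_sd mate-pair insert (gap) size model, bases;
#'   draws are Gaussian truncated to `[2*read_length, 2*insert_mean]`.
#' @param allele_freq_model list describing per-line insertion allele
#'   frequencies. `list(type = "beta", shape1, shape2, shared = FALSE)` draws
#'   Beta frequencies (independently per line, or one shared draw per locus
#'   when `shared = TRUE`); `list(type = "point", values = c(fH, fL, fW))`
#'   fixes them (or an `n_insertions x 3` matrix).
#' @param score_model list with the alignment-score scale and Beta shapes for
#'   true junction reads and noise reads; scores are emitted on the
#'   400-493 scale of the colorspace mapper.
#' @param noise_rate expected fraction of ERV-associated pairs that are
#'   mis-anchored or mis-scored chimeras.
#' @param detection_rate probability that a physically junction-spanning
#'   mate pair survives ERV-library mapping and unique mate anchoring and so
#'   appears as an alignment record (see the emission model in the vignette).
#' @param ref_fraction fraction of planted insertions also present in the
#'   reference assembly (reference vs non-reference loci).
#' @param min_spacing minimum distance between planted insertion slots;
#'   guarantees non-overlap and keeps junction windows of neighbouring loci
#'   disjoint.
#' @param n_genes,sweep_fraction size of the synthetic gene annotation and
#'   fraction of the genome covered by selective-sweep intervals.
#' @param line_ids character ids of the three pools.
#' @param emit_sequences generate actual random DNA for the reference genome
#'   and ERV library (needed only when writing FASTA fixtures).
#'
#' @return a validated list of class `erv_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 3e6,
                       n_erv_families = 20L,
                       erv_length_range = c(7000L, 11000L),
                       ltr_length = 300L,
                       n_insertions = 250L,
                       solo_ltr_fraction = 0.80,
                       full_fraction = 0.05,
                       pool_size_per_line = 11L,
                       coverage_per_line = c(H = 5.53, L = 5.19, W = 3.37),
                       read_length = 50L,
                       insert_mean = 3500L,
                       insert_sd = 350L,
                       allele_freq_model = list(type = "beta", shape1 = 0.5,
                                                shape2 = 0.5, shared = FALSE),
                       score_model = list(min = 400L, max = 493L,
                                          true = c(4, 1.5), noise = c(1.5, 4)),
                       noise_rate = 0.01,
                       detection_rate = 0.02,
                       ref_fraction = 0.3,
                       min_spacing = 30000L,
                       n_genes = 200L,
                       sweep_fraction = 0.10,
                       line_ids = c("H", "L", "W"),
                       emit_sequences = FALSE) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              n_erv_families = as.integer(n_erv_families),
              erv_length_range = erv_length_range, ltr_length = ltr_length,
              n_insertions = as.integer(n_insertions),
              solo_ltr_fraction = solo_ltr_fraction,
              full_fraction = full_fraction,
              pool_size_per_line = as.integer(pool_size_per_line),
              coverage_per_line = coverage_per_line,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              allele_freq_model = allele_freq_model,
              score_model = score_model, noise_rate = noise_rate,
              detection_rate = detection_rate, ref_fraction = ref_fraction,
              min_spacing = min_spacing, n_genes = as.integer(n_genes),
              sweep_fraction = sweep_fraction, line_ids = line_ids,
              emit_sequences = isTRUE(emit_sequences))
  stopifnot(cfg$n_chromosomes > 0, cfg$chromosome_length > 0,
            cfg$n_erv_families > 0, cfg$n_insertions >= 0,
            cfg$ltr_length > 0, length(cfg$erv_length_range) == 2,
            cfg$erv_length_range[1] <= cfg$erv_length_range[2],
            cfg$solo_ltr_fraction >= 0, cfg$solo_ltr_fraction <= 1,
            cfg$full_fraction >= 0,
            cfg$solo_ltr_fraction + cfg$full_fraction <= 1,
            cfg$pool_size_per_line > 0,
            length(cfg$coverage_per_line) == length(cfg$line_ids),
            all(cfg$coverage_per_line >= 0),
            cfg$read_length > 0, cfg$insert_mean > 2 * cfg$read_length,
            cfg$insert_sd >= 0, cfg$noise_rate >= 0, cfg$noise_rate < 1,
            cfg$detection_rate > 0, cfg$detection_rate <= 1,
            cfg$ref_fraction >= 0, cfg$ref_fraction <= 1,
            cfg$min_spacing > 0, cfg$sweep_fraction >= 0,
            cfg$sweep_fraction <= 1, length(cfg$line_ids) == 3)
  names(cfg$coverage_per_line) <- cfg$line_ids
  class(cfg) <- "erv_sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

draw_scores <- function(k, score_model, which = c("true", "noise")) {
  which <- match.arg(which)
  sh <- score_model[[which]]
  rng <- score_model$max - score_model$min
  as.integer(score_model$min + round(rng * stats::rbeta(k, sh[1], sh[2])))
}

draw_allele_freqs <- function(model, n, n_lines) {
  if (model$type == "beta") {
    if (isTRUE(model$shared)) {
      f <- stats::rbeta(n, model$shape1, model$shape2)
      matrix(rep(f, n_lines), ncol = n_lines)
    } else {
      matrix(stats::rbeta(n * n_lines, model$shape1, model$shape2),
             ncol = n_lines)
    }
  } else if (model$type == "point") {
    v <- model$values
    if (is.matrix(v)) {
      stopifnot(nrow(v) == n, ncol(v) == n_lines)
      v
    } else {
      stopifnot(length(v) == n_lines)
      matrix(rep(v, each = n), ncol = n_lines)
    }
  } else {
    stop("unknown allele_freq_model type: ", model$type)
  }
}

#' Simulate ground-truth segregating ERV insertions
#'
#' Plants non-overlapping ERV insertions (full-length, truncated, or
#' solo-LTR) on a synthetic host genome, assigns each a per-line allele
#' frequency under the configured model, and draws per-pool carrier dosages
#' binomially with `2 * pool_size_per_line` trials. A configurable subset is
#' flagged as present in the reference assembly, emulating reference vs
#' non-reference loci. `position` is the 0-based host base immediately 5' of
#' the integration point; reference-assembly insertions occupy
#' `[position, position + erv_span)` in reference coordinates.
#'
#' @param config an [sim_config()] object.
#' @return list with elements `truth` (data frame of insertions), `chrom_lengths`
#'   (named vector), `erv_library` (data frame: erv_id, length), `genome` and
#'   `erv_sequences` ([Biostrings::DNAStringSet] or NULL unless
#'   `emit_sequences`), and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "erv_sim_config"))
  set.seed(config$seed)
  chrom <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(config$chromosome_length,
                                       config$n_chromosomes), chrom)

  erv_ids <- sprintf("ERV_%03d", seq_len(config$n_erv_families))
  erv_len <- as.integer(round(stats::runif(config$n_erv_families,
                                           config$erv_length_range[1],
                                           config$erv_length_range[2])))
  erv_library <- data.frame(erv_id = erv_ids, length = erv_len,
                            stringsAsFactors = FALSE)

  # insertion slots: fixed grid with bounded jitter so that consecutive
  # insertions stay >= 20 kb apart (junction windows of neighbouring loci,
  # including full-length reference spans, cannot merge or cross-pair)
  edge <- 20000
  spacing <- config$min_spacing
  jitter_max <- max(0, spacing - 20000)
  cap <- pmax(0L, as.integer((chrom_lengths - 2 * edge) %/% spacing))
  if (sum(cap) < config$n_insertions) {
    stop("cannot place ", config$n_insertions,
         " non-overlapping insertions: capacity is ", sum(cap))
  }
  n <- config$n_insertions
  truth <- NULL
  if (n > 0) {
    slot_chrom <- rep(chrom, cap)
    slot_idx <- unlist(lapply(cap, function(k) seq_len(k) - 1L), use.names = FALSE)
    pick <- sort(sample.int(sum(cap), n))
    pos <- edge + slot_idx[pick] * spacing +
      floor(stats::runif(n, 0, jitter_max + 1))
    form <- sample(c("full", "truncated", "solo_ltr"), n, replace = TRUE,
                   prob = c(config$full_fraction,
                            1 - config$full_fraction - config$solo_ltr_fraction,
                            config$solo_ltr_fraction))
    fam <- sample.int(config$n_erv_families, n, replace = TRUE)
    span <- ifelse(form == "full", erv_len[fam],
            ifelse(form == "solo_ltr", config$ltr_length,
                   as.integer(round(stats::runif(n, config$ltr_length,
                                                 pmax(config$ltr_length + 1,
                                                      0.7 * erv_len[fam]))))))
    orientation <- sample(c("+", "-"), n, replace = TRUE)
    in_reference <- stats::runif(n) < config$ref_fraction
    af <- draw_allele_freqs(config$allele_freq_model, n, 3L)
    n2 <- 2L * config$pool_size_per_line
    dos <- matrix(stats::rbinom(3L * n, n2, as.vector(af)), ncol = 3L)
    truth <- data.frame(
      insertion_id = sprintf("INS_%05d", seq_len(n)),
      chrom = slot_chrom[pick], position = as.integer(pos),
      orientation = orientation, erv_family = erv_ids[fam], form = form,
      erv_span = as.integer(span), in_reference = in_reference,
      stringsAsFactors = FALSE)
    for (j in 1:3) {
      truth[[paste0("af_", config$line_ids[j])]] <- af[, j]
      truth[[paste0("dos_", config$line_ids[j])]] <- dos[, j]
    }
  } else {
    truth <- data.frame(insertion_id = character(), chrom = character(),
                        position = integer(), orientation = character(),
                        erv_family = character(), form = character(),
                        erv_span = integer(), in_reference = logical(),
                        stringsAsFactors = FALSE)
    for (j in 1:3) {
      truth[[paste0("af_", config$line_ids[j])]] <- numeric()
      truth[[paste0("dos_", config$line_ids[j])]] <- integer()
    }
  }

  genome <- NULL
  erv_sequences <- NULL
  if (config$emit_sequences) {
    genome <- Biostrings::DNAStringSet(vapply(chrom_lengths, random_dna, ""))
    names(genome) <- chrom
    erv_sequences <- Biostrings::DNAStringSet(vapply(erv_len, random_dna, ""))
    names(erv_sequences) <- erv_ids
  }

  list(truth = truth, chrom_lengths = chrom_lengths, erv_library = erv_library,
       genome = genome, erv_sequences = erv_sequences, config = config)
}

#' Simulate ERV-associated mate-pair alignment records
#'
#' Emits one alignment record per detected junction-spanning mate pair: the
#' ERV-side read carries a library hit (erv_id, score on the 400-493 scale,
#' orientation), the mate carries a unique chromosomal anchor (position,
#' strand). Both the 5' (upstream) and 3' (downstream) junctions of every
#' insertion are sampled per line. The expected number of detected pairs per
#' junction, per line, is
#' `dosage * coverage / (2 * pool_size) * (insert - 2 * read_length) /
#' (2 * read_length) * detection_rate`
#' (physical mate-pair coverage of a pooled haplotype times the detection
#' rate), and counts are Poisson around it. Anchor strand encodes the
#' junction side (`+` = upstream flank, `-` = downstream flank); the ERV-side
#' read orientation equals the insertion orientation. A configurable fraction
#' of noise pairs (random anchor, random ERV hit, low-score-skewed) is added.
#'
#' @param sim output of [simulate_truth()].
#' @param config optional override; defaults to `sim$config`.
#' @return data frame of alignment records, one row per mate pair, with
#'   columns `read_id, line_id, erv_id, erv_score, erv_read_orientation,
#'   mate_chrom, mate_pos, mate_strand, mate_anchor_score` plus provenance
#'   columns `source` ("junction"/"noise") and `insertion_id`.
#' @export
simulate_mate_pairs <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "erv_sim_config"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  L <- config$read_length
  n2 <- 2L * config$pool_size_per_line
  out <- vector("list", length(config$line_ids))
  for (li in seq_along(config$line_ids)) {
    line <- config$line_ids[li]
    C <- config$coverage_per_line[[line]]
    if (C <= 0 || nrow(truth) == 0) {
      out[[li]] <- empty_records()
      next
    }
    dos <- truth[[paste0("dos_", line)]]
    lam <- dos * C / n2 * (config$insert_mean - 2 * L) / (2 * L) *
      config$detection_rate
    recs <- vector("list", 2)
    for (si in 1:2) {          # 1 = upstream, 2 = downstream
      k <- stats::rpois(nrow(truth), lam)
      idx <- rep(seq_len(nrow(truth)), k)
      K <- length(idx)
      if (K == 0) { recs[[si]] <- empty_records(); next }
      ins <- pmin(pmax(stats::rnorm(K, config$insert_mean, config$insert_sd),
                       2 * L), 2 * config$insert_mean)
      d <- stats::runif(K, 0, ins - 2 * L)
      if (si == 1) {
        pos <- truth$position[idx] - d - L
        strand <- "+"
      } else {
        jd <- truth$position[idx] +
          ifelse(truth$in_reference[idx], truth$erv_span[idx], 0L)
        pos <- jd + d
        strand <- "-"
      }
      pos <- as.integer(floor(pos))
      keep <- pos >= 0 &
        pos + L <= sim$chrom_lengths[truth$chrom[idx]]
      idx <- idx[keep]; pos <- pos[keep]; K <- length(idx)
      if (K == 0) { recs[[si]] <- empty_records(); next }
      recs[[si]] <- data.frame(
        line_id = line,
        erv_id = truth$erv_family[idx],
        erv_score = draw_scores(K, config$score_model, "true"),
        erv_read_orientation = truth$orientation[idx],
        mate_chrom = truth$chrom[idx], mate_pos = pos, mate_strand = strand,
        mate_anchor_score = 1L, source = "junction",
        insertion_id = truth$insertion_id[idx], stringsAsFactors = FALSE)
    }
    rec <- rbind(recs[[1]], recs[[2]])
    n_noise <- stats::rpois(1, config$noise_rate * nrow(rec))
    if (n_noise > 0) {
      ch <- sample(names(sim$chrom_lengths), n_noise, replace = TRUE)
      noise <- data.frame(
        line_id = line,
        erv_id = sample(sim$erv_library$erv_id, n_noise, replace = TRUE),
        erv_score = draw_scores(n_noise, config$score_model, "noise"),
        erv_read_orientation = sample(c("+", "-"), n_noise, replace = TRUE),
        mate_chrom = ch,
        mate_pos = as.integer(floor(stats::runif(
          n_noise, 0, sim$chrom_lengths[ch] - L))),
        mate_strand = sample(c("+", "-"), n_noise, replace = TRUE),
        mate_anchor_score = sample(0:1, n_noise, replace = TRUE,
                                   prob = c(0.3, 0.7)),
        source = "noise", insertion_id = NA_character_,
        stringsAsFactors = FALSE)
      rec <- rbind(rec, noise)
    }
    if (nrow(rec)) {
      rec <- rec[order(rec$mate_chrom, rec$mate_pos, rec$erv_id), ]
      rec$read_id <- sprintf("%s_r%07d", line, seq_len(nrow(rec)))
    } else {
      rec$read_id <- character()
    }
    rownames(rec) <- NULL
    out[[li]] <- rec[, c("read_id", setdiff(names(rec), "read_id"))]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_records <- function() {
  data.frame(read_id = character(), line_id = character(),
             erv_id = character(), erv_score = integer(),
             erv_read_orientation = character(), mate_chrom = character(),
             mate_pos = integer(), mate_strand = character(),
             mate_anchor_score = integer(), source = character(),
             insertion_id = character(), stringsAsFactors = FALSE)
}

#' Simulate gene, sweep and reference-ERV tree annotation fixtures
#'
#' Deterministic companions to [simulate_truth()]: a synthetic gene
#' annotation (non-overlapping stranded transcripts), selective-sweep
#' intervals covering a configured fraction of each chromosome, and a random
#' phylogeny over the ERV library ids (stand-in for an inferred
#' reference-ERV tree). All are functions of the configuration seed only.
#'
#' @param sim output of [simulate_truth()].
#' @return list with `genes` (data frame: gene_id, chrom, start, end, strand;
#'   0-based half-open), `sweeps` (chrom, start, end) and `tree`
#'   ([ape::phylo] with ERV ids as tip labels).
#' @export
simulate_annotation <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 2L)
  chrom <- names(sim$chrom_lengths)
  spacing <- pmax(20000, floor(sum(sim$chrom_lengths) / max(1, config$n_genes)))
  cap <- pmax(0L, as.integer(sim$chrom_lengths %/% spacing))
  n <- min(config$n_genes, sum(cap))
  genes <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (n > 0) {
    slot_chrom <- rep(chrom, cap)
    slot_idx <- unlist(lapply(cap, function(k) seq_len(k) - 1L), use.names = FALSE)
    pick <- sort(sample.int(sum(cap), n))
    len <- as.integer(round(stats::runif(n, 2000, 15000)))
    start <- as.integer(slot_idx[pick] * spacing +
                          floor(stats::runif(n, 0, spacing - 15001)))
    genes <- data.frame(gene_id = sprintf("GENE_%04d", seq_len(n)),
                        chrom = slot_chrom[pick], start = start,
                        end = start + len,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
  }
  width <- floor(config$sweep_fraction * sim$chrom_lengths)
  sweeps <- data.frame(chrom = chrom,
                       start = as.integer(floor(stats::runif(
                         length(chrom), 0, sim$chrom_lengths - width))),
                       stringsAsFactors = FALSE)
  sweeps$end <- as.integer(sweeps$start + width)
  sweeps <- sweeps[width > 0, , drop = FALSE]

  set.seed(config$seed + 3L)
  tree <- ape::rtree(config$n_erv_families,
                     tip.label = sim$erv_library$erv_id)

  list(genes = genes, sweeps = sweeps, tree = tree)
}

#' Write simulation fixtures to disk
#'
#' Writes the reference genome FASTA, ERV library FASTA, one alignment TSV
#' per line, a ground-truth BED6, a BED12 gene annotation, BED3 sweep
#' intervals and a newick tree over the ERV library. Output is byte-identical
#' across runs with the same configuration (no timestamps). Sequence FASTAs
#' require `emit_sequences = TRUE` in the configuration.
#'
#' @param sim output of [simulate_truth()].
#' @param records output of [simulate_mate_pairs()].
#' @param outdir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
write_fixtures <- function(sim, records, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  config <- sim$config
  paths <- c()
  if (!is.null(sim$genome)) {
    paths["reference"] <- file.path(outdir, "reference.fa")
    Biostrings::writeXStringSet(sim$genome, paths["reference"])
    paths["erv_library"] <- file.path(outdir, "erv_library.fa")
    Biostrings::writeXStringSet(sim$erv_sequences, paths["erv_library"])
  }
  dialect <- c("read_id", "line_id", "erv_id", "erv_score",
               "erv_read_orientation", "mate_chrom", "mate_pos",
               "mate_strand", "mate_anchor_score")
  for (line in config$line_ids) {
    p <- file.path(outdir, sprintf("alignments_%s.tsv", line))
    utils::write.table(records[records$line_id == line, dialect],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("alignments_", line)] <- p
  }
  truth <- sim$truth
  tb <- data.frame(chrom = truth$chrom, start = truth$position,
                   end = truth$position +
                     ifelse(truth$in_reference, truth$erv_span, 1L),
                   name = truth$insertion_id,
                   score = rep(0L, nrow(truth)),
                   strand = truth$orientation)
  paths["truth"] <- file.path(outdir, "truth.bed")
  write_bed(tb, paths["truth"])

  ann <- simulate_annotation(sim)
  g <- ann$genes
  bed12 <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                      name = g$gene_id, score = 0L, strand = g$strand,
                      thickStart = g$start, thickEnd = g$end,
                      itemRgb = "0", blockCount = 1L,
                      blockSizes = paste0(g$end - g$start, ","),
                      blockStarts = "0,")
  paths["genes"] <- file.path(outdir, "genes.bed")
  write_bed(bed12, paths["genes"])
  paths["sweeps"] <- file.path(outdir, "sweeps.bed")
  write_bed(ann$sweeps, paths["sweeps"])
  paths["tree"] <- file.path(outdir, "erv_tree.nwk")
  ape::write.tree(ann$tree, file = paths["tree"])
  paths
}

write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
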