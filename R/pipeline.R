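#' Stage parameters for a full pipeline run
#'
#' Collects every analysis threshold with the study defaults: strict score
#' 425 and relaxed 400 on the 400-493 scale, 3,500 nt clustering window
#' with a 2% read footprint, <20 kb junction separation, exact-test
#' dispatch below 15 reads, alpha 0.05 with Bonferroni correction, 150 kb
#' gene flank with 10 kb bins.
#'
#' @param score_min,relaxed_min,max_window,min_footprint_frac,read_length,max_separation
#'   junction-calling thresholds, see [select_strict_pairs()],
#'   [cluster_junctions()], [pair_junctions()].
#' @param fisher_cutoff,alpha,absent_frac differential-test thresholds, see
#'   [test_locus()], [classify_results()].
#' @param flank,bin_width landscape thresholds, see [intersect_genes()].
#' @param tune_target optional candidate-locus target; when set, the strict
#'   threshold is tuned with [tune_to_target()] before clustering.
#' @return named list of parameters.
#' @export
pipeline_params <- function(score_min = 425, relaxed_min = 400,
                            max_window = 3500, min_footprint_frac = 0.02,
                            read_length = 50, max_separation = 20000,
                            fisher_cutoff = 15, alpha = 0.05,
                            absent_frac = 0.02, flank = 150000,
                            bin_width = 10000, tune_target = NULL) {
  p <- list(score_min = score_min, relaxed_min = relaxed_min,
            max_window = max_window, min_footprint_frac = min_footprint_frac,
            read_length = read_length, max_separation = max_separation,
            fisher_cutoff = fisher_cutoff, alpha = alpha,
            absent_frac = absent_frac, flank = flank, bin_width = bin_width,
            tune_target = tune_target)
  stopifnot(p$score_min > 0, p$relaxed_min > 0, p$max_window > 0,
            p$min_footprint_frac > 0, p$max_separation > 0,
            p$fisher_cutoff > 0, p$alpha > 0, p$alpha < 1, p$flank > 0,
            p$bin_width > 0)
  p
}

#' Match candidate loci to ground-truth insertions
#'
#' A locus matches a planted insertion when the insertion point (or its
#' reference span) lies within `tol` bases of the locus span. Reports the
#' match, the reference-assembly flag of the matched insertion, and the
#' worst-endpoint positional error (upstream endpoint vs the insertion
#' point; downstream endpoint vs the insertion point plus the reference
#' span for reference-assembly insertions).
#'
#' @param loci candidate loci.
#' @param truth ground-truth insertions from [simulate_truth()].
#' @param tol matching tolerance in bases (defaults to the insert size).
#' @return `loci` with added `insertion_id`, `in_reference`,
#'   `endpoint_error` columns (NA when unmatched).
#' @export
match_truth <- function(loci, truth, tol = 3500) {
  loci$insertion_id <- rep(NA_character_, nrow(loci))
  loci$in_reference <- rep(FALSE, nrow(loci))
  loci$endpoint_error <- rep(NA_real_, nrow(loci))
  if (nrow(loci) == 0 || nrow(truth) == 0) return(loci)
  tspan <- truth$position + ifelse(truth$in_reference, truth$erv_span, 0L)
  tgr <- GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(truth$position + 1L,
                                                 pmax(tspan, truth$position + 1L)))
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, loci$end))
  hits <- GenomicRanges::findOverlaps(lgr, tgr, maxgap = tol)
  if (length(hits)) {
    li <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
    err <- pmax(abs(loci$start[li] - truth$position[ti]),
                abs(loci$end[li] - tspan[ti]))
    # nearest insertion wins when several are in reach
    o <- order(li, err)
    first <- !duplicated(li[o])
    li <- li[o][first]; ti <- ti[o][first]; err <- err[o][first]
    loci$insertion_id[li] <- truth$insertion_id[ti]
    loci$in_reference[li] <- truth$in_reference[ti]
    loci$endpoint_error[li] <- err
  }
  loci
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> junction clustering -> differential testing ->
#' landscape annotation -> phylogeny association -> report as one seeded,
#' reproducible run, optionally writing fixtures, result tables and a
#' manifest under `outdir`. Per-line totals for the differential tests are
#' the per-line counts of anchored ERV-associated read pairs.
#'
#' @param config an [sim_config()]; its seed drives every stage.
#' @param params a [pipeline_params()].
#' @param outdir optional run directory; when given, fixtures (if
#'   `config$emit_sequences`), loci, results, summary and a JSON manifest
#'   are written beneath it.
#' @param write_fixture_files also write the simulation fixtures (requires
#'   `outdir`).
#' @return list with all stage outputs: `sim`, `records`, `pairs`,
#'   `clusters`, `loci`, `half_supported`, `line_totals`, `results`,
#'   `summary`, `relations`, `profile`, `sweep_test`, `assignments`,
#'   `tree_annotation`, `dispersion`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), params = pipeline_params(),
                         outdir = NULL, write_fixture_files = FALSE) {
  sim <- simulate_truth(config)
  records <- simulate_mate_pairs(sim)
  ann <- simulate_annotation(sim)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (write_fixture_files) {
    stopifnot(!is.null(outdir))
    write_fixtures(sim, records, file.path(outdir, "fixtures"))
  }

  score_min <- params$score_min
  tuned <- NULL
  if (!is.null(params$tune_target) && nrow(records) > 0) {
    tuned <- tune_to_target(records, target_loci = params$tune_target,
                            max_window = params$max_window,
                            min_footprint_frac = params$min_footprint_frac,
                            read_length = params$read_length,
                            max_separation = params$max_separation)
    score_min <- tuned$score_min
  }
  pairs <- select_strict_pairs(records, score_min = score_min)
  clusters <- cluster_junctions(pairs, max_window = params$max_window,
                                min_footprint_frac = params$min_footprint_frac,
                                read_length = params$read_length)
  paired <- pair_junctions(clusters, max_separation = params$max_separation)
  loci <- append_relaxed_reads(paired$loci, records, score_min = score_min,
                               relaxed_min = params$relaxed_min)
  anchored <- records[!is.na(records$mate_chrom) &
                        records$erv_score >= params$relaxed_min &
                        records$mate_anchor_score >= 1, , drop = FALSE]
  line_totals <- vapply(config$line_ids, function(l)
    max(1L, sum(anchored$line_id == l)), 0L)

  loci <- match_truth(loci, sim$truth, tol = params$max_window)
  tests <- test_loci(loci, line_totals, fisher_cutoff = params$fisher_cutoff)
  results <- classify_results(tests, line_totals,
                              in_reference = loci$in_reference,
                              alpha = params$alpha,
                              absent_frac = params$absent_frac)

  relations <- intersect_genes(loci, ann$genes, flank = params$flank,
                               bin_width = params$bin_width)
  summary <- pattern_summary(results, relations)
  profile <- orientation_profile(relations, bin_width = params$bin_width)
  sweep_test <- sweep_overlap_test(
    loci[results$significant[match(loci$locus_id, results$locus_id)], ,
         drop = FALSE],
    ann$sweeps, sum(sim$chrom_lengths))

  assignments <- assign_best_erv(loci, records)
  newick <- ape::write.tree(ann$tree)
  tree_annotation <- annotate_tree(newick, assignments, results)
  dispersion <- dispersion_summary(tree_annotation$tips,
                                   clade_map_from_tree(ann$tree))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ervsegmap")),
    seed = config$seed,
    params = params[!vapply(params, is.null, TRUE)],
    score_min_used = score_min,
    n_insertions = nrow(sim$truth),
    n_records = nrow(records),
    n_strict_pairs = nrow(pairs),
    n_clusters = nrow(clusters),
    n_candidate_loci = nrow(loci),
    n_half_supported = nrow(paired$half_supported),
    line_totals = as.list(line_totals),
    bonferroni_threshold = as.numeric(attr(results, "threshold")),
    totals = as.list(summary$totals),
    venn = as.list(summary$venn),
    sweep_p_value = sweep_test$p_value,
    intragenic_antisense_fraction = profile$intragenic$antisense_fraction,
    n_clades_hit = dispersion$n_clades_hit)

  if (!is.null(outdir)) {
    write_loci(loci, file.path(outdir, "loci.tsv"))
    utils::write.table(results, file.path(outdir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summary$table, file.path(outdir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(summary$venn),
                         file.path(outdir, "venn.json"), auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(tree_annotation$newick, file.path(outdir, "erv_tree_annotated.nwk"))
    export_gene_lists(relations, results, file.path(outdir, "gene_lists"))
  }

  list(sim = sim, records = records, pairs = pairs, clusters = clusters,
       loci = loci, half_supported = paired$half_supported,
       line_totals = line_totals, results = results, summary = summary,
       relations = relations, profile = profile, sweep_test = sweep_test,
       assignments = assignments, tree_annotation = tree_annotation,
       dispersion = dispersion, tuned = tuned, annotation = ann,
       manifest = manifest)
}
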