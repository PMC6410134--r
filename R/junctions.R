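#' Select strictly scored, uniquely anchored mate pairs
#'
#' Filters alignment records to pairs whose ERV-side read scores at or above
#' the strict threshold and whose mate has a top-quality unique chromosomal
#' anchor. Records with a missing anchor (unknown mate) are skipped and
#' counted. The junction side is derived from the anchor strand: a `+`
#' anchor lies in the 5' (upstream) host flank of the insertion, a `-`
#' anchor in the 3' (downstream) flank; the inferred insertion orientation
#' is the ERV-side read orientation. The four strand/side combinations are:
#'
#' | anchor strand | ERV read orientation | side       | insertion |
#' |---------------|----------------------|------------|-----------|
#' | `+`           | `+`                  | upstream   | sense     |
#' | `-`           | `+`                  | downstream | sense     |
#' | `+`           | `-`                  | upstream   | antisense |
#' | `-`           | `-`                  | downstream | antisense |
#'
#' @param records alignment records (see [simulate_mate_pairs()] for the
#'   column dialect, or [read_alignments()]).
#' @param score_min strict ERV-side score threshold (inclusive).
#' @param anchor_min minimum anchor score counted as a top/unique placement.
#' @return data frame of pairs with added `side` ("up"/"down") and
#'   `orientation` columns; attribute `n_skipped` counts records dropped for
#'   missing anchors.
#' @export
select_strict_pairs <- function(records, score_min = 425, anchor_min = 1) {
  req <- c("read_id", "line_id", "erv_id", "erv_score",
           "erv_read_orientation", "mate_chrom", "mate_pos", "mate_strand",
           "mate_anchor_score")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing record columns: ", paste(miss, collapse = ", "))
  bad <- is.na(records$mate_chrom) | is.na(records$mate_pos)
  n_skipped <- sum(bad)
  if (n_skipped) {
    message(n_skipped, " records skipped (no anchored mate)")
    records <- records[!bad, , drop = FALSE]
  }
  records <- records[!duplicated(records$read_id), , drop = FALSE]
  keep <- records$erv_score >= score_min & records$mate_anchor_score >= anchor_min
  out <- records[keep, , drop = FALSE]
  out$side <- ifelse(out$mate_strand == "+", "up", "down")
  out$orientation <- out$erv_read_orientation
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Cluster junction anchors into ERV-host junction clusters
#'
#' Single-linkage clustering of anchor reads, separately per chromosome,
#' junction side and inferred orientation: anchors whose intervals lie
#' within `max_window` of each other chain into one cluster, and chains
#' whose total interval would exceed `max_window` (the mate-pair insert
#' size, the maximum chromosomal flanking distance to the integration) are
#' split greedily left-to-right so every cluster interval spans at most
#' `max_window` bases. Clusters whose member reads cover (as a union)
#' fewer than `min_footprint_frac * max_window` bases (default 2% of
#' 3,500 = 70) are discarded. Output is sorted by coordinate and is
#' invariant to input row order.
#'
#' @param pairs output of [select_strict_pairs()].
#' @param max_window maximum cluster interval span, bases.
#' @param min_footprint_frac minimum union read footprint as a fraction of
#'   `max_window`.
#' @param read_length anchor read length, bases.
#' @return data frame of junction clusters: `cluster_id, chrom, side,
#'   orientation, start, end, footprint, n_members, erv_ids` (comma-joined,
#'   sorted unique), `members` (comma-joined read ids) and one
#'   `n_<line>` count column per line seen in the input.
#' @export
cluster_junctions <- function(pairs, max_window = 3500,
                              min_footprint_frac = 0.02, read_length = 50) {
  lines <- sort(unique(pairs$line_id))
  if (nrow(pairs) == 0) return(empty_clusters(lines))
  min_footprint <- min_footprint_frac * max_window
  o <- order(pairs$mate_chrom, pairs$side, pairs$orientation, pairs$mate_pos,
             pairs$read_id)
  p <- pairs[o, , drop = FALSE]
  key <- paste(p$mate_chrom, p$side, p$orientation, sep = "\r")
  newgrp <- c(TRUE, key[-1] != key[-length(key)])
  # chain: same group and gap to previous anchor interval <= max_window
  gap <- c(Inf, p$mate_pos[-1] - (p$mate_pos[-nrow(p)] + read_length))
  brk <- newgrp | gap > max_window
  comp <- cumsum(brk)
  # cap: within a chain, start a new cluster when the interval would exceed
  # max_window (greedy left-to-right)
  mpos <- p$mate_pos
  cl <- integer(nrow(p))
  cur <- 0L
  cur_comp <- -1L
  cur_start <- 0L
  for (i in seq_len(nrow(p))) {
    if (comp[i] != cur_comp || mpos[i] + read_length - cur_start > max_window) {
      cur <- cur + 1L
      cur_comp <- comp[i]
      cur_start <- mpos[i]
    }
    cl[i] <- cur
  }
  p$cluster <- cl
  # per-cluster summaries
  sp <- split(seq_len(nrow(p)), cl)
  ir <- IRanges::IRanges(start = p$mate_pos + 1L,
                         width = read_length)
  red <- IRanges::reduce(S4Vectors::split(ir, cl))
  footprint <- sum(IRanges::width(red))
  res <- data.frame(
    chrom = vapply(sp, function(ix) p$mate_chrom[ix[1]], ""),
    side = vapply(sp, function(ix) p$side[ix[1]], ""),
    orientation = vapply(sp, function(ix) p$orientation[ix[1]], ""),
    start = vapply(sp, function(ix) min(p$mate_pos[ix]), 0),
    end = vapply(sp, function(ix) max(p$mate_pos[ix]) + read_length, 0),
    footprint = as.integer(footprint[as.character(seq_along(sp))]),
    n_members = lengths(sp),
    erv_ids = vapply(sp, function(ix)
      paste(sort(unique(p$erv_id[ix])), collapse = ","), ""),
    members = vapply(sp, function(ix)
      paste(sort(p$read_id[ix]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  for (line in lines) {
    res[[paste0("n_", line)]] <-
      vapply(sp, function(ix) sum(p$line_id[ix] == line), 0L)
  }
  res <- res[res$footprint >= min_footprint, , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$side, res$orientation), ,
             drop = FALSE]
  if (nrow(res)) res$cluster_id <- sprintf("J%06d", seq_len(nrow(res)))
  else res$cluster_id <- character()
  rownames(res) <- NULL
  res[, c("cluster_id", setdiff(names(res), "cluster_id"))]
}

empty_clusters <- function(lines = character()) {
  res <- data.frame(cluster_id = character(), chrom = character(),
                    side = character(), orientation = character(),
                    start = numeric(), end = numeric(),
                    footprint = integer(), n_members = integer(),
                    erv_ids = character(), members = character(),
                    stringsAsFactors = FALSE)
  for (line in lines) res[[paste0("n_", line)]] <- integer()
  res
}

#' Pair upstream and downstream junction clusters into candidate loci
#'
#' Pairs one upstream with one downstream junction cluster when they lie on
#' the same chromosome, share the inferred insertion orientation, target at
#' least one common reference ERV, show evidence for both the 5' and 3'
#' flank (an upstream and a downstream cluster, with the upstream cluster
#' not to the right of the downstream one), and span fewer than
#' `max_separation` bases between outer bounds (accommodating 7-11 kb ERVs
#' plus secondary integrations). Matching is greedy nearest-first (smallest
#' span, then leftmost, then lexicographically smallest shared ERV id);
#' every cluster joins at most one locus. Unpaired clusters are returned as
#' half-supported records, reported but excluded from testing.
#'
#' @param clusters output of [cluster_junctions()].
#' @param max_separation maximum locus span, bases (exclusive bound).
#' @return list with `loci` (data frame, one row per candidate locus with
#'   per-line strict counts `n_<line>`) and `half_supported` (unpaired
#'   clusters).
#' @export
pair_junctions <- function(clusters, max_separation = 20000) {
  count_cols <- grep("^n_(?!members)", names(clusters), value = TRUE, perl = TRUE)
  up <- which(clusters$side == "up")
  dn <- which(clusters$side == "down")
  cand <- NULL
  if (length(up) && length(dn)) {
    # candidate pairs by proximity (interval join), then exact filters
    ugr <- GenomicRanges::GRanges(
      paste(clusters$chrom[up], clusters$orientation[up]),
      IRanges::IRanges(clusters$start[up] + 1L, clusters$end[up]))
    dgr <- GenomicRanges::GRanges(
      paste(clusters$chrom[dn], clusters$orientation[dn]),
      IRanges::IRanges(clusters$start[dn] + 1L, clusters$end[dn]))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(ugr, dgr, maxgap = max_separation))
    cand <- data.frame(u = up[S4Vectors::queryHits(hits)],
                       d = dn[S4Vectors::subjectHits(hits)])
    cand <- cand[clusters$start[cand$u] <= clusters$start[cand$d], ,
                 drop = FALSE]
    if (nrow(cand)) {
      cand$span <- clusters$end[cand$d] - clusters$start[cand$u]
      cand <- cand[cand$span < max_separation, , drop = FALSE]
    }
    if (nrow(cand)) {
      shared <- mapply(function(u, d) {
        s <- intersect(strsplit(clusters$erv_ids[u], ",")[[1]],
                       strsplit(clusters$erv_ids[d], ",")[[1]])
        if (length(s)) paste(sort(s), collapse = ",") else NA_character_
      }, cand$u, cand$d)
      cand$shared <- shared
      cand <- cand[!is.na(shared), , drop = FALSE]
    }
  }
  used <- logical(nrow(clusters))
  loci <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$span, clusters$start[cand$u],
                       vapply(strsplit(cand$shared, ","), `[`, "", 1)), ,
                 drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      u <- cand$u[i]; d <- cand$d[i]
      if (used[u] || used[d]) next
      used[u] <- used[d] <- TRUE
      row <- data.frame(chrom = clusters$chrom[u],
                        start = clusters$start[u], end = clusters$end[d],
                        orientation = clusters$orientation[u],
                        erv_ids = cand$shared[i],
                        up_id = clusters$cluster_id[u],
                        down_id = clusters$cluster_id[d],
                        up_start = clusters$start[u], up_end = clusters$end[u],
                        down_start = clusters$start[d],
                        down_end = clusters$end[d],
                        members = paste(clusters$members[u],
                                        clusters$members[d], sep = ","),
                        stringsAsFactors = FALSE)
      for (cc in count_cols) row[[cc]] <- clusters[[cc]][u] + clusters[[cc]][d]
      loci[[length(loci) + 1L]] <- row
    }
  }
  if (length(loci)) {
    loci <- do.call(rbind, loci)
    loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
    loci$locus_id <- sprintf("L%06d", seq_len(nrow(loci)))
    rownames(loci) <- NULL
    loci <- loci[, c("locus_id", setdiff(names(loci), "locus_id"))]
  } else {
    loci <- data.frame(locus_id = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       orientation = character(), erv_ids = character(),
                       up_id = character(), down_id = character(),
                       up_start = numeric(), up_end = numeric(),
                       down_start = numeric(), down_end = numeric(),
                       members = character(), stringsAsFactors = FALSE)
    for (cc in count_cols) loci[[cc]] <- integer()
  }
  list(loci = loci,
       half_supported = clusters[!used, , drop = FALSE])
}

#' Append relaxed-score reads to established junction clusters
#'
#' Reads scoring in `[relaxed_min, score_min)` whose anchors start inside an
#' existing cluster interval of a candidate locus, on the matching side
#' (anchor strand), with matching orientation and a consensus ERV id, are
#' appended to the per-line relaxed counts. New loci are never created and
#' strict counts are unchanged; each relaxed read counts toward at most one
#' locus.
#'
#' @param loci candidate loci from [pair_junctions()].
#' @param records full alignment record set.
#' @param score_min,relaxed_min strict and relaxed score thresholds.
#' @param anchor_min minimum top-anchor score, as in [select_strict_pairs()].
#' @return `loci` with per-line `nrel_<line>` columns (strict + appended).
#' @export
append_relaxed_reads <- function(loci, records, score_min = 425,
                                 relaxed_min = 400, anchor_min = 1) {
  count_cols <- grep("^n_", names(loci), value = TRUE)
  lines <- sub("^n_", "", count_cols)
  for (line in lines) loci[[paste0("nrel_", line)]] <- loci[[paste0("n_", line)]]
  if (nrow(loci) == 0) return(loci)
  rel <- records[!is.na(records$mate_chrom) & !is.na(records$mate_pos) &
                   records$erv_score >= relaxed_min &
                   records$erv_score < score_min &
                   records$mate_anchor_score >= anchor_min, , drop = FALSE]
  if (nrow(rel) == 0) return(loci)
  rel$side <- ifelse(rel$mate_strand == "+", "up", "down")
  erv_sets <- strsplit(loci$erv_ids, ",")
  # interval join of relaxed anchors (start positions) against the two
  # cluster intervals of every locus, keyed by chrom/side/orientation
  iv <- rbind(
    data.frame(locus = seq_len(nrow(loci)), side = "up",
               key = paste(loci$chrom, "up", loci$orientation),
               start = loci$up_start, end = loci$up_end),
    data.frame(locus = seq_len(nrow(loci)), side = "down",
               key = paste(loci$chrom, "down", loci$orientation),
               start = loci$down_start, end = loci$down_end))
  rkey <- paste(rel$mate_chrom, rel$side, rel$erv_read_orientation)
  lv <- unique(c(iv$key, rkey))
  igr <- GenomicRanges::GRanges(factor(iv$key, lv),
                                IRanges::IRanges(iv$start + 1L, iv$end))
  rgr <- GenomicRanges::GRanges(factor(rkey, lv),
                                IRanges::IRanges(rel$mate_pos + 1L,
                                                 rel$mate_pos + 1L))
  hits <- GenomicRanges::findOverlaps(rgr, igr)
  ri <- S4Vectors::queryHits(hits)
  li <- iv$locus[S4Vectors::subjectHits(hits)]
  ok <- mapply(function(r, l) rel$erv_id[r] %in% erv_sets[[l]], ri, li)
  if (length(ri)) { ri <- ri[ok]; li <- li[ok] }
  if (length(ri)) {
    # each relaxed read counts toward one locus only
    first <- !duplicated(ri)
    ri <- ri[first]; li <- li[first]
    inc <- table(factor(li, seq_len(nrow(loci))), rel$line_id[ri])
    for (line in colnames(inc)) {
      col <- paste0("nrel_", line)
      if (col %in% names(loci)) loci[[col]] <- loci[[col]] + as.integer(inc[, line])
    }
  }
  loci
}

#' Tune the strict score threshold toward a target locus count
#'
#' Sweeps the strict score threshold over the observed score range, runs
#' clustering and junction pairing at each value, and returns the threshold
#' whose candidate-locus count is closest to the target (ties resolved
#' toward the higher, more conservative threshold). The default target of
#' ~10,000 reflects the expected number of ERV plus solo-LTR loci given a
#' reference library of full-length ERVs and a ~1:20 full:total ratio; see
#' [default_locus_target()].
#'
#' @param records alignment records.
#' @param target_loci target number of candidate loci.
#' @param thresholds candidate thresholds; defaults to the sorted unique
#'   observed scores.
#' @param ... passed on to [cluster_junctions()] and [pair_junctions()]
#'   (`max_window`, `min_footprint_frac`, `read_length`, `max_separation`).
#' @return list with `score_min` (chosen threshold), `sweep` (data frame of
#'   threshold vs locus count) and `target_loci`.
#' @export
tune_to_target <- function(records, target_loci = 10000, thresholds = NULL,
                           ...) {
  stopifnot(target_loci > 0)
  if (nrow(records) == 0) stop("empty pair set")
  dots <- list(...)
  cl_args <- dots[intersect(names(dots),
                            c("max_window", "min_footprint_frac", "read_length"))]
  pj_args <- dots[intersect(names(dots), "max_separation")]
  if (is.null(thresholds)) thresholds <- sort(unique(records$erv_score))
  n <- vapply(thresholds, function(t) {
    pairs <- select_strict_pairs(records, score_min = t)
    cl <- do.call(cluster_junctions, c(list(pairs), cl_args))
    nrow(do.call(pair_junctions, c(list(cl), pj_args))$loci)
  }, 0L)
  dev <- abs(n - target_loci)
  best <- which(dev == min(dev))
  best <- best[which.max(thresholds[best])]
  if (max(n) < target_loci) {
    warning("target of ", target_loci, " loci not achievable; maximum is ",
            max(n), " - returning the threshold with the closest count")
  }
  list(score_min = thresholds[best],
       sweep = data.frame(score_min = thresholds, n_loci = n),
       target_loci = target_loci)
}

#' Default candidate-locus target from library size
#'
#' Expected total of ERV loci (full-length, truncated and solo-LTR) given
#' the number of full-length ERVs in the reference library and the
#' full-length:total ratio; solo-LTRs alone are about 20x more frequent
#' than full-length proviruses, so a 532-ERV library implies ~10,640 loci,
#' conventionally rounded to a working target of 10,000.
#'
#' @param n_full_ervs full-length ERVs in the library.
#' @param ratio total loci per full-length ERV.
#' @return expected locus count.
#' @export
default_locus_target <- function(n_full_ervs, ratio = 20) {
  stopifnot(n_full_ervs > 0, ratio > 0)
  n_full_ervs * ratio
}

#' Read alignment records from the TSV dialect
#'
#' @param paths one or more TSV files written by [write_fixtures()].
#' @return combined data frame of alignment records.
#' @export
read_alignments <- function(paths) {
  recs <- lapply(paths, function(p)
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Write candidate loci as BED6+ TSV
#'
#' Columns: chrom, start, end, locus_id, score (total strict support),
#' strand (insertion orientation), then per-line strict and relaxed counts
#' and the consensus ERV ids.
#'
#' @param loci candidate loci (after [append_relaxed_reads()]).
#' @param path output file.
#' @export
write_loci <- function(loci, path) {
  count_cols <- grep("^n_", names(loci), value = TRUE)
  rel_cols <- grep("^nrel_", names(loci), value = TRUE)
  score <- if (length(count_cols)) rowSums(loci[, count_cols, drop = FALSE])
           else integer(nrow(loci))
  out <- data.frame(chrom = loci$chrom, start = loci$start, end = loci$end,
                    locus_id = loci$locus_id, score = score,
                    strand = loci$orientation, stringsAsFactors = FALSE)
  out <- cbind(out, loci[, c(count_cols, rel_cols), drop = FALSE],
               erv_ids = loci$erv_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
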