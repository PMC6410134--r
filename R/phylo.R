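#' Assign each candidate locus to its best-matching reference ERV
#'
#' Per-locus support for a reference ERV is the sum of its member reads'
#' alignment scores against that ERV; the highest-support ERV wins, with
#' ties broken toward the lexicographically smaller id. The runner-up
#' margin is the score gap to the second-best ERV (or the full support when
#' only one ERV is hit); an assignment is flagged ambiguous when the margin
#' is below `min_margin` or the top support is tied.
#'
#' @param loci candidate loci with a `members` column of comma-joined read
#'   ids (from [pair_junctions()]).
#' @param records alignment records providing read scores and ERV hits.
#' @param min_margin minimum runner-up margin (score units) for an
#'   unambiguous assignment.
#' @return data frame: locus_id, best_erv_id, support, margin, n_ervs,
#'   ambiguous.
#' @export
assign_best_erv <- function(loci, records, min_margin = 0) {
  if (nrow(loci) == 0) {
    return(data.frame(locus_id = character(), best_erv_id = character(),
                      support = numeric(), margin = numeric(),
                      n_ervs = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(trimws(unlist(strsplit(loci$members, ","))), records$read_id)
  rep_id <- rep(loci$locus_id, lengths(strsplit(loci$members, ",")))
  ok <- !is.na(idx)
  idx <- idx[ok]; rep_id <- rep_id[ok]
  res <- lapply(split(idx, rep_id), function(ix) {
    sup <- tapply(records$erv_score[ix], records$erv_id[ix], sum)
    sup <- sort(sup, decreasing = TRUE)
    if (sup[1] <= 0) stop("locus with no positive ERV support")
    top <- names(sup)[sup == sup[1]]
    best <- sort(top)[1]
    margin <- if (length(sup) > 1) unname(sup[1]) -
      max(sup[names(sup) != best]) else unname(sup[1])
    data.frame(best_erv_id = best, support = unname(sup[1]), margin = margin,
               n_ervs = length(sup),
               ambiguous = margin < min_margin ||
                 (length(sup) > 1 && margin == 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$locus_id <- names(res)
  out <- out[match(intersect(loci$locus_id, out$locus_id), out$locus_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("locus_id", "best_erv_id", "support", "margin", "n_ervs",
          "ambiguous")]
}

#' Annotate a reference-ERV tree with per-line difference symbols
#'
#' Attaches the presence patterns of the loci assigned to each reference
#' ERV as a newick comment (`[&n=...,patterns=...]`) directly after the tip
#' label, leaving the rest of the newick text - topology, branch lengths,
#' unannotated tips - byte-identical to the input. A sidecar tip table is
#' returned alongside. Assignments naming tips absent from the tree are
#' collected as warnings.
#'
#' @param newick input tree: a file path or a newick string.
#' @param assignments locus-to-ERV assignments from [assign_best_erv()].
#' @param results classified per-locus results from [classify_results()];
#'   patterns of significant loci are annotated (all loci when
#'   `significant_only = FALSE`).
#' @param outfile optional path for the annotated newick.
#' @param significant_only annotate only Bonferroni-significant loci.
#' @return list: `newick` (annotated string), `tips` (data frame: tip,
#'   n_loci, patterns), `unknown_tips` (assignments naming absent tips).
#' @export
annotate_tree <- function(newick, assignments, results, outfile = NULL,
                          significant_only = TRUE) {
  txt <- if (length(newick) == 1 && file.exists(newick))
    paste(readLines(newick), collapse = "\n") else newick
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("cannot parse newick input")
  use <- results
  if (significant_only && "significant" %in% names(use)) {
    use <- use[use$significant, , drop = FALSE]
  }
  ann <- merge(assignments, use[, c("locus_id", "pattern")], by = "locus_id")
  ann <- ann[!is.na(ann$pattern), , drop = FALSE]
  unknown <- setdiff(unique(ann$best_erv_id), tree$tip.label)
  if (length(unknown)) {
    warning("assignments name tips absent from the tree: ",
            paste(unknown, collapse = ", "))
    ann <- ann[ann$best_erv_id %in% tree$tip.label, , drop = FALSE]
  }
  sp <- split(ann$pattern, ann$best_erv_id)
  tips <- data.frame(tip = names(sp), n_loci = lengths(sp),
                     patterns = vapply(sp, function(p)
                       paste(sort(p, method = "radix"), collapse = "/"), ""),
                     stringsAsFactors = FALSE)
  rownames(tips) <- NULL
  out <- txt
  for (i in seq_len(nrow(tips))) {
    lab <- tips$tip[i]
    comment <- sprintf("[&n=%d,patterns=%s]", tips$n_loci[i], tips$patterns[i])
    # tip labels are delimited by ( , on the left and : , ) on the right
    out <- gsub(paste0("(?<=[(,])", lab, "(?=[:,)])"),
                paste0(lab, comment), out, perl = TRUE)
  }
  if (!is.null(outfile)) writeLines(out, outfile)
  list(newick = out, tips = tips, unknown_tips = unknown)
}

#' Clade dispersion of annotated tips
#'
#' Summarizes how ERV-associated locus differences spread over the major
#' clades of the reference-ERV tree: per-clade counts of annotated tips,
#' the number of distinct clades hit, and a chi-square test of uniformity
#' of annotations across clades proportional to clade sizes (a significant
#' result indicates concentration inside specific retroviral clades;
#' segregating standing variation is expected to spread broadly).
#'
#' @param tips annotated tip table from [annotate_tree()].
#' @param clade_map data frame `tip, clade` assigning every tree tip to one
#'   clade; annotated tips missing from the map fall into an "unassigned"
#'   bucket.
#' @return list: `clades` (data frame: clade, n_tips, n_annotated),
#'   `n_clades_hit`, `p_value` (NA when no annotations or a single clade).
#' @export
dispersion_summary <- function(tips, clade_map) {
  clades <- sort(unique(clade_map$clade))
  size <- vapply(clades, function(cl)
    sum(clade_map$clade == cl), 0L)
  if (nrow(tips) == 0) {
    return(list(clades = data.frame(clade = clades, n_tips = size,
                                    n_annotated = 0L,
                                    stringsAsFactors = FALSE),
                n_clades_hit = 0L, p_value = NA_real_))
  }
  cl_of <- clade_map$clade[match(tips$tip, clade_map$tip)]
  cl_of[is.na(cl_of)] <- "unassigned"
  if (any(cl_of == "unassigned")) {
    clades <- c(clades, "unassigned")
    size <- c(size, sum(cl_of == "unassigned"))
  }
  n_ann <- vapply(clades, function(cl) sum(cl_of == cl), 0L)
  df <- data.frame(clade = clades, n_tips = size, n_annotated = n_ann,
                   stringsAsFactors = FALSE)
  pv <- if (sum(n_ann) > 0 && length(clades) > 1)
    suppressWarnings(stats::chisq.test(n_ann, p = size / sum(size))$p.value)
  else NA_real_
  list(clades = df, n_clades_hit = sum(n_ann > 0), p_value = pv)
}

#' Derive a major-clade map from a tree
#'
#' Assigns every tip to the maximal subtree hanging off the root (or off
#' nodes within `depth` splits of the root), a simple operational notion of
#' "major clade" for dispersion summaries.
#'
#' @param tree an [ape::phylo] object.
#' @param depth number of splits from the root defining clade roots.
#' @return data frame: tip, clade.
#' @export
clade_map_from_tree <- function(tree, depth = 2) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- root
  for (d in seq_len(depth)) {
    nodes <- unique(unlist(lapply(nodes, function(nd)
      tree$edge[tree$edge[, 1] == nd, 2])))
  }
  assign_tips <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    unlist(lapply(kids, assign_tips))
  }
  out <- do.call(rbind, lapply(seq_along(nodes), function(i)
    data.frame(tip = assign_tips(nodes[i]), clade = sprintf("clade_%02d", i),
               stringsAsFactors = FALSE)))
  out[match(tree$tip.label, out$tip), , drop = FALSE]
}
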