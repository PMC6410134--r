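#' Freeman-Halton exact test for a 2 x 3 contingency table
#'
#' Exact conditional test of independence for a 2 x 3 table, by full
#' enumeration of all tables with the observed margins under the
#' multivariate hypergeometric null. The p-value is the total probability
#' of tables no more probable than the observed one (two-sided by
#' probability ordering, the Freeman-Halton extension of Fisher's exact
#' test).
#'
#' @param tab 2 x 3 integer matrix (rows: locus reads / remaining reads;
#'   columns: lines).
#' @return p-value.
#' @export
freeman_halton_2x3 <- function(tab) {
  stopifnot(is.matrix(tab), nrow(tab) == 2, ncol(tab) == 3, all(tab >= 0))
  r1 <- sum(tab[1, ])
  cs <- colSums(tab)
  N <- sum(tab)
  if (r1 == 0 || r1 == N) return(1)
  # enumerate free cells (a1, a2); a3 = r1 - a1 - a2 must fit column 3
  a1 <- 0:min(r1, cs[1])
  a2 <- 0:min(r1, cs[2])
  g <- expand.grid(a1 = a1, a2 = a2)
  a3 <- r1 - g$a1 - g$a2
  ok <- a3 >= 0 & a3 <= cs[3]
  g <- g[ok, ]; a3 <- a3[ok]
  logp <- lchoose(cs[1], g$a1) + lchoose(cs[2], g$a2) + lchoose(cs[3], a3) -
    lchoose(N, r1)
  obs <- lchoose(cs[1], tab[1, 1]) + lchoose(cs[2], tab[1, 2]) +
    lchoose(cs[3], tab[1, 3]) - lchoose(N, r1)
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  min(1, p)
}

#' Test one candidate locus for differential presence across lines
#'
#' Builds the 2 x 3 contingency table of locus-supporting read counts versus
#' the remaining line-wide ERV-host read pairs and tests for read-mapping
#' differences across the three lines. When the minimum observed locus count
#' is below `fisher_cutoff` (default 15) the Freeman-Halton exact test is
#' used; otherwise the Pearson chi-square statistic (df = 2, expected counts
#' proportional to the line totals, upper tail). Conditioning on line totals
#' absorbs the per-line coverage imbalance. All-zero locus counts return
#' p = 1 by convention (no evidence).
#'
#' @param counts length-3 locus read counts (H, L, W).
#' @param line_totals length-3 line-wide ERV-host read-pair totals.
#' @param fisher_cutoff minimum-count boundary of the exact-test dispatch;
#'   a minimum count equal to the cutoff uses chi-square.
#' @return list with `p_value` and `test` ("fisher", "chisq" or "none").
#' @export
test_locus <- function(counts, line_totals, fisher_cutoff = 15) {
  stopifnot(length(counts) == 3, length(line_totals) == 3,
            all(counts >= 0), all(line_totals > 0),
            all(counts <= line_totals))
  if (all(counts == 0)) return(list(p_value = 1, test = "none"))
  tab <- rbind(counts, line_totals - counts)
  if (min(counts) < fisher_cutoff) {
    list(p_value = freeman_halton_2x3(tab), test = "fisher")
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    list(p_value = p, test = "chisq")
  }
}

#' Test all candidate loci
#'
#' Applies [test_locus()] to every locus. In `mode = "normalized"` the locus
#' counts are first rescaled to a common line total (the mean of
#' `line_totals`), removing the coverage imbalance from the counts
#' themselves rather than through the contingency margins.
#'
#' @param loci candidate loci with per-line count columns.
#' @param line_totals named length-3 vector of per-line ERV-host read-pair
#'   totals.
#' @param fisher_cutoff exact-test dispatch boundary.
#' @param use_relaxed use relaxed (`nrel_`) counts when present.
#' @param mode "raw" (condition on observed totals) or "normalized".
#' @return data frame: locus_id, per-line counts, min_count, test, p_value.
#' @export
test_loci <- function(loci, line_totals, fisher_cutoff = 15,
                      use_relaxed = TRUE, mode = c("raw", "normalized")) {
  mode <- match.arg(mode)
  lines <- names(line_totals)
  stopifnot(length(lines) == 3)
  prefix <- if (use_relaxed && all(paste0("nrel_", lines) %in% names(loci)))
    "nrel_" else "n_"
  cols <- paste0(prefix, lines)
  miss <- setdiff(cols, names(loci))
  for (m in miss) loci[[m]] <- rep(0L, nrow(loci))
  cnt <- as.matrix(loci[, paste0(prefix, lines), drop = FALSE])
  totals <- line_totals
  if (mode == "normalized") {
    m <- mean(line_totals)
    cnt <- round(sweep(cnt, 2, m / line_totals, `*`))
    totals <- stats::setNames(rep(round(m), 3), lines)
  }
  res <- lapply(seq_len(nrow(loci)), function(i)
    test_locus(cnt[i, ], totals, fisher_cutoff))
  data.frame(locus_id = loci$locus_id,
             count_H = cnt[, 1], count_L = cnt[, 2], count_W = cnt[, 3],
             min_count = if (nrow(loci)) apply(cnt, 1, min) else integer(),
             test = vapply(res, `[[`, "", "test"),
             p_value = vapply(res, `[[`, 0, "p_value"),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise threshold `alpha / m` for `m` tested loci. With the study's
#' 12,709 candidate loci and alpha = 0.05 this is 3.93e-06, conventionally
#' reported to one significant figure as 4e-06.
#'
#' @param m number of tests.
#' @param alpha family-wise error rate.
#' @return the threshold, with attribute `rounded` at one significant figure.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a positive count")
  stopifnot(alpha > 0, alpha < 1)
  thr <- alpha / m
  attr(thr, "rounded") <- signif(thr, 1)
  thr
}

#' Classify the presence pattern of a locus across lines
#'
#' Calls each line present or absent and maps the result to one of the
#' seven non-empty presence patterns `H--, -L-, --W, HL-, H-W, -LW, HLW`
#' (ASCII form of the H(dot)(dot)-style row labels; a letter marks
#' presence). A line is called absent when its count does not exceed
#' `max(1, floor(absent_frac * expected))`, where `expected` is the
#' coverage-scaled expectation `line_total * sum(counts) / sum(line_totals)`
#' -- "near-absence" tolerates stray reads proportional to depth. Loci
#' absent everywhere return `NA` (excluded).
#'
#' @param counts length-3 locus counts (H, L, W).
#' @param line_totals length-3 line totals.
#' @param absent_frac near-absence tolerance as a fraction of expectation.
#' @return pattern string, or NA if no line is present.
#' @export
classify_pattern <- function(counts, line_totals, absent_frac = 0.02) {
  stopifnot(length(counts) == 3, length(line_totals) == 3)
  expected <- line_totals * sum(counts) / sum(line_totals)
  thr <- pmax(1, floor(absent_frac * expected))
  present <- counts > thr
  if (!any(present)) return(NA_character_)
  paste0(ifelse(present[1], "H", "-"), ifelse(present[2], "L", "-"),
         ifelse(present[3], "W", "-"))
}

pattern_levels <- c("H--", "-L-", "--W", "HL-", "H-W", "-LW", "HLW")

# minimal gain/loss event sets on the population tree ((H,L),W) with the
# reference assembly as outgroup; branches: H, L, W terminal, HL internal,
# HLW stem. Non-reference loci start absent (gain events, losses allowed
# after a gain); reference loci start present (loss events only).
polarity_table <- list(
  nonref = list(
    "H--" = list(polarity = "gain", resolutions = list(c("gain:H"))),
    "-L-" = list(polarity = "gain", resolutions = list(c("gain:L"))),
    "--W" = list(polarity = "gain", resolutions = list(c("gain:W"))),
    "HL-" = list(polarity = "gain", resolutions = list(c("gain:HL"))),
    "HLW" = list(polarity = "gain", resolutions = list(c("gain:HLW"))),
    "H-W" = list(polarity = "ambiguous",
                 resolutions = list(c("gain:H", "gain:W"),
                                    c("gain:HLW", "loss:L"))),
    "-LW" = list(polarity = "ambiguous",
                 resolutions = list(c("gain:HLW", "loss:H"),
                                    c("gain:L", "gain:W")))),
  ref = list(
    "HLW" = list(polarity = "none", resolutions = list(character())),
    "HL-" = list(polarity = "loss", resolutions = list(c("loss:W"))),
    "H-W" = list(polarity = "loss", resolutions = list(c("loss:L"))),
    "-LW" = list(polarity = "loss", resolutions = list(c("loss:H"))),
    "--W" = list(polarity = "loss", resolutions = list(c("loss:HL"))),
    "H--" = list(polarity = "ambiguous",
                 resolutions = list(c("loss:L", "loss:W"))),
    "-L-" = list(polarity = "ambiguous",
                 resolutions = list(c("loss:H", "loss:W")))))

#' Polarize a presence pattern into gains or losses on the line tree
#'
#' Maps a presence pattern to the minimal set(s) of gain/loss events on the
#' population tree ((H,L),W), rooted by the reference assembly as outgroup.
#' Loci present in the reference assembly are ancestrally present, so
#' absence patterns are explained by losses; non-reference loci are
#' ancestrally absent, so presence patterns are explained by gains (with
#' subsequent losses allowed). Patterns that require more than one event
#' are flagged ambiguous and every minimal resolution is listed (e.g. a
#' non-reference `H-W` locus: independent gains on H and W, or a gain on
#' the stem followed by a loss on L).
#'
#' @param pattern pattern string as from [classify_pattern()].
#' @param in_reference is the locus present in the reference assembly?
#' @return list with `polarity` ("gain", "loss", "none" or "ambiguous"),
#'   `branches` (events of the first minimal resolution, comma-joined),
#'   `ambiguous` flag and `resolutions` (list of event vectors).
#' @export
polarize_pattern <- function(pattern, in_reference) {
  if (is.na(pattern)) {
    return(list(polarity = NA_character_, branches = NA_character_,
                ambiguous = NA, resolutions = list()))
  }
  stopifnot(pattern %in% pattern_levels)
  entry <- polarity_table[[if (in_reference) "ref" else "nonref"]][[pattern]]
  n_events <- length(entry$resolutions[[1]])
  list(polarity = entry$polarity,
       branches = paste(entry$resolutions[[1]], collapse = ","),
       ambiguous = entry$polarity == "ambiguous" || n_events > 1,
       resolutions = entry$resolutions)
}

#' Classify, test and polarize a set of tested loci
#'
#' Convenience wrapper combining [test_loci()] output with pattern
#' classification, Bonferroni significance and polarization.
#'
#' @param tests output of [test_loci()].
#' @param line_totals per-line totals used for the tests.
#' @param in_reference logical vector (per locus) or single value; whether
#'   each locus is present in the reference assembly.
#' @param alpha family-wise error rate.
#' @param absent_frac near-absence tolerance, see [classify_pattern()].
#' @return `tests` with added `pattern`, `significant`, `polarity`,
#'   `branches`, `ambiguous` columns; the Bonferroni threshold is attached
#'   as attribute `threshold` (m = number of tested loci).
#' @export
classify_results <- function(tests, line_totals, in_reference = FALSE,
                             alpha = 0.05, absent_frac = 0.02) {
  m <- nrow(tests)
  thr <- if (m >= 1) bonferroni_threshold(m, alpha) else NA_real_
  cnt <- as.matrix(tests[, c("count_H", "count_L", "count_W"), drop = FALSE])
  in_reference <- rep_len(in_reference, max(1, m))
  tests$pattern <- vapply(seq_len(m), function(i)
    classify_pattern(cnt[i, ], line_totals, absent_frac), "")
  tests$significant <- !is.na(tests$p_value) & tests$p_value < as.numeric(thr)
  pol <- lapply(seq_len(m), function(i)
    polarize_pattern(tests$pattern[i], in_reference[i]))
  tests$polarity <- vapply(pol, `[[`, "", "polarity")
  tests$branches <- vapply(pol, `[[`, "", "branches")
  tests$ambiguous <- vapply(pol, function(x) isTRUE(x$ambiguous), TRUE)
  tests$in_reference <- in_reference[seq_len(m)]
  attr(tests, "threshold") <- thr
  tests
}

#' Summarize tested loci per presence pattern
#'
#' Builds the per-pattern summary table: candidate loci, Bonferroni-corrected
#' significant loci, significant loci adjacent to genes, and distinct
#' adjacent genes, one row per presence pattern (the all-present HLW row
#' carries no differential counts, reported as NA). Totals and the
#' three-line Venn region counts are attached; see [pattern_summary_totals()].
#'
#' @param results output of [classify_results()].
#' @param relations optional locus-gene relations (from [intersect_genes()])
#'   used for the gene-adjacency columns.
#' @return list with `table` (7-row data frame), `totals` and `venn`.
#' @export
pattern_summary <- function(results, relations = NULL) {
  tab <- data.frame(pattern = pattern_levels, candidate_loci = 0L,
                    corrected_loci = NA_integer_,
                    ervs_adjacent_genes = NA_integer_,
                    genes_adjacent_ervs = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pattern_levels)) {
    p <- pattern_levels[i]
    sel <- !is.na(results$pattern) & results$pattern == p
    tab$candidate_loci[i] <- sum(sel)
    if (p != "HLW") {
      sig <- sel & results$significant
      tab$corrected_loci[i] <- sum(sig)
      if (!is.null(relations)) {
        adj <- relations[relations$locus_id %in% results$locus_id[sig], ,
                         drop = FALSE]
        tab$ervs_adjacent_genes[i] <-
          length(unique(adj$locus_id))
        tab$genes_adjacent_ervs[i] <- length(unique(adj$gene_id))
      }
    }
  }
  c(list(table = tab), pattern_summary_totals(tab))
}

#' Totals and Venn counts from a per-pattern summary table
#'
#' Reporting arithmetic over a per-pattern table (computed by
#' [pattern_summary()] or loaded from [published_locus_table()]): total
#' candidate loci over all patterns, differential candidates (all patterns
#' except the all-present HLW row), their fraction, corrected-significant
#' loci, gene-adjacent ERVs and adjacent genes, plus the three-line Venn
#' region counts implied by the patterns.
#'
#' @param tab data frame with columns `pattern, candidate_loci,
#'   corrected_loci, ervs_adjacent_genes, genes_adjacent_ervs`.
#' @return list with `totals` (named numeric) and `venn` (named counts of
#'   the 7 Venn regions).
#' @export
pattern_summary_totals <- function(tab) {
  stopifnot(all(c("pattern", "candidate_loci") %in% names(tab)))
  diff_rows <- tab$pattern != "HLW"
  totals <- c(
    candidate_loci = sum(tab$candidate_loci),
    differential_loci = sum(tab$candidate_loci[diff_rows]),
    nominal_difference_fraction =
      sum(tab$candidate_loci[diff_rows]) / sum(tab$candidate_loci),
    corrected_loci = sum(tab$corrected_loci, na.rm = TRUE),
    ervs_adjacent_genes = sum(tab$ervs_adjacent_genes, na.rm = TRUE),
    genes_adjacent_ervs = sum(tab$genes_adjacent_ervs, na.rm = TRUE))
  venn <- stats::setNames(tab$candidate_loci[match(pattern_levels,
                                                   tab$pattern)],
                          c("H", "L", "W", "HL", "HW", "LW", "HLW"))
  list(totals = totals, venn = venn)
}

#' Published per-pattern candidate locus table
#'
#' The printed per-pattern candidate ERV locus counts for the three chicken
#' lines (candidate loci, Bonferroni-corrected loci, ERVs adjacent to genes
#' within 150 kb, and adjacent genes), shipped as a plain-text table. Input
#' for the reporting arithmetic in [pattern_summary_totals()].
#'
#' @return 7-row data frame keyed by presence pattern.
#' @export
published_locus_table <- function() {
  path <- system.file("extdata", "published_locus_table.tsv",
                      package = "ervsegmap", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
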