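# shared builders for small in-code fixtures

# a minimal alignment record (one mate pair) with overridable fields
make_record <- function(read_id = "r1", line_id = "H", erv_id = "ERV_001",
                        erv_score = 450L, erv_read_orientation = "+",
                        mate_chrom = "chr1", mate_pos = 1000L,
                        mate_strand = "+", mate_anchor_score = 1L) {
  data.frame(read_id = read_id, line_id = line_id, erv_id = erv_id,
             erv_score = erv_score,
             erv_read_orientation = erv_read_orientation,
             mate_chrom = mate_chrom, mate_pos = mate_pos,
             mate_strand = mate_strand, mate_anchor_score = mate_anchor_score,
             stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# records for one planted insertion: n_up/n_down anchored pairs per line
insertion_records <- function(pos, chrom = "chr1", erv_id = "ERV_001",
                              orientation = "+", lines = c(H = 5, L = 5, W = 5),
                              score = 450L, read_length = 50L, spread = 400L,
                              prefix = "r") {
  recs <- list()
  k <- 0
  for (line in names(lines)) {
    n <- lines[[line]]
    if (n == 0) next
    off <- seq(0, spread, length.out = max(n, 2))[seq_len(n)]
    up <- make_record(read_id = sprintf("%s%s_u%03d", prefix, line, seq_len(n)),
                      line_id = line, erv_id = erv_id, erv_score = score,
                      erv_read_orientation = orientation, mate_chrom = chrom,
                      mate_pos = as.integer(pos - read_length - off),
                      mate_strand = "+")
    dn <- make_record(read_id = sprintf("%s%s_d%03d", prefix, line, seq_len(n)),
                      line_id = line, erv_id = erv_id, erv_score = score,
                      erv_read_orientation = orientation, mate_chrom = chrom,
                      mate_pos = as.integer(pos + off),
                      mate_strand = "-")
    recs[[line]] <- rbind(up, dn)
  }
  do.call(rbind, recs)
}

# brute-force transitive-closure clustering oracle: anchors (equal length)
# link when the gap between their read intervals is at most max_window;
# components spanning more than max_window are split greedily left-to-right
oracle_cluster <- function(pos, max_window = 3500, read_length = 50) {
  n <- length(pos)
  if (n == 0) return(integer())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(0, max(pos[i], pos[j]) - (min(pos[i], pos[j]) + read_length))
    if (gap <= max_window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  # split oversized components
  cl <- integer(n)
  next_id <- 0L
  for (cp in unique(comp)) {
    ix <- which(comp == cp)
    ix <- ix[order(pos[ix])]
    cur_start <- -Inf
    for (i in ix) {
      if (pos[i] + read_length - cur_start > max_window) {
        next_id <- next_id + 1L
        cur_start <- pos[i]
      }
      cl[i] <- next_id
    }
  }
  cl
}

# exact Freeman-Halton oracle by direct conditional enumeration with
# hypergeometric weights (dmultinomial over the two free cells)
oracle_fh_2x3 <- function(tab) {
  r1 <- sum(tab[1, ]); cs <- colSums(tab); N <- sum(tab)
  if (r1 == 0 || r1 == N) return(1)
  probs <- c()
  obs <- NA
  for (a1 in 0:min(r1, cs[1])) for (a2 in 0:min(r1 - a1, cs[2])) {
    a3 <- r1 - a1 - a2
    if (a3 > cs[3]) next
    pr <- exp(lchoose(cs[1], a1) + lchoose(cs[2], a2) + lchoose(cs[3], a3) -
                lchoose(N, r1))
    probs <- c(probs, pr)
    if (a1 == tab[1, 1] && a2 == tab[1, 2]) obs <- pr
  }
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# enumerate minimal gain/loss event sets on ((H,L),W) + reference outgroup
# paths from the stem to each tip; the last event on a path wins
oracle_polarize <- function(pattern, in_reference) {
  tips <- c("H", "L", "W")
  present_target <- stats::setNames(
    strsplit(pattern, "")[[1]] != "-", tips)
  paths <- list(H = c("HLW", "HL", "H"), L = c("HLW", "HL", "L"),
                W = c("HLW", "W"))
  branches <- c("H", "L", "W", "HL", "HLW")
  states <- c("none", "gain", "loss")
  best <- NULL; best_n <- Inf
  grid <- expand.grid(rep(list(states), length(branches)),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    ev <- stats::setNames(unlist(grid[r, ]), branches)
    if (in_reference && any(ev == "gain")) next
    ok <- TRUE
    for (tp in tips) {
      state <- if (in_reference) TRUE else FALSE
      for (b in paths[[tp]]) {
        if (ev[b] == "gain") state <- TRUE
        if (ev[b] == "loss") state <- FALSE
      }
      if (state != present_target[tp]) { ok <- FALSE; break }
    }
    if (!ok) next
    n <- sum(ev != "none")
    set <- if (n == 0) character(0)
           else sort(paste0(ev[ev != "none"], ":", names(ev)[ev != "none"]))
    if (n < best_n) { best <- list(set); best_n <- n }
    else if (n == best_n && !any(vapply(best, identical, TRUE, set)))
      best <- c(best, list(set))
  }
  list(n_events = best_n, resolutions = best)
}

# quadratic all-pairs locus-gene relation oracle
oracle_relations <- function(loci, genes, flank = 150000) {
  out <- list()
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(genes))) {
    if (loci$chrom[i] != genes$chrom[j]) next
    ov <- loci$start[i] < genes$end[j] && loci$end[i] > genes$start[j]
    d <- if (ov) 0 else max(genes$start[j] - loci$end[i],
                            loci$start[i] - genes$end[j])
    if (d > flank) next
    before <- loci$end[i] <= genes$start[j]
    rel <- if (ov) "intragenic"
           else if (before == (genes$strand[j] == "+")) "upstream"
           else "downstream"
    out[[length(out) + 1]] <- data.frame(
      locus_id = loci$locus_id[i], gene_id = genes$gene_id[j],
      relation = rel, distance = d, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(locus_id = character(), gene_id = character(),
                  relation = character(), distance = numeric())
}
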