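test_that("strict selection applies the score threshold inclusively", {
  recs <- make_records(
    make_record("a", erv_score = 424L),
    make_record("b", erv_score = 425L),
    make_record("c", erv_score = 493L),
    make_record("d", erv_score = 470L, mate_anchor_score = 0L))
  out <- select_strict_pairs(recs)
  expect_equal(out$read_id, c("b", "c"))
  expect_equal(out$side, c("up", "up"))
  expect_equal(nrow(select_strict_pairs(recs[0, ])), 0)
})

test_that("strict selection drops and counts records without a mate anchor", {
  recs <- make_records(make_record("a"), make_record("b"))
  recs$mate_chrom[2] <- NA
  expect_message(out <- select_strict_pairs(recs), "skipped")
  expect_equal(attr(out, "n_skipped"), 1)
  expect_equal(out$read_id, "a")
})

test_that("mixed input of N pairs with k below threshold emits N - k", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    scores <- sample(380:493, n, replace = TRUE)
    recs <- make_record(sprintf("r%02d", 1:n), erv_score = scores,
                        mate_pos = sample.int(1e6, n))
    out <- select_strict_pairs(recs)
    expect_equal(nrow(out), n - sum(scores < 425))   # brute-force count
  }
})

test_that("footprint rule keeps 70-base unions and discards lone 50-nt reads", {
  # two 50 nt anchors overlapping by 30 -> union 70 = 2% of 3500 -> kept
  recs <- make_records(make_record("a", mate_pos = 1000L),
                       make_record("b", mate_pos = 1020L))
  cl <- cluster_junctions(select_strict_pairs(recs))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$footprint, 70L)
  expect_equal(cl$n_members, 2L)
  # one lone 50 nt anchor: footprint 50 < 70 -> discarded
  cl1 <- cluster_junctions(select_strict_pairs(make_record("a")))
  expect_equal(nrow(cl1), 0)
})

test_that("anchors 4000 bases apart never share a cluster", {
  recs <- make_records(
    make_record(c("a1", "a2"), mate_pos = c(1000L, 1030L)),
    make_record(c("b1", "b2"), mate_pos = c(5000L, 5030L)))
  cl <- cluster_junctions(select_strict_pairs(recs))
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$end - cl$start <= 3500))
})

test_that("clustering equals brute-force transitive closure on small inputs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    pos <- sort(sample.int(30000, n))
    recs <- make_record(sprintf("r%03d", 1:n), mate_pos = as.integer(pos))
    cl <- cluster_junctions(select_strict_pairs(recs),
                            min_footprint_frac = 1e-9)
    got <- integer(n)
    for (i in seq_len(nrow(cl))) {
      ids <- strsplit(cl$members[i], ",")[[1]]
      got[match(ids, recs$read_id)] <- i
    }
    want <- oracle_cluster(pos)
    # same partition: equal cluster labels up to renaming
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
    expect_true(all(cl$end - cl$start <= 3500))
  }
})

test_that("cluster output is invariant to input row order", {
  set.seed(8)
  n <- 60
  recs <- make_record(sprintf("r%03d", 1:n),
                      mate_pos = sample.int(50000, n),
                      mate_strand = sample(c("+", "-"), n, TRUE),
                      erv_score = sample(400:493, n, TRUE))
  p1 <- select_strict_pairs(recs)
  p2 <- select_strict_pairs(recs[sample.int(n), ])
  c1 <- cluster_junctions(p1)
  c2 <- cluster_junctions(p2)
  rownames(c1) <- rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("per-line cluster counts conserve member pairs", {
  recs <- insertion_records(50000, lines = c(H = 4, L = 3, W = 2))
  cl <- cluster_junctions(select_strict_pairs(recs))
  expect_equal(cl$n_H + cl$n_L + cl$n_W, cl$n_members)
  expect_equal(sum(cl$n_members), nrow(recs))
})

test_that("junction pairing respects separation, orientation and shared ERV", {
  mk_cluster <- function(id, side, start, end, erv = "ERV_001", ori = "+") {
    data.frame(cluster_id = id, chrom = "chr1", side = side,
               orientation = ori, start = start, end = end, footprint = 100L,
               n_members = 2L, erv_ids = erv, members = paste0(id, "_a,", id, "_b"),
               n_H = 2L, n_L = 0L, n_W = 0L, stringsAsFactors = FALSE)
  }
  # 21 kb apart -> not paired
  cl <- rbind(mk_cluster("u", "up", 1000, 1500),
              mk_cluster("d", "down", 22100, 22600))
  expect_equal(nrow(pair_junctions(cl)$loci), 0)
  expect_equal(nrow(pair_junctions(cl)$half_supported), 2)
  # disjoint ERV target sets -> not paired
  cl <- rbind(mk_cluster("u", "up", 1000, 1500, erv = "ERV_00a"),
              mk_cluster("d", "down", 3000, 3500, erv = "ERV_00b"))
  expect_equal(nrow(pair_junctions(cl)$loci), 0)
  # opposite inferred orientations -> not paired
  cl <- rbind(mk_cluster("u", "up", 1000, 1500, ori = "+"),
              mk_cluster("d", "down", 3000, 3500, ori = "-"))
  expect_equal(nrow(pair_junctions(cl)$loci), 0)
  # compatible -> one locus with summed counts
  cl <- rbind(mk_cluster("u", "up", 1000, 1500, erv = "ERV_001,ERV_002"),
              mk_cluster("d", "down", 3000, 3500, erv = "ERV_002,ERV_003"))
  res <- pair_junctions(cl)$loci
  expect_equal(nrow(res), 1)
  expect_equal(res$erv_ids, "ERV_002")
  expect_equal(res$start, 1000)
  expect_equal(res$end, 3500)
  expect_equal(res$n_H, 4L)
})

test_that("greedy pairing is nearest-first and matches the exhaustive oracle", {
  mk <- function(id, side, start) {
    data.frame(cluster_id = id, chrom = "chr1", side = side,
               orientation = "+", start = start, end = start + 500,
               footprint = 100L, n_members = 2L, erv_ids = "ERV_001",
               members = paste0(id, "_a"), n_H = 2L, n_L = 0L, n_W = 0L,
               stringsAsFactors = FALSE)
  }
  cl <- rbind(mk("u1", "up", 10000), mk("d1", "down", 15000),
              mk("d2", "down", 18000))
  res <- pair_junctions(cl)
  expect_equal(nrow(res$loci), 1)
  expect_equal(res$loci$down_id, "d1")        # nearest downstream wins
  expect_equal(res$half_supported$cluster_id, "d2")

  # exhaustive check: over random compatible layouts, greedy nearest-first
  # equals the minimum-span assignment found by brute force over matchings
  set.seed(21)
  for (rep in 1:10) {
    nu <- sample(1:3, 1); nd <- sample(1:3, 1)
    ups <- sort(sample.int(30000, nu))
    dns <- sort(sample.int(30000, nd))
    cl <- rbind(
      do.call(rbind, lapply(seq_len(nu), function(i) mk(paste0("u", i), "up", ups[i]))),
      do.call(rbind, lapply(seq_len(nd), function(i) mk(paste0("d", i), "down", dns[i]))))
    got <- pair_junctions(cl)$loci
    # oracle: repeatedly take the globally smallest valid span
    pairs <- expand.grid(u = seq_len(nu), d = seq_len(nd))
    pairs$span <- dns[pairs$d] + 500 - ups[pairs$u]
    pairs <- pairs[ups[pairs$u] <= dns[pairs$d] & pairs$span < 20000, ]
    pairs <- pairs[order(pairs$span, ups[pairs$u]), ]
    taken_u <- c(); taken_d <- c(); want <- 0
    for (i in seq_len(nrow(pairs))) {
      if (pairs$u[i] %in% taken_u || pairs$d[i] %in% taken_d) next
      taken_u <- c(taken_u, pairs$u[i]); taken_d <- c(taken_d, pairs$d[i])
      want <- want + 1
    }
    expect_equal(nrow(got), want)
  }
})

test_that("relaxed reads append only inside cluster intervals, matching all keys", {
  recs <- insertion_records(50000, lines = c(H = 3, L = 3, W = 3))
  pairs <- select_strict_pairs(recs)
  cl <- cluster_junctions(pairs)
  loci <- pair_junctions(cl)$loci
  expect_equal(nrow(loci), 1)

  # no relaxed reads: counts_relaxed == counts
  l0 <- append_relaxed_reads(loci, recs)
  expect_equal(l0$nrel_H, l0$n_H)

  up_start <- loci$up_start; up_end <- loci$up_end
  rel_in <- make_record("relH", erv_score = 410L,
                        mate_pos = as.integer(up_end - 1L))
  rel_out <- make_record("relX", erv_score = 410L,
                         mate_pos = as.integer(up_end))  # 1 base outside
  rel_wrong_erv <- make_record("relE", erv_id = "ERV_999", erv_score = 410L,
                               mate_pos = as.integer(up_start + 1L))
  rel_strict <- make_record("relS", erv_score = 430L,
                            mate_pos = as.integer(up_start + 1L))
  l1 <- append_relaxed_reads(loci, rbind(recs, rel_in, rel_out,
                                         rel_wrong_erv, rel_strict))
  expect_equal(l1$nrel_H, loci$n_H + 1L)     # only rel_in appended
  expect_equal(l1$nrel_L, loci$n_L)
  expect_equal(l1$n_H, loci$n_H)             # strict counts untouched
})

test_that("threshold tuning is monotone and targets the locus count", {
  set.seed(31)
  # 30 insertions whose read scores span the 400-493 range
  recs <- do.call(rbind, lapply(1:30, function(i)
    insertion_records(i * 40000, lines = c(H = 4, L = 4, W = 4),
                      score = sample(400:493, 1),
                      prefix = sprintf("i%02d", i))))
  tuned <- tune_to_target(recs, target_loci = 15)
  expect_true(all(diff(tuned$sweep$n_loci) <= 0))   # non-increasing in score
  expect_equal(tuned$sweep$n_loci[tuned$sweep$score_min == tuned$score_min],
               tuned$sweep$n_loci[which.min(abs(tuned$sweep$n_loci - 15))])
  # unachievable target -> warning, closest (lowest) threshold
  expect_warning(t2 <- tune_to_target(recs, target_loci = 1000), "not achievable")
  expect_equal(t2$score_min, min(recs$erv_score))
  expect_error(tune_to_target(recs[0, ], target_loci = 10), "empty")
})

test_that("the default locus target follows the full-ERV count and 1:20 ratio", {
  expect_equal(default_locus_target(532), 10640)
  expect_error(default_locus_target(0))
})

test_that("loci are recovered with high recall and bounded positional error", {
  cfg <- sim_config(seed = 17, n_chromosomes = 3, chromosome_length = 3e6,
                    n_insertions = 150, noise_rate = 0, detection_rate = 0.06,
                    insert_sd = 0,
                    allele_freq_model = list(type = "point", values = c(1, 1, 1)))
  run <- run_pipeline(cfg)
  # >= 10 pairs per side per insertion expected, zero noise
  recall <- mean(cfg_ids <- run$sim$truth$insertion_id %in% run$loci$insertion_id)
  expect_gte(recall, 0.95)
  expect_true(all(run$loci$endpoint_error <= 3500, na.rm = TRUE))
  # partition: every strict pair in at most one cluster, cluster in one locus
  members <- unlist(strsplit(run$clusters$members, ","))
  expect_false(any(duplicated(members)))
  cl_used <- c(run$loci$up_id, run$loci$down_id)
  expect_false(any(duplicated(cl_used)))
})

test_that("locus set is invariant to shuffling input records", {
  cfg <- sim_config(seed = 23, n_insertions = 40)
  sim <- simulate_truth(cfg)
  recs <- simulate_mate_pairs(sim)
  set.seed(1)
  shuffled <- recs[sample.int(nrow(recs)), ]
  l1 <- pair_junctions(cluster_junctions(select_strict_pairs(recs)))$loci
  l2 <- pair_junctions(cluster_junctions(select_strict_pairs(shuffled)))$loci
  rownames(l1) <- rownames(l2) <- NULL
  expect_equal(l1, l2)
})
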