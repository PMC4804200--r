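mk_assigned <- function(pident, sstart, send, genome_id = "A") {
  data.frame(qseqid = sprintf("r%03d", seq_along(pident)), sseqid = genome_id,
             pident = pident, length = send - sstart + 1L, mismatch = 0L,
             gapopen = 0L, qstart = 1L, qend = send - sstart + 1L,
             sstart = sstart, send = send, evalue = 1e-40, bitscore = 200,
             strand = "+", genome_id = genome_id, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

mk_ann <- function(starts, ends, ids, seq_id = "A", clusters = NA) {
  data.frame(seq_id = seq_id, feature_kind = "gene", start = starts,
             end = ends, strand = "+", gene_id = ids,
             cluster_label = clusters, stringsAsFactors = FALSE)
}

test_that("transcripts count per gene above the strict identity threshold,
           once per overlapped gene", {
  ann <- mk_ann(c(0L, 100L, 300L), c(100L, 200L, 600L),
                c("g1", "g2", "g3"))
  # internal read intervals: [10,110) overlaps g1+g2? no: [10,110) vs g1
  # [0,100) and g2 [100,200): 1-based 11..110 overlaps both
  reads <- mk_assigned(pident = c(99, 94, 99),
                       sstart = c(11L, 301L, 451L),
                       send = c(110L, 400L, 550L))
  counts <- count_transcripts_per_gene(reads, ann)
  got <- stats::setNames(counts$mt_count, counts$gene_id)
  expect_equal(got[["g1"]], 1L)   # read 1 overlaps g1 ...
  expect_equal(got[["g2"]], 1L)   # ... and g2: counted once for each
  expect_equal(got[["g3"]], 1L)   # read 2 at pident 94 does not count
  expect_gte(sum(counts$mt_count), 3L)  # column sum can exceed read count
})

test_that("housekeeping normalization divides by the mean of recA and gyrB", {
  counts <- data.frame(genome_id = "A",
                       gene_id = c("X", "recA", "gyrB"),
                       mt_count = c(100L, 20L, 30L),
                       stringsAsFactors = FALSE)
  norm <- normalize_by_housekeeping(counts)
  expect_equal(norm$per_cell[norm$gene_id == "X"], 4)
  hk <- norm$per_cell[norm$gene_id %in% c("recA", "gyrB")]
  expect_equal(mean(hk), 1)  # forced by the definition

  zero <- counts
  zero$mt_count[2:3] <- 0L
  norm0 <- normalize_by_housekeeping(zero)
  expect_true(all(is.na(norm0$per_cell)))

  expect_error(normalize_by_housekeeping(counts, hk_gene_ids = c("recA",
                                                                 "rpoB")),
               "rpoB")
})

test_that("metagenome normalization is the depth-scaled MT/MG ratio with
           missing flags", {
  counts <- data.frame(genome_id = "A", gene_id = c("a", "b", "c"),
                       mt_count = c(100L, 0L, 50L),
                       mg_count = c(50L, 10L, 0L),
                       stringsAsFactors = FALSE)
  norm <- normalize_by_metagenome(counts, mt_depth = 1e6, mg_depth = 2e6)
  expect_equal(norm$mg_norm[1], 4)      # (1e-4)/(2.5e-5)
  expect_equal(norm$mg_norm[2], 0)      # zero MT, nonzero MG
  expect_true(is.na(norm$mg_norm[3]))   # zero MG -> missing
  expect_error(normalize_by_metagenome(counts, 0, 1), "depths")
})

test_that("normalizations are scale-equivariant", {
  set.seed(1)
  counts <- data.frame(genome_id = "A",
                       gene_id = c(sprintf("g%02d", 1:10), "recA", "gyrB"),
                       mt_count = rpois(12, 50),
                       mg_count = rpois(12, 30),
                       stringsAsFactors = FALSE)
  n1 <- normalize_by_housekeeping(counts)
  scaled <- counts
  scaled$mt_count <- counts$mt_count * 7L
  n2 <- normalize_by_housekeeping(scaled)
  expect_equal(n2$per_cell, n1$per_cell)  # per-cell invariant to MT scaling

  m1 <- normalize_by_metagenome(counts, 1e6, 2e6)
  m2 <- normalize_by_metagenome(scaled, 1e6, 2e6)
  expect_equal(m2$mg_norm, 7 * m1$mg_norm)  # mg_norm scales with MT counts
  # consistent scaling of counts and depths leaves mg_norm unchanged
  both <- counts
  both$mt_count <- counts$mt_count * 3L
  both$mg_count <- counts$mg_count * 5L
  m3 <- normalize_by_metagenome(both, 3e6, 10e6)
  expect_equal(m3$mg_norm, m1$mg_norm)
})

test_that("cluster aggregation computes relative contributions and rejects
           multi-cluster genes", {
  counts <- data.frame(genome_id = "A",
                       gene_id = c("nifH", "nifD", "atpA", "g1"),
                       mt_count = c(30L, 20L, 40L, 10L),
                       stringsAsFactors = FALSE)
  cmap <- data.frame(gene_id = c("nifH", "nifD", "atpA"),
                     cluster_label = c("nif_operon", "nif_operon",
                                       "atp_synthase"),
                     stringsAsFactors = FALSE)
  agg <- aggregate_clusters(counts, cmap)
  expect_equal(agg$transcript_count[agg$cluster_label == "nif_operon"], 50L)
  expect_equal(agg$relative_contribution[agg$cluster_label == "nif_operon"],
               50)
  expect_lte(sum(agg$relative_contribution), 100)

  only_nif <- counts
  only_nif$mt_count <- c(30L, 20L, 0L, 0L)
  agg2 <- aggregate_clusters(only_nif, cmap)
  expect_equal(
    agg2$relative_contribution[agg2$cluster_label == "nif_operon"], 100)
  expect_equal(agg2$transcript_count[agg2$cluster_label == "atp_synthase"],
               0L)

  bad <- rbind(cmap, data.frame(gene_id = "nifH", cluster_label = "PSI"))
  expect_error(aggregate_clusters(counts, bad), "more than one cluster")
})

test_that("cluster regression reproduces closed-form OLS", {
  r <- regress_clusters(c(1, 2, 3), c(1, 2, 2))
  expect_equal(r$slope, 0.5)
  expect_equal(r$intercept, 2 / 3)
  expect_equal(r$r_squared, 0.75)

  perfect <- suppressWarnings(regress_clusters(1:6, 2 * (1:6)))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$r_squared, 1)

  flat <- regress_clusters(1:6, rep(5, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)

  expect_error(regress_clusters(rep(2, 5), 1:5), "zero variance")
  expect_error(regress_clusters(1:2, 1:2), "at least 3")

  for (seed in 1:5) {
    set.seed(seed)
    x <- rpois(8, 40)
    y <- 2 * x + rnorm(8, 0, 5)
    got <- regress_clusters(x, y)
    want <- oracle_ols(x, y)
    expect_equal(got$slope, want$slope)
    expect_equal(got$intercept, want$intercept)
    expect_equal(got$r_squared, want$r_squared)
    expect_gt(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
})

test_that("simulated expression weights are recovered by per-gene counting", {
  com <- small_community(seed = 71)
  w <- default_expression_weights(com$annotations)
  n <- 20000
  sim <- simulate_reads(com, read_sim_config(
    n_reads = n, mode = "MT", expression_weights = w,
    lineage_weights = c(A = 1, B = 0), seed = 72))
  rl <- stats::setNames(rep(100L, n), sim$reads$id)
  rr <- recruit_sample(sim$truth_alignments, rl,
                       c(A = com$genome_length, B = com$genome_length),
                       masks = masks_from_annotations(com$annotations))
  ok <- rr$assigned[!rr$assigned$ambiguous & rr$assigned$genome_id == "A", ]
  counts <- count_transcripts_per_gene(
    ok, com$annotations[com$annotations$seq_id == "A", ])
  frac <- counts$mt_count / sum(counts$mt_count)
  names(frac) <- counts$gene_id
  for (g in names(w)) {
    expect_lt(abs(frac[[g]] - w[[g]]),
              3 * sqrt(w[[g]] * (1 - w[[g]]) / sum(counts$mt_count)) + 1e-9)
  }
})
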