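test_that("best hit per (read, genome) follows bitscore then identity then
           coordinates", {
  base <- toy_filter_table()$records[1, ]
  mk <- function(...) {
    r <- base
    args <- list(...)
    r[names(args)] <- args
    r
  }
  recs <- rbind(
    mk(qseqid = "r1", bitscore = 180),
    mk(qseqid = "r1", bitscore = 150),
    mk(qseqid = "r2", bitscore = 100, pident = 99),
    mk(qseqid = "r2", bitscore = 100, pident = 98),
    mk(qseqid = "r3", bitscore = 100, pident = 99, sstart = 200L, send = 299L),
    mk(qseqid = "r3", bitscore = 100, pident = 99, sstart = 100L, send = 199L),
    mk(qseqid = "r4")
  )
  best <- best_hit_per_genome(recs)
  expect_equal(nrow(best), 4L)
  expect_equal(best$bitscore[best$qseqid == "r1"], 180)
  expect_equal(best$pident[best$qseqid == "r2"], 99)
  expect_equal(best$sstart[best$qseqid == "r3"], 100L)
})

test_that("the four filter rules remove the worked six-record table down to
           two with first-fail attribution", {
  toy <- toy_filter_table()
  res <- apply_filters(toy$records, toy$read_lengths, toy$masks,
                       filter_config())
  expect_equal(sort(res$records$qseqid), c("r1", "r6"))
  expect_equal(res$log[["identity"]], 1L)
  expect_equal(res$log[["evalue"]], 1L)
  expect_equal(res$log[["coverage"]], 1L)
  expect_equal(res$log[["mask"]], 1L)
  expect_equal(res$log[["retained"]], 2L)
})

test_that("filter thresholds are inclusive and empty input yields a zero log", {
  toy <- toy_filter_table()
  r <- toy$records[1, ]
  r$pident <- 50
  r$evalue <- 1e-4
  r$qstart <- 1L
  r$qend <- 90L  # coverage exactly 0.90
  res <- apply_filters(r, toy$read_lengths, NULL, filter_config())
  expect_equal(nrow(res$records), 1L)

  res0 <- apply_filters(toy$records[0, ], toy$read_lengths, toy$masks)
  expect_equal(nrow(res0$records), 0L)
  expect_true(all(res0$log == 0L))
})

test_that("a missing read length is an error naming the read", {
  toy <- toy_filter_table()
  expect_error(apply_filters(toy$records, c(r1 = 100L), toy$masks),
               "r2")
})

test_that("the retained set does not depend on filter order", {
  cfg <- filter_config()
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    rec <- toy_filter_table()$records[rep(1, n), ]
    rec$qseqid <- sprintf("q%02d", 1:n)
    rec$pident <- runif(n, 40, 100)
    rec$evalue <- 10^runif(n, -50, -2)
    rec$qend <- sample(80:100, n, TRUE)
    rec$sstart <- sample(1:2000, n, TRUE)
    rec$send <- rec$sstart + 99L
    rl <- stats::setNames(rep(100L, n), rec$qseqid)
    masks <- data.frame(genome_id = "A", start = 1000L, end = 1100L)
    got <- apply_filters(rec, rl, masks, cfg)
    keep <- oracle_filter_keep(rec, rl, masks, cfg)
    expect_equal(sort(got$records$qseqid), sort(rec$qseqid[keep]))
    expect_equal(got$log[["retained"]], sum(keep))
  }
})

test_that("competitive assignment picks the closest-hit genome and flags
           full ties as ambiguous", {
  base <- toy_filter_table()$records[1, ]
  mk <- function(q, g, bit, pid) {
    r <- base
    r$qseqid <- q
    r$genome_id <- g
    r$bitscore <- bit
    r$pident <- pid
    r
  }
  recs <- rbind(mk("r1", "A", 180, 99), mk("r1", "B", 150, 99),
                mk("r2", "B", 120, 95),
                mk("r3", "A", 100, 97), mk("r3", "B", 100, 97),
                mk("r4", "A", 100, 98), mk("r4", "B", 100, 97))
  a <- competitive_assign(recs)
  expect_equal(a$genome_id[a$qseqid == "r1"], "A")
  expect_equal(a$genome_id[a$qseqid == "r2"], "B")
  expect_true(a$ambiguous[a$qseqid == "r3"])
  expect_true(is.na(a$genome_id[a$qseqid == "r3"]))
  expect_equal(a$genome_id[a$qseqid == "r4"], "A")  # bitscore tie -> pident
})

test_that("genome recovery unions intervals above the strict population
           threshold", {
  base <- toy_filter_table()$records[1, ]
  mk <- function(pid, s, e) {
    r <- base
    r$pident <- pid
    r$sstart <- s
    r$send <- e
    r
  }
  # internal [0,50) and [40,60) -> 1-based inclusive 1..50 and 41..60
  recs <- rbind(mk(99, 1L, 50L), mk(99, 41L, 60L))
  rec <- genome_recovery(recs, 100L)
  expect_equal(rec$covered_positions, 60L)
  expect_equal(rec$recovery_pct, 60)

  expect_equal(genome_recovery(recs[0, ], 100L)$recovery_pct, 0)
  # pident exactly at the threshold is excluded (strict >)
  expect_equal(genome_recovery(mk(95, 1L, 50L), 100L)$recovery_pct, 0)
  expect_error(genome_recovery(mk(99, 50L, 101L), 100L), "outside")
})

test_that("identity histogram bins, top-bin closure and underflow sum to the
           assigned count", {
  base <- toy_filter_table()$records[1, ]
  recs <- base[rep(1, 5), ]
  recs$pident <- c(99.5, 99.2, 83.0, 100.0, 69.9)
  h <- identity_histogram(recs)
  bins <- h$bins
  expect_equal(bins$count[bins$bin_lo == 99], 3L)  # 99.5, 99.2 and 100.0
  expect_equal(bins$count[bins$bin_lo == 83], 1L)
  expect_equal(h$underflow, 1L)
  expect_equal(sum(bins$count) + h$underflow, nrow(recs))
})

test_that("competitive assignment recovers every unambiguous read's origin
           when reads are error-free", {
  com <- small_community(seed = 41)
  sim <- simulate_reads(com, read_sim_config(
    n_reads = 2000, mode = "MG", lineage_weights = c(A = 0.6, B = 0.4),
    error_rate = 0, seed = 42))
  rl <- stats::setNames(rep(100L, 2000), sim$reads$id)
  rr <- recruit_sample(sim$truth_alignments, rl,
                       c(A = com$genome_length, B = com$genome_length),
                       masks = masks_from_annotations(com$annotations))
  ok <- rr$assigned[!rr$assigned$ambiguous, ]
  tr <- sim$truth[match(ok$qseqid, sim$truth$read_id), ]
  expect_equal(mean(ok$genome_id == tr$origin_lineage), 1)
  # at error 0 the ambiguous reads are exactly those spanning no divergent
  # site
  diffs <- which(chars_differ(com$genomes$A, com$genomes$B))
  amb <- rr$assigned[rr$assigned$ambiguous, ]
  tr_amb <- sim$truth[match(amb$qseqid, sim$truth$read_id), ]
  n_div <- vapply(seq_len(nrow(tr_amb)), function(i) {
    sum(diffs > tr_amb$start[i] & diffs <= tr_amb$end[i])
  }, 0L)
  expect_true(all(n_div == 0L))
})

test_that("the naive aligner reproduces the simulator's truth alignments", {
  com <- small_community(seed = 51)
  sim <- simulate_reads(com, read_sim_config(n_reads = 300, mode = "MG",
                                             error_rate = 0, seed = 52))
  aln <- align_reads_naive(sim$reads, com$genomes, k = 13)
  tr <- sim$truth
  own <- aln[paste(aln$qseqid, aln$genome_id) %in%
               paste(tr$read_id, tr$origin_lineage), ]
  own <- own[match(tr$read_id, own$qseqid), ]
  expect_false(anyNA(own$sstart))
  expect_equal(own$sstart, tr$start + 1L)
  expect_true(all(own$pident == 100))

  # reads with errors: where a seed survives, the true diagonal is found
  sim2 <- simulate_reads(com, read_sim_config(n_reads = 300, mode = "MG",
                                              error_rate = 0.02, seed = 53))
  aln2 <- align_reads_naive(sim2$reads, com$genomes, k = 13)
  truth2 <- sim2$truth_alignments
  key <- paste(aln2$qseqid, aln2$genome_id)
  tkey <- paste(truth2$qseqid, truth2$genome_id)
  shared <- intersect(key, tkey)
  a <- aln2[match(shared, key), ]
  t2 <- truth2[match(shared, tkey), ]
  same_diag <- a$sstart == t2$sstart
  expect_gt(mean(same_diag), 0.95)
  expect_equal(a$mismatch[same_diag], t2$mismatch[same_diag])

  # random reads: no crash, rarely any hit
  set.seed(54)
  rnd <- data.frame(
    id = "rnd1",
    residues = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    stringsAsFactors = FALSE)
  expect_no_error(align_reads_naive(rnd, com$genomes, k = 13))
  expect_error(align_reads_naive(rnd, com$genomes, k = 200), "exceeds")
})
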