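test_that("genome pair divergence is zero in the degenerate case and matches
           the substitution model otherwise", {
  com0 <- simulate_genome_pair(community_config(genome_length = 20000L,
                                                n_genes = 12L,
                                                gene_length = 500L,
                                                divergence = 0, seed = 4))
  expect_identical(com0$genomes$A, com0$ancestor)
  expect_identical(com0$genomes$B, com0$ancestor)
  expect_equal(com0$divergence_realized, 0)

  # expected A-vs-B difference fraction allowing for coincident substitution:
  # 2 q (1-q) + q^2 * 2/3 with q = divergence/2
  com <- simulate_genome_pair(community_config(divergence = 0.05, seed = 11))
  q <- 0.025
  p_exp <- 2 * q * (1 - q) + q^2 * (2 / 3)
  sd_p <- sqrt(p_exp * (1 - p_exp) / com$genome_length)
  expect_lt(abs(com$divergence_realized - p_exp), 5 * sd_p)
})

test_that("simulators are bit-reproducible under a fixed seed", {
  c1 <- simulate_genome_pair(community_config(genome_length = 20000L,
                                              n_genes = 12L, seed = 9))
  c2 <- simulate_genome_pair(community_config(genome_length = 20000L,
                                              n_genes = 12L, seed = 9))
  expect_identical(c1$genomes, c2$genomes)

  cfg <- read_sim_config(n_reads = 200, mode = "MG", seed = 5)
  s1 <- simulate_reads(c1, cfg)
  s2 <- simulate_reads(c1, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth_alignments, s2$truth_alignments)

  k1 <- simulate_codon_pair(codon_sim_config(n_codons = 100, seed = 3))
  k2 <- simulate_codon_pair(codon_sim_config(n_codons = 100, seed = 3))
  expect_identical(k1$pair, k2$pair)
})

test_that("error-free reads are exact substrings with exact truth identity", {
  com <- small_community(seed = 2)
  sim <- simulate_reads(com, read_sim_config(n_reads = 100, mode = "MG",
                                             error_rate = 0, seed = 7))
  expect_true(all(sim$truth$true_identity == 100))
  for (i in sample.int(100, 10)) {
    tr <- sim$truth[i, ]
    expect_identical(
      substr(com$genomes[[tr$origin_lineage]], tr$start + 1, tr$end),
      sim$reads$residues[i])
  }
})

test_that("truth alignment identity to the origin genome equals the
           error-count identity exactly", {
  com <- small_community(seed = 6)
  sim <- simulate_reads(com, read_sim_config(n_reads = 500, mode = "MG",
                                             error_rate = 0.02, seed = 8))
  aln <- sim$truth_alignments
  own <- aln[paste(aln$qseqid, aln$genome_id) %in%
               paste(sim$truth$read_id, sim$truth$origin_lineage), ]
  own <- own[match(sim$truth$read_id, own$qseqid), ]
  expect_equal(own$pident, sim$truth$true_identity)
  expect_equal(own$mismatch, sim$truth$n_errors)
})

test_that("lineage draws follow the configured weights (binomial bound)", {
  com <- small_community(seed = 2)
  sim <- simulate_reads(com, read_sim_config(
    n_reads = 10000, mode = "MG", lineage_weights = c(A = 0.9, B = 0.1),
    seed = 13))
  nA <- sum(sim$truth$origin_lineage == "A")
  expect_lt(abs(nA - 9000), 3 * sqrt(10000 * 0.9 * 0.1))
})

test_that("MT reads are wholly contained in genes and nif mass follows the
           expression weights", {
  com <- small_community(seed = 5)
  w <- default_expression_weights(com$annotations)
  expect_equal(sum(w), 1)
  nif_genes <- unique(com$annotations$gene_id[
    !is.na(com$annotations$cluster_label) &
      com$annotations$cluster_label == "nif_operon"])
  expect_equal(sum(w[nif_genes]), 0.25)

  n <- 10000
  sim <- simulate_reads(com, read_sim_config(
    n_reads = n, mode = "MT", expression_weights = w, seed = 21))
  genes <- unique(com$annotations[com$annotations$feature_kind == "gene",
                                  c("gene_id", "start", "end")])
  gene_of <- function(s) genes$gene_id[genes$start <= s & s + 100 <= genes$end]
  hit_gene <- vapply(sim$truth$start, function(s) {
    g <- gene_of(s)
    if (length(g) == 1) g else NA_character_
  }, "")
  expect_false(anyNA(hit_gene))  # containment
  in_nif <- hit_gene %in% nif_genes
  expect_lt(abs(mean(in_nif) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("genes shorter than the read length are excluded from MT weights
           with a warning", {
  com <- small_community(seed = 5)
  w <- default_expression_weights(com$annotations)
  ann2 <- com$annotations
  extra <- ann2[ann2$gene_id == "nifH" & ann2$seq_id == "A", ]
  # append a too-short gene on both lineages
  for (sq in c("A", "B")) {
    row <- extra
    row$seq_id <- sq
    row$gene_id <- "tiny"
    row$cluster_label <- NA_character_
    row$start <- 100L
    row$end <- 150L
    ann2 <- rbind(ann2, row)
  }
  expect_warning(default_expression_weights(ann2), "shorter than read_length")
  com2 <- com
  com2$annotations <- ann2
  w2 <- c(w * 0.9, tiny = 0.1)
  expect_warning(
    sim <- simulate_reads(com2, read_sim_config(n_reads = 50, mode = "MT",
                                                expression_weights = w2,
                                                seed = 2)),
    "shorter than read_length")
  expect_equal(nrow(sim$truth), 50L)
})

test_that("MG coverage matches the Lander-Waterman expectation", {
  com <- small_community(seed = 30, with_masks = FALSE)
  L <- com$genome_length
  n <- 2 * L / 100  # per-base coverage 2 for lineage A alone
  sim <- simulate_reads(com, read_sim_config(
    n_reads = n, mode = "MG", lineage_weights = c(A = 1, B = 0),
    error_rate = 0, seed = 31))
  cov <- logical(L)
  for (i in seq_len(nrow(sim$truth))) {
    cov[(sim$truth$start[i] + 1):sim$truth$end[i]] <- TRUE
  }
  expect_lt(abs(mean(cov) - (1 - exp(-2))), 0.03)
})

test_that("codon pair simulation hits its dS target and omega in truth units", {
  sim0 <- simulate_codon_pair(codon_sim_config(n_codons = 100, omega = 0.5,
                                               expected_dS = 0, seed = 1))
  expect_identical(sim0$pair$seq1, sim0$pair$seq2)

  sim <- simulate_codon_pair(codon_sim_config(n_codons = 2000, omega = 0.2,
                                              expected_dS = 0.3, seed = 17))
  expect_equal(sim$events$n_syn / sim$events$S_ancestor, 0.3,
               tolerance = 0.01)
  expect_error(
    simulate_codon_pair(codon_sim_config(n_codons = 10, omega = 0.5,
                                         expected_dS = 4, seed = 1,
                                         max_proposals = 20L)),
    "unreachable")
})

test_that("NG86 recovers a neutral omega from simulated pairs
           (median over replicates)", {
  om <- vapply(1:200, function(k) {
    sim <- simulate_codon_pair(codon_sim_config(n_codons = 500, omega = 1,
                                                expected_dS = 0.3,
                                                seed = 40000 + k))
    kaks(sim$pair$seq1, sim$pair$seq2)$omega
  }, 0)
  expect_gt(median(om), 0.85)
  expect_lt(median(om), 1.15)
})
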