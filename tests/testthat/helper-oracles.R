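# Independent brute-force oracles, written against the definitions rather
# than the package internals.

oracle_bases <- c("A", "C", "G", "T")
oracle_code <- as.list(Biostrings::GENETIC_CODE)

oracle_translate <- function(codon) oracle_code[[codon]]

# Site counting: enumerate all nine single-base mutants directly.
oracle_codon_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(oracle_bases, ch[p])) {
      mut <- ch
      mut[p] <- b
      aa <- oracle_translate(paste(mut, collapse = ""))
      if (aa != "*" && aa == aa0) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# Pathway averaging: recursively enumerate substitution orderings.
oracle_count_differences <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diffpos <- which(ch1 != ch2)
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  paths <- perm_list(diffpos)
  res <- lapply(paths, function(ord) {
    cur <- ch1
    sd <- nd <- 0
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- ch2[p]
      a1 <- oracle_translate(paste(cur, collapse = ""))
      a2 <- oracle_translate(paste(nxt, collapse = ""))
      if (a2 == "*") valid <- FALSE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, valid = valid)
  })
  valid <- vapply(res, `[[`, TRUE, "valid")
  use <- if (any(valid)) res[valid] else res
  c(sd = mean(vapply(use, `[[`, 0, "sd")),
    nd = mean(vapply(use, `[[`, 0, "nd")))
}

oracle_sense_codons <- function() {
  all <- apply(expand.grid(oracle_bases, oracle_bases, oracle_bases), 1,
               paste, collapse = "")
  all[vapply(all, function(cd) oracle_translate(cd) != "*", TRUE)]
}

# Per-position boolean-mask breadth of coverage (0-based half-open input not
# used: takes 1-based inclusive subject intervals as in the record table).
oracle_recovery <- function(sstart, send, pident, genome_length,
                            population_identity = 95) {
  covered <- logical(genome_length)
  for (i in seq_along(sstart)) {
    if (pident[i] > population_identity) {
      covered[sstart[i]:send[i]] <- TRUE
    }
  }
  100 * sum(covered) / genome_length
}

# Plain per-record re-application of the four filter rules.
oracle_filter_keep <- function(records, read_lengths, masks, cfg) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    rl <- read_lengths[[r$qseqid]]
    ok <- r$pident >= cfg$min_pident &&
      r$evalue <= cfg$max_evalue &&
      (r$qend - r$qstart + 1) / rl >= cfg$min_query_coverage
    if (ok && !is.null(masks) && nrow(masks) > 0) {
      m <- masks[masks$genome_id == r$genome_id, , drop = FALSE]
      for (j in seq_len(nrow(m))) {
        # mask is 0-based half-open; record subject is 1-based inclusive
        if (r$sstart <= m$end[j] && r$send >= m$start[j] + 1) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  keep
}

# Closed-form simple OLS.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# The worked six-record filter table: read length 100 throughout; one rRNA
# mask on genome A at [1000, 1100) (0-based half-open).
toy_filter_table <- function() {
  rec <- data.frame(
    qseqid = paste0("r", 1:6),
    sseqid = "A_ctg1",
    pident = c(99, 99, 99, 49, 99, 96),
    length = c(95, 85, 100, 100, 100, 90),
    mismatch = 0L, gapopen = 0L,
    qstart = 1L,
    qend = c(95L, 85L, 100L, 100L, 100L, 90L),
    sstart = c(5001L, 6001L, 902L, 7001L, 8001L, 9001L),
    send = c(5095L, 6085L, 1001L, 7100L, 8100L, 9090L),
    evalue = c(1e-40, 1e-40, 1e-40, 1e-40, 1e-3, 1e-40),
    bitscore = c(180, 160, 190, 190, 190, 170),
    strand = "+", genome_id = "A",
    stringsAsFactors = FALSE
  )
  masks <- data.frame(genome_id = "A", start = 1000L, end = 1100L,
                      stringsAsFactors = FALSE)
  read_lengths <- stats::setNames(rep(100L, 6), rec$qseqid)
  list(records = rec, masks = masks, read_lengths = read_lengths)
}

chars_differ <- function(a, b) {
  strsplit(a, "")[[1]] != strsplit(b, "")[[1]]
}

# Small community used by several tests (no masks; tight but valid layout).
small_community <- function(seed = 1, genome_length = 50000L, n_genes = 45L,
                            divergence = 0.05, with_masks = TRUE) {
  masks <- if (with_masks) list(c(500L, 2500L)) else list()
  its <- if (with_masks) list(c(2500L, 2800L)) else list()
  simulate_genome_pair(community_config(
    genome_length = genome_length, n_genes = n_genes, gene_length = 900L,
    divergence = divergence, rrna_intervals = masks, its_intervals = its,
    seed = seed))
}
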