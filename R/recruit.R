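# Competitive fragment recruitment: filtering of tabular read-vs-genome
# alignments, closest-hit assignment between two reference genomes, genome
# recovery (breadth of coverage above the population identity threshold)
# and 1%-identity histograms.

#' Filtering and binning configuration for fragment recruitment
#'
#' Defaults follow the standard recruitment protocol for these analyses:
#' minimum 50% identity and e-value 1e-4 at the alignment step, reads
#' aligned along less than 90% of their length excluded, reads above 95%
#' identity counted as the same population as the reference, and identity
#' histograms in 1% bins from 70 to 100%.
#'
#' @param min_pident Minimum percent identity (inclusive).
#' @param max_evalue Maximum e-value (inclusive).
#' @param min_query_coverage Minimum aligned fraction of the read,
#'   `(qend - qstart + 1) / read_length` (inclusive).
#' @param population_identity Percent identity above which (strictly) a read
#'   is counted as belonging to the reference population.
#' @param histogram_lo,histogram_hi,histogram_step Identity histogram range
#'   and bin width in percent.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_pident = 50, max_evalue = 1e-4,
                          min_query_coverage = 0.90,
                          population_identity = 95,
                          histogram_lo = 70, histogram_hi = 100,
                          histogram_step = 1) {
  cfg <- list(min_pident = min_pident, max_evalue = max_evalue,
              min_query_coverage = min_query_coverage,
              population_identity = population_identity,
              histogram_lo = histogram_lo, histogram_hi = histogram_hi,
              histogram_step = histogram_step)
  if (cfg$min_pident < 0 || cfg$min_pident > cfg$population_identity ||
      cfg$population_identity > 100) {
    stop("need 0 <= min_pident <= population_identity <= 100")
  }
  if (cfg$min_query_coverage <= 0 || cfg$min_query_coverage > 1) {
    stop("min_query_coverage must be in (0, 1]")
  }
  if (cfg$histogram_lo >= cfg$histogram_hi || cfg$histogram_step <= 0) {
    stop("invalid histogram range")
  }
  structure(cfg, class = "filter_config")
}

#' Reduce multiple HSPs to the best hit per (read, genome)
#'
#' For each `(qseqid, genome_id)` pair keeps the record with the highest
#' bitscore; ties broken by higher percent identity, then by the
#' lexicographically smallest `(sstart, send)`.
#'
#' @param records Alignment data frame (see [read_tabular_alignments()]).
#' @return The reduced data frame, one row per read-genome pair.
#' @export
best_hit_per_genome <- function(records) {
  if (nrow(records) == 0L) return(records)
  o <- order(records$qseqid, records$genome_id, -records$bitscore,
             -records$pident, records$sstart, records$send)
  r <- records[o, , drop = FALSE]
  keep <- !duplicated(paste0(r$qseqid, "\r", r$genome_id))
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply recruitment filters with first-fail attribution
#'
#' A record is retained iff `pident >= min_pident`, `evalue <= max_evalue`,
#' `(qend - qstart + 1)/read_length >= min_query_coverage`, and its subject
#' interval overlaps no rRNA/ITS mask interval by 1 bp or more. The filter
#' log attributes each removal to the FIRST failing rule in the order
#' identity, evalue, coverage, mask; the retained set itself does not depend
#' on the order.
#'
#' @param records Alignment data frame.
#' @param read_lengths Named integer vector, one length per `qseqid`.
#' @param masks `NULL` or a data frame `(genome_id, start, end)` of 0-based
#'   half-open masked intervals (see [masks_from_annotations()]).
#' @param cfg A [filter_config()].
#' @return List with `records` (retained rows) and `log` (named counts:
#'   input, identity, evalue, coverage, mask, retained).
#' @export
apply_filters <- function(records, read_lengths, masks = NULL,
                          cfg = filter_config()) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = records,
                log = c(input = 0L, identity = 0L, evalue = 0L,
                        coverage = 0L, mask = 0L, retained = 0L)))
  }
  rl <- read_lengths[records$qseqid]
  if (anyNA(rl)) {
    stop("missing read length for read '",
         records$qseqid[is.na(rl)][1L], "'")
  }
  fail_identity <- records$pident < cfg$min_pident
  fail_evalue <- records$evalue > cfg$max_evalue
  fail_coverage <- (records$qend - records$qstart + 1) / rl <
    cfg$min_query_coverage
  fail_mask <- rep(FALSE, n)
  if (!is.null(masks) && nrow(masks) > 0L) {
    for (g in unique(masks$genome_id)) {
      sel <- which(records$genome_id == g)
      if (!length(sel)) next
      msel <- masks[masks$genome_id == g, , drop = FALSE]
      hits <- IRanges::overlapsAny(
        IRanges::IRanges(start = records$sstart[sel], end = records$send[sel]),
        IRanges::IRanges(start = msel$start + 1L, end = msel$end)
      )
      fail_mask[sel] <- hits
    }
  }
  first <- rep("retained", n)
  first[fail_mask] <- "mask"
  first[fail_coverage] <- "coverage"
  first[fail_evalue] <- "evalue"
  first[fail_identity] <- "identity"
  keep <- first == "retained"
  log <- c(input = n,
           identity = sum(first == "identity"),
           evalue = sum(first == "evalue"),
           coverage = sum(first == "coverage"),
           mask = sum(first == "mask"),
           retained = sum(keep))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, log = log)
}

#' Extract rRNA/ITS mask intervals from an annotation table
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param genome_map Optional named vector mapping `seq_id` to genome id;
#'   by default `seq_id` is used as the genome id.
#' @return Data frame `(genome_id, start, end)` (0-based half-open).
#' @export
masks_from_annotations <- function(annotations, genome_map = NULL) {
  m <- annotations[annotations$feature_kind %in% c("rRNA", "ITS"), ,
                   drop = FALSE]
  gid <- if (is.null(genome_map)) m$seq_id else {
    g <- genome_map[m$seq_id]
    if (anyNA(g)) stop("seq_id missing from genome_map")
    unname(g)
  }
  data.frame(genome_id = gid, start = m$start, end = m$end,
             stringsAsFactors = FALSE)
}

#' Competitively assign each read to its closest-hit genome
#'
#' Expects records already reduced by [best_hit_per_genome()] and filtered.
#' Each read is assigned to the genome with the highest bitscore; bitscore
#' ties are broken by higher percent identity; a full tie marks the read
#' ambiguous (its `genome_id` is set to `NA` and it is excluded from
#' per-genome summaries).
#'
#' @param records Filtered best-hit alignment data frame.
#' @return Data frame with one row per read (the winning record) plus a
#'   logical `ambiguous` column; deterministic for any input order.
#' @export
competitive_assign <- function(records) {
  if (nrow(records) == 0L) {
    out <- records
    out$ambiguous <- logical(0)
    return(out)
  }
  o <- order(records$qseqid, -records$bitscore, -records$pident,
             records$genome_id, records$sstart, records$send)
  r <- records[o, , drop = FALSE]
  first <- !duplicated(r$qseqid)
  idx <- which(first)
  nxt <- idx + 1L
  has_second <- nxt <= nrow(r) & !first[pmin(nxt, nrow(r))]
  amb <- rep(FALSE, length(idx))
  ok <- which(has_second)
  amb[ok] <- r$bitscore[idx[ok]] == r$bitscore[nxt[ok]] &
    r$pident[idx[ok]] == r$pident[nxt[ok]] &
    r$genome_id[idx[ok]] != r$genome_id[nxt[ok]]
  out <- r[idx, , drop = FALSE]
  out$ambiguous <- amb
  out$genome_id[amb] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Genome recovery: breadth of coverage above the population threshold
#'
#' Takes the subject intervals of assigned reads with percent identity
#' strictly above `population_identity`, unions them, and reports the
#' covered position count and its percentage of the full genome length
#' (masked rRNA/ITS regions are part of the denominator).
#'
#' @param assigned Assigned (non-ambiguous) records for one genome.
#' @param genome_length Reference genome length in bp.
#' @param cfg A [filter_config()].
#' @return Named list `covered_positions`, `recovery_pct`, `n_population`.
#' @export
genome_recovery <- function(assigned, genome_length, cfg = filter_config()) {
  pop <- assigned[assigned$pident > cfg$population_identity, , drop = FALSE]
  if (nrow(pop) > 0L) {
    if (any(pop$sstart < 1L) || any(pop$send > genome_length)) {
      stop("subject interval outside [0, genome_length)")
    }
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = pop$sstart, end = pop$send))))
  } else {
    covered <- 0L
  }
  list(covered_positions = as.integer(covered),
       recovery_pct = 100 * covered / genome_length,
       n_population = nrow(pop))
}

#' Percent-identity histogram of assigned reads
#'
#' Bins `[k, k + step)` from `histogram_lo` up to `histogram_hi`, with the
#' top bin closed (`pident == histogram_hi` falls in the last bin) and an
#' underflow count for identities below `histogram_lo`. Bin counts plus the
#' underflow sum to the number of assigned reads.
#'
#' @param assigned Assigned records for one genome.
#' @param cfg A [filter_config()].
#' @return List with `bins` (data frame `bin_lo`, `bin_hi`, `count`) and
#'   `underflow`.
#' @export
identity_histogram <- function(assigned, cfg = filter_config()) {
  lo <- cfg$histogram_lo
  hi <- cfg$histogram_hi
  step <- cfg$histogram_step
  edges <- seq(lo, hi, by = step)
  nb <- length(edges) - 1L
  p <- assigned$pident
  under <- sum(p < lo)
  inb <- p[p >= lo]
  bidx <- pmin(floor((inb - lo) / step) + 1L, nb)  # top bin closed
  counts <- tabulate(bidx, nbins = nb)
  list(bins = data.frame(bin_lo = edges[-length(edges)],
                         bin_hi = edges[-1L], count = counts),
       underflow = as.integer(under))
}

#' Run the full recruitment chain for one sample
#'
#' Best-hit reduction, filtering, competitive assignment, and per-genome
#' summaries (assigned counts, population counts, genome recovery and
#' identity histogram).
#'
#' @param records Raw alignment data frame for one sample.
#' @param read_lengths Named read lengths.
#' @param genome_lengths Named genome lengths (one per genome id).
#' @param masks Optional mask intervals (see [apply_filters()]).
#' @param cfg A [filter_config()].
#' @return Object of class `recruitment_result`: list with `summary` (data
#'   frame, one row per genome: n_assigned, n_population, covered_positions,
#'   genome_length, recovery_pct), `histograms` (per genome), `assigned`
#'   (per-read winner records incl. ambiguous rows), `filter_log`,
#'   `n_ambiguous`.
#' @export
recruit_sample <- function(records, read_lengths, genome_lengths,
                           masks = NULL, cfg = filter_config()) {
  best <- best_hit_per_genome(records)
  flt <- apply_filters(best, read_lengths, masks, cfg)
  assigned <- competitive_assign(flt$records)
  ok <- assigned[!assigned$ambiguous, , drop = FALSE]
  genomes <- names(genome_lengths)
  rows <- vector("list", length(genomes))
  histograms <- vector("list", length(genomes))
  names(histograms) <- genomes
  for (i in seq_along(genomes)) {
    g <- genomes[i]
    gr <- ok[ok$genome_id == g, , drop = FALSE]
    rec <- genome_recovery(gr, genome_lengths[[g]], cfg)
    histograms[[g]] <- identity_histogram(gr, cfg)
    rows[[i]] <- data.frame(
      genome_id = g, n_assigned = nrow(gr),
      n_population = rec$n_population,
      covered_positions = rec$covered_positions,
      genome_length = as.integer(genome_lengths[[g]]),
      recovery_pct = rec$recovery_pct,
      stringsAsFactors = FALSE
    )
  }
  structure(list(summary = do.call(rbind, rows), histograms = histograms,
                 assigned = assigned, filter_log = flt$log,
                 n_ambiguous = sum(assigned$ambiguous), cfg = cfg),
            class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat("Competitive fragment recruitment\n")
  lg <- x$filter_log
  cat(sprintf("  alignments in: %d; removed identity %d, evalue %d, coverage %d, mask %d; retained %d\n",
              lg[["input"]], lg[["identity"]], lg[["evalue"]],
              lg[["coverage"]], lg[["mask"]], lg[["retained"]]))
  cat(sprintf("  ambiguous reads (full ties): %d\n", x$n_ambiguous))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  genome %s: %d assigned (%d above population threshold), recovery %.2f%%\n",
                s$genome_id, s$n_assigned, s$n_population, s$recovery_pct))
  }
  invisible(x)
}

#' @export
plot.recruitment_result <- function(x, ...) {
  genomes <- names(x$histograms)
  oldpar <- graphics::par(mfrow = c(1, length(genomes)))
  on.exit(graphics::par(oldpar), add = TRUE)
  for (g in genomes) {
    h <- x$histograms[[g]]
    graphics::barplot(h$bins$count, names.arg = h$bins$bin_lo,
                      main = paste("Genome", g),
                      xlab = "% identity (bin lower edge)",
                      ylab = "assigned reads", ...)
  }
  invisible(x)
}

#' Naive ungapped read aligner (k-mer seed and extend)
#'
#' A stand-in aligner for the no-indel synthetic regime: exact k-mer seeds
#' against each genome, ungapped full-read extension on every candidate
#' diagonal, and the best diagonal per (read, genome) reported with exact
#' percent identity and mismatch count. Reads with no exact seed on a
#' genome yield no record for it. Scores use the same bitscore/e-value
#' surrogates as the simulator.
#'
#' @param reads Data frame with `id` and `residues`.
#' @param genomes Named list (or named character vector) of genome strings.
#' @param k Seed length (default 13); must not exceed the read length.
#' @return Alignment data frame in the tabular format.
#' @export
align_reads_naive <- function(reads, genomes, k = 13L) {
  if (is.data.frame(genomes)) {
    genomes <- stats::setNames(as.list(genomes$residues), genomes$id)
  }
  rl <- nchar(reads$residues)
  if (length(unique(rl)) > 1L) stop("reads must have equal length")
  rl <- rl[1L]
  if (k > rl) stop("k exceeds read length")
  n <- nrow(reads)
  bases <- c("A", "C", "G", "T")
  enc <- function(chars) match(chars, bases) - 1L  # non-ACGT -> NA

  read_mat <- matrix(unlist(strsplit(reads$residues, "")), nrow = rl)
  rcode <- matrix(as.numeric(enc(read_mat)), nrow = rl)
  nq <- rl - k + 1L
  qcodes <- matrix(0, nrow = nq, ncol = n)
  for (j in 0:(k - 1L)) {
    qcodes <- qcodes * 4 + rcode[(1L + j):(nq + j), , drop = FALSE]
  }

  out <- vector("list", length(genomes))
  for (gi in seq_along(genomes)) {
    gname <- names(genomes)[gi]
    gchars <- chars_of(genomes[[gi]])
    L <- length(gchars)
    gnum <- as.numeric(enc(gchars))
    ng <- L - k + 1L
    gcodes <- numeric(ng)
    for (j in 0:(k - 1L)) {
      gcodes <- gcodes * 4 + gnum[(1L + j):(ng + j)]
    }
    ordg <- order(gcodes, na.last = NA)
    sorted <- gcodes[ordg]

    q <- as.vector(qcodes)
    hi <- findInterval(q, sorted)
    lo <- findInterval(q - 0.5, sorted)
    m <- hi - lo
    m[is.na(q)] <- 0L
    hit <- which(m > 0L)
    if (!length(hit)) next
    gpos <- ordg[sequence(m[hit]) + rep(lo[hit], m[hit])]
    read_idx <- rep((hit - 1L) %/% nq + 1L, m[hit])
    offset <- rep((hit - 1L) %% nq, m[hit])
    diag_start <- gpos - offset          # 1-based genome start of the read
    keep <- diag_start >= 1L & diag_start + rl - 1L <= L
    read_idx <- read_idx[keep]
    diag_start <- diag_start[keep]
    key <- (read_idx - 1) * (L + 1) + diag_start
    dup <- duplicated(key)
    read_idx <- read_idx[!dup]
    diag_start <- diag_start[!dup]
    if (!length(read_idx)) next

    pos <- outer(0:(rl - 1L), diag_start, `+`)  # diag_start is 1-based
    mm <- colSums(matrix(gchars[pos], nrow = rl) !=
                    read_mat[, read_idx, drop = FALSE])
    o <- order(read_idx, mm, diag_start)
    ri <- read_idx[o]
    best <- !duplicated(ri)
    ri <- ri[best]
    ds <- diag_start[o][best]
    mmb <- mm[o][best]
    bits <- 2 * (rl - mmb) - 3 * mmb
    out[[gi]] <- data.frame(
      qseqid = reads$id[ri], sseqid = gname,
      pident = 100 * (rl - mmb) / rl, length = rl,
      mismatch = as.integer(mmb), gapopen = 0L,
      qstart = 1L, qend = rl,
      sstart = ds, send = ds + rl - 1L,
      evalue = 10^(-bits / 10), bitscore = as.numeric(bits),
      strand = "+", genome_id = gname,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_alignment_table()
  rownames(res) <- NULL
  res
}
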