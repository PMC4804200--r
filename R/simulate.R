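# Ground-truthed synthetic community: a pair of closely related symbiont
# genomes diverged from a common ancestor, size-fraction-dependent lineage
# mixtures of metagenomic (MG) and metatranscriptomic (MT) reads, and
# in-frame codon-pair alignments with known dN/dS. Every simulator is
# bit-reproducible under its seed and returns the ground truth needed for
# oracle tests.

#' Configuration for a synthetic two-lineage community
#'
#' @param genome_length Genome length in bp.
#' @param n_genes Number of protein-coding genes (>= 12 so that the nif
#'   operon and the recA/gyrB housekeeping pair can be placed).
#' @param gene_length Gene length in bp.
#' @param divergence Expected per-site substitution fraction between the two
#'   lineages (each evolves `divergence/2` from the ancestor); in [0, 0.3].
#' @param gc_content GC fraction of the ancestral genome.
#' @param rrna_intervals,its_intervals Lists of 0-based half-open intervals
#'   (two-element vectors) to annotate as rRNA / ITS; genes are laid out
#'   after the last masked position.
#' @param seed Integer seed.
#' @return Object of class `community_config`.
#' @export
community_config <- function(genome_length = 200000L, n_genes = 150L,
                             gene_length = 900L, divergence = 0.05,
                             gc_content = 0.35,
                             rrna_intervals = list(c(1000L, 6000L)),
                             its_intervals = list(c(6000L, 6600L)),
                             seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              divergence = divergence, gc_content = gc_content,
              rrna_intervals = rrna_intervals, its_intervals = its_intervals,
              seed = as.integer(seed))
  if (cfg$divergence < 0 || cfg$divergence > 0.3) {
    stop("divergence must be in [0, 0.3]")
  }
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) stop("gc_content in (0,1)")
  if (cfg$n_genes < 12L) stop("n_genes must be >= 12")
  iv <- c(cfg$rrna_intervals, cfg$its_intervals)
  if (length(iv)) {
    m <- do.call(rbind, iv)
    if (any(m[, 1] >= m[, 2]) || any(m[, 1] < 0) ||
        any(m[, 2] > cfg$genome_length)) {
      stop("mask interval outside [0, genome_length)")
    }
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2])) {
      stop("rRNA/ITS intervals overlap")
    }
  }
  structure(cfg, class = "community_config")
}

# Canonical gene naming/cluster layout: nif operon first, then the
# housekeeping pair, then ATP synthase, cytochrome b6f and PSI clusters,
# remaining genes unlabeled.
community_gene_layout <- function(n_genes) {
  nif <- c("nifH", "nifD", "nifK", "nifB", "nifE", "nifN", "nifX", "nifU",
           "nifS")
  atp <- c("atpA", "atpB", "atpC", "atpD", "atpE", "atpF", "atpG", "atpH")
  cyt <- c("petA", "petB", "petC", "petD", "petG", "petM")
  psi <- c("psaA", "psaB", "psaC", "psaD", "psaE", "psaF", "psaI", "psaJ",
           "psaK", "psaL", "psaM", "psaX")
  ids <- character(n_genes)
  labs <- rep(NA_character_, n_genes)
  named <- list(nif_operon = nif, housekeeping = c("recA", "gyrB"),
                atp_synthase = atp, cyt_b6f = cyt, PSI = psi)
  pos <- 1L
  for (lab in names(named)) {
    take <- named[[lab]]
    n_take <- min(length(take), n_genes - pos + 1L)
    if (n_take <= 0L) break
    ids[pos:(pos + n_take - 1L)] <- take[seq_len(n_take)]
    labs[pos:(pos + n_take - 1L)] <- lab
    pos <- pos + n_take
  }
  if (pos <= n_genes) {
    ids[pos:n_genes] <- sprintf("g%03d", seq_len(n_genes - pos + 1L))
  }
  data.frame(gene_id = ids, cluster_label = labs, stringsAsFactors = FALSE)
}

#' Simulate a pair of closely related genomes from a common ancestor
#'
#' The ancestor is an i.i.d. sequence at the configured GC content. Each
#' lineage substitutes each site independently with probability
#' `divergence/2`, drawing uniformly among the three alternative bases
#' (Jukes-Cantor-like, no indels), so annotations carry over at identical
#' coordinates. Genes are laid out evenly after the rRNA/ITS block, with the
#' nif operon, recA/gyrB and the other expression clusters labeled.
#'
#' @param config A [community_config()].
#' @return Object of class `community`: list with `ancestor`, `genomes`
#'   (named list of DNA strings, lineages `"A"` and `"B"`), `genome_length`,
#'   `annotations` (rows for both lineages; `seq_id` equals the lineage id),
#'   `genome_map`, `divergence_realized` (Hamming fraction A vs B) and
#'   `config`.
#' @export
simulate_genome_pair <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  masks <- c(config$rrna_intervals, config$its_intervals)
  first_free <- if (length(masks)) max(vapply(masks, `[`, 0, 2L)) else 0L
  span <- L - first_free
  need <- config$n_genes * config$gene_length
  if (need > span) stop("genes do not fit in the genome after masked regions")
  gap <- (span - need) %/% (config$n_genes + 1L)
  starts <- first_free + gap + (seq_len(config$n_genes) - 1L) *
    (config$gene_length + gap)
  layout <- community_gene_layout(config$n_genes)

  mutate_lineage <- function(chars, rate) {
    hit <- which(stats::runif(L) < rate)
    if (length(hit)) {
      idx <- match(chars[hit], c("A", "C", "G", "T"))
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- c("A", "C", "G", "T")[((idx - 1L + shift) %% 4L) + 1L]
    }
    chars
  }
  gA <- mutate_lineage(anc, config$divergence / 2)
  gB <- mutate_lineage(anc, config$divergence / 2)

  ann_one <- function(seq_id) {
    gene_ann <- data.frame(
      seq_id = seq_id, feature_kind = "gene",
      start = starts, end = starts + config$gene_length,
      strand = "+", gene_id = layout$gene_id,
      cluster_label = layout$cluster_label, stringsAsFactors = FALSE
    )
    mask_ann <- NULL
    mk <- function(ivs, kind, prefix) {
      if (!length(ivs)) return(NULL)
      m <- do.call(rbind, ivs)
      data.frame(seq_id = seq_id, feature_kind = kind,
                 start = m[, 1], end = m[, 2], strand = "+",
                 gene_id = paste0(prefix, seq_along(ivs)),
                 cluster_label = NA_character_, stringsAsFactors = FALSE)
    }
    rbind(gene_ann, mk(config$rrna_intervals, "rRNA", "rrn"),
          mk(config$its_intervals, "ITS", "its"))
  }
  annotations <- rbind(ann_one("A"), ann_one("B"))

  structure(list(
    ancestor = string_of(anc),
    genomes = list(A = string_of(gA), B = string_of(gB)),
    genome_length = L,
    annotations = annotations,
    genome_map = c(A = "A", B = "B"),
    divergence_realized = mean(gA != gB),
    config = config
  ), class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat("Synthetic two-lineage community\n")
  cat(sprintf("  genome length: %d bp; genes: %d; realized A-vs-B divergence: %.4f\n",
              x$genome_length, sum(x$annotations$feature_kind == "gene") / 2,
              x$divergence_realized))
  invisible(x)
}

#' Configuration for read simulation
#'
#' @param n_reads Number of reads to draw.
#' @param mode `"MG"` (metagenome: uniform starts along the genome) or
#'   `"MT"` (metatranscriptome: reads drawn from gene intervals according to
#'   `expression_weights`).
#' @param read_length Read length in bp (the sequencing chemistry modeled is
#'   100-base reads).
#' @param lineage_weights Named fractions over lineages, summing to 1; the
#'   knob that makes lineage abundances differ across size-fraction samples.
#' @param error_rate Per-base substitution probability.
#' @param expression_weights Named per-gene fractions summing to 1 (MT mode);
#'   see [default_expression_weights()]. Genes shorter than `read_length`
#'   are dropped with a warning and the weights renormalized.
#' @param seed Integer seed.
#' @return Object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads, mode = c("MG", "MT"), read_length = 100L,
                            lineage_weights = c(A = 0.5, B = 0.5),
                            error_rate = 0.005, expression_weights = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (abs(sum(lineage_weights) - 1) > 1e-9) {
    stop("lineage_weights must sum to 1")
  }
  if (is.null(names(lineage_weights)) || any(!nzchar(names(lineage_weights)))) {
    stop("lineage_weights must be named by lineage")
  }
  if (mode == "MT" && is.null(expression_weights)) {
    stop("MT mode requires expression_weights")
  }
  if (!is.null(expression_weights) &&
      abs(sum(expression_weights) - 1) > 1e-9) {
    stop("expression_weights must sum to 1")
  }
  structure(list(n_reads = as.integer(n_reads), mode = mode,
                 read_length = as.integer(read_length),
                 lineage_weights = lineage_weights,
                 error_rate = error_rate,
                 expression_weights = expression_weights,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Default per-gene expression profile for MT simulation
#'
#' Puts a configurable transcript mass on each labeled gene cluster —
#' one quarter on the nif operon by default, reflecting the dominance of
#' nitrogen-fixation transcripts in these symbionts — spread uniformly
#' within the cluster, with the remaining mass uniform over unlabeled genes.
#'
#' @param annotations Annotation data frame from [simulate_genome_pair()].
#' @param nif_mass,atp_mass,cyt_mass,psi_mass,hk_mass Cluster masses.
#' @param read_length Genes shorter than this are excluded (with a warning).
#' @return Named numeric weights over gene ids, summing to 1.
#' @export
default_expression_weights <- function(annotations, nif_mass = 0.25,
                                       atp_mass = 0.10, cyt_mass = 0.06,
                                       psi_mass = 0.12, hk_mass = 0.04,
                                       read_length = 100L) {
  genes <- unique(annotations[annotations$feature_kind == "gene",
                              c("gene_id", "cluster_label", "start", "end")])
  short <- (genes$end - genes$start) < read_length
  if (any(short)) {
    warning("excluding ", sum(short), " gene(s) shorter than read_length ",
            "from expression weights")
    genes <- genes[!short, ]
  }
  mass <- c(nif_operon = nif_mass, atp_synthase = atp_mass, cyt_b6f = cyt_mass,
            PSI = psi_mass, housekeeping = hk_mass)
  w <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  used <- 0
  for (lab in names(mass)) {
    members <- genes$gene_id[!is.na(genes$cluster_label) &
                               genes$cluster_label == lab]
    if (length(members)) {
      w[members] <- mass[[lab]] / length(members)
      used <- used + mass[[lab]]
    }
  }
  rest <- genes$gene_id[is.na(genes$cluster_label)]
  if (length(rest)) {
    w[rest] <- (1 - used) / length(rest)
  } else {
    w <- w / sum(w)
  }
  w
}

#' Simulate MG or MT reads with full ground truth
#'
#' Each read's origin lineage is drawn from `lineage_weights`. MG reads
#' start uniformly on `[0, L - read_length]`; MT reads are wholly contained
#' in a gene drawn from `expression_weights`, with a uniform start inside
#' the gene. Each base is substituted independently with `error_rate`
#' (always to a different base). Alongside the reads, the simulator emits a
#' truth table and exact ungapped full-length alignments of every read
#' against BOTH genomes (identical coordinates; no indels are simulated), so
#' the whole downstream pipeline can run without an aligner. The bitscore
#' surrogate is `2*matches - 3*mismatches` and the e-value surrogate
#' `10^(-bitscore/10)`; only their ordering matters downstream.
#'
#' @param community A [simulate_genome_pair()] result.
#' @param config A [read_sim_config()].
#' @return List with `reads` (data frame: id, description, residues),
#'   `truth` (read_id, origin_lineage, start, end (0-based half-open),
#'   n_errors, true_identity), `truth_alignments` (tabular alignment records
#'   vs both genomes) and `config`.
#' @export
simulate_reads <- function(community, config) {
  stopifnot(inherits(community, "community"),
            inherits(config, "read_sim_config"))
  rl <- config$read_length
  L <- community$genome_length
  if (rl > L) stop("read_length exceeds genome_length")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_reads
  lineages <- names(config$lineage_weights)
  if (!all(lineages %in% names(community$genomes))) {
    stop("lineage_weights name unknown lineages")
  }
  origin <- sample(lineages, n, replace = TRUE,
                   prob = config$lineage_weights)

  if (config$mode == "MG") {
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
  } else {
    w <- config$expression_weights
    genes <- unique(community$annotations[
      community$annotations$feature_kind == "gene",
      c("gene_id", "start", "end")])
    miss <- setdiff(names(w), genes$gene_id)
    if (length(miss)) stop("expression weight on unannotated gene '",
                           miss[1L], "'")
    glen <- genes$end - genes$start
    names(glen) <- genes$gene_id
    gstart <- stats::setNames(genes$start, genes$gene_id)
    short <- glen[names(w)] < rl
    if (any(short)) {
      warning("excluding ", sum(short),
              " gene(s) shorter than read_length from expression weights")
      w <- w[!short]
      w <- w / sum(w)
    }
    gene_of_read <- sample(names(w), n, replace = TRUE, prob = w)
    span <- glen[gene_of_read] - rl + 1L
    offs <- floor(stats::runif(n) * span)
    starts <- unname(gstart[gene_of_read] + offs)
  }

  genome_chars <- lapply(community$genomes, chars_of)
  read_mat <- matrix("", nrow = rl, ncol = n)
  n_errors <- integer(n)
  for (lin in lineages) {
    sel <- which(origin == lin)
    if (!length(sel)) next
    pos <- outer(seq_len(rl), starts[sel], `+`)  # 1-based genome positions
    m <- matrix(genome_chars[[lin]][pos], nrow = rl)
    err <- matrix(stats::runif(rl * length(sel)) < config$error_rate,
                  nrow = rl)
    if (any(err)) {
      idx <- match(m[err], c("A", "C", "G", "T"))
      shift <- sample.int(3L, sum(err), replace = TRUE)
      m[err] <- c("A", "C", "G", "T")[((idx - 1L + shift) %% 4L) + 1L]
    }
    read_mat[, sel] <- m
    n_errors[sel] <- colSums(err)
  }
  read_ids <- sprintf("read_%06d", seq_len(n))
  residues <- apply(read_mat, 2L, paste0, collapse = "")

  truth <- data.frame(
    read_id = read_ids, origin_lineage = origin,
    start = starts, end = starts + rl, n_errors = n_errors,
    true_identity = 100 * (1 - n_errors / rl),
    stringsAsFactors = FALSE
  )

  aln <- lapply(names(community$genomes), function(g) {
    pos <- outer(seq_len(rl), starts, `+`)
    ref <- matrix(genome_chars[[g]][pos], nrow = rl)
    mm <- colSums(ref != read_mat)
    bits <- 2 * (rl - mm) - 3 * mm
    data.frame(
      qseqid = read_ids, sseqid = g,
      pident = 100 * (rl - mm) / rl, length = rl,
      mismatch = as.integer(mm), gapopen = 0L,
      qstart = 1L, qend = rl,
      sstart = starts + 1L, send = starts + rl,
      evalue = 10^(-bits / 10), bitscore = as.numeric(bits),
      strand = "+", genome_id = g,
      stringsAsFactors = FALSE
    )
  })
  truth_alignments <- do.call(rbind, aln)
  rownames(truth_alignments) <- NULL

  list(reads = data.frame(id = read_ids, description = "",
                          residues = residues, stringsAsFactors = FALSE),
       truth = truth, truth_alignments = truth_alignments, config = config)
}

#' Configuration for codon-pair simulation
#'
#' @param n_codons Number of codons (>= 10).
#' @param omega Target dN/dS ratio (> 0).
#' @param expected_dS Target synonymous substitutions per synonymous site on
#'   the pair path.
#' @param seed Integer seed.
#' @param max_proposals Proposal budget before giving up (guards tiny
#'   `n_codons` with unreachable `expected_dS`).
#' @return Object of class `codon_sim_config`.
#' @export
codon_sim_config <- function(n_codons, omega = 0.2, expected_dS = 0.3,
                             seed = 1L, max_proposals = NULL) {
  if (omega <= 0) stop("omega must be > 0")
  if (n_codons < 10L) stop("n_codons must be >= 10")
  if (expected_dS < 0) stop("expected_dS must be >= 0")
  if (is.null(max_proposals)) {
    max_proposals <- max(10000L,
                         ceiling(300 * n_codons * max(expected_dS, 0.01)))
  }
  structure(list(n_codons = as.integer(n_codons), omega = omega,
                 expected_dS = expected_dS, seed = as.integer(seed),
                 max_proposals = as.integer(max_proposals)),
            class = "codon_sim_config")
}

#' Simulate an in-frame codon pair with known dN/dS
#'
#' Starts from a random ancestor of sense codons and evolves a descendant by
#' proposing single-nucleotide codon changes (uniform over positions and
#' alternative bases). Proposals creating stop codons are rejected;
#' synonymous and nonsynonymous proposals are accepted with probabilities in
#' the ratio `1 : omega * r`, where the per-codon factor
#' `r = (nonsynonymous mutants incl. stops) / (viable nonsynonymous
#' mutants)` compensates for the rejected stop channels, which
#' Nei-Gojobori site counting includes among the nonsynonymous sites.
#' `omega` is therefore the target dN/dS measured in NG86 site units: a
#' neutral simulation (`omega = 1`) realizes equal synonymous and
#' nonsynonymous per-site event rates. Both acceptance probabilities are
#' scaled jointly so neither exceeds 1 (this also handles `omega > 1`).
#' Events accumulate until the accepted synonymous events per ancestral
#' synonymous site reach `expected_dS`, so the Jukes-Cantor-corrected NG86
#' estimate recovers `expected_dS` in expectation.
#'
#' @param config A [codon_sim_config()].
#' @return List with `pair` (data frame: gene_id, seq1 = ancestor,
#'   seq2 = descendant), `events` (realized accepted synonymous /
#'   nonsynonymous event counts and proposals used) and `config`.
#' @export
simulate_codon_pair <- function(config) {
  stopifnot(inherits(config, "codon_sim_config"))
  tab <- ng86_tables()
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  sense <- which(!tab$is_stop)
  anc <- sample(sense, config$n_codons, replace = TRUE)
  S_anc <- sum(tab$s_sites[anc])
  # integer event target (rounded, not first-crossing) so the realized
  # synonymous rate is unbiased for expected_dS
  target_syn <- round(config$expected_dS * S_anc)

  # Per-codon stop-channel compensation: NG86 counts mutations to stops as
  # nonsynonymous sites, but those proposals are rejected; re-weighting the
  # nonsynonymous acceptance by r keeps the per-site event-rate ratio at
  # omega.
  nonsyn_mut <- 9 - 3 * tab$s_sites
  r_comp <- nonsyn_mut / (nonsyn_mut - tab$n_stop_mut)
  p_non_raw <- config$omega * r_comp
  scale <- max(1, max(p_non_raw[sense]))
  p_syn <- 1 / scale
  p_non_codon <- p_non_raw / scale

  cur <- anc
  n_syn <- 0L
  n_nonsyn <- 0L
  proposals <- 0L
  while (n_syn < target_syn) {
    proposals <- proposals + 1L
    if (proposals > config$max_proposals) {
      stop("expected_dS unreachable within ", config$max_proposals,
           " proposals (n_codons too small?)")
    }
    pos <- sample.int(config$n_codons, 1L)
    i <- cur[pos]
    j <- tab$mut9[i, sample.int(9L, 1L)]
    if (tab$is_stop[j]) next
    syn <- tab$aa[j] == tab$aa[i]
    acc <- if (syn) p_syn else p_non_codon[i]
    if (acc < 1 && stats::runif(1L) >= acc) next
    cur[pos] <- j
    if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
  }
  codons <- tab$codons
  list(
    pair = data.frame(gene_id = "sim",
                      seq1 = paste0(codons[anc], collapse = ""),
                      seq2 = paste0(codons[cur], collapse = ""),
                      stringsAsFactors = FALSE),
    events = list(n_syn = n_syn, n_nonsyn = n_nonsyn, proposals = proposals,
                  S_ancestor = S_anc),
    config = config
  )
}
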