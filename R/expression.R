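# Whole-genome expression profiling: per-gene metatranscript and metagenome
# read counting above the population identity threshold, the two
# normalization schemes (single-copy housekeeping genes; depth-scaled MT/MG
# ratio), gene-cluster aggregation and cross-sample regression.

# Shared per-gene counter: a read contributes to a gene iff its identity is
# strictly above the population threshold and its subject interval overlaps
# the gene by >= 1 bp (a read spanning two genes counts once for each).
count_reads_per_gene <- function(assigned, annotations, cfg = filter_config(),
                                 genome_map = NULL) {
  genes <- annotations[annotations$feature_kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene annotations supplied")
  gid_of_seq <- function(seq_id) {
    if (is.null(genome_map)) return(seq_id)
    g <- genome_map[seq_id]
    if (anyNA(g)) stop("seq_id missing from genome_map")
    unname(g)
  }
  genes$genome_id <- gid_of_seq(genes$seq_id)
  use <- assigned[!is.na(assigned$genome_id) &
                    assigned$pident > cfg$population_identity, , drop = FALSE]
  counts <- integer(nrow(genes))
  for (g in unique(genes$genome_id)) {
    gsel <- which(genes$genome_id == g)
    rsel <- which(use$genome_id == g)
    if (!length(rsel)) next
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(start = genes$start[gsel] + 1L, end = genes$end[gsel]),
      IRanges::IRanges(start = use$sstart[rsel], end = use$send[rsel])
    )
    counts[gsel] <- ov
  }
  data.frame(genome_id = genes$genome_id, gene_id = genes$gene_id,
             count = counts, stringsAsFactors = FALSE)
}

#' Count metatranscripts covering each gene
#'
#' Counts competitively assigned MT reads per annotated gene: a read counts
#' for a gene when its identity is strictly above the population threshold
#' (95% by default) and its alignment overlaps the gene interval by at
#' least 1 bp. Reads overlapping several genes count once for each; genes
#' with no reads are kept with a zero.
#'
#' @param assigned Assigned MT records (see [competitive_assign()]).
#' @param annotations Annotation data frame.
#' @param cfg A [filter_config()] (supplies the population threshold).
#' @param genome_map Optional `seq_id` to genome map.
#' @return Data frame `(genome_id, gene_id, mt_count)`.
#' @export
count_transcripts_per_gene <- function(assigned, annotations,
                                       cfg = filter_config(),
                                       genome_map = NULL) {
  out <- count_reads_per_gene(assigned, annotations, cfg, genome_map)
  names(out)[names(out) == "count"] <- "mt_count"
  out
}

#' Count metagenomic reads covering each gene
#'
#' Same contract as [count_transcripts_per_gene()], applied to the paired
#' metagenome sample.
#'
#' @inheritParams count_transcripts_per_gene
#' @return Data frame `(genome_id, gene_id, mg_count)`.
#' @export
count_metagenome_per_gene <- function(assigned, annotations,
                                      cfg = filter_config(),
                                      genome_map = NULL) {
  out <- count_reads_per_gene(assigned, annotations, cfg, genome_map)
  names(out)[names(out) == "count"] <- "mg_count"
  out
}

#' Merge MT and MG per-gene counts into one table
#'
#' @param mt Output of [count_transcripts_per_gene()].
#' @param mg Output of [count_metagenome_per_gene()].
#' @return Data frame `(genome_id, gene_id, mt_count, mg_count)`.
#' @export
gene_count_table <- function(mt, mg) {
  out <- merge(mt, mg, by = c("genome_id", "gene_id"), all = TRUE,
               sort = TRUE)
  out$mt_count[is.na(out$mt_count)] <- 0L
  out$mg_count[is.na(out$mg_count)] <- 0L
  out
}

#' Normalize transcript counts by single-copy housekeeping genes
#'
#' Per-cell expression proxy: each gene's MT count divided by a summary
#' (mean by default) of the MT counts of single-copy housekeeping genes
#' (recA and gyrB), computed per genome. A zero denominator flags all
#' values of that genome as missing rather than raising a division error.
#'
#' @param counts Data frame with `genome_id`, `gene_id`, `mt_count`.
#' @param hk_gene_ids Housekeeping gene ids (must be annotated/counted).
#' @param stat Denominator summary: `"mean"` (default), `"sum"` or
#'   `"geometric"`.
#' @return `counts` with an added `per_cell` column (`NA` when missing).
#' @export
normalize_by_housekeeping <- function(counts, hk_gene_ids = c("recA", "gyrB"),
                                      stat = c("mean", "sum", "geometric")) {
  stat <- match.arg(stat)
  counts$per_cell <- NA_real_
  for (g in unique(counts$genome_id)) {
    sel <- counts$genome_id == g
    hk <- counts$mt_count[sel][match(hk_gene_ids, counts$gene_id[sel])]
    if (anyNA(hk)) {
      stop("housekeeping gene '",
           hk_gene_ids[is.na(hk)][1L], "' absent for genome ", g)
    }
    denom <- switch(stat,
                    mean = mean(hk),
                    sum = sum(hk),
                    geometric = exp(mean(log(hk))))
    if (is.na(denom) || denom <= 0) next  # flagged missing
    counts$per_cell[sel] <- counts$mt_count[sel] / denom
  }
  counts
}

#' Normalize transcript counts by metagenomic gene counts and depth
#'
#' Depth-scaled MT/MG ratio:
#' `mg_norm(g) = (mt_count(g)/mt_depth) / (mg_count(g)/mg_depth)`.
#' Genes with zero MG reads are flagged missing (`NA`).
#'
#' @param counts Data frame with `mt_count` and `mg_count`.
#' @param mt_depth,mg_depth Sequencing depths (total reads) of the MT and MG
#'   samples; must be positive.
#' @return `counts` with an added `mg_norm` column.
#' @export
normalize_by_metagenome <- function(counts, mt_depth, mg_depth) {
  if (mt_depth <= 0 || mg_depth <= 0) stop("sequencing depths must be > 0")
  mg_norm <- (counts$mt_count / mt_depth) / (counts$mg_count / mg_depth)
  mg_norm[counts$mg_count == 0] <- NA_real_
  counts$mg_norm <- mg_norm
  counts
}

#' Aggregate transcript counts into gene clusters
#'
#' Sums MT counts per cluster label and reports each cluster's relative
#' contribution as a percentage of the genome's total MT count over ALL
#' genes (labeled or not), so contributions sum to at most 100.
#'
#' @param counts Data frame with `genome_id`, `gene_id`, `mt_count`.
#' @param cluster_map Data frame `(gene_id, cluster_label)`; a gene may
#'   belong to at most one cluster.
#' @return Data frame `(genome_id, cluster_label, transcript_count,
#'   relative_contribution)`.
#' @export
aggregate_clusters <- function(counts, cluster_map) {
  cm <- unique(cluster_map[!is.na(cluster_map$cluster_label) &
                             nzchar(cluster_map$cluster_label),
                           c("gene_id", "cluster_label")])
  if (anyDuplicated(cm$gene_id)) {
    stop("gene '", cm$gene_id[duplicated(cm$gene_id)][1L],
         "' assigned to more than one cluster")
  }
  labels <- unique(cm$cluster_label)
  out <- list()
  for (g in unique(counts$genome_id)) {
    sel <- counts[counts$genome_id == g, , drop = FALSE]
    total <- sum(sel$mt_count)
    lab_of <- cm$cluster_label[match(sel$gene_id, cm$gene_id)]
    for (lab in labels) {
      cnt <- sum(sel$mt_count[!is.na(lab_of) & lab_of == lab])
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g, cluster_label = lab, transcript_count = cnt,
        relative_contribution = if (total > 0) 100 * cnt / total else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Regress a cluster's transcript counts on the nif operon's across samples
#'
#' Ordinary least squares of another cluster's per-sample transcript counts
#' on the nitrogen-fixation operon's, with a two-sided t-test on the slope
#' (n - 2 degrees of freedom).
#'
#' @param nif_counts Per-sample nif operon transcript counts (x).
#' @param other_counts Per-sample counts of the other cluster (y).
#' @return Object of class `cluster_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
regress_clusters <- function(nif_counts, other_counts) {
  n <- length(nif_counts)
  if (n != length(other_counts)) stop("count vectors differ in length")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::var(nif_counts) == 0) stop("zero variance in nif counts")
  if (stats::var(other_counts) == 0) {
    # degenerate flat response: slope 0, no explained variance
    return(structure(list(slope = 0, intercept = other_counts[1L],
                          r_squared = 0, p_value = 1, n = n),
                     class = "cluster_regression"))
  }
  fit <- stats::lm(other_counts ~ nif_counts)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = max(sm$coefficients[2L, 4L],
                               .Machine$double.xmin), n = n),
            class = "cluster_regression")
}

#' @export
print.cluster_regression <- function(x, ...) {
  cat(sprintf("Cluster regression (n = %d): y = %.4g + %.4g x,  R^2 = %.4f,  P = %.3g\n",
              x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
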