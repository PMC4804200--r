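#' Read a FASTA file into a sequence table
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns a plain data frame with
#' one row per record. Residues are uppercased. Characters outside
#' `{A,C,G,T,N}` are either rejected or mapped to `N` depending on
#' `ambiguous`.
#'
#' @param path Path to a FASTA file.
#' @param ambiguous Either `"reject"` (default: any residue outside ACGTN is
#'   an error, naming the offending record) or `"mask"` (such residues are
#'   replaced by `N`).
#' @return A data frame with columns `id`, `description` and `residues`
#'   (one DNA string per record), in file order.
#' @export
read_fasta <- function(path, ambiguous = c("reject", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  if (any(!nzchar(ids))) stop("empty FASTA header in ", path)
  if (any(!nzchar(residues))) {
    stop("empty sequence for record '", ids[!nzchar(residues)][1L], "' in ", path)
  }
  bad <- grepl("[^ACGTN]", residues)
  if (any(bad)) {
    if (ambiguous == "reject") {
      stop("non-ACGTN residues in record '", ids[bad][1L], "' in ", path)
    }
    residues[bad] <- gsub("[^ACGTN]", "N", residues[bad])
  }
  data.frame(id = ids, description = desc, residues = residues,
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param seqs Data frame with columns `id`, `residues` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(seqs$residues)
  desc <- if ("description" %in% names(seqs)) seqs$description else
    rep("", nrow(seqs))
  names(set) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read 12-column tabular read-vs-genome alignments
#'
#' Parses the standard 12-column tab-separated local-alignment format
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) as emitted by BLAST+ with `-outfmt 6`. Subject
#' coordinates are normalized to subject-forward order (`sstart <= send`)
#' with the original orientation kept in a `strand` column; a `genome_id`
#' column is resolved from `sseqid` through an explicit contig-to-genome map.
#'
#' @param path Path to the tab-separated alignment file.
#' @param genome_map Named character vector mapping each `sseqid` (contig) to
#'   a genome identifier, or a two-column data frame `(sseqid, genome_id)`.
#' @return Data frame with the 12 standard columns plus `strand` and
#'   `genome_id`; subject coordinates 1-based inclusive, subject-forward.
#' @export
read_tabular_alignments <- function(path, genome_map) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_alignment_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 12L)) {
    stop("line ", which(ncols < 12L)[1L], " of ", path,
         " has ", ncols[ncols < 12L][1L], " columns; expected >= 12")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x)) {
      stop("unparsable ", what, " at line ", which(is.na(x))[1L], " of ", path)
    }
    x
  }
  rec <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = num(3L, "pident"), length = as.integer(num(4L, "length")),
    mismatch = as.integer(num(5L, "mismatch")),
    gapopen = as.integer(num(6L, "gapopen")),
    qstart = as.integer(num(7L, "qstart")), qend = as.integer(num(8L, "qend")),
    sstart = as.integer(num(9L, "sstart")), send = as.integer(num(10L, "send")),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(rec$qstart > rec$qend)) stop("qstart > qend at line ",
                                       which(rec$qstart > rec$qend)[1L])
  if (any(rec$pident < 0 | rec$pident > 100)) stop("pident outside [0,100]")
  if (any(rec$evalue < 0)) stop("negative evalue")
  rec$strand <- ifelse(rec$sstart > rec$send, "-", "+")
  lo <- pmin(rec$sstart, rec$send)
  hi <- pmax(rec$sstart, rec$send)
  rec$sstart <- lo
  rec$send <- hi
  rec$genome_id <- resolve_genome_ids(rec$sseqid, genome_map)
  rec
}

empty_alignment_table <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             strand = character(), genome_id = character(),
             stringsAsFactors = FALSE)
}

resolve_genome_ids <- function(sseqid, genome_map) {
  if (is.data.frame(genome_map)) {
    stopifnot(ncol(genome_map) >= 2L)
    genome_map <- stats::setNames(as.character(genome_map[[2L]]),
                                  as.character(genome_map[[1L]]))
  }
  stopifnot(is.character(genome_map), !is.null(names(genome_map)))
  gid <- unname(genome_map[sseqid])
  if (anyNA(gid)) {
    stop("sseqid '", sseqid[is.na(gid)][1L], "' not present in genome map")
  }
  gid
}

#' Read gene/rRNA/ITS annotations from GFF3 or BED
#'
#' Both dialects are converted to the package-internal 0-based half-open
#' convention: GFF3 records are 1-based inclusive on file, BED records are
#' already 0-based half-open. Feature kinds are restricted to `gene`, `rRNA`
#' and `ITS`. For GFF3 the cluster label is taken from the attribute named by
#' `cluster_attr`; for BED it is taken from optional column 8 (column 7, when
#' present, holds the feature kind, defaulting to `gene`).
#'
#' @param path Annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param genome_lengths Optional named vector of sequence lengths; when
#'   supplied, coordinates beyond the sequence end are an error.
#' @param cluster_attr GFF3 attribute key carrying the gene-cluster label.
#' @return Data frame with columns `seq_id`, `feature_kind`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`, `cluster_label` (`NA` when
#'   absent).
#' @export
read_annotations <- function(path, dialect = c("gff3", "bed"),
                             genome_lengths = NULL, cluster_attr = "cluster") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gff3") {
    g <- rtracklayer::readGFF(path)
    ann <- data.frame(
      seq_id = as.character(g$seqid),
      feature_kind = as.character(g$type),
      start = as.integer(g$start) - 1L,   # to 0-based half-open
      end = as.integer(g$end),
      strand = as.character(g$strand),
      gene_id = as.character(g$ID),
      cluster_label = if (cluster_attr %in% names(g))
        as.character(g[[cluster_attr]]) else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(bed) < 4L) stop("BED file needs >= 4 columns: ", path)
    ann <- data.frame(
      seq_id = as.character(bed[[1L]]),
      feature_kind = if (ncol(bed) >= 7L) as.character(bed[[7L]]) else "gene",
      start = as.integer(bed[[2L]]),
      end = as.integer(bed[[3L]]),
      strand = if (ncol(bed) >= 6L) as.character(bed[[6L]]) else "+",
      gene_id = as.character(bed[[4L]]),
      cluster_label = if (ncol(bed) >= 8L) as.character(bed[[8L]]) else
        NA_character_,
      stringsAsFactors = FALSE
    )
  }
  ann$cluster_label[!is.na(ann$cluster_label) & !nzchar(ann$cluster_label)] <-
    NA_character_
  bad_kind <- !ann$feature_kind %in% c("gene", "rRNA", "ITS")
  if (any(bad_kind)) {
    stop("unsupported feature kind '", ann$feature_kind[bad_kind][1L],
         "' in ", path, " (expected gene, rRNA or ITS)")
  }
  if (any(ann$end <= ann$start)) stop("annotation with end <= start in ", path)
  if (any(ann$start < 0L)) stop("negative coordinate in ", path)
  if (!is.null(genome_lengths)) {
    len <- genome_lengths[ann$seq_id]
    if (anyNA(len)) stop("annotation on unknown sequence '",
                         ann$seq_id[is.na(len)][1L], "'")
    if (any(ann$end > len)) {
      stop("annotation beyond sequence end for gene '",
           ann$gene_id[ann$end > len][1L], "'")
    }
  }
  genes <- ann[ann$feature_kind == "gene", ]
  if (anyDuplicated(paste(genes$seq_id, genes$gene_id))) {
    stop("duplicate gene_id on one sequence in ", path)
  }
  ann
}

#' Write annotations to GFF3
#'
#' Inverse of [read_annotations()] for the GFF3 dialect: internal 0-based
#' half-open coordinates are converted back to 1-based inclusive.
#'
#' @param ann Annotation data frame (see [read_annotations()]).
#' @param path Output path.
#' @param cluster_attr Attribute key used for the cluster label.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(ann, path, cluster_attr = "cluster") {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seq_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$type <- ann$feature_kind
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)[[cluster_attr]] <- ann$cluster_label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write result tables as TSV files with a manifest
#'
#' Writes each table as `<name>.tsv` under `out_dir` with a deterministic
#' column order (as given) and fixed floating-point precision, so identical
#' inputs produce byte-identical files.
#'
#' @param tables Named list of data frames; names become file stems.
#' @param out_dir Output directory (created if missing).
#' @param digits Number of significant digits for numeric columns.
#' @return Data frame manifest with columns `file` and `n_rows`.
#' @export
write_results <- function(tables, out_dir, digits = 6L) {
  if (!is.list(tables) || length(tables) == 0L || is.null(names(tables)) ||
      any(!nzchar(names(tables)))) {
    stop("'tables' must be a non-empty named list of data frames")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(is.data.frame(tab))
    out <- tab
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
      }
    }
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    files <- c(files, basename(f))
    rows <- c(rows, nrow(tab))
  }
  data.frame(file = files, n_rows = rows, stringsAsFactors = FALSE)
}
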