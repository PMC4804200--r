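# End-to-end orchestration from one YAML config: simulate (optional) ->
# recruit -> expression -> selection, with deterministic per-stage seeds
# derived from a single global seed and a run manifest listing every
# emitted file.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "symbiorecruit_out",
    filter = list(min_pident = 50, max_evalue = 1e-4,
                  min_query_coverage = 0.90, population_identity = 95,
                  histogram_lo = 70, histogram_hi = 100, histogram_step = 1),
    expression = list(hk_genes = c("recA", "gyrB"), hk_stat = "mean"),
    selection = list(B = 1000L, alpha = 0.05)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent list), fills defaults
#' (filter 50 / 1e-4 / 0.90 / 95, histogram 70-100 x 1, B = 1000,
#' alpha = 0.05), rejects unknown keys and reports all validation errors at
#' once rather than stopping at the first.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Normalized config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  errors <- character(0)
  known_top <- c("seed", "out_dir", "simulate", "inputs", "filter",
                 "expression", "selection", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  def <- pipeline_defaults()
  cfg <- utils::modifyList(def, config[names(config) %in% known_top])

  f <- cfg$filter
  known_f <- names(def$filter)
  unknown <- setdiff(names(f), known_f)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown filter key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  num_in <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    !is.na(x) && x >= lo && x <= hi
  if (!num_in(f$min_pident, 0, 100)) {
    errors <- c(errors, "filter$min_pident must be in [0, 100]")
  }
  if (!num_in(f$min_query_coverage, 1e-12, 1)) {
    errors <- c(errors, "filter$min_query_coverage must be in (0, 1]")
  }
  if (!num_in(f$population_identity, 0, 100)) {
    errors <- c(errors, "filter$population_identity must be in [0, 100]")
  } else if (num_in(f$min_pident, 0, 100) &&
             f$population_identity < f$min_pident) {
    errors <- c(errors, "filter$population_identity below filter$min_pident")
  }
  if (!num_in(f$max_evalue, 0, Inf)) {
    errors <- c(errors, "filter$max_evalue must be >= 0")
  }
  if (!num_in(cfg$selection$alpha, 1e-12, 1)) {
    errors <- c(errors, "selection$alpha must be in (0, 1]")
  }
  if (!num_in(cfg$selection$B, 1, Inf)) {
    errors <- c(errors, "selection$B must be a positive integer")
  }
  if (!num_in(cfg$seed, -2^31 + 1, 2^31 - 1)) {
    errors <- c(errors, "seed must be an integer")
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    errors <- c(errors, "config needs either a 'simulate' or an 'inputs' block")
  }
  if (!is.null(cfg$inputs)) {
    for (key in c("alignments", "annotations")) {
      p <- cfg$inputs[[key]]
      if (is.null(p)) {
        errors <- c(errors, paste0("inputs$", key, " is required"))
      } else if (!file.exists(p)) {
        errors <- c(errors, paste0("inputs$", key, " not found: ", p))
      }
    }
    if (is.null(cfg$inputs$genome_lengths)) {
      errors <- c(errors, "inputs$genome_lengths is required")
    }
  }
  if (!is.null(cfg$simulate)) {
    smp <- cfg$simulate$samples
    if (is.null(smp) || !length(smp)) {
      errors <- c(errors, "simulate$samples must list at least one sample")
    } else {
      for (i in seq_along(smp)) {
        s <- smp[[i]]
        if (is.null(s$name) || is.null(s$mode) || is.null(s$n_reads)) {
          errors <- c(errors,
                      sprintf("simulate$samples[[%d]] needs name, mode, n_reads", i))
        } else if (!s$mode %in% c("MG", "MT")) {
          errors <- c(errors,
                      sprintf("simulate$samples[[%d]]$mode must be MG or MT", i))
        }
      }
    }
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the whole pipeline from one configuration
#'
#' Executes simulate (when a `simulate` block is present) -> recruit (per
#' sample) -> expression -> selection, writing TSV outputs and a manifest
#' under `out_dir`. Per-stage seeds are derived deterministically from the
#' single global seed, so an identical config produces byte-identical
#' outputs. A stage failure aborts with the failing stage named; files
#' already written are retained and the manifest carries a FAILED marker.
#'
#' @param config Path to a YAML config or a list (see [validate_config()]).
#' @return Invisibly, a `run_manifest` object: list with `files` (data
#'   frame: stage, file, n_rows) and `config`.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- data.frame(stage = character(), file = character(),
                      n_rows = integer(), stringsAsFactors = FALSE)
  add <- function(stage, manifest) {
    files <<- rbind(files, data.frame(stage = stage, file = manifest$file,
                                      n_rows = manifest$n_rows,
                                      stringsAsFactors = FALSE))
  }
  fcfg <- do.call(filter_config, cfg$filter)
  stage <- "validate"
  result <- try({
    samples <- list()       # per sample: alignments, read_lengths, mode, depth
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      message("[simulate] building synthetic community")
      ccfg_args <- cfg$simulate$community
      if (is.null(ccfg_args)) ccfg_args <- list()
      ccfg_args$seed <- derive_seed(cfg$seed, 1L)
      community <- do.call(community_config, ccfg_args)
      com <- simulate_genome_pair(community)
      write_fasta(data.frame(id = names(com$genomes),
                             residues = unlist(com$genomes),
                             stringsAsFactors = FALSE),
                  file.path(out_dir, "genomes.fasta"))
      write_annotations_gff3(com$annotations,
                             file.path(out_dir, "annotations.gff3"))
      annotations <- com$annotations
      genome_lengths <- stats::setNames(
        rep(com$genome_length, length(com$genomes)), names(com$genomes))
      for (i in seq_along(cfg$simulate$samples)) {
        s <- cfg$simulate$samples[[i]]
        lw <- if (is.null(s$lineage_weights)) c(A = 0.5, B = 0.5) else
          unlist(s$lineage_weights)
        ew <- if (s$mode == "MT")
          default_expression_weights(annotations) else NULL
        rcfg <- read_sim_config(
          n_reads = s$n_reads, mode = s$mode,
          read_length = if (is.null(s$read_length)) 100L else s$read_length,
          lineage_weights = lw,
          error_rate = if (is.null(s$error_rate)) 0.005 else s$error_rate,
          expression_weights = ew,
          seed = derive_seed(cfg$seed, 100L + i)
        )
        sim <- simulate_reads(com, rcfg)
        write_fasta(sim$reads,
                    file.path(out_dir, paste0(s$name, "_reads.fasta")))
        add("simulate", write_results(
          stats::setNames(list(sim$truth, sim$truth_alignments),
                          paste0(s$name, c("_truth", "_truth_alignments"))),
          out_dir))
        samples[[s$name]] <- list(
          alignments = sim$truth_alignments,
          read_lengths = stats::setNames(rep(rcfg$read_length,
                                             nrow(sim$reads)),
                                         sim$reads$id),
          mode = s$mode, depth = s$n_reads
        )
      }
      message(sprintf("[simulate] %d samples, realized divergence %.4f",
                      length(samples), com$divergence_realized))
    } else {
      stage <- "load"
      annotations <- read_annotations(cfg$inputs$annotations, dialect = "gff3")
      genome_lengths <- unlist(cfg$inputs$genome_lengths)
      gmap <- if (!is.null(cfg$inputs$genome_map)) {
        gm <- utils::read.table(cfg$inputs$genome_map, sep = "\t",
                                header = FALSE, stringsAsFactors = FALSE)
        stats::setNames(gm[[2L]], gm[[1L]])
      } else {
        stats::setNames(names(genome_lengths), names(genome_lengths))
      }
      aln <- read_tabular_alignments(cfg$inputs$alignments, gmap)
      reads <- read_fasta(cfg$inputs$reads)
      samples[["sample"]] <- list(
        alignments = aln,
        read_lengths = stats::setNames(nchar(reads$residues), reads$id),
        mode = if (is.null(cfg$inputs$mode)) "MG" else cfg$inputs$mode,
        depth = nrow(reads)
      )
    }

    stage <- "recruit"
    masks <- masks_from_annotations(annotations)
    recruited <- list()
    for (nm in names(samples)) {
      s <- samples[[nm]]
      rr <- recruit_sample(s$alignments, s$read_lengths, genome_lengths,
                           masks = masks, cfg = fcfg)
      recruited[[nm]] <- rr
      lg <- rr$filter_log
      message(sprintf(
        "[recruit] %s: input %d, removed identity=%d evalue=%d coverage=%d mask=%d, retained %d, ambiguous %d",
        nm, lg[["input"]], lg[["identity"]], lg[["evalue"]],
        lg[["coverage"]], lg[["mask"]], lg[["retained"]], rr$n_ambiguous))
      hist_tab <- do.call(rbind, lapply(names(rr$histograms), function(g) {
        h <- rr$histograms[[g]]
        rbind(data.frame(genome_id = g, bin_lo = NA_real_,
                         bin_hi = fcfg$histogram_lo, count = h$underflow),
              data.frame(genome_id = g, h$bins))
      }))
      flog <- data.frame(rule = names(rr$filter_log),
                         count = as.integer(rr$filter_log),
                         stringsAsFactors = FALSE)
      add("recruit", write_results(
        stats::setNames(list(rr$summary, hist_tab, rr$assigned, flog),
                        paste0(nm, c("_recruitment_summary", "_histogram",
                                     "_assigned_reads", "_filter_log"))),
        out_dir))
    }

    mt_names <- names(samples)[vapply(samples, function(s) s$mode == "MT",
                                      TRUE)]
    mg_names <- names(samples)[vapply(samples, function(s) s$mode == "MG",
                                      TRUE)]
    if (length(mt_names) && length(mg_names)) {
      stage <- "expression"
      mt_nm <- if (!is.null(cfg$expression$mt_sample))
        cfg$expression$mt_sample else mt_names[1L]
      mg_nm <- if (!is.null(cfg$expression$mg_sample))
        cfg$expression$mg_sample else mg_names[1L]
      amt <- recruited[[mt_nm]]$assigned
      amg <- recruited[[mg_nm]]$assigned
      mt_counts <- count_transcripts_per_gene(
        amt[!amt$ambiguous, ], annotations, fcfg)
      mg_counts <- count_metagenome_per_gene(
        amg[!amg$ambiguous, ], annotations, fcfg)
      tab <- gene_count_table(mt_counts, mg_counts)
      tab <- normalize_by_housekeeping(tab,
                                       hk_gene_ids = cfg$expression$hk_genes,
                                       stat = cfg$expression$hk_stat)
      tab <- normalize_by_metagenome(tab, samples[[mt_nm]]$depth,
                                     samples[[mg_nm]]$depth)
      cmap <- unique(annotations[annotations$feature_kind == "gene",
                                 c("gene_id", "cluster_label")])
      clust <- aggregate_clusters(tab, cmap)
      message(sprintf("[expression] %.0f genes counted (MT %s vs MG %s)",
                      nrow(tab) / length(genome_lengths), mt_nm, mg_nm))
      add("expression", write_results(
        list(gene_counts = tab, cluster_summary = clust), out_dir))

      if (length(mt_names) >= 3L) {
        per_sample <- lapply(mt_names, function(nm) {
          a <- recruited[[nm]]$assigned
          cc <- count_transcripts_per_gene(a[!a$ambiguous, ], annotations,
                                           fcfg)
          names(cc)[names(cc) == "mt_count"] <- "mt_count"
          ag <- aggregate_clusters(
            stats::setNames(cc, c("genome_id", "gene_id", "mt_count")), cmap)
          tot <- stats::aggregate(transcript_count ~ cluster_label, ag, sum)
          stats::setNames(tot$transcript_count, tot$cluster_label)
        })
        clusters <- names(per_sample[[1L]])
        nif <- vapply(per_sample, `[[`, 0, "nif_operon")
        reg_rows <- lapply(setdiff(clusters, c("nif_operon", "housekeeping")),
                           function(cl) {
          y <- vapply(per_sample, `[[`, 0, cl)
          r <- regress_clusters(nif, y)
          data.frame(cluster_label = cl, slope = r$slope,
                     intercept = r$intercept, r_squared = r$r_squared,
                     p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
        })
        add("expression", write_results(
          list(regression = do.call(rbind, reg_rows)), out_dir))
      }
    }

    if (!is.null(cfg$selection$n_pairs)) {
      stage <- "selection"
      sc <- cfg$selection
      pairs <- do.call(rbind, lapply(seq_len(sc$n_pairs), function(k) {
        sim <- simulate_codon_pair(codon_sim_config(
          n_codons = if (is.null(sc$n_codons)) 300L else sc$n_codons,
          omega = if (is.null(sc$omega)) 0.2 else sc$omega,
          expected_dS = if (is.null(sc$expected_dS)) 0.3 else sc$expected_dS,
          seed = derive_seed(cfg$seed, 1000L + k)
        ))
        p <- sim$pair
        p$gene_id <- sprintf("pair_%04d", k)
        p
      }))
      scr <- kaks_screen(pairs, B = sc$B, seed = derive_seed(cfg$seed, 2000L),
                         alpha = sc$alpha)
      s <- scr$summary
      message(sprintf(
        "[selection] %d pairs: purifying %d, positive %d, not significant %d",
        s$n_genes, s$n_purifying_significant, s$n_positive_significant,
        s$n_not_significant))
      add("selection", write_results(list(
        kaks_results = scr$results,
        selection_summary = data.frame(
          n_genes = s$n_genes,
          n_purifying_significant = s$n_purifying_significant,
          n_positive_significant = s$n_positive_significant,
          n_not_significant = s$n_not_significant,
          alpha = s$alpha)
      ), out_dir))
    }
    "OK"
  }, silent = TRUE)

  status <- if (inherits(result, "try-error")) "FAILED" else "OK"
  manifest <- list(files = files, config = unclass(cfg), status = status,
                   failed_stage = if (status == "FAILED") stage else NA)
  utils::write.table(
    cbind(files, status = status), file.path(out_dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_echo.yaml"))
  if (status == "FAILED") {
    stop("pipeline failed in stage '", stage, "': ",
         attr(result, "condition")$message)
  }
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest (", x$status, ")\n", sep = "")
  cat(sprintf("  %d files written under %s\n", nrow(x$files),
              x$config$out_dir))
  print(x$files, row.names = FALSE)
  invisible(x)
}
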