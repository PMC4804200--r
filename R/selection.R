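# Nei-Gojobori (1986) Ka/Ks machinery: per-codon synonymous/nonsynonymous
# site fractions and pathway-averaged difference counts, precomputed once as
# lookup tables over the 64 codons / 64x64 codon pairs under the standard
# genetic code.

.codon_cache <- new.env(parent = emptyenv())

CODON_BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic index order
#' @return Character vector of length 64.
#' @keywords internal
all_codons <- function() {
  paste0(rep(CODON_BASES, each = 16L),
         rep(rep(CODON_BASES, each = 4L), 4L),
         rep(CODON_BASES, 16L))
}

codon_index <- function(codons) match(codons, all_codons())

codon_aa <- function() {
  unname(Biostrings::GENETIC_CODE[all_codons()])
}

# Build and cache: per-codon site fractions, 64x64 pathway-averaged
# difference tables, and per-codon single-mutation tables used by the
# simulator.
ng86_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  codons <- all_codons()
  aa <- codon_aa()
  is_stop <- aa == "*"
  chars <- do.call(rbind, strsplit(codons, ""))

  # mutants[i, p, b]: index of codon i with position p set to base b
  mutant_idx <- array(NA_integer_, dim = c(64L, 3L, 4L))
  for (p in 1:3) {
    for (b in 1:4) {
      mut <- chars
      mut[, p] <- CODON_BASES[b]
      mutant_idx[, p, b] <- codon_index(paste0(mut[, 1], mut[, 2], mut[, 3]))
    }
  }

  # the 9 single-nucleotide mutants of each codon (simulator proposal set)
  mut9 <- matrix(NA_integer_, 64L, 9L)
  for (i in 1:64) {
    ms <- integer(0)
    for (p in 1:3) {
      for (b in 1:4) {
        j <- mutant_idx[i, p, b]
        if (j != i) ms <- c(ms, j)
      }
    }
    mut9[i, ] <- ms
  }

  # NG86 site fractions: each position contributes (# synonymous changes)/3;
  # changes to stop codons count as nonsynonymous.
  s_sites <- rep(NA_real_, 64L)
  n_stop_mut <- rep(NA_integer_, 64L)
  for (i in which(!is_stop)) {
    s <- 0
    nstop <- 0L
    for (p in 1:3) {
      for (b in 1:4) {
        j <- mutant_idx[i, p, b]
        if (j == i) next
        if (is_stop[j]) nstop <- nstop + 1L
        else if (aa[j] == aa[i]) s <- s + 1 / 3
      }
    }
    s_sites[i] <- s
    n_stop_mut[i] <- nstop
  }

  # Pathway-averaged (sd, nd) for every ordered codon pair of sense codons.
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  sd_tab <- matrix(0, 64L, 64L)
  nd_tab <- matrix(0, 64L, 64L)
  allstop_tab <- matrix(FALSE, 64L, 64L)  # every pathway hits a stop codon
  for (i in which(!is_stop)) {
    for (j in which(!is_stop)) {
      if (i == j) next
      diffpos <- which(chars[i, ] != chars[j, ])
      k <- length(diffpos)
      paths <- perms[[as.character(k)]]
      path_sd <- numeric(0)
      path_nd <- numeric(0)
      path_ok <- logical(0)
      for (ord in paths) {
        cur <- i
        sd <- 0
        nd <- 0
        ok <- TRUE
        for (step in ord) {
          p <- diffpos[step]
          b <- match(chars[j, p], CODON_BASES)
          nxt <- mutant_idx[cur, p, b]
          if (is_stop[nxt]) { ok <- FALSE }
          if (aa[nxt] == aa[cur]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        path_sd <- c(path_sd, sd)
        path_nd <- c(path_nd, nd)
        path_ok <- c(path_ok, ok)
      }
      if (any(path_ok)) {
        sd_tab[i, j] <- mean(path_sd[path_ok])
        nd_tab[i, j] <- mean(path_nd[path_ok])
      } else {
        # all orderings pass through a stop: fall back to uniform weighting
        sd_tab[i, j] <- mean(path_sd)
        nd_tab[i, j] <- mean(path_nd)
        allstop_tab[i, j] <- TRUE
      }
    }
  }

  .codon_cache$tables <- list(
    codons = codons, aa = aa, is_stop = is_stop,
    mutant_idx = mutant_idx, mut9 = mut9, s_sites = s_sites,
    n_stop_mut = n_stop_mut,
    sd = sd_tab, nd = nd_tab, allstop = allstop_tab
  )
  .codon_cache$tables
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori site counting under the standard genetic code: each of the
#' nine single-nucleotide mutants of the codon is classified as synonymous or
#' nonsynonymous (mutants that are stop codons count as nonsynonymous), and
#' each codon position contributes the synonymous fraction of its three
#' possible changes.
#'
#' @param codon Three-letter string over `{A,C,G,T}`; must not be a stop
#'   codon.
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n == 3`.
#' @examples
#' codon_sites("TTT")  # s = 1/3
#' codon_sites("ATG")  # s = 0 (Met has no synonym)
#' @export
codon_sites <- function(codon) {
  tab <- ng86_tables()
  i <- codon_index(toupper(codon))
  if (is.na(i)) stop("codon '", codon, "' contains non-ACGT characters")
  if (tab$is_stop[i]) stop("codon '", codon, "' is a stop codon")
  s <- tab$s_sites[i]
  c(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' For codons differing at `k` positions, the `k!` substitution orderings are
#' enumerated; each step is classified synonymous or nonsynonymous and the
#' counts are averaged uniformly over the orderings. Orderings passing
#' through a stop codon are excluded and the remainder re-weighted; if every
#' ordering passes through a stop, all orderings are weighted uniformly and
#' the result flagged.
#'
#' @param codon1,codon2 Sense codons over `{A,C,G,T}`.
#' @return Named numeric vector `c(sd = ..., nd = ...)`; the attribute
#'   `all_paths_through_stop` is `TRUE` when the fallback weighting was used.
#' @examples
#' count_differences("TTT", "TTA")  # (0, 1): Phe -> Leu
#' count_differences("TTT", "GTA")  # (0.5, 1.5): average of two pathways
#' @export
count_differences <- function(codon1, codon2) {
  tab <- ng86_tables()
  i <- codon_index(toupper(codon1))
  j <- codon_index(toupper(codon2))
  if (is.na(i) || is.na(j)) stop("codon with non-ACGT characters")
  if (tab$is_stop[i] || tab$is_stop[j]) stop("stop codon in comparison")
  out <- c(sd = tab$sd[i, j], nd = tab$nd[i, j])
  attr(out, "all_paths_through_stop") <- tab$allstop[i, j]
  out
}

# Split an in-frame sequence into codon index vector; non-ACGT codons -> NA.
codon_indices <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  codon_index(substring(seq, seq(1L, n, 3L), seq(3L, n, 3L)))
}

#' Nei-Gojobori Ka/Ks estimate for one in-frame codon pair alignment
#'
#' Computes synonymous (`S`) and nonsynonymous (`N`) site counts averaged
#' over the two sequences, pathway-averaged difference counts (`Sd`, `Nd`),
#' the proportions `pS = Sd/S` and `pN = Nd/N`, and Jukes-Cantor corrected
#' distances `dS` (Ks) and `dN` (Ka), `d = -(3/4) log(1 - (4/3) p)`. Codons
#' containing gaps, ambiguous bases or stop codons in either sequence are
#' skipped. `p >= 3/4` is flagged as saturated (distance undefined);
#' `dS == 0` leaves `omega` undefined.
#'
#' @param seq1,seq2 In-frame DNA strings of equal length divisible by 3.
#' @param gene_id Optional identifier carried into the result.
#' @return Object of class `kaks_result`: a list with fields `gene_id`, `S`,
#'   `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons` (compared),
#'   `flags`, and per-codon vectors (`codon_s`, `codon_sd`, `codon_nd`) used
#'   by the bootstrap Z-test.
#' @export
kaks <- function(seq1, seq2, gene_id = NA_character_) {
  if (nchar(seq1) != nchar(seq2)) stop("sequences must have equal length")
  tab <- ng86_tables()
  i1 <- codon_indices(seq1)
  i2 <- codon_indices(seq2)
  keep <- !is.na(i1) & !is.na(i2) & !tab$is_stop[ifelse(is.na(i1), 1L, i1)] &
    !tab$is_stop[ifelse(is.na(i2), 1L, i2)]
  i1 <- i1[keep]
  i2 <- i2[keep]
  m <- length(i1)
  if (m == 0L) stop("no comparable codons after skipping")

  codon_s <- (tab$s_sites[i1] + tab$s_sites[i2]) / 2  # per-codon syn sites
  codon_sd <- tab$sd[cbind(i1, i2)]
  codon_nd <- tab$nd[cbind(i1, i2)]

  S <- sum(codon_s)
  N <- 3 * m - S
  Sd <- sum(codon_sd)
  Nd <- sum(codon_nd)
  pS <- Sd / S
  pN <- Nd / N
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  flags <- character(0)
  if (is.na(dS) || is.na(dN)) flags <- c(flags, "saturated")
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  if (is.na(omega)) flags <- c(flags, "undefined_omega")
  structure(list(
    gene_id = gene_id, S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
    n_codons = m, flags = flags,
    codon_s = codon_s, codon_sd = codon_sd, codon_nd = codon_nd
  ), class = "kaks_result")
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) log(1 - (4/3) p)`; returns `NA` (saturation) for `p >= 3/4`.
#' Monotone increasing on `[0, 3/4)` with `d(0) = 0`.
#'
#' @param p Observed proportion of differences per site.
#' @return Corrected distance, or `NA_real_` when saturated.
#' @export
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("Nei-Gojobori Ka/Ks estimate",
      if (!is.na(x$gene_id)) paste0(" [", x$gene_id, "]"), "\n", sep = "")
  cat(sprintf("  codons compared: %d   S = %.2f   N = %.2f\n",
              x$n_codons, x$S, x$N))
  cat(sprintf("  Sd = %.2f  Nd = %.2f  pS = %.4f  pN = %.4f\n",
              x$Sd, x$Nd, x$pS, x$pN))
  cat(sprintf("  dS (Ks) = %s  dN (Ka) = %s  dN/dS = %s\n",
              fmt_or_na(x$dS), fmt_or_na(x$dN), fmt_or_na(x$omega)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$Z)) {
    cat(sprintf("  Z = %.3f  p = %.4g (%s, %s variance)\n",
                x$Z, x$p_value, x$alternative, x$variance_method))
  }
  invisible(x)
}

fmt_or_na <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

#' Codon-based Z-test for selection on a Ka/Ks estimate
#'
#' Tests the difference `dS - dN` against its standard error:
#' `Z = (dS - dN) / sqrt(var(dS) + var(dN))`. The default variance is a
#' bootstrap over codon columns (codon pairs resampled with replacement,
#' seeded); the analytic alternative uses the binomial variances of `pS` and
#' `pN` propagated through the Jukes-Cantor correction by the delta method.
#' With `alternative = "purifying"` the p-value is the one-tailed upper
#' normal tail of `Z` (evidence that `dN < dS`); `"positive"` tests the
#' opposite tail; `"two.sided"` doubles the smaller tail.
#'
#' @param fit A `kaks_result` from [kaks()].
#' @param B Bootstrap replicates (bootstrap variance only).
#' @param seed Integer seed for the bootstrap resampling.
#' @param alternative `"purifying"` (default), `"positive"` or `"two.sided"`.
#' @param variance `"bootstrap"` (default) or `"analytic"`.
#' @return The `kaks_result` augmented with `Z`, `p_value`, `var_dS`,
#'   `var_dN`, `variance_method`, `alternative`, `B` and possibly a
#'   `degenerate` flag (zero variance: `p_value = 1`).
#' @export
z_test <- function(fit, B = 1000L, seed = 1L,
                   alternative = c("purifying", "positive", "two.sided"),
                   variance = c("bootstrap", "analytic")) {
  stopifnot(inherits(fit, "kaks_result"))
  alternative <- match.arg(alternative)
  variance <- match.arg(variance)
  m <- fit$n_codons
  if (variance == "bootstrap") {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    W <- stats::rmultinom(B, m, rep(1 / m, m))  # m x B resampling counts
    Sb <- as.numeric(crossprod(W, fit$codon_s))
    Nb <- 3 * m - Sb
    Sdb <- as.numeric(crossprod(W, fit$codon_sd))
    Ndb <- as.numeric(crossprod(W, fit$codon_nd))
    dSb <- jc_correct(Sdb / Sb)
    dNb <- jc_correct(Ndb / Nb)
    theta <- dSb - dNb
    var_theta <- stats::var(theta, na.rm = TRUE)
    var_dS <- stats::var(dSb, na.rm = TRUE)
    var_dN <- stats::var(dNb, na.rm = TRUE)
    se <- sqrt(var_theta)
  } else {
    var_pS <- fit$pS * (1 - fit$pS) / fit$S
    var_pN <- fit$pN * (1 - fit$pN) / fit$N
    # delta method through d(p) = -(3/4) log(1 - 4p/3): d'(p) = 1/(1 - 4p/3)
    var_dS <- var_pS / (1 - (4 / 3) * fit$pS)^2
    var_dN <- var_pN / (1 - (4 / 3) * fit$pN)^2
    se <- sqrt(var_dS + var_dN)
  }
  flags <- fit$flags
  if (is.na(se) || se == 0 || is.na(fit$dS) || is.na(fit$dN)) {
    Z <- NA_real_
    p <- 1
    flags <- unique(c(flags, "degenerate"))
  } else {
    Z <- (fit$dS - fit$dN) / se
    p <- switch(alternative,
      purifying = stats::pnorm(Z, lower.tail = FALSE),
      positive = stats::pnorm(-Z, lower.tail = FALSE),
      two.sided = 2 * stats::pnorm(-abs(Z))
    )
  }
  fit$Z <- Z
  fit$p_value <- p
  fit$var_dS <- var_dS
  fit$var_dN <- var_dN
  fit$variance_method <- variance
  fit$alternative <- alternative
  fit$B <- if (variance == "bootstrap") as.integer(B) else NA_integer_
  fit$flags <- flags
  fit
}

#' Genome-wide Ka/Ks screen over ortholog codon-pair alignments
#'
#' Runs [kaks()] and [z_test()] for every pair and returns a per-gene result
#' table plus a selection summary. Pairs are supplied as a data frame with
#' columns `gene_id`, `seq1`, `seq2` (in-frame, equal length).
#'
#' @param pairs Data frame of in-frame ortholog pairs.
#' @param B,seed,alternative,variance Passed to [z_test()]; each gene's
#'   bootstrap seed is derived deterministically from `seed`.
#' @param alpha Significance level for the summary (default 0.05, no
#'   multiple-testing correction).
#' @return Object of class `kaks_screen`: list with `results` (one row per
#'   gene: S, N, Sd, Nd, pS, pN, dS, dN, omega, Z, p_value, flags) and
#'   `summary` (see [selection_summary()]).
#' @export
kaks_screen <- function(pairs, B = 1000L, seed = 1L,
                        alternative = "purifying", variance = "bootstrap",
                        alpha = 0.05) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_id", "seq1", "seq2") %in% names(pairs)))
  n <- nrow(pairs)
  res <- vector("list", n)
  for (k in seq_len(n)) {
    fit <- kaks(pairs$seq1[k], pairs$seq2[k], gene_id = pairs$gene_id[k])
    fit <- z_test(fit, B = B, seed = derive_seed(seed, k),
                  alternative = alternative, variance = variance)
    res[[k]] <- data.frame(
      gene_id = fit$gene_id, n_codons = fit$n_codons,
      S = fit$S, N = fit$N, Sd = fit$Sd, Nd = fit$Nd,
      pS = fit$pS, pN = fit$pN, dS = fit$dS, dN = fit$dN,
      omega = fit$omega, Z = fit$Z, p_value = fit$p_value,
      flags = paste(fit$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res)
  structure(list(results = results,
                 summary = selection_summary(results, alpha = alpha),
                 alpha = alpha, B = as.integer(B), seed = as.integer(seed),
                 variance = variance, alternative = alternative),
            class = "kaks_screen")
}

#' Summarize a Ka/Ks screen into selection categories
#'
#' Counts genes under significant purifying selection (`p < alpha` and
#' `dN < dS`), significant positive selection (`p < alpha` and `dN > dS`)
#' and the not-significant remainder. No multiple-testing correction is
#' applied.
#'
#' @param results Per-gene result data frame (from [kaks_screen()]).
#' @param alpha Significance level.
#' @return List with `n_genes`, `n_purifying_significant`,
#'   `n_positive_significant`, `n_not_significant`, `alpha`.
#' @export
selection_summary <- function(results, alpha = 0.05) {
  sig <- !is.na(results$p_value) & results$p_value < alpha
  dSdN_ok <- !is.na(results$dS) & !is.na(results$dN)
  purifying <- sig & dSdN_ok & results$dN < results$dS
  positive <- sig & dSdN_ok & results$dN > results$dS
  list(
    n_genes = nrow(results),
    n_purifying_significant = sum(purifying),
    n_positive_significant = sum(positive),
    n_not_significant = nrow(results) - sum(purifying) - sum(positive),
    alpha = alpha
  )
}

#' @export
print.kaks_screen <- function(x, ...) {
  s <- x$summary
  cat("Genome-wide Ka/Ks selection screen\n")
  cat(sprintf("  %d gene pairs; codon-based Z-test (%s, %s variance, alpha = %g)\n",
              s$n_genes, x$alternative, x$variance, s$alpha))
  cat(sprintf("  purifying (p < alpha, dN < dS): %d\n",
              s$n_purifying_significant))
  cat(sprintf("  positive  (p < alpha, dN > dS): %d\n",
              s$n_positive_significant))
  cat(sprintf("  not significant:                %d\n", s$n_not_significant))
  med <- stats::median(x$results$omega, na.rm = TRUE)
  if (!is.na(med)) cat(sprintf("  median dN/dS: %.3f\n", med))
  invisible(x)
}

#' @export
summary.kaks_screen <- function(object, ...) object$summary
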