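---
title: "Methods: competitive recruitment, expression profiling and the Ka/Ks screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive recruitment, expression profiling and the Ka/Ks screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific setting

`symbiorecruit` profiles a pair of closely related, uncultivated symbiont
lineages — the motivating case is the unicellular diazotrophic
cyanobacterium UCYN-A, whose two sub-lineages partner with prymnesiophyte
algae of different cell sizes — from size-fractionated metagenome (MG) and
metatranscriptome (MT) shotgun samples. Because the two reference genomes
are largely syntenic and only a few percent divergent, reads must be
assigned *competitively*: each read goes to the closest-hit genome, and
population-level statistics are computed per genome. On top of the
recruitment layer the package implements whole-genome expression profiling
with two normalization schemes, gene-cluster aggregation with cross-sample
regression, and a genome-wide Nei–Gojobori (NG86) Ka/Ks screen with a
codon-based Z-test for purifying selection. A ground-truthed simulator
generates all inputs synthetically, so every stage is testable end to end
without sequencing data.

## Fragment recruitment

Inputs are 12-column tabular local alignments (the standard BLAST
`-outfmt 6` layout) of reads against both reference genomes, plus a
contig-to-genome map. The chain is:

1. **Best hit per (read, genome)** — highest bitscore, ties broken by
   higher percent identity, then smallest subject coordinates.
2. **Filters** (`filter_config()`), each inclusive at its boundary:
   * `min_pident = 50` (%) and `max_evalue = 1e-4` — the alignment-step
     thresholds;
   * `min_query_coverage = 0.90` — the aligned fraction of the read,
     `(qend - qstart + 1) / read_length`; reads aligned along less than
     90% of their length are excluded. The query *span* is used rather
     than the `length` column so gap columns cannot inflate coverage;
   * rRNA/ITS **mask**: any alignment overlapping an annotated 23S/16S/5S
     rRNA gene or ITS region by at least 1 bp is removed. These loci are
     conserved across taxa and would recruit reads from unrelated
     organisms. Overlap-based removal is the conservative choice; removal
     by separate read classification would be an alternative.
   The filter log attributes each removal to the first failing rule in the
   order identity, evalue, coverage, mask; the retained *set* is
   order-independent (a tested invariant).
3. **Competitive assignment** — highest bitscore wins, bitscore ties fall
   back to identity, and a full tie marks the read ambiguous. Ambiguous
   reads are excluded from both genomes' summaries and counted separately;
   with no stated convention for ties, silently splitting or duplicating
   them would bias both genomes' statistics.
4. **Genome recovery** — the breadth-of-coverage statistic: the fraction
   of reference positions covered by assigned reads with identity
   *strictly above* the population threshold (`population_identity = 95`
   %). The threshold separates reads of the same population as the
   reference from reads of related populations. The denominator is the
   full genome length including masked regions, so recovery is comparable
   across configurations with different masks; it is configurable.
5. **Identity histograms** — 1%-wide bins from 70 to 100% identity, top
   bin closed, plus an underflow bin, summing exactly to the assigned
   count.

Boundary conventions matter at desk scale and are fixed as: filter
thresholds inclusive (a record at exactly 50% identity, e-value 1e-4 or
coverage 0.90 is retained), population threshold strict (a read at exactly
95.0% does not count towards recovery or expression).

`align_reads_naive()` is a small exact-seeding (k = 13), ungapped
extension aligner for the no-indel synthetic regime, so end-to-end runs
need no external aligner; real data should be aligned with a production
tool and imported as tabular alignments.

## Expression profiling

A transcript counts for a gene when its identity is strictly above the
population threshold and its alignment overlaps the gene interval by at
least 1 bp. "Covering" is deliberately weak: with 100-bp reads against
~1-kb genes, any-overlap and full-containment counting differ by little,
and any-overlap makes no assumption about read positioning. A read
overlapping two genes counts once for each (no fractional splitting), so
gene-count columns can sum to more than the read count. Genes with no
reads are kept as zeros.

Two normalizations are computed:

* **per cell** — each gene's MT count divided by the mean MT count of the
  single-copy housekeeping genes *recA* and *gyrB*. The mean is the
  default operator (sum and geometric mean are available); whichever is
  used, the housekeeping genes themselves average to 1, a tested identity.
  A zero housekeeping denominator flags the whole genome's values missing
  rather than erroring.
* **MG-normalized** — `(mt_count/mt_depth) / (mg_count/mg_depth)`, the
  depth-scaled transcript-to-gene-copy ratio. Genes with zero MG reads are
  flagged missing.

Cluster aggregation sums MT counts over labeled gene clusters (nif operon,
F0F1 ATP synthase, cytochrome b6f, PSI, housekeeping) and reports each
cluster's percentage of the genome's total transcript count.
`regress_clusters()` is ordinary least squares of another cluster's
per-sample counts on the nif operon's, with the usual two-sided t-test on
the slope (n − 2 df); it reproduces closed-form OLS exactly on small
instances (tested).

## The Ka/Ks screen

For each pre-aligned in-frame ortholog pair (the package does not build
codon alignments; the simulator emits them, and external aligner output is
accepted):

* **Sites**: each codon position contributes the synonymous fraction of
  its three possible changes; mutations creating stop codons count as
  nonsynonymous. `S + N = 3 ×` (compared codons), exactly. This is one of
  the two common NG86 conventions; the difference only touches
  stop-adjacent codons.
* **Differences**: codons differing at k positions are resolved by
  averaging over the k! substitution orderings; orderings passing through
  a stop codon are excluded and the rest re-weighted (with a flagged
  uniform fallback if every ordering hits a stop). Both sites and
  differences are verified against an exhaustive brute-force enumeration
  over all 61 sense codons and all 61 × 61 codon pairs.
* **Distances**: Jukes–Cantor correction `d = -(3/4) log(1 - (4/3) p)`,
  flagged saturated at `p >= 3/4`; `omega = dN/dS` is undefined when
  `dS = 0`.
* **Z-test**: `Z = (dS - dN) / sqrt(var dS + var dN)`, one-tailed for
  purifying selection by default, matching the directional question the
  screen asks; a positive-selection tail and a two-sided form are
  available. The default variance is a bootstrap over codon columns
  (B = 1000, seeded, reproducible); the analytic alternative propagates
  binomial variances of pS and pN through the JC correction by the delta
  method. The two agree in the rejection decision on the large majority of
  strong-signal pairs (tested at ≥ 90%). Codons containing gaps, N or
  stops in either sequence are skipped; an all-degenerate pair returns
  p = 1 with a flag rather than an error.
* **Summary**: genes with p below alpha split into purifying (dN < dS)
  and positive (dN > dS); no multiple-testing correction is applied, so
  the per-gene calls are directly comparable to single-gene tests.

## The synthetic community generator

The generator emulates the statistical structure the analysis relies on,
with every random draw seeded and bit-reproducible:

* **Genome pair**: an i.i.d. ancestor at 35% GC (typical of these
  streamlined symbiont genomes), 200 kb with 150 genes of 900 bp by
  default; each lineage substitutes each site independently at
  `divergence/2` (uniform over the three alternatives, Jukes–Cantor-like),
  so annotations carry over at identical coordinates. The default 5%
  divergence is a configurable stand-in for a closely related genome pair,
  not a measured value. rRNA/ITS intervals are placed as masked loci.
* **Reads**: 100-bp single-end reads (the modeled chemistry), origin
  lineage drawn per sample-specific weights — the knob that reproduces
  size-fraction-dependent lineage mixtures. MG starts are uniform; MT
  reads are wholly contained in genes drawn from an expression profile
  whose default puts one quarter of the transcript mass on the nif operon,
  with smaller masses on ATP synthase, cytochrome b6f, PSI and the
  housekeeping pair, and the remainder uniform. Per-base substitution
  errors (0.5% default) always change the base. Alongside the reads the
  generator emits exact ungapped truth alignments to *both* genomes
  (bitscore surrogate `2·matches − 3·mismatches`, e-value surrogate
  `10^(−bitscore/10)`; only their ordering matters downstream), so the
  pipeline runs with no aligner in the loop.
* **Codon pairs**: a random sense-codon ancestor evolves by proposed
  single-nucleotide changes. Stop-creating proposals are rejected, and the
  nonsynonymous acceptance is re-weighted per codon by the ratio of all
  nonsynonymous mutants (including stops, which NG86 counts as
  nonsynonymous sites) to viable ones. Without this re-weighting a
  nominally neutral simulation realizes dN/dS ≈ 0.94 in NG86 site units —
  the blocked stop channels are counted as nonsynonymous opportunity that
  can never be used — which would make `omega` systematically mislabeled
  and a neutral null slightly purifying. With it, `omega` is the realized
  NG86-unit dN/dS, which is what the downstream estimator measures. Both
  acceptance probabilities are scaled jointly so neither exceeds 1, which
  also covers `omega > 1`. Events accumulate until the accepted synonymous
  events per ancestral synonymous site reach `expected_dS` (an integer
  event target, so the realized rate is unbiased); the realized event
  counts are returned as ground truth.

What the generator does **not** emulate: indels (truth alignments are
exact and ungapped by construction), quality scores, duplicates, chimeras,
strandedness, rate heterogeneity along the genome, genome rearrangements,
and any community beyond the two focal lineages. Passing tests therefore
demonstrate the correctness of the statistics under the stated model, not
robustness to alignment artifacts or compositional complexity in real
samples.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; conversion to and
  from GFF3 (1-based inclusive) and BED (0-based half-open) happens only
  at file boundaries. Subject intervals in alignment records stay 1-based
  inclusive as in the tabular format, normalized to subject-forward order
  with a strand flag.
* Contig-to-genome mapping is an explicit user-supplied table, not a
  name-prefix heuristic, so multi-contig assemblies work unchanged.
* All tie-breaks (best-hit reduction, competitive assignment) are total
  orders, so results are independent of input row order.
* One global pipeline seed deterministically derives per-stage seeds
  through a fixed linear-congruential step kept below 2^31, so a single
  integer reproduces a whole run byte-for-byte; outputs are written with
  fixed numeric formatting for the same reason.
* Genes shorter than the read length are excluded from MT expression
  weights with a warning, keeping "transcript contained in gene"
  unambiguous.
* Test problem sizes are chosen to give tight statistical bounds at
  interactive runtimes: 200-kb genomes with 500–10,000 reads for the
  recruitment oracles and discrimination checks, coverages 0.5–3 for the
  Lander–Waterman comparison (expected covered fraction `1 − e^(−C)`),
  20,000 MT reads for expression recovery (3-standard-deviation binomial
  bands), 1,000 neutral pairs of 500 codons (B = 200) for the Z-test size
  and 200 pairs of 1,000 codons for its power.

## Known limitations

* NG86 with JC correction is a counting method: at synonymous divergences
  beyond ~0.5 the pathway-averaging approximation biases the null of the
  Z-test noticeably, and saturation (`p >= 3/4`) is flagged rather than
  rescued. Likelihood methods should be preferred for deep divergences.
* The per-gene identity threshold reuses the recruitment population
  threshold (> 95%); transcripts from a population more divergent than
  that are invisible to the expression layer by design.
* The naive aligner is exact-match seeded and ungapped; it is a test
  harness, not a read mapper.
* Ortholog identification and codon alignment are out of scope; the Ka/Ks
  screen trusts its input pairing.
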