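---
title: "Methods: feature derivation, P-value aggregation, and enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature derivation, P-value aggregation, and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichmap)
```

This vignette documents the statistical and structural conventions the
package commits to: how computed gene features are derived from a GTF,
how site-level P-values become gene-level P-values, what the enrichment
statistics are and what their null models assume, and which design
choices were genuinely open and how they were settled.

## 1. Coordinate conventions and feature derivation

All coordinates are 1-based inclusive, the GTF convention. BED input is
converted at the parser boundary (`start + 1`), and nothing downstream
ever sees half-open intervals.

From the seven canonical feature types present in an Ensembl-dialect
GTF (exon, CDS, five/three prime UTR, start/stop codon, transcript
span), `derive_features()` computes five more per transcript, plus the
TSS:

* **Intron** *i* is the gap between consecutive exons *i* and *i + 1*:
  `[exon_end[i] + 1, exon_start[i+1] - 1]`. A transcript with *k* exons
  therefore has exactly *k − 1* introns, and exons plus introns tile
  the transcript span with no gap or overlap — both properties are
  asserted over seeded fixture annotations in the test suite.
* **Splice donor / acceptor** are the first and last bases of each
  intron *in transcription direction*: on the minus strand the donor
  sits at the intron's high-coordinate end. Defaults are 2 bp each,
  covering the near-universal GT/AG dinucleotides; both windows are
  clamped inside short introns, so they are always subsets of their
  parent intron (they may overlap each other in a 2–3 bp intron, which
  is allowed).
* **Upstream / downstream** windows flank the transcript span,
  strand-aware, 5,000 bp each by default — a conventional promoter-
  proximal scale for regulatory annotation. Windows are clipped at
  position 1; no right-end clipping is possible because a GTF does not
  carry chromosome lengths.
* **TSS** is the single transcription-start base. It is stored in the
  interval index but excluded from the default reportable set of
  twelve feature types, because a TSS hit is already expressed through
  the transcript (and, where applicable, exon/upstream) context;
  `include_tss = TRUE` in `query_point()` exposes it. This was an
  open call — one could equally report it as a thirteenth type — and
  the flag keeps both behaviours available.

Windows are derived **per transcript**, not per gene. A position can
therefore be exonic for one isoform and intronic for another of the
same gene, and both hits are reported; collapsing to the gene level
would silently discard isoform information that users of coordinate
annotation typically want.

Transcript rows missing from a GTF are inferred as the span of their
exons; gene rows missing are inferred as the span of their transcripts;
duplicated feature rows are dropped. Rows with unrecognised feature
keywords are skipped and counted rather than rejected, since Ensembl
GTFs carry types (e.g. `Selenocysteine`) irrelevant to interval
annotation.

## 2. Nearest-gene assignment

`nearest_gene()` measures distance to the **gene body span**, not the
upstream-extended span: the result is then independent of the window
configuration used to build the index, which makes aggregation results
reproducible across annotation configurations. Distance is 0 if and
only if the signal overlaps the span; otherwise it is the bp offset to
the nearer boundary (a signal one base past the gene end has distance
1). Ties are broken by smaller gene start, then lexicographic gene ID —
an arbitrary but deterministic rule. Signals carry no strand (CpG sites
and SNPs do not have one); gene strand only shaped how features were
derived.

Candidate genes are collected from the interval machinery of
`GenomicRanges` (overlaps plus the nearest gene on each flank — the
flanks are gathered explicitly because `distanceToNearest()` does not
surface equidistant ties on opposite sides), then the arithmetic
distance and tie-break are applied. The test suite checks the full
result against a plain per-signal linear scan.

## 3. Gene-level P-value aggregation

Aggregation is two-step: assign every signal to exactly one nearest
gene, then combine each gene's k raw P-values. One gene per signal (as
opposed to every overlapping gene) keeps the site → gene map a
partition, so no site is double-counted across genes.

The four combiners are the canonical textbook forms:

| method | statistic | null behaviour (independent uniform inputs) |
|---|---|---|
| fisher | $p = P(\chi^2_{2k} \ge -2\sum \ln p_i)$ | exact uniform |
| sidak  | $1-(1-p_{\min})^k$ | conservative for k > 1 |
| simes  | $\min_i k\,p_{(i)}/i$ | exact uniform |
| fdr    | $\min_i \mathrm{BH}(p)_i$ | = Simes |

Sidak is applied to the minimum (single-step correction of the best
signal); a per-element product variant exists but is harder to
interpret as "the gene's best evidence, corrected", so it was not
used. "FDR" is interpreted as the minimum BH-adjusted value within the
gene — the only standard scalar an FDR procedure yields per gene — and
its algebraic identity with Simes is asserted on random lists rather
than assumed. All four return the input unchanged at k = 1, are
permutation-invariant and monotone, and their empirical rejection rates
under a simulated global null (10,000 genes, k ∈ {1..10}) are checked
to be at or below the nominal α within 3 binomial standard errors.

Zero P-values are rejected at validation (Fisher is undefined at
ln 0). A `p_floor` argument clamps instead, for upstream tools that
underflow; it is off by default so silent clamping can never distort a
result. No dependence-aware combination (e.g. Brown's method) is
offered: sites within a gene are often correlated, so the combined
P-values should be read as evidence ranking, not calibrated tail
probabilities — which is also why aggregation is framed as happening
*before* genome-wide correction.

## 4. Enrichment statistics

**ORA.** The background is enforced to be the uploaded study list:
population N = study genes, K = set ∩ background, n = significant
genes, x = significant ∩ set, and the one-sided upper tail
P(X ≥ x) comes from `stats::phyper`. Intersecting sets with the
background *before* sizing K is what makes a custom background
meaningful; a genome-wide K would bias toward well-annotated genes.
Sets with intersected size outside [`min_set` = 2, `max_set` = 5000]
are skipped — size-1 sets cannot be meaningfully enriched, and the cap
only guards against degenerate whole-genome sets. Only enrichment is
tested (no depletion tail). BH adjustment is applied across the tested
terms of one library; adjusting within a library keeps sources with
very different term counts from distorting each other.

**GSEA.** For a pre-ranked list of n genes and a set with m in-list
members, the running sum steps up by
$|s|^w / \sum_{hits} |s|^w$ at hits and down by $1/(n-m)$ at misses;
the enrichment score is the signed extremum. Weight w = 0 (default) is
the classic equal-increment KS form; w = 1 gives the score-weighted
variant. Ties in scores are broken by gene ID so the ES is
deterministic. Significance uses **gene-label permutation** — member
labels redrawn uniformly, `p = (1 + #{|ES*| ≥ |ES|}) / (1 + n_perm)` —
because the input is a pre-ranked list: with no expression matrix there
is no phenotype to permute. The +1 in numerator and denominator keeps
p > 0 and the estimate unbiased under the null. Sets with fewer than 2
in-list members are skipped, as is a set covering the entire list
(the miss decrement 1/(n−m) is undefined); constant score vectors are
an error since no ranking exists. The implementation evaluates the
extremum from hit positions in O(m) per permutation; tests compare it
against a literal O(n) walk of the full list and against an exhaustive
contiguous-block oracle.

**TF enrichment** is ORA with TF → target sets. Because public TF
target collections are human-derived, non-human study lists are first
mapped to human symbols through the ID table; unmapped genes are
dropped and both N and K are computed on the mapped universe only —
testing enrichment on a universe the sets cannot reach would deflate
every P-value. A symbol reachable from both a significant and a
non-significant source gene counts as significant.

## 5. ID conversion

The correspondence table is record-oriented; a lookup returns every
record matching the input in the source namespace and every distinct
non-missing target value. Many-to-many mappings are always surfaced
(`status = "multi"`), never collapsed to a first match — ortholog
mapping is precisely where silent collapsing corrupts results. Ensembl
and Entrez matching is case-sensitive; symbol matching is
case-insensitive by default because casing conventions differ across
species (*Casp3* vs *CASP3*), with an opt-out. Human orthologs are
joined by case-insensitive symbol match between the species' VGNC-style
symbols and HGNC symbols, mirroring how those nomenclature committees
coordinate names.

## 6. Synthetic fixtures: what they do and do not emulate

`fixture_spec()` defaults to 20 genes on 2 chromosomes (1–2
transcripts per gene, 1–4 exons, exon lengths 50–300 bp, introns
60–400 bp) and 200 signals, 20% of genes active — small enough that
brute-force oracles over all intervals stay trivial, large enough to
contain every structural edge case (both strands, single-exon
transcripts, overlapping genes, intergenic signals). Active genes
draw site P-values from Beta(0.1, 1), a sharply right-skewed
distribution concentrating near 0 as genuine association signal does;
null genes draw Uniform(0, 1). The planted GMT term's members are
exactly the active genes, giving a known-answer target for recovery
tests.

The generators are pure functions of the spec — the same seed yields
byte-identical files, and the caller's RNG state is saved and
restored — so tests can treat fixtures as values.

What the fixtures do **not** emulate: linkage/correlation between
nearby sites (signals are independent given the gene), realistic gene
density or length distributions, chromosome-scale structure, unmapped
contigs, or annotation errors. Passing the recovery tests therefore
demonstrates that the statistical machinery is implemented correctly
and recovers planted structure under its own assumptions — not that
those assumptions hold in any particular real dataset.

## 7. Numerical and scale choices

* Hypergeometric and chi-square tails come from R's `phyper`/`pchisq`;
  the suite verifies them against exhaustive enumeration (all
  populations N ≤ 12) and adaptive quadrature (relative tolerance
  1e-10) respectively, so the closed forms are never taken on faith.
* Property tests run at sizes where their oracles are exact and fast:
  100 seeded fixture annotations for the structural laws, 1,000 random
  positions per fixture for the interval-query oracles, 10,000
  simulated genes for the null calibration, 100 GSEA and 50 end-to-end
  replicates for planted-term recovery. These sizes were chosen as the
  package's own test design; the generators accept larger values.
* GSEA permutation counts in tests (150–300) sit well above the
  enforced minimum of 100; the CLI default is 1,000.
* The annotation index serialises to a single portable RDS file
  (`write_annotation()`/`read_annotation()`), asserted to round-trip
  losslessly, so a CLI user can build once and annotate repeatedly.

## 8. Known limitations

* Nearest-gene assignment ignores strand and regulatory topology; a
  signal in a gene desert is still assigned to some gene, arbitrarily
  far away. Filtering by `nearest_distance` is the user's lever.
* Combined gene-level P-values assume independent sites; correlated
  sites make Fisher anti-conservative. Rank-based use is safe.
* GSEA reports ES and permutation p only — no normalised enrichment
  score or leading-edge subset; cross-set ES comparison is therefore
  size-confounded by construction.
* The GTF reader trusts Ensembl dialect attribute keys (`gene_id`,
  `gene_name`, `transcript_id`); RefSeq GFF3 is out of scope.
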