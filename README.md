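# enrichmap

Offline interpretation of coordinate-based and gene-list-based omics
signals, aimed at livestock (and other non-model) genomics, where study
outputs typically arrive as either nucleotide-level signals (CpG sites
from whole-genome bisulfite sequencing, GWAS SNPs) or candidate gene
lists (differential expression, co-expression modules). Everything runs
from local files — an Ensembl-dialect GTF, TSV signal/gene lists, and
GMT gene set libraries — with no database or network dependency.

## What it does

**Coordinate → feature mapping.** `load_gtf()` parses a GTF, keeps the
seven canonical feature types (exon, CDS, 5′/3′ UTR, start/stop codon,
transcript span) and derives five computed ones per transcript: introns
(gaps between consecutive exons), splice donors/acceptors (the first and
last *d* bp of each intron in transcription direction, default 2 bp,
the canonical GT/AG dinucleotides), and strand-aware upstream/downstream
windows (default 5,000 bp, clipped at position 1). Transcription start
sites are carried in the index as an additional 1-bp computed feature.
`annotate_signals()` intersects signals (points or regions, TSV or BED)
with the interval index and reports every overlapping
(gene, transcript, feature) triple.

**P-value aggregation.** `aggregate_pvalues()` maps each signal to its
nearest gene (gene-body distance, deterministic tie-breaking) and
combines the per-gene site P-values with one of four rules, producing a
gene-level P-value prior to genome-wide correction:

- Fisher: $X = -2\sum_i \ln p_i \sim \chi^2_{2k}$ under the null;
- Sidak: $1 - (1 - p_{\min})^k$;
- Simes: $\min_i \, k\, p_{(i)} / i$;
- FDR: the minimum Benjamini–Hochberg-adjusted value within the gene
  (identical to Simes; asserted as a cross-check in the test suite).

**Enrichment.** `ora()` is the classic hypergeometric
overrepresentation test with an *enforced* study background: the
uploaded gene list is the universe $N$, gene sets are intersected with
it before computing set sizes $K$, and the one-sided tail
$P(X \ge x)$ is evaluated for the $x$ significant-∩-set genes among the
$n$ significant. `gsea()` scores a pre-ranked list with a
Kolmogorov–Smirnov-style running sum (hits step up, misses step down;
the enrichment score is the signed extremum) and assesses significance
by seeded gene-label permutation. `tf_enrichment()` applies the same
hypergeometric machinery to transcription-factor → target sets, with
optional ortholog mapping onto human symbols first. All results carry
the overlapping gene IDs and BH-adjusted P-values.

**ID conversion.** `convert_ids()` translates among Ensembl, Entrez,
symbol, VGNC, and human-ortholog namespaces via correspondence tables
loaded from standard TSV extracts (`load_id_tables()`); many-to-many
mappings are always surfaced, never collapsed.

**Fixtures.** `fixture_spec()` / `make_gtf()` / `make_signals()` /
`make_gmt()` / `make_id_tables()` generate a deterministic synthetic
study — genome annotation, signals with planted active genes, gene set
library with a planted enriched term — so every pipeline can be
exercised end to end without downloading anything.

## Worked example

```r
library(enrichmap)

spec <- fixture_spec(seed = 1)              # 20 genes, 200 signals
make_gtf(spec, "fixture.gtf")
ann  <- load_gtf("fixture.gtf")
ann
#> genome_annotation: 20 genes, 31 transcripts, 424 indexed intervals
#>   chromosomes: chr1, chr2
#>   windows: upstream 5000, downstream 5000, donor 2, acceptor 2 bp

sig <- make_signals(spec, ann)
agg <- aggregate_pvalues(sig, ann, method = "fisher")
head(agg[, 1:4], 3)
#>    gene_id  symbol  k p_aggregated
#> 1 FGENE006 FSYM006 16 1.238544e-33
#> 2 FGENE019 FSYM019 10 9.544381e-26
#> 3 FGENE008 FSYM008  8 1.261060e-22

# genes with small aggregated P-values are the planted active genes
fixture_active_genes(spec)
#> [1] "FGENE006" "FGENE008" "FGENE015" "FGENE019"

study <- data.frame(gene_id = agg$gene_id,
                    significant = p.adjust(agg$p_aggregated, "BH") < 0.05)
res <- ora(study, make_gmt(spec, ann$genes$gene_id))
res[1, c("term_id", "n_overlap", "n_set_in_background", "p_raw", "p_adjusted")]
#>   term_id n_overlap n_set_in_background      p_raw p_adjusted
#> 1 PLANTED         4                   5 0.00128999 0.01418989
```

The planted term — whose members are exactly the active genes — comes
out on top: 4 of its 5 members are among the significant genes, against
a background of 20, giving a hypergeometric tail of 0.0013.

A command-line front end wrapping the same functions (subcommands
`fixtures`, `build-index`, `annotate`, `aggregate`, `ora`, `gsea`,
`tf`, `convert`) is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "enrichmap.R", package = "enrichmap"))') --help
```

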