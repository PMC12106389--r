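#' Specification for synthetic test fixtures
#'
#' Describes a self-contained synthetic study: a small genome annotation,
#' coordinate-level signals with planted "active" genes, and gene set
#' libraries with an optional planted enriched term.  All generators are
#' pure functions of the spec: the same spec (same seed) produces
#' byte-identical files, and the caller's RNG state is never disturbed.
#'
#' Active genes receive site P-values drawn from Beta(0.1, 1) — strongly
#' right-skewed toward 0, mimicking genuine association signal — while
#' null genes receive Uniform(0, 1) P-values.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param chrom_count number of chromosomes the genes are spread over.
#' @param transcripts_per_gene,exons_per_transcript integer ranges
#'   `c(lo, hi)`.
#' @param exon_len,intron_len,intergenic_len bp ranges `c(lo, hi)`.
#' @param n_signals number of coordinate-level signals.
#' @param frac_active fraction of genes planted as active, in [0, 1].
#' @param frac_intergenic fraction of signals placed away from any gene
#'   body.
#' @param beta_shape1,beta_shape2 Beta parameters for active-gene
#'   P-values.
#' @param n_gene_sets number of random gene sets.
#' @param set_size integer range of set sizes.
#' @param planted_term plant one term (`"PLANTED"`) whose members are the
#'   active genes.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 20L, chrom_count = 2L,
                         transcripts_per_gene = c(1L, 2L),
                         exons_per_transcript = c(1L, 4L),
                         exon_len = c(50L, 300L),
                         intron_len = c(60L, 400L),
                         intergenic_len = c(2000L, 8000L),
                         n_signals = 200L, frac_active = 0.2,
                         frac_intergenic = 0.1,
                         beta_shape1 = 0.1, beta_shape2 = 1,
                         n_gene_sets = 10L, set_size = c(5L, 15L),
                         planted_term = TRUE) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               chrom_count = as.integer(chrom_count),
               transcripts_per_gene = as.integer(transcripts_per_gene),
               exons_per_transcript = as.integer(exons_per_transcript),
               exon_len = as.integer(exon_len),
               intron_len = as.integer(intron_len),
               intergenic_len = as.integer(intergenic_len),
               n_signals = as.integer(n_signals),
               frac_active = frac_active, frac_intergenic = frac_intergenic,
               beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
               n_gene_sets = as.integer(n_gene_sets),
               set_size = as.integer(set_size),
               planted_term = isTRUE(planted_term))
  stopifnot(spec$n_genes >= 1, spec$chrom_count >= 1, spec$n_signals >= 1,
            is_count_range(spec$transcripts_per_gene),
            is_count_range(spec$exons_per_transcript),
            is_count_range(spec$exon_len), is_count_range(spec$intron_len),
            is_count_range(spec$intergenic_len), is_count_range(spec$set_size),
            spec$frac_active >= 0, spec$frac_active <= 1,
            spec$frac_intergenic >= 0, spec$frac_intergenic <= 1)
  structure(spec, class = "fixture_spec")
}

.rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
  sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L

#' Planted active genes of a fixture
#'
#' Deterministic subset of the fixture's gene IDs designated "active"
#' (signal-bearing); shared by [make_signals()] and [make_gmt()].
#'
#' @param spec a [fixture_spec()].
#' @return sorted character vector of active gene IDs.
#' @export
fixture_active_genes <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_active <- max(1L, round(spec$frac_active * spec$n_genes))
  gids <- sprintf("FGENE%03d", seq_len(spec$n_genes))
  with_seed(spec$seed + 1L, sort(sample_int(gids, n_active)))
}

#' Generate a synthetic Ensembl-dialect GTF
#'
#' Lays genes sequentially along `chrom_count` chromosomes with random
#' intergenic gaps, on both strands, with per-transcript exon chains.
#' Edge cases are planted on purpose: single-exon transcripts arise
#' whenever the exon-count range allows, and roughly every seventh gene is
#' shifted back to overlap its predecessor.  Multi-exon transcripts carry
#' CDS/UTR/codon rows within their first and last exons so all canonical
#' feature types are exercised.  Output is deterministic: the same spec
#' yields a byte-identical file.
#'
#' @param spec a [fixture_spec()].
#' @param path output GTF path.
#' @return invisibly, the path; parse with [load_gtf()].
#' @export
make_gtf <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  max_tx_len <- spec$exons_per_transcript[2] * spec$exon_len[2] +
    (spec$exons_per_transcript[2] - 1) * spec$intron_len[2]
  lines <- with_seed(spec$seed, {
    out <- c("#!genome-build synthetic-fixture",
             "#!genome-version 1")
    cursor <- rep(1L, spec$chrom_count)
    prev_gene_end <- rep(NA_integer_, spec$chrom_count)
    for (g in seq_len(spec$n_genes)) {
      chrom_i <- ((g - 1L) %% spec$chrom_count) + 1L
      chrom <- sprintf("chr%d", chrom_i)
      gid <- sprintf("FGENE%03d", g)
      sym <- sprintf("FSYM%03d", g)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      gap <- .rint(spec$intergenic_len)
      gstart <- cursor[chrom_i] + gap
      # overlapping-genes edge case: pull every 7th gene back onto the
      # previous gene of the same chromosome
      if (g %% 7L == 0L && !is.na(prev_gene_end[chrom_i]) &&
          prev_gene_end[chrom_i] > 200L)
        gstart <- max(1L, prev_gene_end[chrom_i] - 100L)
      n_tx <- .rint(spec$transcripts_per_gene)
      tx_lines <- character(0)
      gene_end <- gstart
      for (t in seq_len(n_tx)) {
        tid <- sprintf("%s.T%d", gid, t)
        tx_start <- gstart + if (t == 1L) 0L else .rint(c(0L, 50L))
        n_ex <- .rint(spec$exons_per_transcript)
        es <- integer(n_ex); ee <- integer(n_ex)
        pos <- tx_start
        for (e in seq_len(n_ex)) {
          len <- .rint(spec$exon_len)
          es[e] <- pos; ee[e] <- pos + len - 1L
          pos <- ee[e] + 1L + .rint(spec$intron_len)
        }
        tx_end <- ee[n_ex]
        gene_end <- max(gene_end, tx_end)
        attrs <- function(extra = "") sprintf(
          'gene_id "%s"; gene_name "%s"; transcript_id "%s";%s',
          gid, sym, tid, extra)
        row <- function(type, s, e, a) sprintf(
          "%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e,
          strand, a)
        tx_lines <- c(tx_lines, row("transcript", tx_start, tx_end, attrs()))
        for (e in seq_len(n_ex))
          tx_lines <- c(tx_lines, row("exon", es[e], ee[e],
                                      attrs(sprintf(' exon_number "%d";', e))))
        if (n_ex >= 2L && (ee[1] - es[1]) >= 40L) {
          cds_s <- es[1] + 10L; cds_e <- ee[1] - 10L
          tx_lines <- c(tx_lines,
            row("five_prime_utr", es[1], cds_s - 1L, attrs()),
            row("CDS", cds_s, cds_e, attrs()),
            row("start_codon", cds_s, cds_s + 2L, attrs()),
            row("stop_codon", cds_e - 2L, cds_e, attrs()),
            row("three_prime_utr", cds_e + 1L, ee[1], attrs()))
        }
      }
      gene_attr <- sprintf('gene_id "%s"; gene_name "%s";', gid, sym)
      out <- c(out, sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                            chrom, gstart, gene_end, strand, gene_attr),
               tx_lines)
      prev_gene_end[chrom_i] <- gene_end
      cursor[chrom_i] <- max(cursor[chrom_i], gene_end + 1L)
    }
    out
  })
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic coordinate-level signals
#'
#' Emulates site-level omics signals (e.g. CpG sites with association
#' P-values).  Most signals are placed inside or near a randomly chosen
#' gene; a fraction land in intergenic space.  Signals whose chosen gene
#' is active draw their P-value from Beta(shape1, shape2); all others draw
#' from Uniform(0, 1).  A sidecar truth file records the intended gene and
#' its activity label for recovery tests.
#'
#' @param spec a [fixture_spec()].
#' @param annotation the `genome_annotation` parsed from [make_gtf()]
#'   output.
#' @param path output signal TSV (`chrom`, `pos`, `end`, `pvalue`).
#' @param truth_path optional sidecar TSV (`signal`, `chrom`, `pos`,
#'   `intended_gene`, `active`).
#' @return invisibly, the signal data.frame (with truth columns attached
#'   as attribute `truth`).
#' @export
make_signals <- function(spec, annotation, path = NULL, truth_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  active <- fixture_active_genes(spec)
  df <- with_seed(spec$seed + 2L, {
    rows <- lapply(seq_len(spec$n_signals), function(i) {
      intergenic <- stats::runif(1) < spec$frac_intergenic
      gi <- sample.int(nrow(genes), 1L)
      g <- genes[gi, ]
      if (intergenic) {
        pos <- g$end + 200L + .rint(c(0L, 1500L))
        gene <- NA_character_
      } else {
        pos <- g$start + .rint(c(0L, max(1L, g$end - g$start)))
        gene <- g$gene_id
      }
      is_active <- !is.na(gene) && gene %in% active
      pv <- if (is_active) stats::rbeta(1, spec$beta_shape1, spec$beta_shape2)
            else stats::runif(1)
      pv <- min(max(pv, 1e-300), 1)
      data.frame(chrom = g$chrom, pos = pos, end = pos, pvalue = pv,
                 intended_gene = gene, active = is_active,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  sig <- df[, c("chrom", "pos", "end", "pvalue")]
  truth <- data.frame(signal = seq_len(nrow(df)),
                      chrom = df$chrom, pos = df$pos,
                      intended_gene = df$intended_gene, active = df$active,
                      stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth_path))
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  attr(sig, "truth") <- truth
  invisible(sig)
}

#' Generate a synthetic gene set library (GMT)
#'
#' Random gene sets drawn from the supplied gene universe, plus, when
#' `spec$planted_term` is set, one term `"PLANTED"` whose members are the
#' fixture's active genes (padded with random genes up to the minimum set
#' size) — an enriched term that downstream ORA/GSEA should recover.
#'
#' @param spec a [fixture_spec()].
#' @param gene_ids gene universe to draw members from.
#' @param path optional GMT output path.
#' @return the `gene_set_library` (invisibly if `path` given).
#' @export
make_gmt <- function(spec, gene_ids, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), length(gene_ids) >= 2)
  active <- intersect(fixture_active_genes(spec), gene_ids)
  lib <- with_seed(spec$seed + 3L, {
    sets <- list()
    for (i in seq_len(spec$n_gene_sets)) {
      sz <- min(.rint(spec$set_size), length(gene_ids))
      sets[[sprintf("FSET%03d", i)]] <- sort(sample_int(gene_ids, sz))
    }
    if (spec$planted_term && length(active)) {
      members <- active
      pad <- spec$set_size[1] - length(members)
      if (pad > 0)
        members <- c(members,
                     sample_int(setdiff(gene_ids, members),
                                min(pad, length(gene_ids) - length(members))))
      sets[["PLANTED"]] <- sort(members)
    }
    gene_set_library(sets, source = "custom", species = "synthetic")
  })
  if (!is.null(path)) { write_gmt(lib, path); return(invisible(lib)) }
  lib
}

#' Generate synthetic gene ID correspondence tables
#'
#' Writes TSV extracts in the layouts expected by [load_id_tables()] for
#' the fixture's genes: gene2ensembl (Entrez/Ensembl backbone), gene_info
#' (symbols), VGNC, and HGNC human orthologs.  `ortholog_fraction < 1`
#' drops a deterministic subset of genes from the HGNC table, emulating
#' incomplete ortholog coverage.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @param ortholog_fraction fraction of genes given a human ortholog.
#' @return named character vector of the written file paths, suitable to
#'   pass to [load_id_tables()].
#' @export
make_id_tables <- function(spec, dir, ortholog_fraction = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_genes
  gids <- sprintf("FGENE%03d", seq_len(n))
  entrez <- as.character(100000L + seq_len(n))
  syms <- sprintf("FSYM%03d", seq_len(n))
  paths <- c(gene2ensembl = file.path(dir, "gene2ensembl.tsv"),
             gene_info = file.path(dir, "gene_info.tsv"),
             vgnc = file.path(dir, "vgnc.tsv"),
             hgnc = file.path(dir, "hgnc.tsv"))
  write.table(data.frame(tax_id = 9913L, GeneID = entrez,
                         Ensembl_gene_identifier = gids),
              paths["gene2ensembl"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(tax_id = 9913L, GeneID = entrez, Symbol = syms),
              paths["gene_info"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(vgnc_id = sprintf("VGNC:%d", seq_len(n)),
                         symbol = syms, ensembl_gene_id = gids),
              paths["vgnc"], sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- with_seed(spec$seed + 4L,
                    sort(sample.int(n, max(1L, round(ortholog_fraction * n)))))
  write.table(data.frame(symbol = toupper(syms[keep]),
                         ensembl_gene_id = sprintf("ENSG%011d", keep)),
              paths["hgnc"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
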