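#' Feature types recognised by the coordinate annotator
#'
#' The twelve reportable genomic feature types: seven canonical types read
#' directly from the GTF (exon, CDS, the two UTRs, the two codons, and the
#' transcript span) and five computed from them (intron, splice donor and
#' acceptor, upstream and downstream windows).  The transcription start site
#' (`"tss"`) is additionally carried in the interval index as a computed
#' 1-bp feature but is not part of the default reportable set; pass
#' `include_tss = TRUE` to the query functions to expose it.
#'
#' @param computed_only if `TRUE`, return only the computed types.
#' @return character vector of feature type names.
#' @export
feature_types <- function(computed_only = FALSE) {
  canonical <- c("exon", "cds", "five_prime_utr", "three_prime_utr",
                 "start_codon", "stop_codon", "transcript")
  computed <- c("upstream", "downstream", "intron",
                "splice_donor", "splice_acceptor")
  if (computed_only) computed else c(canonical, computed)
}

# canonical GTF type keyword -> internal feature type
.gtf_type_map <- c(
  exon = "exon", CDS = "cds", cds = "cds",
  five_prime_utr = "five_prime_utr", three_prime_utr = "three_prime_utr",
  start_codon = "start_codon", stop_codon = "stop_codon",
  transcript = "transcript", mRNA = "transcript"
)

#' Region configuration for computed features
#'
#' Lengths, in base pairs, of the feature windows computed from canonical
#' gene structure.  Upstream and downstream windows default to 5000 bp;
#' splice donor/acceptor default to 2 bp (the canonical GT/AG dinucleotides
#' at the intron ends).
#'
#' @param upstream,downstream window length in bp (>= 1).
#' @param splice_donor bp taken into the intron from its 5' end
#'   (transcription direction).
#' @param splice_acceptor bp taken into the intron from its 3' end.
#' @return an object of class `region_config`.
#' @export
region_config <- function(upstream = 5000L, downstream = 5000L,
                          splice_donor = 2L, splice_acceptor = 2L) {
  cfg <- list(upstream = as.integer(upstream),
              downstream = as.integer(downstream),
              splice_donor = as.integer(splice_donor),
              splice_acceptor = as.integer(splice_acceptor))
  if (any(vapply(cfg, function(x) length(x) != 1 || is.na(x) || x < 1, TRUE)))
    stop_fmt("all region lengths must be single integers >= 1")
  structure(cfg, class = "region_config")
}

#' Derive computed features for one transcript
#'
#' Given a transcript's sorted, non-overlapping exons, derive the computed
#' feature intervals: introns (gaps between consecutive exons), splice donor
#' (first `splice_donor` bp of each intron at its 5' end in transcription
#' direction), splice acceptor (last `splice_acceptor` bp at the intron 3'
#' end), the upstream and downstream windows flanking the transcript span
#' (strand-aware, clipped at position 1), and the 1-bp transcription start
#' site.  A single-exon transcript yields no intronic features but still has
#' upstream, downstream, and TSS.
#'
#' @param exons data.frame or matrix with columns `start`, `end`
#'   (1-based inclusive), sorted by start, non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param config a [region_config()].
#' @return data.frame with columns `feature_type`, `start`, `end`.
#' @export
derive_features <- function(exons, strand, config = region_config()) {
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons)))
    stop_fmt("exons must have columns start, end")
  stopifnot(strand %in% c("+", "-"))
  es <- as.integer(exons$start); ee <- as.integer(exons$end)
  o <- order(es); es <- es[o]; ee <- ee[o]
  if (any(es > ee)) stop_fmt("exon with start > end")
  if (length(es) > 1 && any(es[-1] <= ee[-length(ee)]))
    stop_fmt("exons overlap or touch; expected disjoint sorted exons")
  tx_start <- es[1]; tx_end <- ee[length(ee)]

  out <- list()
  add <- function(type, s, e) {
    if (length(s) && all(s <= e))
      out[[length(out) + 1]] <<- data.frame(feature_type = type,
                                            start = as.integer(s),
                                            end = as.integer(e))
  }

  k <- length(es)
  if (k >= 2) {
    is_ <- ee[-k] + 1L    # intron starts (genomic)
    ie_ <- es[-1] - 1L    # intron ends
    keep <- is_ <= ie_
    is_ <- is_[keep]; ie_ <- ie_[keep]
    if (length(is_)) {
      add("intron", is_, ie_)
      dl <- config$splice_donor; al <- config$splice_acceptor
      if (strand == "+") {
        add("splice_donor", is_, pmin(ie_, is_ + dl - 1L))
        add("splice_acceptor", pmax(is_, ie_ - al + 1L), ie_)
      } else {
        # transcription runs right-to-left: intron 5' end is the high side
        add("splice_donor", pmax(is_, ie_ - dl + 1L), ie_)
        add("splice_acceptor", is_, pmin(ie_, is_ + al - 1L))
      }
    }
  }

  ul <- config$upstream; dn <- config$downstream
  if (strand == "+") {
    if (tx_start > 1L) add("upstream", max(1L, tx_start - ul), tx_start - 1L)
    add("downstream", tx_end + 1L, tx_end + dn)
    add("tss", tx_start, tx_start)
  } else {
    add("upstream", tx_end + 1L, tx_end + ul)
    if (tx_start > 1L) add("downstream", max(1L, tx_start - dn), tx_start - 1L)
    add("tss", tx_end, tx_end)
  }
  if (!length(out))
    return(data.frame(feature_type = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

# Validate raw GTF lines before handing the file to rtracklayer: every
# non-comment line must have 9 tab-separated fields.
.check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  ntab <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  bad <- which(body & ntab != 8L)
  if (length(bad))
    stop_fmt("malformed GTF line %d in %s: expected 9 tab-separated columns, found %d",
             bad[1], path, ntab[bad[1]] + 1L)
  invisible(sum(body))
}

.empty_annotation <- function(config) {
  feats <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      transcript_id = character(), feature_type = character(),
                      stringsAsFactors = FALSE)
  structure(list(
    genes = data.frame(gene_id = character(), symbol = character(),
                       chrom = character(), start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = character(), gene_id = character(),
                             start = integer(), end = integer(),
                             stringsAsFactors = FALSE),
    features = feats,
    index = GenomicRanges::GRanges(),
    config = config, n_skipped = 0L, record_errors = character()
  ), class = "genome_annotation")
}

#' Parse a GTF and build a feature-indexed genome annotation
#'
#' Reads an Ensembl-dialect GTF (via [rtracklayer::import()]), keeps the
#' canonical feature rows (gene, transcript, exon, CDS, UTRs, codons),
#' derives the computed features per transcript with [derive_features()],
#' and assembles an interval-queryable, strand-aware index.  Rows whose
#' feature keyword is not recognised are skipped and counted
#' (`$n_skipped`).  Exon/CDS rows lacking a `transcript_id` are collected
#' as record-level errors (`$record_errors`), not fatal.  Transcript rows
#' missing from the file are inferred as the span of their exons; gene rows
#' missing are inferred as the span of their transcripts.  Duplicate
#' feature rows (same transcript, interval, type) are de-duplicated.
#'
#' @param path path to a GTF file (1-based inclusive coordinates).
#' @param config a [region_config()] controlling computed-feature lengths.
#' @return object of class `genome_annotation` with elements `genes`,
#'   `transcripts`, `features` (one row per indexed interval), `index`
#'   (a `GRanges` mirror of `features`), `config`, `n_skipped`,
#'   `record_errors`.
#' @export
load_gtf <- function(path, config = region_config()) {
  if (!file.exists(path)) stop_fmt("GTF file not found: %s", path)
  n_body <- .check_gtf_lines(path)
  if (n_body == 0L) return(.empty_annotation(config))

  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(.empty_annotation(config))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = if (!is.null(gr$gene_id)) as.character(gr$gene_id) else NA_character_,
    symbol = if (!is.null(gr$gene_name)) as.character(gr$gene_name) else NA_character_,
    transcript_id = if (!is.null(gr$transcript_id)) as.character(gr$transcript_id) else NA_character_,
    stringsAsFactors = FALSE
  )

  known <- df$type %in% c(names(.gtf_type_map), "gene")
  n_skipped <- sum(!known)
  df <- df[known, , drop = FALSE]

  record_errors <- character()
  needs_tx <- df$type %in% names(.gtf_type_map) & df$type != "transcript" &
    df$type != "mRNA"
  orphan <- needs_tx & (is.na(df$transcript_id) | !nzchar(df$transcript_id))
  if (any(orphan)) {
    record_errors <- sprintf("%s at %s:%d-%d has no transcript_id",
                             df$type[orphan], df$chrom[orphan],
                             df$start[orphan], df$end[orphan])
    df <- df[!orphan, , drop = FALSE]
  }

  feat <- df[df$type %in% names(.gtf_type_map), , drop = FALSE]
  feat$feature_type <- unname(.gtf_type_map[feat$type])
  # de-duplicate repeated canonical rows (same transcript, interval, type)
  feat <- feat[!duplicated(feat[c("chrom", "start", "end", "strand",
                                  "feature_type", "gene_id",
                                  "transcript_id")]), , drop = FALSE]

  # transcript table: explicit rows, else inferred from exon spans
  tx_rows <- feat[feat$feature_type == "transcript", , drop = FALSE]
  sub_rows <- feat[feat$feature_type != "transcript", , drop = FALSE]
  tx_ids <- unique(c(tx_rows$transcript_id, sub_rows$transcript_id))
  tx_ids <- tx_ids[!is.na(tx_ids)]
  if (!length(tx_ids)) return(.empty_annotation(config))

  tx_info <- lapply(tx_ids, function(tid) {
    tr <- tx_rows[tx_rows$transcript_id == tid, , drop = FALSE]
    sr <- sub_rows[sub_rows$transcript_id == tid, , drop = FALSE]
    any_r <- rbind(tr, sr)
    data.frame(transcript_id = tid,
               gene_id = any_r$gene_id[which(!is.na(any_r$gene_id))[1]],
               chrom = any_r$chrom[1], strand = any_r$strand[1],
               start = min(any_r$start), end = max(any_r$end),
               stringsAsFactors = FALSE)
  })
  transcripts <- do.call(rbind, tx_info)

  # gene table: explicit gene rows, else span of transcripts
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  gene_ids <- unique(c(gene_rows$gene_id, transcripts$gene_id))
  gene_ids <- gene_ids[!is.na(gene_ids)]
  genes <- do.call(rbind, lapply(gene_ids, function(gid) {
    grow <- gene_rows[!is.na(gene_rows$gene_id) & gene_rows$gene_id == gid, ,
                      drop = FALSE]
    trows <- transcripts[transcripts$gene_id == gid, , drop = FALSE]
    if (nrow(grow)) {
      data.frame(gene_id = gid, symbol = grow$symbol[1], chrom = grow$chrom[1],
                 start = min(grow$start, trows$start),
                 end = max(grow$end, trows$end),
                 strand = grow$strand[1], stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = gid, symbol = NA_character_, chrom = trows$chrom[1],
                 start = min(trows$start), end = max(trows$end),
                 strand = trows$strand[1], stringsAsFactors = FALSE)
    }
  }))

  # per-transcript feature assembly: canonical rows + derived features
  feat_list <- vector("list", nrow(transcripts) + 1L)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    sr <- sub_rows[sub_rows$transcript_id == tx$transcript_id, , drop = FALSE]
    canon <- data.frame(feature_type = c("transcript", sr$feature_type),
                        start = c(tx$start, sr$start),
                        end = c(tx$end, sr$end), stringsAsFactors = FALSE)
    ex <- sr[sr$feature_type == "exon", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0L) ex <- data.frame(start = tx$start, end = tx$end)
    drv <- derive_features(ex, tx$strand, config)
    all_f <- rbind(canon, drv)
    all_f$chrom <- tx$chrom; all_f$strand <- tx$strand
    all_f$gene_id <- tx$gene_id; all_f$transcript_id <- tx$transcript_id
    feat_list[[i]] <- all_f
  }
  features <- do.call(rbind, feat_list)
  features <- features[, c("chrom", "start", "end", "strand", "gene_id",
                           "transcript_id", "feature_type")]
  features <- unique(features)
  features <- features[order(features$chrom, features$start, features$end,
                             features$gene_id, features$transcript_id,
                             features$feature_type), , drop = FALSE]
  rownames(features) <- NULL

  idx <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand
  )
  S4Vectors::mcols(idx)$gene_id <- features$gene_id
  S4Vectors::mcols(idx)$transcript_id <- features$transcript_id
  S4Vectors::mcols(idx)$feature_type <- features$feature_type

  structure(list(genes = genes[order(genes$gene_id), , drop = FALSE],
                 transcripts = transcripts,
                 features = features, index = idx, config = config,
                 n_skipped = n_skipped, record_errors = record_errors),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d indexed intervals\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$features)))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(x$genes$chrom)), collapse = ", ")))
  cat(sprintf("  windows: upstream %d, downstream %d, donor %d, acceptor %d bp\n",
              x$config$upstream, x$config$downstream,
              x$config$splice_donor, x$config$splice_acceptor))
  if (x$n_skipped) cat(sprintf("  %d unknown-type GTF rows skipped\n", x$n_skipped))
  if (length(x$record_errors))
    cat(sprintf("  %d record-level errors collected\n", length(x$record_errors)))
  invisible(x)
}

#' Query all features overlapping a single position
#'
#' Returns every indexed (gene, transcript, feature type, interval) whose
#' interval contains `pos`, in deterministic (gene_id, transcript_id,
#' feature_type) order.  Unknown chromosomes yield an empty result with a
#' warning (assemblies differ; this is not an error).
#'
#' @param annotation a `genome_annotation`.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param include_tss also report the 1-bp `tss` feature (off by default;
#'   the reportable set is the twelve types of [feature_types()]).
#' @return data.frame with columns `gene_id`, `transcript_id`,
#'   `feature_type`, `start`, `end`.
#' @export
query_point <- function(annotation, chrom, pos, include_tss = FALSE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  f <- annotation$features
  if (nrow(f) && !chrom %in% f$chrom)
    warning(sprintf("chromosome '%s' not present in annotation", chrom),
            call. = FALSE)
  hits <- f[f$chrom == chrom & f$start <= pos & f$end >= pos, , drop = FALSE]
  if (!include_tss) hits <- hits[hits$feature_type != "tss", , drop = FALSE]
  hits <- hits[order(hits$gene_id, hits$transcript_id, hits$feature_type,
                     hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("gene_id", "transcript_id", "feature_type", "start", "end")]
}

#' Save / load a genome annotation index
#'
#' Round-trip lossless (de)serialization of a built index to one portable
#' file, so a CLI can build once and annotate many times.
#'
#' @param annotation a `genome_annotation`.
#' @param path file path.
#' @return `read_annotation` returns the `genome_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  saveRDS(annotation, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- readRDS(path)
  if (!inherits(ann, "genome_annotation"))
    stop_fmt("%s does not contain a genome_annotation", path)
  ann
}
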