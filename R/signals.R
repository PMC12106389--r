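#' Read a coordinate-level signal file
#'
#' Accepts a TSV/CSV with a header containing at least `chrom` and `pos`
#' (optionally `end` and `pvalue`; extra columns are preserved verbatim),
#' or a headerless BED 3+ file (detected by a `.bed` extension), whose
#' 0-based half-open intervals are converted to 1-based inclusive on read.
#'
#' @param path input file.
#' @return data.frame with columns `chrom`, `pos`, `end` (defaulting to
#'   `pos`), optional `pvalue`, plus any extra columns.
#' @export
read_signals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop_fmt("BED file %s has fewer than 3 columns", path)
    out <- data.frame(chrom = as.character(df[[1]]),
                      pos = as.integer(df[[2]]) + 1L,
                      end = as.integer(df[[3]]), stringsAsFactors = FALSE)
    if (ncol(df) >= 4) out <- cbind(out, df[, 4:ncol(df), drop = FALSE])
    return(out)
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop_fmt("signal file %s must have columns 'chrom' and 'pos'", path)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$end <- if ("end" %in% names(df)) as.integer(df$end) else df$pos
  df
}

.validate_signals <- function(signals) {
  stopifnot(is.data.frame(signals), all(c("chrom", "pos") %in% names(signals)))
  if (!"end" %in% names(signals)) signals$end <- signals$pos
  signals$end[is.na(signals$end)] <- signals$pos[is.na(signals$end)]
  bad <- is.na(signals$pos) | signals$pos < 1 | signals$pos > signals$end
  list(signals = signals, bad = which(bad))
}

#' Find the nearest gene for each signal
#'
#' Distance is measured to the gene body span (not the upstream-extended
#' span) on the same chromosome: 0 when the signal overlaps the span,
#' otherwise the bp offset between the signal and the nearer span boundary
#' (a signal one base past the gene end has distance 1).  Ties are broken
#' by smaller gene start, then
#' lexicographic gene_id.  Signals on chromosomes carrying no genes get
#' `NA` gene and distance.  Signals have no strand; gene strand is ignored.
#'
#' @param signals data.frame with `chrom`, `pos` and optional `end`.
#' @param annotation a `genome_annotation`.
#' @return data.frame with columns `gene_id` and `distance`, one row per
#'   input signal, in input order.
#' @export
nearest_gene <- function(signals, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  v <- .validate_signals(signals)
  signals <- v$signals
  n <- nrow(signals)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n))
  genes <- annotation$genes
  if (!nrow(genes) || !n) return(out)

  lev <- union(unique(signals$chrom), unique(genes$chrom))
  s1 <- pmax(1L, ifelse(is.na(signals$pos), 1L, signals$pos))
  e1 <- pmax(s1, ifelse(is.na(signals$end), 1L, signals$end))
  sg <- GenomicRanges::GRanges(
    factor(signals$chrom, levels = lev), IRanges::IRanges(s1, e1))
  gg <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lev),
    IRanges::IRanges(genes$start, genes$end))

  # candidate nearest genes per signal: overlapping genes plus the nearest
  # gene on each flank (distanceToNearest does not surface equidistant
  # ties on opposite sides, so collect both sides explicitly)
  cand <- rbind(
    as.matrix(GenomicRanges::findOverlaps(sg, gg, ignore.strand = TRUE)),
    as.matrix(GenomicRanges::precede(sg, gg, select = "all",
                                     ignore.strand = TRUE)),
    as.matrix(GenomicRanges::follow(sg, gg, select = "all",
                                    ignore.strand = TRUE))
  )
  if (!nrow(cand)) return(out)
  qh <- cand[, 1L]; sh <- cand[, 2L]
  # bp offset to the gene span: 0 iff the signal overlaps it
  d <- pmax(0L, genes$start[sh] - e1[qh], s1[qh] - genes$end[sh])
  # tie-break among equal-distance candidates: smaller gene start, then id
  ord <- order(qh, d, genes$start[sh], genes$gene_id[sh])
  qh <- qh[ord]; sh <- sh[ord]; d <- d[ord]
  first <- !duplicated(qh)
  out$gene_id[qh[first]] <- genes$gene_id[sh[first]]
  out$distance[qh[first]] <- as.integer(d[first])
  if (length(v$bad)) { out$gene_id[v$bad] <- NA; out$distance[v$bad] <- NA }
  out
}

#' Annotate signals with overlapping gene features
#'
#' Intersects each signal (a point, or a region when `end > pos`; any
#' overlap of >= 1 bp counts) with the feature interval index and reports
#' every hit whose feature type is in `selected_types`.  Inputs are never
#' mutated; output order equals input order.  Rows failing validation
#' (`pos < 1` or `pos > end`) are skipped and reported.
#'
#' @param signals data.frame with columns `chrom`, `pos`, optional `end`,
#'   extra columns passed through.
#' @param annotation a `genome_annotation`.
#' @param selected_types subset of [feature_types()] (plus optionally
#'   `"tss"`); non-empty.
#' @param nearest also compute nearest-gene assignment (default `TRUE`).
#' @return object of class `annotated_signals`: a list with `signals`
#'   (input rows plus `signal_idx`, `n_hits`, `nearest_gene_id`,
#'   `nearest_distance`), `hits` (long table: `signal_idx`, `gene_id`,
#'   `transcript_id`, `feature_type`, `start`, `end`), and `skipped`
#'   (input row numbers that failed validation).
#' @export
annotate_signals <- function(signals, annotation,
                             selected_types = feature_types(),
                             nearest = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!length(selected_types)) stop_fmt("selected_types must be non-empty")
  bad_types <- setdiff(selected_types, c(feature_types(), "tss"))
  if (length(bad_types))
    stop_fmt("unknown feature type(s): %s", semicolon(bad_types))

  v <- .validate_signals(signals)
  signals <- v$signals
  keep <- setdiff(seq_len(nrow(signals)), v$bad)
  if (length(v$bad))
    warning(sprintf("%d signal row(s) failed validation and were skipped: %s",
                    length(v$bad), semicolon(head(v$bad, 5))), call. = FALSE)
  sig <- signals[keep, , drop = FALSE]
  sig$signal_idx <- keep

  f <- annotation$features
  hits <- data.frame(signal_idx = integer(), gene_id = character(),
                     transcript_id = character(), feature_type = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  if (nrow(sig) && nrow(f)) {
    fsel <- f[f$feature_type %in% selected_types, , drop = FALSE]
    if (nrow(fsel)) {
      lev <- union(unique(sig$chrom), unique(fsel$chrom))
      sg <- GenomicRanges::GRanges(factor(sig$chrom, levels = lev),
                                   IRanges::IRanges(sig$pos, sig$end))
      fg <- GenomicRanges::GRanges(factor(fsel$chrom, levels = lev),
                                   IRanges::IRanges(fsel$start, fsel$end))
      ov <- GenomicRanges::findOverlaps(sg, fg, ignore.strand = TRUE)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        hits <- data.frame(signal_idx = sig$signal_idx[qh],
                           gene_id = fsel$gene_id[sh],
                           transcript_id = fsel$transcript_id[sh],
                           feature_type = fsel$feature_type[sh],
                           start = fsel$start[sh], end = fsel$end[sh],
                           stringsAsFactors = FALSE)
        hits <- hits[order(hits$signal_idx, hits$gene_id, hits$transcript_id,
                           hits$feature_type, hits$start), , drop = FALSE]
        rownames(hits) <- NULL
      }
    }
  }
  sig$n_hits <- as.integer(table(factor(hits$signal_idx,
                                        levels = sig$signal_idx)))
  if (nearest) {
    ng <- nearest_gene(sig, annotation)
    sig$nearest_gene_id <- ng$gene_id
    sig$nearest_distance <- ng$distance
  }
  structure(list(signals = sig, hits = hits, skipped = v$bad),
            class = "annotated_signals")
}

#' @export
print.annotated_signals <- function(x, ...) {
  cat(sprintf("annotated_signals: %d signals (%d skipped), %d feature hits\n",
              nrow(x$signals), length(x$skipped), nrow(x$hits)))
  invisible(x)
}

#' Wide per-signal feature indicator table
#'
#' One row per annotated signal, one 0/1 indicator column per feature type,
#' summarising which feature types each signal overlaps.
#'
#' @param annotated an `annotated_signals` object.
#' @param types feature types to report as columns.
#' @return data.frame: `signal_idx`, `chrom`, `pos`, `end`, then one
#'   indicator column per type.
#' @export
signal_feature_matrix <- function(annotated, types = feature_types()) {
  stopifnot(inherits(annotated, "annotated_signals"))
  sig <- annotated$signals
  out <- sig[, c("signal_idx", "chrom", "pos", "end"), drop = FALSE]
  for (ty in types) {
    idx <- unique(annotated$hits$signal_idx[annotated$hits$feature_type == ty])
    out[[ty]] <- as.integer(out$signal_idx %in% idx)
  }
  rownames(out) <- NULL
  out
}

#' Write annotation results to TSV
#'
#' Writes the long (one row per signal-feature hit) table and, optionally,
#' the wide indicator summary.
#'
#' @param annotated an `annotated_signals` object.
#' @param path output TSV for the hit table.
#' @param summary_path optional TSV path for [signal_feature_matrix()].
#' @export
write_annotated_signals <- function(annotated, path, summary_path = NULL) {
  stopifnot(inherits(annotated, "annotated_signals"))
  long <- merge(annotated$signals[, c("signal_idx", "chrom", "pos", "end")],
                annotated$hits, by = "signal_idx", all.x = TRUE)
  long <- long[order(long$signal_idx), , drop = FALSE]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    write.table(signal_feature_matrix(annotated), summary_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
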