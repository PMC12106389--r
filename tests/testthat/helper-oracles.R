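# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops, enumeration, and quadrature.

# --- hypergeometric tail by exhaustive enumeration -------------------------
# P(X >= x) where X = successes among n draws without replacement from a
# population of N with K successes.  Enumerates all C(N, n) draws.
enum_hyper_tail <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)   # items 1..K are the successes
  mean(succ >= x)
}

# --- Fisher combination by chi-square quadrature ---------------------------
quad_fisher <- function(p) {
  X <- -2 * sum(log(p))
  k <- length(p)
  if (X == 0) return(1)
  val <- stats::integrate(function(t) stats::dchisq(t, df = 2 * k),
                          lower = X, upper = Inf,
                          rel.tol = 1e-13, abs.tol = 0)$value
  min(1, val)
}

# --- brute-force interval scan over an annotation's stored intervals -------
scan_point_hits <- function(annotation, chrom, pos, end = pos,
                            types = feature_types()) {
  f <- annotation$features
  hit <- f$chrom == chrom & f$start <= end & f$end >= pos &
    f$feature_type %in% types
  out <- f[hit, c("gene_id", "transcript_id", "feature_type", "start", "end")]
  out <- out[order(out$gene_id, out$transcript_id, out$feature_type,
                   out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- brute-force nearest gene ----------------------------------------------
scan_nearest <- function(annotation, chrom, pos, end = pos) {
  g <- annotation$genes[annotation$genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_integer_))
  d <- pmax(0L, pmax(g$start - end, pos - g$end))
  o <- order(d, g$start, g$gene_id)
  list(gene_id = g$gene_id[o[1]], distance = d[o[1]])
}

# --- direct O(n) running-sum walk (GSEA oracle) ----------------------------
walk_es <- function(in_set, scores, weight = 0) {
  n <- length(in_set)
  m <- sum(in_set)
  w <- if (weight == 0) rep(1, n) else abs(scores)
  inc <- ifelse(in_set, w / sum(w[in_set]), -1 / (n - m))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# --- independent GTF re-parse: canonical rows + expected derived counts ----
# Parses the raw lines with regexes (no rtracklayer) and counts, per
# transcript, the exons and the derived features they imply.
reparse_gtf_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(f, `[[`, "", 3)
  attr9 <- vapply(f, `[[`, "", 9)
  tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attr9)
  tid[!grepl("transcript_id", attr9)] <- NA
  ex <- type == "exon" & !is.na(tid)
  ex_start <- as.integer(vapply(f, `[[`, "", 4))[ex]
  tx <- tid[ex]
  exons_per_tx <- table(tx)
  n_tx <- length(unique(tid[!is.na(tid)]))
  list(
    n_exons = sum(ex),
    n_introns = sum(pmax(0L, as.integer(exons_per_tx) - 1L)),
    n_tx = n_tx,
    n_upstream = n_tx,        # one window per transcript (may be clipped away
                              # only when a transcript starts at position 1)
    n_downstream = n_tx,
    exons_per_tx = exons_per_tx
  )
}

# --- tiny in-code GTF builders ---------------------------------------------
gtf_line <- function(chrom, type, s, e, strand, attrs) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e, strand, attrs)
}

write_tiny_gtf <- function(path, strand = "+",
                           exons = list(c(100L, 200L), c(300L, 400L),
                                        c(600L, 700L))) {
  a <- 'gene_id "G1"; gene_name "SYM1"; transcript_id "T1";'
  s <- min(vapply(exons, `[[`, 0L, 1)); e <- max(vapply(exons, `[[`, 0L, 2))
  lines <- c(
    gtf_line("chr1", "gene", s, e, strand, 'gene_id "G1"; gene_name "SYM1";'),
    gtf_line("chr1", "transcript", s, e, strand, a),
    vapply(exons, function(x) gtf_line("chr1", "exon", x[1], x[2], strand, a), "")
  )
  writeLines(lines, path)
  path
}

# Annotation used by several files: the default 20-gene fixture, built once.
fixture_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 1L)
      gtf <- file.path(tempdir(), "fixture_seed1.gtf")
      make_gtf(spec, gtf)
      cache <<- load_gtf(gtf)
    }
    cache
  }
})
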