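#' Read / write a gene set library in GMT format
#'
#' GMT: one set per line, `term_id TAB term_name TAB member TAB member ...`.
#' Round-trips losslessly through [write_gmt()].
#'
#' @param path GMT file path.
#' @param source library source tag (e.g. `"GO"`, `"KEGG"`, `"TF"`,
#'   `"custom"`).
#' @param species optional species tag.
#' @return object of class `gene_set_library`: list with `source`,
#'   `species`, and `sets` — a named (by term_id) list of
#'   `list(term_id, term_name, members)`.
#' @export
read_gmt <- function(path, source = "custom", species = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_fmt("GMT line %d: expected >= 3 tab-separated fields, found %d",
               i, length(f))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop_fmt("GMT line %d: set '%s' has no members", i, f[1])
    sets[[i]] <- list(term_id = f[1], term_name = f[2], members = members)
    ids[i] <- f[1]
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_fmt("duplicate term_id in GMT: %s", dup[1])
  names(sets) <- ids
  structure(list(source = source, species = species, sets = sets),
            class = "gene_set_library")
}

#' Build a gene set library in memory
#'
#' @param sets named list: term_id -> character vector of member gene IDs,
#'   or a list of `list(term_id, term_name, members)`.
#' @param term_names optional character vector of descriptions.
#' @inheritParams read_gmt
#' @return a `gene_set_library`.
#' @export
gene_set_library <- function(sets, term_names = NULL, source = "custom",
                             species = NA_character_) {
  if (length(sets) && is.character(sets[[1]])) {
    ids <- names(sets)
    if (is.null(ids)) stop_fmt("sets must be named by term_id")
    nm <- term_names %||% ids
    sets <- Map(function(id, name, members)
      list(term_id = id, term_name = name, members = unique(members)),
      ids, nm, sets)
  }
  ids <- vapply(sets, `[[`, "", "term_id")
  if (anyDuplicated(ids)) stop_fmt("duplicate term_id: %s", ids[duplicated(ids)][1])
  names(sets) <- ids
  structure(list(source = source, species = species, sets = sets),
            class = "gene_set_library")
}

#' @rdname read_gmt
#' @param library a `gene_set_library`.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(library$sets, function(s)
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_library <- function(x, ...) {
  sizes <- lengths(lapply(x$sets, `[[`, "members"))
  cat(sprintf("gene_set_library [%s]: %d sets, member counts %s-%s\n",
              x$source, length(x$sets),
              if (length(sizes)) min(sizes) else 0,
              if (length(sizes)) max(sizes) else 0))
  invisible(x)
}

.check_study <- function(study) {
  stopifnot(is.data.frame(study),
            all(c("gene_id", "significant") %in% names(study)))
  study$gene_id <- as.character(study$gene_id)
  study$significant <- as.logical(study$significant)
  study <- study[!duplicated(study$gene_id), , drop = FALSE]
  if (!any(study$significant)) stop_fmt("no significant genes in study list")
  if (all(study$significant))
    warning("all background genes are flagged significant; every P-value is 1",
            call. = FALSE)
  study
}

#' Overrepresentation analysis (hypergeometric test)
#'
#' Tests, per gene set, whether the significant subset of the study list
#' contains more members of the set than expected by chance, against the
#' study's own background universe (the background is enforced: it is the
#' full uploaded gene list, not a genome-wide default).  Gene sets are
#' first intersected with the background; sets whose intersected size falls
#' outside `[min_set, max_set]` are skipped.  The one-sided upper-tail
#' hypergeometric probability P(X >= overlap) is computed with population
#' N = background size, K = set size in background, n = number of
#' significant genes.  Benjamini-Hochberg adjustment is applied across the
#' tested terms of the library.
#'
#' @param study data.frame with columns `gene_id` and `significant`
#'   (logical or 0/1); all rows form the background, flagged rows the
#'   significant subset.
#' @param library a `gene_set_library`.
#' @param min_set,max_set bounds on the background-intersected set size.
#' @return data.frame sorted by `p_raw`: `term_id`, `term_name`, `source`,
#'   `n_background`, `n_significant`, `n_set_in_background`, `n_overlap`,
#'   `fold_enrichment`, `p_raw`, `p_adjusted`, `overlap_genes`
#'   (semicolon-joined).
#' @export
ora <- function(study, library, min_set = 2L, max_set = 5000L) {
  stopifnot(inherits(library, "gene_set_library"))
  study <- .check_study(study)
  background <- study$gene_id
  signif_genes <- study$gene_id[study$significant]
  N <- length(background); n <- length(signif_genes)

  rows <- lapply(library$sets, function(s) {
    in_bg <- intersect(s$members, background)
    K <- length(in_bg)
    if (K < min_set || K > max_set) return(NULL)
    ov <- intersect(in_bg, signif_genes)
    x <- length(ov)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               source = library$source, n_background = N, n_significant = n,
               n_set_in_background = K, n_overlap = x,
               fold_enrichment = (x / n) / (K / N),
               p_raw = p, overlap_genes = semicolon(sort(ov)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      source = character(), n_background = integer(),
                      n_significant = integer(), n_set_in_background = integer(),
                      n_overlap = integer(), fold_enrichment = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  res <- res[order(res$p_raw, res$term_id),
             c("term_id", "term_name", "source", "n_background",
               "n_significant", "n_set_in_background", "n_overlap",
               "fold_enrichment", "p_raw", "p_adjusted", "overlap_genes")]
  rownames(res) <- NULL
  res
}

# Running-sum enrichment score from sorted hit positions.
# pos: 1-based sorted positions of set members in the ranked list;
# n: list length; w: per-hit increments summing to 1 (weight 0: rep(1/m, m)).
# The walk's extrema occur immediately after each hit and immediately
# before each hit; ES is the signed extremum of largest magnitude.
.es_from_positions <- function(pos, n, w) {
  m <- length(pos)
  miss <- 1 / (n - m)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(m)) * miss
  before <- c(0, cw[-m]) - (pos - 1 - (seq_len(m) - 1)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Gene set enrichment analysis on a pre-ranked list
#'
#' Kolmogorov-Smirnov-style running-sum enrichment.  Walking the list from
#' top (largest score) to bottom, set members ("hits") increment the sum by
#' `|score|^weight / sum(|score_hits|^weight)` and non-members decrement it
#' by `1/(n_list - n_set)`; the enrichment score (ES) is the signed
#' extremum of the walk, positive when the set concentrates at the top of
#' the ranking and negative at the bottom.  `weight = 0` (default) is the
#' classic equal-step KS form; `weight = 1` is the score-weighted variant.
#' Significance is assessed by gene-label permutation: member labels are
#' re-drawn uniformly over the ranked genes `n_perm` times and
#' `p = (1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)`.  BH adjustment is
#' applied across tested terms.  Ties in scores are broken by gene_id so
#' the ES is deterministic.
#'
#' @param ranked data.frame with columns `gene_id` (no duplicates) and
#'   `score` (real ranking statistic, not all equal).
#' @param library a `gene_set_library`.
#' @param n_perm number of label permutations (>= 100).
#' @param weight 0 or 1.
#' @param seed integer seed for the permutation RNG; the caller's RNG state
#'   is left untouched.
#' @param min_set,max_set bounds on the in-list set size; sets with fewer
#'   than 2 members in the list, or covering the whole list, are skipped
#'   with a warning.
#' @return data.frame sorted by `p_raw`: `term_id`, `term_name`, `source`,
#'   `n_list`, `n_set_in_list`, `es`, `p_raw`, `p_adjusted`,
#'   `overlap_genes`.
#' @export
gsea <- function(ranked, library, n_perm = 1000L, weight = 0, seed = 1L,
                 min_set = 2L, max_set = 5000L) {
  stopifnot(inherits(library, "gene_set_library"))
  stopifnot(is.data.frame(ranked), all(c("gene_id", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) stop_fmt("duplicate gene_id in ranked list")
  if (n_perm < 100) stop_fmt("n_perm must be >= 100")
  if (!weight %in% c(0, 1)) stop_fmt("weight must be 0 or 1")
  score <- as.numeric(ranked$score)
  if (anyNA(score)) stop_fmt("NA ranking score")
  if (length(unique(score)) == 1L)
    stop_fmt("constant ranking scores: list cannot be ordered")
  o <- order(-score, ranked$gene_id)
  genes <- as.character(ranked$gene_id)[o]
  score <- score[o]
  n <- length(genes)
  wvec <- if (weight == 0) rep(1, n) else abs(score)

  es_of <- function(pos) {
    w <- wvec[pos]
    .es_from_positions(pos, n, w / sum(w))
  }

  rows <- with_seed(seed, {
    out <- list()
    for (s in library$sets) {
      pos <- sort(match(intersect(s$members, genes), genes))
      m <- length(pos)
      if (m < max(2L, min_set) || m >= n || m > max_set) {
        warning(sprintf("set '%s' skipped (%d member(s) in ranked list)",
                        s$term_id, m), call. = FALSE)
        next
      }
      es_obs <- es_of(pos)
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        perm_pos <- sort(sample.int(n, m))
        if (abs(es_of(perm_pos)) >= abs(es_obs)) exceed <- exceed + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        term_id = s$term_id, term_name = s$term_name, source = library$source,
        n_list = n, n_set_in_list = m, es = es_obs,
        p_raw = (1 + exceed) / (1 + n_perm),
        overlap_genes = semicolon(genes[pos]), stringsAsFactors = FALSE)
    }
    out
  })
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      source = character(), n_list = integer(),
                      n_set_in_list = integer(), es = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  res <- res[order(res$p_raw, res$term_id),
             c("term_id", "term_name", "source", "n_list", "n_set_in_list",
               "es", "p_raw", "p_adjusted", "overlap_genes")]
  rownames(res) <- NULL
  res
}

#' Transcription factor target enrichment
#'
#' Hypergeometric enrichment of TF -> target-gene sets (human-derived) in a
#' study gene list.  Statistics are identical to [ora()]; the term is the
#' transcription factor.  When the study genes are not human, supply an
#' [id_mapping_table()] (`id_table`) and the namespaces to map through:
#' study genes are first converted to human symbols, unmapped genes are
#' dropped, and both the background (N) and the set sizes (K) are computed
#' on the mapped universe only.
#'
#' @inheritParams ora
#' @param tf_library a `gene_set_library` of TF target sets keyed by TF
#'   name, with members as human gene symbols.
#' @param id_table optional `id_mapping_table` for ortholog mapping.
#' @param from_ns study-gene namespace in `id_table` (e.g. `"ensembl"`).
#' @param to_ns target namespace, default `"hgnc_human_symbol"`.
#' @return as [ora()], with one extra attribute `n_unmapped` when mapping
#'   was performed.
#' @export
tf_enrichment <- function(study, tf_library, min_set = 2L, max_set = 5000L,
                          id_table = NULL, from_ns = "ensembl",
                          to_ns = "hgnc_human_symbol") {
  study <- .check_study(study)
  n_unmapped <- NA_integer_
  if (!is.null(id_table)) {
    conv <- convert_ids(study$gene_id, from_ns, to_ns, id_table)
    mapped <- conv$status != "unmapped"
    n_unmapped <- sum(!mapped)
    if (!any(mapped))
      stop_fmt(paste("no study genes map to human orthologs;",
                     "TF target sets are human-derived, so study IDs must be",
                     "convertible to human symbols via the mapping table"))
    rows <- lapply(which(mapped), function(i) {
      data.frame(gene_id = conv$outputs[[i]],
                 significant = study$significant[i], stringsAsFactors = FALSE)
    })
    study <- do.call(rbind, rows)
    # a human symbol reached from both a significant and a non-significant
    # source gene counts as significant
    sig <- tapply(study$significant, study$gene_id, any)
    study <- data.frame(gene_id = names(sig), significant = as.logical(sig),
                        stringsAsFactors = FALSE)
  }
  res <- ora(study, tf_library, min_set = min_set, max_set = max_set)
  attr(res, "n_unmapped") <- n_unmapped
  res
}
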