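.id_namespaces <- c("ensembl", "entrez", "symbol", "vgnc",
                    "hgnc_human_symbol", "human_ensembl")

.ns_column <- c(ensembl = "ensembl_id", entrez = "entrez_id",
                symbol = "symbol", vgnc = "vgnc_id",
                hgnc_human_symbol = "hgnc_human_symbol",
                human_ensembl = "human_ensembl_id")

#' Gene ID correspondence table
#'
#' A record-oriented table linking a species' gene identifiers across
#' sources: Ensembl gene ID, NCBI Entrez ID, display symbol, VGNC ID, and
#' the human ortholog (HGNC symbol and human Ensembl ID).  Any field may
#' be missing; many-to-many correspondences are kept as separate records,
#' never collapsed.
#'
#' @param records data.frame with any of the columns `ensembl_id`,
#'   `entrez_id`, `symbol`, `vgnc_id`, `hgnc_human_symbol`,
#'   `human_ensembl_id`; missing columns are added as NA.
#' @return object of class `id_mapping_table` (a data.frame).
#' @export
id_mapping_table <- function(records) {
  stopifnot(is.data.frame(records))
  cols <- unname(.ns_column)
  unknown <- setdiff(names(records), cols)
  if (length(unknown))
    stop_fmt("unknown ID table column(s): %s; valid: %s",
             semicolon(unknown), semicolon(cols))
  for (cc in cols) {
    if (!cc %in% names(records)) records[[cc]] <- NA_character_
    records[[cc]] <- as.character(records[[cc]])
    records[[cc]][!is.na(records[[cc]]) & !nzchar(records[[cc]])] <- NA
  }
  records <- records[, cols]
  all_na <- rowSums(!is.na(records)) == 0
  records <- records[!all_na, , drop = FALSE]
  records <- unique(records)
  rownames(records) <- NULL
  class(records) <- c("id_mapping_table", "data.frame")
  records
}

.read_id_tsv <- function(path, required, label) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "")
  names(df) <- sub("^#", "", names(df))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_fmt("%s table %s is missing required column(s): %s",
             label, path, semicolon(missing))
  df
}

#' Load and merge gene ID correspondence tables
#'
#' Reads TSV extracts in the layouts of the public ID sources and merges
#' them into one [id_mapping_table()].  Recognised entries of `paths`:
#' \describe{
#'   \item{gene2ensembl}{columns `GeneID`, `Ensembl_gene_identifier`
#'     (tax_id and others ignored) — the Entrez/Ensembl backbone.}
#'   \item{gene_info}{columns `GeneID`, `Symbol` — display symbols.}
#'   \item{vgnc}{columns `vgnc_id`, `ensembl_gene_id`, optional `symbol`.}
#'   \item{hgnc}{columns `symbol`, `ensembl_gene_id` of the human
#'     orthologs; joined to species records by case-insensitive symbol
#'     match (VGNC symbols mirror their HGNC counterparts).}
#' }
#' Only the listed columns are read; empty fields become NA but the record
#' is retained.  Conflicting many-to-many mappings are all preserved.
#'
#' @param paths named list/character vector of file paths; any subset of
#'   the recognised names.
#' @return an `id_mapping_table`.
#' @export
load_id_tables <- function(paths) {
  paths <- as.list(paths)
  unknown <- setdiff(names(paths), c("gene2ensembl", "gene_info", "vgnc", "hgnc"))
  if (length(unknown))
    stop_fmt("unknown ID table source(s): %s", semicolon(unknown))

  rec <- data.frame(ensembl_id = character(), entrez_id = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(paths$gene2ensembl)) {
    g2e <- .read_id_tsv(paths$gene2ensembl,
                        c("GeneID", "Ensembl_gene_identifier"), "gene2ensembl")
    rec <- data.frame(ensembl_id = as.character(g2e$Ensembl_gene_identifier),
                      entrez_id = as.character(g2e$GeneID),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(paths$gene_info)) {
    gi <- .read_id_tsv(paths$gene_info, c("GeneID", "Symbol"), "gene_info")
    sym <- data.frame(entrez_id = as.character(gi$GeneID),
                      symbol = as.character(gi$Symbol),
                      stringsAsFactors = FALSE)
    rec <- if (nrow(rec)) merge(rec, sym, by = "entrez_id", all = TRUE)
           else cbind(sym, ensembl_id = NA_character_)
  }
  if (!"symbol" %in% names(rec)) rec$symbol <- NA_character_
  if (!is.null(paths$vgnc)) {
    vg <- .read_id_tsv(paths$vgnc, c("vgnc_id", "ensembl_gene_id"), "VGNC")
    vrec <- data.frame(ensembl_id = as.character(vg$ensembl_gene_id),
                       vgnc_id = as.character(vg$vgnc_id),
                       vgnc_symbol = if ("symbol" %in% names(vg))
                         as.character(vg$symbol) else NA_character_,
                       stringsAsFactors = FALSE)
    rec <- if (nrow(rec)) merge(rec, vrec, by = "ensembl_id", all = TRUE)
           else cbind(vrec, entrez_id = NA_character_, symbol = NA_character_)
    fill <- is.na(rec$symbol) & !is.na(rec$vgnc_symbol)
    rec$symbol[fill] <- rec$vgnc_symbol[fill]
    rec$vgnc_symbol <- NULL
  }
  if (!"vgnc_id" %in% names(rec)) rec$vgnc_id <- NA_character_
  if (!is.null(paths$hgnc)) {
    hg <- .read_id_tsv(paths$hgnc, c("symbol", "ensembl_gene_id"), "HGNC")
    hrec <- data.frame(join_key = toupper(as.character(hg$symbol)),
                       hgnc_human_symbol = as.character(hg$symbol),
                       human_ensembl_id = as.character(hg$ensembl_gene_id),
                       stringsAsFactors = FALSE)
    rec$join_key <- toupper(rec$symbol)
    rec <- merge(rec, hrec, by = "join_key", all.x = TRUE)
    rec$join_key <- NULL
  }
  id_mapping_table(rec)
}

#' @export
print.id_mapping_table <- function(x, ...) {
  cat(sprintf("id_mapping_table: %d records; populated fields: %s\n",
              nrow(x),
              semicolon(names(x)[colSums(!is.na(as.data.frame(x))) > 0])))
  invisible(x)
}

#' Convert gene identifiers between namespaces
#'
#' For each input ID, all records matching it in the source namespace are
#' found and every distinct non-missing value of the target namespace is
#' returned.  Many-to-many mappings are surfaced, never collapsed to a
#' first match.  Matching is case-sensitive for `ensembl`, `entrez`,
#' `vgnc`, and `human_ensembl`, and case-insensitive for symbol namespaces
#' by default (symbol casing conventions differ across species).
#'
#' @param ids character vector of input identifiers.
#' @param from_ns,to_ns distinct namespaces, among `"ensembl"`,
#'   `"entrez"`, `"symbol"`, `"vgnc"`, `"hgnc_human_symbol"`,
#'   `"human_ensembl"`.
#' @param table an `id_mapping_table`.
#' @param symbol_case_insensitive match symbols ignoring case.
#' @return data.frame in input order: `input`, `outputs` (list column),
#'   `n_outputs`, `status` (`mapped`, `unmapped`, or `multi`), `output`
#'   (semicolon-joined convenience column).
#' @export
convert_ids <- function(ids, from_ns, to_ns, table,
                        symbol_case_insensitive = TRUE) {
  stopifnot(inherits(table, "id_mapping_table"))
  for (ns in c(from_ns, to_ns))
    if (!ns %in% .id_namespaces)
      stop_fmt("unknown namespace '%s'; valid namespaces: %s",
               ns, semicolon(.id_namespaces))
  if (from_ns == to_ns) stop_fmt("from_ns and to_ns must differ")
  fc <- table[[.ns_column[[from_ns]]]]
  tc <- table[[.ns_column[[to_ns]]]]
  fold <- symbol_case_insensitive &&
    from_ns %in% c("symbol", "hgnc_human_symbol")
  key <- if (fold) toupper(fc) else fc

  ids <- as.character(ids)
  res <- lapply(ids, function(id) {
    q <- if (fold) toupper(id) else id
    hits <- which(!is.na(key) & key == q)
    sort(unique(tc[hits][!is.na(tc[hits])]))
  })
  n_out <- lengths(res)
  data.frame(input = ids,
             outputs = I(res),
             n_outputs = n_out,
             status = ifelse(n_out == 0, "unmapped",
                             ifelse(n_out == 1, "mapped", "multi")),
             output = vapply(res, semicolon, ""),
             stringsAsFactors = FALSE)
}
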