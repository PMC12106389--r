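.check_pvalues <- function(p, p_floor = NULL) {
  if (!length(p)) stop_fmt("empty P-value list")
  if (anyNA(p)) stop_fmt("NA P-value")
  if (!is.null(p_floor)) p <- pmax(p, p_floor)
  if (any(p <= 0))
    stop_fmt("P-value <= 0 (Fisher's method is undefined at ln 0); supply p_floor to clamp")
  if (any(p > 1)) stop_fmt("P-value > 1")
  p
}

#' Combine P-values within a gene
#'
#' The four site-to-gene combination rules.  Each maps a vector of k raw
#' P-values in (0, 1] to one value in (0, 1]; each returns the input
#' unchanged at k = 1 and is invariant to input order.
#'
#' \describe{
#'   \item{`combine_fisher`}{Fisher's combination: X = -2 sum(ln p_i) is
#'     referred to a chi-square with 2k degrees of freedom (upper tail).
#'     Exact-uniform under the null for independent uniform inputs.}
#'   \item{`combine_sidak`}{Sidak correction of the minimum:
#'     1 - (1 - min p)^k.  Conservative for k > 1.}
#'   \item{`combine_simes`}{Simes: min over i of k * p_(i) / i, with
#'     p_(1) <= ... <= p_(k), capped at 1.}
#'   \item{`combine_fdr`}{minimum Benjamini-Hochberg adjusted value within
#'     the gene's list; algebraically identical to Simes.}
#' }
#'
#' @param p numeric vector of raw P-values in (0, 1], length >= 1.
#' @param p_floor optional lower clamp applied before combining (handles
#'   p = 0 from underflowing upstream tools); default off.
#' @return combined P-value in (0, 1].
#' @export
combine_fisher <- function(p, p_floor = NULL) {
  p <- .check_pvalues(p, p_floor)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' @rdname combine_fisher
#' @export
combine_sidak <- function(p, p_floor = NULL) {
  p <- .check_pvalues(p, p_floor)
  1 - (1 - min(p))^length(p)
}

#' @rdname combine_fisher
#' @export
combine_simes <- function(p, p_floor = NULL) {
  p <- .check_pvalues(p, p_floor)
  k <- length(p)
  min(1, min(k * sort(p) / seq_len(k)))
}

#' @rdname combine_fisher
#' @export
combine_fdr <- function(p, p_floor = NULL) {
  p <- .check_pvalues(p, p_floor)
  min(stats::p.adjust(p, method = "BH"))
}

.combiners <- list(fisher = combine_fisher, sidak = combine_sidak,
                   simes = combine_simes, fdr = combine_fdr)

#' Aggregation methods available
#' @return character vector: `"fisher"`, `"sidak"`, `"simes"`, `"fdr"`.
#' @export
aggregation_methods <- function() names(.combiners)

#' Assign site-level signals to their nearest gene
#'
#' First step of P-value aggregation: each coordinate-level signal is
#' assigned to exactly one gene, the nearest by gene-body distance
#' ([nearest_gene()]).  Signals on gene-free chromosomes are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param signals data.frame with `chrom`, `pos`, optional `end`, and a
#'   mandatory `pvalue` column in (0, 1].
#' @param annotation a `genome_annotation`.
#' @param p_floor optional lower clamp for P-values.
#' @return named list: gene_id -> numeric vector of member P-values, with
#'   attributes `n_dropped` and `member_rows` (gene_id -> input row
#'   numbers).
#' @export
assign_signals <- function(signals, annotation, p_floor = NULL) {
  if (!"pvalue" %in% names(signals))
    stop_fmt("signals must carry a 'pvalue' column")
  pv <- as.numeric(signals$pvalue)
  bad <- which(is.na(pv) | pv > 1 | pv < 0 |
                 (pv <= 0 & is.null(p_floor)))
  if (length(bad))
    stop_fmt("invalid P-value at signal row(s): %s", semicolon(head(bad, 5)))
  if (!is.null(p_floor)) pv <- pmax(pv, p_floor)
  ng <- nearest_gene(signals, annotation)
  keep <- !is.na(ng$gene_id)
  groups <- split(pv[keep], ng$gene_id[keep])
  rows <- split(which(keep), ng$gene_id[keep])
  attr(groups, "n_dropped") <- sum(!keep)
  attr(groups, "member_rows") <- rows
  groups
}

#' Aggregate site-level P-values to gene level
#'
#' Two-step procedure: map each signal to its nearest gene, then combine
#' each gene's member P-values with the chosen method.  The result is one
#' aggregated P-value per gene with at least one mapped signal, giving the
#' collective significance of all signals near that gene prior to any
#' genome-wide multiple-testing correction.
#'
#' @param signals data.frame with `chrom`, `pos`, optional `end`, `pvalue`.
#' @param annotation a `genome_annotation`.
#' @param method one of [aggregation_methods()].
#' @param p_floor optional lower clamp for P-values.
#' @return data.frame sorted by `p_aggregated` (ties by gene_id):
#'   `gene_id`, `symbol`, `k` (signals mapped), `p_aggregated`, `method`,
#'   `member_signals` (semicolon-joined input row numbers).  Attribute
#'   `n_dropped` counts signals with no gene on their chromosome.
#' @export
aggregate_pvalues <- function(signals, annotation,
                              method = c("fisher", "sidak", "simes", "fdr"),
                              p_floor = NULL) {
  method <- match.arg(method)
  fn <- .combiners[[method]]
  groups <- assign_signals(signals, annotation, p_floor = p_floor)
  rows <- attr(groups, "member_rows")
  gids <- names(groups)
  res <- data.frame(
    gene_id = gids,
    symbol = annotation$genes$symbol[match(gids, annotation$genes$gene_id)],
    k = unname(lengths(groups)),
    p_aggregated = unname(vapply(groups, fn, numeric(1))),
    method = method,
    member_signals = unname(vapply(gids, function(g) semicolon(rows[[g]]), "")),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_aggregated, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- attr(groups, "n_dropped")
  res
}
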