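#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for enrichment in a query list against a gene
#' universe. Sets are intersected with the universe before testing; sets
#' smaller than `min_set_size` after intersection, or overlapping the query
#' in fewer than `min_overlap` genes, are not reported. The p-value is the
#' upper tail P(X >= overlap) of the hypergeometric distribution with
#' population `universe_size`, successes `set_size` and draws `query_size`;
#' Benjamini-Hochberg FDR is computed across all tested sets (including
#' those below `min_overlap`, which are then dropped from the report).
#'
#' @param query Character vector of gene ids (a subset of `universe`; ids
#'   outside the universe are dropped with a warning).
#' @param sets Named list of gene-id vectors, e.g. from [read_gmt()].
#' @param universe Character vector of background gene ids.
#' @param min_set_size Smallest set size (after universe intersection) to
#'   test (default 5).
#' @param min_overlap Smallest overlap to report (default 1).
#' @return data.frame ordered by p then set id, with columns `set_id`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p`, `fdr`.
#' @export
hypergeometric_ora <- function(query, sets, universe, min_set_size = 5L,
                               min_overlap = 1L) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe intersection")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  n <- length(query)
  big_n <- length(universe)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    if (length(s) < min_set_size) return(NULL)
    ov <- length(intersect(s, query))
    p <- ora_pvalue(ov, length(s), n, big_n)
    data.frame(set_id = id, overlap = ov, set_size = length(s),
               query_size = n, universe_size = big_n, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set_id = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[out$overlap >= min_overlap, , drop = FALSE]
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= overlap) for an overlap of `ov` genes between a query of size `n`
#' and a set of size `k` drawn from a universe of size `big_n`.
#'
#' @param ov Observed overlap.
#' @param k Set size.
#' @param n Query size.
#' @param big_n Universe size.
#' @return p-value in (0, 1].
#' @export
ora_pvalue <- function(ov, k, n, big_n) {
  stats::phyper(ov - 1, k, big_n - k, n, lower.tail = FALSE)
}

#' Enrichment of several gene groups
#'
#' Runs [hypergeometric_ora()] for each named group (e.g. per-tissue TSG
#' lists, housekeeping tiers, network modules). Groups disjoint from the
#' universe yield an empty table with a warning rather than an error.
#'
#' @param groups Named list of gene-id vectors.
#' @param sets Named list of gene sets.
#' @param universe Background gene ids.
#' @param ... Passed to [hypergeometric_ora()].
#' @return Named list of per-group enrichment tables.
#' @export
enrich_gene_groups <- function(groups, sets, universe, ...) {
  if (!length(groups)) stop("no groups supplied")
  if (is.null(names(groups))) stop("'groups' must be named")
  lapply(stats::setNames(names(groups), names(groups)), function(g) {
    q <- intersect(unique(groups[[g]]), universe)
    if (!length(q)) {
      warning("group '", g, "' is disjoint from the universe; empty table")
      return(data.frame(set_id = character(), overlap = integer(),
                        set_size = integer(), query_size = integer(),
                        universe_size = integer(), p = numeric(),
                        fdr = numeric(), stringsAsFactors = FALSE))
    }
    hypergeometric_ora(q, sets, universe, ...)
  })
}
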