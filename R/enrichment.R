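# Over-representation analysis (ORA) of gene lists against gene-set
# collections, with the profiled gene universe as background.

#' Over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene
#' list and each gene set, against a background universe of profiled
#' genes. Gene sets are restricted to the background before computing
#' set sizes, and sets falling outside `[min_size, max_size]` after
#' restriction are not tested. `p = P(X >= k)` for overlap `k`, set size
#' `m`, query size `n` and universe size `N`; BH-adjusted across tested
#' sets.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the profiled gene universe.
#' @param fdr_cutoff Enrichment threshold on BH FDR (default 0.05).
#' @param min_size,max_size Set-size bounds after restriction to the
#'   background (defaults 5 and 2000).
#' @return Data frame, one row per tested set: `set`, `k`, `m`, `n`,
#'   `N`, `p`, `fdr`, `enriched`, sorted by increasing p.
#' @export
ora <- function(query, collection, background, fdr_cutoff = 0.05,
                min_size = 5L, max_size = 2000L) {
  background <- unique(canon_gene(background))
  query <- unique(canon_gene(query))
  bad <- setdiff(query, background)
  if (length(bad) > 0L) {
    abort("query gene(s) not in background: %s",
          paste(head(bad, 10L), collapse = ", "))
  }
  if (is.null(names(collection)) || any(names(collection) == "")) {
    abort("gene-set collection must be a named list")
  }
  sets <- lapply(collection, function(s) intersect(unique(canon_gene(s)), background))
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    k <- length(intersect(query, sets[[nm]]))
    data.frame(set = nm, k = k, m = m, n = n, N = N,
               p = phyper(k - 1L, m, N - m, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(set = character(0), k = integer(0), m = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0), enriched = logical(0)))
  }
  res$fdr <- bh_adjust(res$p)
  res$enriched <- res$fdr < fdr_cutoff
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank enriched sets for bubble-plot display
#'
#' Orders records by descending `-log10(FDR)` (ties broken
#' alphabetically by set name); zero FDRs are capped.
#'
#' @param enriched An [ora()] result table (typically filtered to
#'   `enriched` rows).
#' @param cap Maximum `-log10(FDR)` assigned to FDR = 0 (default 300).
#' @return The table with a `neg_log10_fdr` column, in display order.
#' @export
rank_for_plot <- function(enriched, cap = 300) {
  assert_columns(enriched, c("set", "fdr"), "enrichment table")
  if (any(enriched$fdr < 0)) abort("FDR values must be >= 0")
  enriched$neg_log10_fdr <- ifelse(enriched$fdr == 0, cap,
                                   pmin(-log10(enriched$fdr), cap))
  out <- enriched[order(-enriched$neg_log10_fdr, enriched$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
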