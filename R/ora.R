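#' Hypergeometric over-representation analysis
#'
#' For each gene set (term), tests whether the query list overlaps the term
#' more than expected when drawing `n_hits` genes from the universe: the
#' upper-tail hypergeometric probability `P(X >= k_hit)`. Query genes outside
#' the universe are dropped (with a message giving the count); term members
#' are intersected with the universe; terms outside
#' `[min_term_size, max_term_size]` (after intersection) are skipped.
#' Benjamini-Hochberg adjustment runs across the tested terms and the table
#' is sorted by `padj`, then `p`.
#'
#' @param query character vector of genes of interest.
#' @param universe character vector of all eligible genes (e.g. everything
#'   passing the expression filter).
#' @param collection named list of term -> gene vectors (see [read_gmt()]).
#' @param min_term_size,max_term_size term-size gates after intersection with
#'   the universe.
#' @return data.frame: `term`, `k_hit`, `n_hits`, `K_term`, `N`, `p`, `padj`,
#'   `fold_enrichment`.
#' @export
hypergeom_ora <- function(query, universe, collection,
                          min_term_size = 3, max_term_size = 2000) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query))
    stop("query and universe must be non-empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(unique(collection[[term]]), universe)
    K <- length(members)
    if (K < min_term_size || K > max_term_size) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k_hit = k, n_hits = n, K_term = K, N = N, p = p,
               fold_enrichment = (k / n) / (K / N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), k_hit = integer(),
                      n_hits = integer(), K_term = integer(), N = integer(),
                      p = numeric(), padj = numeric(),
                      fold_enrichment = numeric()))
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$padj, out$p), c("term", "k_hit", "n_hits", "K_term",
                                       "N", "p", "padj", "fold_enrichment")]
  rownames(out) <- NULL
  out
}
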