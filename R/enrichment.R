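# Over-representation analysis: right-tail hypergeometric test of a gene
# list against gene-set collections, with BH FDR across sets.

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} ( p_(j) * m / j )`, capped at 1; order-preserving
#' and never below the raw p. Thin, argument-checked wrapper around
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, with universe size N, set size K (after intersecting
#' the set with the universe), list size n and overlap k, the enrichment p
#' is the right tail `P[X >= k]` for `X ~ Hypergeom(N, K, n)` — the
#' one-sided Fisher exact test. BH adjustment is applied across all tested
#' sets; results are sorted by p, then set id.
#'
#' @param gene_list Character vector of genes of interest; must be a subset
#'   of `universe`.
#' @param universe Character vector: the background, typically all features
#'   assayed on the platform (not the genome).
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @return Data frame `set_id`, `k` (overlap), `K` (set size), `n` (list
#'   size), `N` (universe size), `p`, `q`, `genes` (overlap, comma-joined).
#' @export
hypergeom_ora <- function(gene_list, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, universe)
  if (length(stray)) {
    stop("gene(s) in list but not universe: ", paste(stray, collapse = ", "))
  }
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    if (!K) return(NULL)
    hit <- intersect(gene_list, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(), q = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), c("set_id", "k", "K", "n", "N", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}
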