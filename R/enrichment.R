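# Over-representation analysis of a hit list against GMT gene sets.

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the hit list overlaps it more than
#' expected by chance given the universe: with `N` universe genes, `K` of
#' them in the set, `n` hits and `k` hits in the set, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. Sets are intersected with the
#' universe before testing and sets smaller than `min_set_size` after
#' intersection are skipped. P-values are Benjamini-Hochberg adjusted
#' across the tested sets.
#'
#' @param hits Character vector of significant gene symbols (must be a
#'   subset of `universe`).
#' @param universe Character vector: the genes that could have been hits
#'   (here, typically all genes that entered MR).
#' @param catalog Named list of gene sets (e.g. from [read_gmt()]).
#' @param min_set_size Minimum post-intersection set size (default 3).
#' @return A `data.frame` with one row per tested set: `set_name`,
#'   `overlap_k`, `set_size_K`, `hits_n`, `universe_N`, `pvalue`,
#'   `fdr_pvalue`, `overlapping_symbols` (comma-separated), ordered by
#'   increasing p-value.
#' @export
ora <- function(hits, universe, catalog, min_set_size = 3) {
  hits <- canonicalize_symbols(hits)
  universe <- canonicalize_symbols(universe)
  if (!all(hits %in% universe)) {
    stop("hits must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(catalog), function(nm) {
    set <- intersect(canonicalize_symbols(catalog[[nm]]), universe)
    K <- length(set)
    if (K < min_set_size) return(NULL)
    ov <- intersect(hits, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_k = k, set_size_K = K, hits_n = n,
               universe_N = N, pvalue = p,
               overlapping_symbols = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(set_name = character(0), overlap_k = integer(0),
                      set_size_K = integer(0), hits_n = integer(0),
                      universe_N = integer(0), pvalue = numeric(0),
                      fdr_pvalue = numeric(0),
                      overlapping_symbols = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr_pvalue <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$set_name),
             c("set_name", "overlap_k", "set_size_K", "hits_n",
               "universe_N", "pvalue", "fdr_pvalue", "overlapping_symbols")]
  rownames(out) <- NULL
  out
}
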