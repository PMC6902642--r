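# Hypergeometric over-representation analysis with Benjamini-Hochberg FDR
# and enrichment ratios.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, M, s)`: drawing `s` genes without
#' replacement from a reference of `N` genes of which `M` are marked.
#' Computed through the log-space tail of [stats::phyper()] for numerical
#' stability.
#'
#' @param k Observed overlap count.
#' @param N Reference (population) size.
#' @param M Marked genes in the reference.
#' @param s Query (sample) size.
#' @return Tail probability in `[0, 1]`.
#' @examples
#' hypergeom_tail(2, 15802, 10, 64)
#' @export
hypergeom_tail <- function(k, N, M, s) {
  if (k < 0 || s < 0 || M < 0 || N < 1) stop("counts must be non-negative (N >= 1)")
  if (s > N || M > N || k > s) stop("need k <= s <= N and M <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, M, N - M, s, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-aligned with the input and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list against gene sets
#'
#' For each set: `M` = set members within the reference, `k` = set members
#' within the query; one-sided hypergeometric p = `P(X >= k)`;
#' Benjamini-Hochberg FDR across all tested sets; enrichment ratio
#' `(k/s) / (M/N)` (0 when `k = 0`). Query genes outside the reference are
#' dropped with a logged count.
#'
#' @param query Character vector of query gene symbols.
#' @param reference Character vector: the gene universe (e.g. all genes in
#'   the expression matrix).
#' @param sets A [gene_set_collection].
#' @param alpha Significance threshold on the FDR (default 0.05).
#' @param min_set_size Minimum `M` for a set to be tested (default 1).
#' @return Object of class `ora_result`: data frame with columns `name`,
#'   `k`, `s`, `M`, `N`, `p_value`, `fdr`, `enrichment_ratio`,
#'   `significant`, sorted by fdr, then p, then name.
#' @export
run_ora <- function(query, reference, sets, alpha = 0.05, min_set_size = 1L) {
  reference <- unique(normalize_symbols(reference))
  if (length(reference) == 0L) stop("empty reference universe")
  query0 <- unique(normalize_symbols(query))
  query <- intersect(query0, reference)
  dropped <- length(query0) - length(query)
  if (dropped > 0L) {
    message(sprintf("%d query gene(s) outside the reference dropped", dropped))
  }
  if (length(query) == 0L) stop("empty query after intersecting with the reference")
  N <- length(reference)
  s <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], reference)
    M <- length(members)
    if (M < min_set_size) return(NULL)
    k <- length(intersect(members, query))
    data.frame(name = nm, k = k, s = s, M = M, N = N,
               p_value = hypergeom_tail(k, N, M, s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no set passes the minimum size filter")
  res$fdr <- bh_fdr(res$p_value)
  res$enrichment_ratio <- ifelse(res$k == 0, 0,
                                 (res$k / res$s) / (res$M / res$N))
  res$significant <- res$fdr <= alpha
  res <- res[order(res$fdr, res$p_value, res$name), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d sets tested, %d significant\n",
              nrow(x), sum(x$significant)))
  top <- utils::head(as.data.frame(x), 10L)
  top$p_value <- signif(top$p_value, 3)
  top$fdr <- signif(top$fdr, 3)
  top$enrichment_ratio <- round(top$enrichment_ratio, 2)
  print(top, row.names = FALSE)
  invisible(x)
}
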