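# ARACNe-style network inference: rank-quantile binned mutual information
# between every TF and every gene, edge significance against a pooled
# permutation null (p < 0.005), and data processing inequality pruning at
# tolerance 0.2.

#' Default bin count for the MI estimator
#'
#' `max(2, floor(sqrt(n / 5)))` bins for `n` samples, so each marginal bin
#' keeps enough observations for a stable plug-in estimate.
#'
#' @param n Sample count.
#' @return Integer bin count.
#' @export
default_bins <- function(n) {
  max(2L, as.integer(floor(sqrt(n / 5))))
}

# equal-frequency (rank-quantile) bin assignment; ties get the average rank
# and therefore always share a bin. Errors on a constant (degenerate) vector.
rank_bins <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) stop("constant profile: all ranks tied (degenerate gene)")
  b <- as.integer(ceiling(r * n_bins / n))
  pmin.int(pmax.int(b, 1L), n_bins)
}

# plug-in MI (nats) from two integer bin vectors
mi_from_bins <- function(bx, by, n_bins) {
  n <- length(bx)
  joint <- tabulate(bx + n_bins * (by - 1L), nbins = n_bins * n_bins)
  px <- tabulate(bx, nbins = n_bins)
  py <- tabulate(by, nbins = n_bins)
  nz <- joint > 0L
  j <- joint[nz] / n
  ex <- (px[((which(nz) - 1L) %% n_bins) + 1L] / n) *
        (py[((which(nz) - 1L) %/% n_bins) + 1L] / n)
  max(0, sum(j * log(j / ex)))
}

#' Mutual information between two expression profiles
#'
#' Plug-in mutual information (in nats) of the joint histogram on an
#' equal-frequency (rank-quantile) `n_bins` x `n_bins` grid. Being
#' rank-based, the estimate is invariant under any strictly monotone
#' transform of either argument, and is symmetric.
#'
#' @param x,y Numeric vectors of equal length `n >= 2 * n_bins`.
#' @param n_bins Number of marginal bins (default [default_bins()] of `n`).
#' @return Non-negative mutual information in nats.
#' @examples
#' x <- rnorm(64)
#' mutual_information(x, x, n_bins = 8)  # = log(8)
#' @export
mutual_information <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (length(x) < 2L * n_bins) {
    stop(sprintf("need n >= 2 * n_bins samples (n = %d, n_bins = %d)",
                 length(x), n_bins))
  }
  mi_from_bins(rank_bins(x, n_bins), rank_bins(y, n_bins), as.integer(n_bins))
}

# MI of one binned profile against many rows of a binned matrix at once.
# Vectorised over the n_bins^2 joint cells; equals mi_from_bins row by row.
mi_profile_vs_matrix <- function(b_tf, bin_mat, n_bins) {
  n <- length(b_tf)
  ng <- nrow(bin_mat)
  offset <- matrix(n_bins * (b_tf - 1L), ng, n, byrow = TRUE)
  idx <- bin_mat + offset
  joint <- matrix(0, ng, n_bins * n_bins)
  for (v in seq_len(n_bins * n_bins)) joint[, v] <- rowSums(idx == v)
  p_tf <- tabulate(b_tf, nbins = n_bins) / n
  # row marginals of each gene
  pg <- matrix(0, ng, n_bins)
  for (v in seq_len(n_bins)) pg[, v] <- rowSums(bin_mat == v)
  pg <- pg / n
  cell_gene_bin <- ((seq_len(n_bins * n_bins) - 1L) %% n_bins) + 1L
  cell_tf_bin <- ((seq_len(n_bins * n_bins) - 1L) %/% n_bins) + 1L
  expected <- pg[, cell_gene_bin, drop = FALSE] *
    matrix(p_tf[cell_tf_bin], ng, n_bins * n_bins, byrow = TRUE)
  jp <- joint / n
  term <- jp * log(jp / expected)
  term[jp == 0] <- 0
  pmax(0, rowSums(term))
}

#' Build the pooled MI permutation null
#'
#' Samples `n_perm_pairs` random gene pairs, permutes the sample order of
#' one member (destroying any dependence while preserving both marginals),
#' and records the resulting MI values. This pooled null calibrates edge
#' p-values for the whole network.
#'
#' @param dataset An [expression_dataset].
#' @param n_bins Bin count (default [default_bins()] of the sample count).
#' @param n_perm_pairs Number of permuted pairs (>= 1000).
#' @param seed Integer seed.
#' @return Object of class `mi_null`: list with sorted `null_mis`,
#'   `n_perm_pairs` and `n_bins`.
#' @export
build_mi_null <- function(dataset, n_bins = NULL, n_perm_pairs = 10000L,
                          seed = 1L) {
  if (nrow(dataset$values) < 2L) stop("dataset must contain >= 2 genes")
  if (n_perm_pairs < 1000L) stop("n_perm_pairs must be >= 1000")
  n <- ncol(dataset$values)
  n_bins <- as.integer(n_bins %||% default_bins(n))
  bins <- t(apply(dataset$values, 1L, rank_bins, n_bins = n_bins))
  ng <- nrow(bins)
  with_seed(seed, {
    i <- sample.int(ng, n_perm_pairs, replace = TRUE)
    j <- sample.int(ng - 1L, n_perm_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # j != i
    mis <- numeric(n_perm_pairs)
    for (k in seq_len(n_perm_pairs)) {
      mis[k] <- mi_from_bins(bins[i[k], ], bins[j[k], sample.int(n)], n_bins)
    }
    structure(list(null_mis = sort(mis), n_perm_pairs = n_perm_pairs,
                   n_bins = n_bins),
              class = "mi_null")
  })
}

# empirical upper-tail p with add-one correction against a sorted null
empirical_p <- function(stat, sorted_null) {
  n <- length(sorted_null)
  cnt_ge <- n - findInterval(stat, sorted_null, left.open = TRUE)
  (1 + cnt_ge) / (1 + n)
}

#' Build the significant-MI network
#'
#' Computes mutual information for every TF x gene pair (TF-TF pairs once),
#' assigns each pair the empirical p-value
#' `(1 + #\{null >= mi\}) / (1 + #null)` against the pooled permutation
#' null, and keeps pairs with `p < alpha`.
#'
#' @param dataset An [expression_dataset].
#' @param tfs Character vector of TF symbols (at least one must be present
#'   in the dataset).
#' @param n_bins Bin count (default from the sample count, and must match
#'   the null's).
#' @param alpha Significance level (default 0.005).
#' @param null An `mi_null` from [build_mi_null()].
#' @return Object of class `mi_network`: a data frame with columns
#'   `gene_a` (TF), `gene_b`, `mi`, `p_value`, plus attribute `tf_genes`.
#' @export
build_mi_network <- function(dataset, tfs, n_bins = NULL, alpha = 0.005,
                             null) {
  stopifnot(alpha > 0, alpha < 1)
  genes <- rownames(dataset$values)
  tfs <- intersect(normalize_symbols(tfs), genes)
  if (length(tfs) == 0L) stop("no TF from the list is present in the dataset")
  n <- ncol(dataset$values)
  n_bins <- as.integer(n_bins %||% default_bins(n))
  if (!is.null(null$n_bins) && null$n_bins != n_bins) {
    stop("bin count differs between network and null")
  }
  bins <- t(apply(dataset$values, 1L, rank_bins, n_bins = n_bins))
  tf_idx <- match(tfs, genes)
  is_tf <- seq_along(genes) %in% tf_idx
  out <- vector("list", length(tfs))
  for (ti in seq_along(tfs)) {
    g <- tf_idx[ti]
    # all non-TF genes, plus TFs with larger index (each TF-TF pair once)
    partner <- which(!is_tf | (is_tf & seq_along(genes) > g))
    partner <- setdiff(partner, g)
    mis <- mi_profile_vs_matrix(bins[g, ], bins[partner, , drop = FALSE],
                                n_bins)
    p <- empirical_p(mis, null$null_mis)
    keep <- p < alpha
    if (any(keep)) {
      out[[ti]] <- data.frame(
        gene_a = genes[g], gene_b = genes[partner[keep]],
        mi = mis[keep], p_value = p[keep], stringsAsFactors = FALSE
      )
    }
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        mi = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("mi_network", "data.frame"), tf_genes = tfs)
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d edges over %d TFs\n",
              nrow(x), length(attr(x, "tf_genes"))))
  invisible(x)
}

#' Prune indirect edges with the data processing inequality
#'
#' For every triangle (i, j, k) whose three edges are all present, the edge
#' (i, j) is marked for removal when
#' `mi(i,j) < (1 - tolerance) * mi(i,k)` and
#' `mi(i,j) < (1 - tolerance) * mi(j,k)` -- i.e. it is the clear weakest
#' edge of the triangle and hence the most likely indirect interaction. All
#' marks are computed on the input network and removed simultaneously.
#'
#' @param network An `mi_network` (or plain data frame with `gene_a`,
#'   `gene_b`, `mi` columns).
#' @param tolerance DPI tolerance in `[0, 1)` (default 0.2): the weakest
#'   edge survives unless it falls below `1 - tolerance` times both others.
#' @return The pruned network; edge set is a subset of the input, MI values
#'   unchanged.
#' @export
apply_dpi <- function(network, tolerance = 0.2) {
  stopifnot(tolerance >= 0, tolerance < 1)
  if (nrow(network) == 0L) return(network)
  nodes <- unique(c(network$gene_a, network$gene_b))
  ia <- match(network$gene_a, nodes)
  ib <- match(network$gene_b, nodes)
  nn <- length(nodes)
  mi_mat <- matrix(NA_real_, nn, nn)
  mi_mat[cbind(ia, ib)] <- network$mi
  mi_mat[cbind(ib, ia)] <- network$mi
  adj <- vector("list", nn)
  for (v in seq_len(nn)) adj[[v]] <- integer()
  for (e in seq_len(nrow(network))) {
    adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
    adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
  }
  fac <- 1 - tolerance
  drop <- logical(nrow(network))
  for (e in seq_len(nrow(network))) {
    ks <- intersect(adj[[ia[e]]], adj[[ib[e]]])
    if (length(ks) == 0L) next
    m <- network$mi[e]
    drop[e] <- any(m < fac * mi_mat[ia[e], ks] & m < fac * mi_mat[ib[e], ks])
  }
  out <- network[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tf_genes") <- attr(network, "tf_genes")
  class(out) <- class(network)
  out
}
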