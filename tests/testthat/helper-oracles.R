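# Independent brute-force oracles. These deliberately re-derive each
# statistic with the most literal computation available (explicit loops,
# term-by-term sums) so they share no code with the implementation.

# plug-in MI from an explicit cell-by-cell joint table of the same
# rank-quantile binning contract
oracle_mi <- function(x, y, n_bins) {
  n <- length(x)
  bx <- as.integer(ceiling(rank(x, ties.method = "average") * n_bins / n))
  by <- as.integer(ceiling(rank(y, ties.method = "average") * n_bins / n))
  bx <- pmin(pmax(bx, 1L), n_bins); by <- pmin(pmax(by, 1L), n_bins)
  mi <- 0
  for (a in seq_len(n_bins)) {
    for (b in seq_len(n_bins)) {
      nab <- sum(bx == a & by == b)
      if (nab > 0) {
        pab <- nab / n
        mi <- mi + pab * log(pab / ((sum(bx == a) / n) * (sum(by == b) / n)))
      }
    }
  }
  mi
}

# DPI by exhaustive enumeration of all node triples of a small graph
oracle_dpi <- function(edges, tolerance) {
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  mi_of <- function(u, v) {
    hit <- (edges$gene_a == u & edges$gene_b == v) |
           (edges$gene_a == v & edges$gene_b == u)
    if (any(hit)) edges$mi[which(hit)[1L]] else NA_real_
  }
  drop <- logical(nrow(edges))
  if (length(nodes) >= 3L) {
    triples <- utils::combn(nodes, 3L)
    for (t in seq_len(ncol(triples))) {
      u <- triples[1L, t]; v <- triples[2L, t]; w <- triples[3L, t]
      muv <- mi_of(u, v); muw <- mi_of(u, w); mvw <- mi_of(v, w)
      if (anyNA(c(muv, muw, mvw))) next
      fac <- 1 - tolerance
      mark <- function(a, b, m, o1, o2) {
        hit <- (edges$gene_a == a & edges$gene_b == b) |
               (edges$gene_a == b & edges$gene_b == a)
        if (m < fac * o1 && m < fac * o2) drop[hit] <<- TRUE
      }
      mark(u, v, muv, muw, mvw)
      mark(u, w, muw, muv, mvw)
      mark(v, w, mvw, muv, muw)
    }
  }
  edges[!drop, , drop = FALSE]
}

# GSEA enrichment score by a literal position-by-position walk
oracle_gsea <- function(z, members, weights = NULL) {
  ord <- order(-z, names(z))
  ranked <- names(z)[ord]
  n <- length(z)
  m <- sum(ranked %in% members)
  hit_w <- numeric(n)
  for (i in seq_len(n)) {
    if (ranked[i] %in% members) {
      w <- abs(z[[ranked[i]]])
      if (!is.null(weights) && ranked[i] %in% names(weights)) {
        w <- w * weights[[ranked[i]]]
      }
      hit_w[i] <- w
    }
  }
  if (sum(hit_w) == 0) {
    hit_w[ranked %in% members] <- 1 / m
  } else {
    hit_w <- hit_w / sum(hit_w)
  }
  running <- numeric(n)
  acc <- 0
  best <- 0
  for (i in seq_len(n)) {
    acc <- if (ranked[i] %in% members) acc + hit_w[i] else acc - 1 / (n - m)
    running[i] <- acc
    # same documented tie rule: earliest position wins on a magnitude tie
    if (abs(acc) > abs(best) + 1e-12) best <- acc
  }
  best
}

# hypergeometric upper tail by log-space term-by-term summation
oracle_hypergeom_tail <- function(k, N, M, s) {
  if (k == 0) return(1)
  jj <- k:min(M, s)
  if (length(jj) == 0L) return(0)
  terms <- lchoose(M, jj) + lchoose(N - M, s - jj) - lchoose(N, s)
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

# Spearman rho by ranking then the explicit Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Welch statistic from the closed-form formulas
oracle_welch <- function(a, b) {
  n1 <- length(a); n0 <- length(b)
  se2 <- var(a) / n1 + var(b) / n0
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n0)^2 / (n0 - 1))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# rank-based AUC of scores for the positive class
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
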