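# Pathway-restricted molecular signature: per-gene Welch t statistics (case
# minus control) mapped to exact standard-normal Z-scores, plus the
# label-permutation null model that calibrates regulon enrichment.

# Vectorised Welch t-test over the rows of two matrices.
# Returns list(t, p, df). Zero variance in both groups: equal means -> t =
# 0, p = 1; different means -> error (the statistic is undefined).
welch_rows <- function(case_mat, ctrl_mat) {
  n1 <- ncol(case_mat); n0 <- ncol(ctrl_mat)
  if (n1 < 2L || n0 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(case_mat); m0 <- rowMeans(ctrl_mat)
  v1 <- rowSums((case_mat - m1)^2) / (n1 - 1L)
  v0 <- rowSums((ctrl_mat - m0)^2) / (n0 - 1L)
  se2 <- v1 / n1 + v0 / n0
  degenerate <- se2 == 0
  if (any(degenerate & m1 != m0)) {
    bad <- which(degenerate & m1 != m0)[1L]
    stop("zero variance in both groups with different means (gene ",
         rownames(case_mat)[bad] %||% bad, "): t undefined")
  }
  t_stat <- ifelse(degenerate, 0, (m1 - m0) / sqrt(se2))
  df <- ifelse(degenerate, n1 + n0 - 2L,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v0^2 / (n0^2 * (n0 - 1L))))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t_stat), df))
  list(t = unname(t_stat), p = unname(p), df = unname(df))
}

#' Per-gene Welch t-test
#'
#' Welch (unequal-variance) two-sample t statistic, case minus control,
#' with its two-sided p-value. Welch is the appropriate default for
#' strongly unbalanced designs.
#'
#' @param case_values,control_values Numeric vectors (>= 2 values each).
#' @return List with elements `t` and `p`.
#' @examples
#' gene_ttest(c(2, 3, 4), c(1, 2, 3))
#' @export
gene_ttest <- function(case_values, control_values) {
  res <- welch_rows(matrix(case_values, nrow = 1L),
                    matrix(control_values, nrow = 1L))
  list(t = res$t, p = res$p)
}

# signed standard-normal quantile transform of (t, p), clamped at |z| = 8
t_to_z <- function(t_stat, p) {
  z <- sign(t_stat) * stats::qnorm(p / 2, lower.tail = FALSE)
  z[t_stat == 0] <- 0
  pmin(pmax(z, -8), 8)
}

#' Compute the pathway-restricted molecular signature
#'
#' For every gene in the union of the restriction gene sets that is present
#' in the dataset, runs the case-vs-control Welch t-test and converts the
#' result to a Z-score, `z = sign(t) * qnorm(1 - p/2)` (exactly standard
#' normal under the null regardless of the per-gene degrees of freedom),
#' clamped at `|z| <= 8`. Genes outside the restriction are absent from the
#' signature.
#'
#' @param dataset An [expression_dataset].
#' @param restriction A [gene_set_collection] (its sets are pooled into one
#'   gene universe) or a character vector of gene symbols.
#' @return Object of class `molecular_signature`: a named numeric vector of
#'   Z-scores with attributes `case_n`, `control_n`, `restricted_to`.
#' @export
compute_signature <- function(dataset, restriction) {
  cc <- class_counts(dataset)
  restr_genes <- if (inherits(restriction, "gene_set_collection")) {
    collection_universe(restriction)
  } else {
    unique(normalize_symbols(restriction))
  }
  genes <- intersect(rownames(dataset$values), restr_genes)
  if (length(genes) == 0L) {
    stop("no restriction gene is present in the expression matrix")
  }
  x <- dataset$values[genes, , drop = FALSE]
  res <- welch_rows(x[, dataset$labels == "case", drop = FALSE],
                    x[, dataset$labels == "control", drop = FALSE])
  z <- stats::setNames(t_to_z(res$t, res$p), genes)
  structure(z, class = "molecular_signature",
            case_n = unname(cc["case"]), control_n = unname(cc["control"]),
            restricted_to = if (inherits(restriction, "gene_set_collection")) {
              names(restriction$sets)
            } else "custom")
}

#' @export
print.molecular_signature <- function(x, ...) {
  cat(sprintf(
    "molecular_signature: %d genes (%d case vs %d control); z range [%.2f, %.2f]\n",
    length(x), attr(x, "case_n"), attr(x, "control_n"), min(x), max(x)
  ))
  invisible(x)
}

#' Build the label-permutation null model
#'
#' Generates `k` permutations of the case/control labels (class sizes
#' preserved) and recomputes the molecular signature under each, giving a
#' genes x k matrix of null Z-scores. Deterministic given `seed`.
#'
#' @param dataset An [expression_dataset].
#' @param restriction As in [compute_signature()].
#' @param k Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Object of class `signature_null`: numeric matrix (signature
#'   genes x k) with attribute `seed`.
#' @export
build_null_model <- function(dataset, restriction, k = 1000L, seed = 1L) {
  if (k < 100L) stop("k must be >= 100")
  cc <- class_counts(dataset)
  n <- ncol(dataset$values)
  if (lchoose(n, cc["case"]) < log(k)) {
    stop("fewer than k distinct label permutations exist; ",
         "use exact enumeration for such small designs")
  }
  observed <- compute_signature(dataset, restriction)
  genes <- names(observed)
  x <- dataset$values[genes, , drop = FALSE]
  null_z <- matrix(NA_real_, length(genes), k,
                   dimnames = list(genes, NULL))
  with_seed(seed, {
    for (j in seq_len(k)) {
      perm <- sample.int(n)
      case_cols <- perm[seq_len(cc["case"])]
      ctrl_cols <- perm[(cc["case"] + 1L):n]
      res <- welch_rows(x[, case_cols, drop = FALSE],
                        x[, ctrl_cols, drop = FALSE])
      null_z[, j] <- t_to_z(res$t, res$p)
    }
  })
  structure(null_z, class = "signature_null", seed = seed)
}

#' @export
print.signature_null <- function(x, ...) {
  cat(sprintf("signature_null: %d genes x %d permutations\n",
              nrow(x), ncol(x)))
  invisible(x)
}
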