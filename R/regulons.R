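# Turn the undirected significant-MI network into a directed regulon set:
# direction is imposed TF -> target, the mode of regulation is the Spearman
# correlation of TF and target expression, and the weight is the edge MI
# max-normalised within each regulon.

#' Mode of regulation from Spearman correlation
#'
#' Spearman rank correlation between a TF's expression profile and a
#' target's, with average-rank tie handling. Positive values are read as
#' activation, negative as repression.
#'
#' @param tf_profile,target_profile Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_mode <- function(tf_profile, target_profile) {
  if (length(tf_profile) != length(target_profile)) {
    stop("profiles must have equal length")
  }
  if (length(tf_profile) < 3L) stop("need >= 3 samples")
  if (stats::sd(tf_profile) == 0 || stats::sd(target_profile) == 0) {
    stop("constant profile: Spearman mode undefined")
  }
  stats::cor(tf_profile, target_profile, method = "spearman")
}

#' Build regulons from an MI network
#'
#' For each TF, the regulon targets are its network neighbours; the mode is
#' [spearman_mode()] of the two expression profiles; the weight is the edge
#' MI divided by the largest edge MI within that TF's regulon (so every
#' non-empty regulon has maximum weight exactly 1). A TF-TF edge puts each
#' TF in the other's regulon.
#'
#' @param network An `mi_network` from [build_mi_network()] /
#'   [apply_dpi()].
#' @param dataset The [expression_dataset] the network was inferred from
#'   (every network gene must be present).
#' @return A [regulon_set].
#' @export
build_regulons <- function(network, dataset) {
  if (nrow(network) == 0L) return(regulon_set())
  genes <- rownames(dataset$values)
  missing <- setdiff(unique(c(network$gene_a, network$gene_b)), genes)
  if (length(missing) > 0L) {
    stop("network genes absent from dataset: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  tf_genes <- attr(network, "tf_genes") %||% unique(network$gene_a)
  # direct every edge TF -> partner; TF-TF edges go both ways
  a_is_tf <- network$gene_a %in% tf_genes
  b_is_tf <- network$gene_b %in% tf_genes
  tf <- c(network$gene_a[a_is_tf], network$gene_b[b_is_tf])
  target <- c(network$gene_b[a_is_tf], network$gene_a[b_is_tf])
  mi <- c(network$mi[a_is_tf], network$mi[b_is_tf])

  ranks <- t(apply(dataset$values, 1L, rank, ties.method = "average"))
  mode <- numeric(length(tf))
  for (f in unique(tf)) {
    sel <- which(tf == f)
    rf <- ranks[f, ]
    if (stats::sd(rf) == 0) stop("constant TF profile: ", f)
    rt <- ranks[target[sel], , drop = FALSE]
    sds <- apply(rt, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant target profile: ", target[sel][which(sds == 0)[1L]])
    }
    mode[sel] <- as.numeric(stats::cor(rf, t(rt)))
  }
  w <- stats::ave(mi, tf, FUN = function(v) v / max(v))
  regulon_set(tf, target, mode, w)
}

#' Signature-restricted regulon sizes
#'
#' Number of each TF's targets that belong to the molecular-signature gene
#' universe. The master-regulator analysis only tests regulons whose
#' signature-restricted size passes a minimum (20 by default).
#'
#' @param regulons A [regulon_set].
#' @param signature_genes Character vector of signature gene symbols.
#' @return Named integer vector, one count per TF in the regulon set.
#' @export
regulon_signature_size <- function(regulons, signature_genes) {
  if (nrow(regulons) == 0L) return(stats::setNames(integer(), character()))
  hit <- regulons$target %in% signature_genes
  counts <- tapply(hit, regulons$tf, sum)
  stats::setNames(as.integer(counts), names(counts))
}
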