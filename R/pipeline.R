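# End-to-end orchestration: expression matrix + TF list + pathway sets in,
# ranked master regulators out.

#' Fit the signature-restricted master-regulator model
#'
#' Runs the full pipeline on a two-condition expression dataset:
#' 1. pooled-null mutual-information network over all TF x gene pairs
#'    ([build_mi_null()], [build_mi_network()]), pruned by the data
#'    processing inequality ([apply_dpi()]);
#' 2. directed regulons with Spearman modes and max-normalised MI weights
#'    ([build_regulons()]);
#' 3. pathway-restricted molecular signature and label-permutation null
#'    model ([compute_signature()], [build_null_model()]);
#' 4. GSEA-based regulon ranking with NES, Gaussian-tail p and BH FDR
#'    ([run_mra()]).
#'
#' @param dataset An [expression_dataset].
#' @param tfs Character vector of transcription-factor symbols.
#' @param pathways A [gene_set_collection]; its pooled gene universe is the
#'   molecular signature restriction.
#' @param alpha Edge significance level for the MI network (default 0.005).
#' @param dpi_tolerance Data processing inequality tolerance (default 0.2).
#' @param n_bins MI bin count (default from the sample count).
#' @param n_perm_pairs Size of the pooled MI null (default 10000).
#' @param n_signature_perms Label permutations for the signature null
#'   (default 1000).
#' @param min_targets Minimum signature-restricted regulon size tested
#'   (default 20).
#' @param use_weights Use MI-derived weights in the enrichment score
#'   (default `TRUE`).
#' @param seed Integer seed driving both permutation nulls.
#' @return An `mra` object (see [run_mra()]) with extra elements `network`
#'   (the pruned `mi_network`) and `null` (the `signature_null`).
#' @examples
#' \donttest{
#' sim <- generate_dataset(sim_config(n_tf = 10, n_background_genes = 50,
#'                                    n_pathways = 5, seed = 7))
#' fit <- master_regulators(sim$dataset, sim$truth$tf_genes,
#'                          sim$truth$pathways, n_signature_perms = 100)
#' print(fit)
#' }
#' @export
master_regulators <- function(dataset, tfs, pathways,
                              alpha = 0.005, dpi_tolerance = 0.2,
                              n_bins = NULL, n_perm_pairs = 10000L,
                              n_signature_perms = 1000L,
                              min_targets = 20L, use_weights = TRUE,
                              seed = 1L) {
  null_mi <- build_mi_null(dataset, n_bins = n_bins,
                           n_perm_pairs = n_perm_pairs, seed = seed)
  net <- build_mi_network(dataset, tfs, n_bins = n_bins, alpha = alpha,
                          null = null_mi)
  net <- apply_dpi(net, tolerance = dpi_tolerance)
  regulons <- build_regulons(net, dataset)
  signature <- compute_signature(dataset, pathways)
  null_sig <- build_null_model(dataset, pathways, k = n_signature_perms,
                               seed = seed + 1L)
  fit <- run_mra(regulons, signature, null_sig, min_targets = min_targets,
                 use_weights = use_weights)
  fit$network <- net
  fit$null <- null_sig
  fit
}
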