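# Master-regulator analysis: rank regulons by a two-set weighted
# Kolmogorov-Smirnov (GSEA) enrichment of the molecular signature, with NES
# and p calibrated against the label-permutation null model.

#' GSEA enrichment score of a gene set against a ranked signature
#'
#' Genes are ranked by Z-score descending (ties broken by gene symbol so
#' the ranking is deterministic); a weighted Kolmogorov-Smirnov running sum
#' walks down the list, incrementing at member genes proportionally to
#' `|z|` (optionally scaled by per-member weights) and decrementing at
#' non-members by `1 / (n - m)`. The enrichment score is the signed
#' deviation of maximum magnitude; if two deviations tie in magnitude
#' (within numerical tolerance), the one reached earlier in the walk is
#' reported.
#'
#' @param gene_scores Named numeric vector of Z-scores (a
#'   [molecular_signature] works as-is).
#' @param member_set Character vector of member gene symbols; the
#'   intersection with the signature must be non-empty and smaller than the
#'   whole universe.
#' @param member_weights Optional named numeric vector (one weight per
#'   member) multiplying the `|z|` hit increments.
#' @return Enrichment score in `[-1, 1]`.
#' @examples
#' z <- c(A = 3, B = 2, C = -2, D = -3)
#' gsea_es(z, "A")  #  1
#' gsea_es(z, "D")  # -1
#' @export
gsea_es <- function(gene_scores, member_set, member_weights = NULL) {
  z <- as.numeric(gene_scores)
  names(z) <- names(gene_scores)
  members <- intersect(member_set, names(z))
  n <- length(z)
  m <- length(members)
  if (m == 0L) stop("member set is empty after intersecting with the signature")
  if (m >= n) stop("member set covers the whole signature universe")
  ord <- order(-z, names(z))
  ranked <- names(z)[ord]
  hit <- ranked %in% members
  w <- abs(z)[ord]
  if (!is.null(member_weights)) {
    mw <- rep(1, n)
    idx <- match(names(member_weights), ranked)
    mw[idx[!is.na(idx)]] <- member_weights[!is.na(idx)]
    w <- w * mw
  }
  w[!hit] <- 0
  total <- sum(w)
  if (total == 0) {
    w[hit] <- 1 / m  # all member scores zero: fall back to equal increments
  } else {
    w <- w / total
  }
  step <- ifelse(hit, w, -1 / (n - m))
  running <- cumsum(step)
  pick_extreme(running)
}

# signed deviation of maximum magnitude; on a magnitude tie (within
# numerical tolerance) the earliest position in running order wins
pick_extreme <- function(values, tol = 1e-12) {
  mx <- max(abs(values))
  values[which(abs(values) >= mx - tol)[1L]]
}

#' Regulon enrichment score with mode-of-regulation splitting
#'
#' Signature-restricted targets are split by mode sign: positive (or zero)
#' modes form the activated set, negative modes the repressed set. The
#' activated set is scored on the Z-descending ranking, the repressed set
#' on the reversed (-Z) ranking, and the two scores are combined as a
#' size-weighted average. A positive combined score means the targets moved
#' the way an *active* TF predicts; a negative score the way an
#' *inactivated* TF predicts.
#'
#' @param targets,modes Parallel vectors: target symbols and their modes.
#' @param signature A [molecular_signature] (or named Z-score vector).
#' @param weights Optional per-target weights (parallel to `targets`)
#'   multiplying hit increments; used when `use_weights = TRUE` in
#'   [run_mra()].
#' @return Combined enrichment score in `[-1, 1]`.
#' @export
regulon_es <- function(targets, modes, signature, weights = NULL) {
  keep <- targets %in% names(signature)
  targets <- targets[keep]
  modes <- modes[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(targets) == 0L) stop("no regulon target is in the signature")
  pos <- modes >= 0
  z <- as.numeric(signature)
  names(z) <- names(signature)
  es_pos <- es_neg <- 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  wts <- function(sel) {
    if (is.null(weights)) NULL else stats::setNames(weights[sel], targets[sel])
  }
  if (n_pos > 0L) es_pos <- gsea_es(z, targets[pos], wts(pos))
  if (n_neg > 0L) es_neg <- gsea_es(-z, targets[!pos], wts(!pos))
  (n_pos * es_pos + n_neg * es_neg) / (n_pos + n_neg)
}

#' Normalised enrichment score and Gaussian-tail p-value
#'
#' Standardises an observed enrichment score against its null distribution,
#' `nes = (es - mean(null)) / sd(null)`, and converts it to a two-sided
#' p-value under a Gaussian approximation of the null,
#' `p = 2 * (1 - pnorm(|nes|))`.
#'
#' @param es Observed enrichment score.
#' @param null_es Numeric vector (>= 100) of null enrichment scores.
#' @return List with elements `nes` and `p`.
#' @export
nes_and_p <- function(es, null_es) {
  if (length(null_es) < 100L) stop("need >= 100 null enrichment scores")
  s <- stats::sd(null_es)
  if (s == 0) stop("null enrichment scores have zero variance")
  nes <- (es - mean(null_es)) / s
  p <- 2 * stats::pnorm(-abs(nes))
  list(nes = nes, p = max(p, .Machine$double.xmin))
}

# ---- fast ranking/ES machinery used for the null loop -------------------
# Precompute a ranking of z (descending, symbol tie-break): positions and
# |z| in ranked order, so per-regulon ES costs O(m) instead of O(n log n).
prep_ranking <- function(z) {
  ord <- order(-z, names(z))
  pos <- integer(length(z))
  pos[ord] <- seq_along(z)
  list(absz_ranked = abs(z)[ord],
       pos = stats::setNames(pos, names(z)),
       n = length(z))
}

# ES from precomputed ranking: extremes of the running sum occur only just
# before or just after a hit, so only 2m candidates need checking.
es_from_ranking <- function(ranking, member_pos, member_w) {
  n <- ranking$n
  o <- order(member_pos)
  p <- member_pos[o]
  m <- length(p)
  w <- ranking$absz_ranked[p] * member_w[o]
  total <- sum(w)
  w <- if (total == 0) rep(1 / m, m) else w / total
  miss <- 1 / (n - m)
  cw <- cumsum(w)
  after <- cw - (p - seq_len(m)) * miss        # value just after each hit
  before <- after - w                          # value just before each hit
  # interleave so candidates appear in running order for the tie rule
  cand <- unname(as.vector(rbind(before, after)))
  pick_extreme(cand)
}

# regulon_es via the fast path, given rankings for +z and -z
regulon_es_fast <- function(rk_pos, rk_neg, tpos, tneg, wpos, wneg) {
  n_pos <- length(tpos); n_neg <- length(tneg)
  es_pos <- if (n_pos > 0L) es_from_ranking(rk_pos, rk_pos$pos[tpos], wpos) else 0
  es_neg <- if (n_neg > 0L) es_from_ranking(rk_neg, rk_neg$pos[tneg], wneg) else 0
  (n_pos * es_pos + n_neg * es_neg) / (n_pos + n_neg)
}

#' Run the master-regulator analysis
#'
#' Scores every regulon with at least `min_targets` signature-restricted
#' targets: the observed enrichment score against the real signature, a
#' null enrichment distribution obtained by rescoring the regulon against
#' every column of the label-permutation null model, NES and p from
#' [nes_and_p()], Benjamini-Hochberg FDR across all tested regulons, and a
#' rank (ascending p, ties by descending `|NES|`, then TF symbol).
#'
#' @param regulons A [regulon_set].
#' @param signature A [molecular_signature].
#' @param null A `signature_null` from [build_null_model()].
#' @param min_targets Minimum signature-restricted regulon size (default
#'   20).
#' @param use_weights Scale hit increments by the regulon's MI-derived
#'   weights (default `TRUE`).
#' @return Object of class `mra`: list with `table` (one row per tested
#'   regulon: `regulon`, `size`, `es`, `nes`, `p_value`, `fdr`, `rank`,
#'   sorted by rank), plus the inputs needed by the methods
#'   (`regulons`, `signature`, `min_targets`).
#' @seealso [master_regulators()] for the end-to-end pipeline,
#'   [coverage_curve()] for signature coverage of the top regulons.
#' @export
run_mra <- function(regulons, signature, null, min_targets = 20L,
                    use_weights = TRUE) {
  sizes <- regulon_signature_size(regulons, names(signature))
  tested <- names(sizes)[sizes >= min_targets]
  if (length(tested) == 0L) {
    stop(sprintf("no regulon has >= %d targets in the signature", min_targets))
  }
  per_tf <- split_regulons(regulons)[tested]
  z_obs <- as.numeric(signature)
  names(z_obs) <- names(signature)

  # restrict each regulon to signature genes once, split by mode sign
  reg_parts <- lapply(per_tf, function(df) {
    df <- df[df$target %in% names(signature), , drop = FALSE]
    pos <- df$mode >= 0
    list(tpos = df$target[pos], tneg = df$target[!pos],
         wpos = if (use_weights) df$weight[pos] else rep(1, sum(pos)),
         wneg = if (use_weights) df$weight[!pos] else rep(1, sum(!pos)))
  })

  rkp_obs <- prep_ranking(z_obs)
  rkn_obs <- prep_ranking(-z_obs)
  es_obs <- vapply(reg_parts, function(pp) {
    regulon_es_fast(rkp_obs, rkn_obs, pp$tpos, pp$tneg, pp$wpos, pp$wneg)
  }, 0)

  k <- ncol(null)
  es_null <- matrix(NA_real_, length(tested), k,
                    dimnames = list(tested, NULL))
  for (j in seq_len(k)) {
    zj <- null[, j]
    rkp <- prep_ranking(zj)
    rkn <- prep_ranking(-zj)
    es_null[, j] <- vapply(reg_parts, function(pp) {
      regulon_es_fast(rkp, rkn, pp$tpos, pp$tneg, pp$wpos, pp$wneg)
    }, 0)
  }

  nes <- p <- numeric(length(tested))
  for (i in seq_along(tested)) {
    np <- nes_and_p(es_obs[i], es_null[i, ])
    nes[i] <- np$nes
    p[i] <- np$p
  }
  fdr <- stats::p.adjust(p, method = "BH")
  ord <- order(p, -abs(nes), tested)
  tab <- data.frame(
    regulon = tested[ord],
    size = unname(sizes[tested][ord]),
    es = unname(es_obs[ord]),
    nes = nes[ord],
    p_value = p[ord],
    fdr = fdr[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, regulons = regulons, signature = signature,
                 min_targets = min_targets, n_null = k),
            class = "mra")
}

#' @export
print.mra <- function(x, ...) {
  cat(sprintf(
    "Master-regulator analysis: %d regulons tested (>= %d signature targets), %d null permutations\n",
    nrow(x$table), x$min_targets, x$n_null
  ))
  top <- utils::head(x$table, 10L)
  top$es <- round(top$es, 3)
  top$nes <- round(top$nes, 2)
  top$p_value <- signif(top$p_value, 3)
  top$fdr <- signif(top$fdr, 3)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mra <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  cat(sprintf("%d regulons tested; %d with FDR <= %g; %d repressive (NES < 0)\n",
              nrow(tab), sum(tab$fdr <= alpha), alpha, sum(tab$nes < 0)))
  cov <- coverage_curve(object, object$regulons, names(object$signature))
  k10 <- min(10L, nrow(cov))
  cat(sprintf("top-%d regulons cover %d/%d signature genes (%.1f%%)\n",
              k10, cov$covered[k10], length(object$signature),
              100 * cov$fraction[k10]))
  invisible(object)
}

#' @export
coef.mra <- function(object, ...) {
  stats::setNames(object$table$nes, object$table$regulon)
}

#' @export
plot.mra <- function(x, max_k = 50L, ...) {
  cov <- coverage_curve(x, x$regulons, names(x$signature))
  kk <- seq_len(min(max_k, nrow(cov)))
  graphics::plot(kk, 100 * cov$fraction[kk], type = "s",
                 xlab = "top-k regulons",
                 ylab = "% of signature genes covered",
                 main = "Signature coverage of ranked master regulators", ...)
  invisible(x)
}

#' Cumulative signature coverage of the ranked regulons
#'
#' For each `k`, the number (and fraction) of signature genes contained in
#' the union of the top-`k` ranked regulons' targets.
#'
#' @param result An `mra` object (or its table).
#' @param regulons The [regulon_set] the analysis used.
#' @param signature_genes Character vector of signature gene symbols.
#' @return Data frame with columns `k`, `covered`, `fraction`
#'   (non-decreasing in `k`).
#' @export
coverage_curve <- function(result, regulons, signature_genes) {
  tab <- if (inherits(result, "mra")) result$table else result
  if (nrow(tab) == 0L) stop("empty master-regulator result")
  per_tf <- split_regulons(regulons)
  sig <- unique(signature_genes)
  covered_set <- character(0)
  covered <- integer(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    tg <- per_tf[[tab$regulon[k]]]$target
    covered_set <- union(covered_set, intersect(tg, sig))
    covered[k] <- length(covered_set)
  }
  data.frame(k = seq_len(nrow(tab)), covered = covered,
             fraction = covered / length(sig))
}
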