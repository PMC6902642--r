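# Per-sample, per-pathway deregulation scores: pathway expression is
# normalised against the control samples, reduced by PCA, summarised by a
# Hastie-Stuetzle principal curve, and each sample's arc-length position
# along the curve -- centred at the control median and normalised by curve
# length -- is its pathway deregulation score (PDS).

#' Normalise pathway expression to the control reference
#'
#' Restricts the dataset to the pathway genes present in the matrix and
#' standardises each gene by its control-sample mean and standard
#' deviation. Genes with zero control variance are dropped (with a
#' message); absent genes are silently excluded with a logged count.
#'
#' @param dataset An [expression_dataset] with >= 2 control samples.
#' @param pathway_genes Character vector of pathway gene symbols.
#' @return Numeric matrix (usable genes x all samples), control columns
#'   standardised to mean 0 / sd 1 per gene.
#' @export
normalize_to_reference <- function(dataset, pathway_genes) {
  cc <- class_counts(dataset)
  genes <- intersect(unique(normalize_symbols(pathway_genes)),
                     rownames(dataset$values))
  n_absent <- length(unique(normalize_symbols(pathway_genes))) - length(genes)
  if (n_absent > 0L) {
    message(sprintf("%d pathway gene(s) absent from the matrix, excluded",
                    n_absent))
  }
  if (length(genes) < 2L) stop("fewer than 2 pathway genes present in the matrix")
  x <- dataset$values[genes, , drop = FALSE]
  ctrl <- x[, dataset$labels == "control", drop = FALSE]
  mu <- rowMeans(ctrl)
  sdev <- apply(ctrl, 1L, stats::sd)
  keep <- sdev > 0
  if (any(!keep)) {
    message(sprintf("dropping %d gene(s) with zero control variance", sum(!keep)))
  }
  if (sum(keep) < 2L) stop("fewer than 2 usable pathway genes after filtering")
  (x[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
}

# squared distances from points to the segment a->b; returns list(d2, t)
# with t the within-segment projection parameter in [0, 1]
dist_to_segment <- function(points, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  diff <- sweep(points, 2L, a)
  t <- if (len2 == 0) rep(0, nrow(points)) else
    pmin(pmax(as.numeric(diff %*% ab) / len2, 0), 1)
  proj <- outer(t, ab)
  d2 <- rowSums((diff - proj)^2)
  list(d2 = d2, t = t)
}

# Project points onto the polyline `vertices` (ordered rows). Returns
# arc-length positions and squared distances.
project_to_polyline <- function(points, vertices) {
  k <- nrow(vertices)
  seg_len <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                           vertices[-k, , drop = FALSE])^2))
  cum_len <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, nrow(points))
  best_lambda <- rep(0, nrow(points))
  for (s in seq_len(k - 1L)) {
    pr <- dist_to_segment(points, vertices[s, ], vertices[s + 1L, ])
    upd <- pr$d2 < best_d2
    best_d2[upd] <- pr$d2[upd]
    best_lambda[upd] <- cum_len[s] + pr$t[upd] * seg_len[s]
  }
  list(lambda = best_lambda, d2 = best_d2, length = cum_len[k])
}

# one smoothing pass: spline (or line, when too few distinct values) of
# each coordinate against arc length, evaluated at the points' own lambdas.
# A fixed, modest effective df regularises the self-consistency iteration;
# df = NULL falls back to GCV.
smooth_coordinates <- function(points, lambda, df = 5) {
  n_unique <- length(unique(lambda))
  vapply(seq_len(ncol(points)), function(j) {
    y <- points[, j]
    if (n_unique >= 5L) {
      fit <- if (is.null(df)) {
        suppressWarnings(stats::smooth.spline(lambda, y, cv = FALSE))
      } else {
        suppressWarnings(stats::smooth.spline(lambda, y,
                                              df = min(df, n_unique - 1L)))
      }
      as.numeric(stats::predict(fit, lambda)$y)
    } else {
      as.numeric(stats::fitted(stats::lm(y ~ lambda)))
    }
  }, numeric(nrow(points)))
}

#' Fit a principal curve
#'
#' Hastie-Stuetzle alternation: initialise arc-length positions on the
#' first principal component, then repeat (a) smooth each coordinate
#' against arc length with a cubic smoothing spline of fixed, modest
#' effective degrees of freedom (the bounded flexibility keeps the
#' self-consistency iteration from chasing individual points; set
#' `df = NULL` for a GCV-chosen penalty), (b)
#' re-project all points onto the resulting polyline. Iteration stops when
#' the relative improvement of total squared projection distance falls
#' below `tol`, when `max_iter` is reached, or when a step fails to
#' improve the fit (the previous curve is kept, so the recorded distance
#' sequence is non-increasing).
#'
#' @param points Numeric matrix, samples x dimensions (>= 3 distinct
#'   points).
#' @param max_iter Maximum number of iterations.
#' @param tol Relative convergence tolerance on total squared distance.
#' @param df Effective degrees of freedom of the coordinate smoothers
#'   (default 5); `NULL` selects the penalty by generalised
#'   cross-validation instead.
#' @return Object of class `principal_curve`: list with `vertices` (ordered
#'   polyline), `lambda` (arc-length position per sample), `dist2` (total
#'   squared projection distance), `dist2_trace` (per-iteration values),
#'   `length` (total arc length) and `converged`.
#' @export
fit_principal_curve <- function(points, max_iter = 30L, tol = 1e-4, df = 5) {
  points <- as.matrix(points)
  if (nrow(unique(points)) < 3L) stop("need >= 3 distinct points")
  if (ncol(points) == 1L) {
    # one-dimensional cloud: the curve is the value axis itself
    lambda <- points[, 1L] - min(points[, 1L])
    ord <- order(points[, 1L])
    vertices <- points[ord, , drop = FALSE]
    return(structure(list(vertices = vertices, lambda = lambda,
                          dist2 = 0, dist2_trace = 0,
                          length = diff(range(points[, 1L])),
                          converged = TRUE),
                     class = "principal_curve"))
  }
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  lambda <- pc$x[, 1L]
  best <- NULL
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fitted_pts <- smooth_coordinates(points, lambda, df = df)
    ord <- order(lambda)
    vertices <- fitted_pts[ord, , drop = FALSE]
    proj <- project_to_polyline(points, vertices)
    d2 <- sum(proj$d2)
    if (!is.null(best) && d2 > best$dist2) break  # keep the better curve
    best <- list(vertices = vertices, lambda = proj$lambda, dist2 = d2,
                 length = proj$length)
    trace <- c(trace, d2)
    if (length(trace) >= 2L) {
      prev <- trace[length(trace) - 1L]
      if ((prev - d2) <= tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    if (d2 < 1e-12) { converged <- TRUE; break }
    lambda <- proj$lambda
  }
  structure(c(best, list(dist2_trace = trace, converged = converged)),
            class = "principal_curve")
}

#' @export
print.principal_curve <- function(x, ...) {
  cat(sprintf(
    "principal_curve: %d vertices in %d dims, length %.3f, total squared distance %.4g (%s)\n",
    nrow(x$vertices), ncol(x$vertices), x$length, x$dist2,
    if (x$converged) "converged" else "max iterations"
  ))
  invisible(x)
}

#' Compute pathway deregulation scores
#'
#' Per pathway: normalise expression against the control reference, reduce
#' by PCA to the fewest components explaining `var_fraction` of the
#' variance (at most `max_components`), fit a principal curve to all
#' samples, project every sample to its arc-length position, orient the
#' curve so that the control median precedes the case median, and score
#' `pds = (lambda - median(control lambda)) / curve length`. Control
#' samples therefore have median PDS exactly 0, and scores are signed:
#' positive values lie beyond the controls in the case direction.
#' Pathways that fail (too few usable genes, degenerate geometry) are
#' skipped with a message rather than aborting the matrix.
#'
#' @param dataset An [expression_dataset].
#' @param pathways A [gene_set_collection].
#' @param var_fraction Fraction of variance the retained principal
#'   components must reach (default 0.8).
#' @param max_components Cap on retained components (default 10).
#' @param max_iter,tol,df Passed to [fit_principal_curve()].
#' @return Object of class `pds_matrix`: pathways x samples numeric matrix
#'   with attribute `meta` (per-pathway genes used and components kept).
#' @export
compute_pds <- function(dataset, pathways, var_fraction = 0.8,
                        max_components = 10L, max_iter = 30L, tol = 1e-4,
                        df = 5) {
  is_ctrl <- dataset$labels == "control"
  rows <- list()
  meta <- list()
  for (nm in names(pathways$sets)) {
    res <- tryCatch({
      z <- normalize_to_reference(dataset, pathways$sets[[nm]])
      pts <- t(z)
      pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
      cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      ncomp <- min(which(cumvar >= var_fraction)[1L], max_components,
                   ncol(pc$x))
      scores <- pc$x[, seq_len(ncomp), drop = FALSE]
      curve <- fit_principal_curve(scores, max_iter = max_iter, tol = tol,
                                   df = df)
      if (curve$length <= 0) stop("degenerate curve of zero length")
      lambda <- curve$lambda
      if (stats::median(lambda[is_ctrl]) > stats::median(lambda[!is_ctrl])) {
        lambda <- curve$length - lambda
      }
      list(pds = (lambda - stats::median(lambda[is_ctrl])) / curve$length,
           genes = rownames(z), ncomp = ncomp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("pathway %s skipped: %s", nm, conditionMessage(res)))
      next
    }
    rows[[nm]] <- res$pds
    meta[[nm]] <- list(genes = res$genes, components = res$ncomp)
  }
  if (length(rows) == 0L) stop("no pathway could be scored")
  mat <- do.call(rbind, rows)
  colnames(mat) <- colnames(dataset$values)
  structure(mat, class = c("pds_matrix", "matrix"), meta = meta)
}

#' @export
print.pds_matrix <- function(x, ...) {
  cat(sprintf("pds_matrix: %d pathways x %d samples; PDS range [%.2f, %.2f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
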