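test_that("mutual information has the exact values forced by its binning contract", {
  x <- as.numeric(1:64)
  # identical profiles: diagonal joint distribution -> MI = log(bins)
  expect_equal(mutual_information(x, x, n_bins = 8), log(8), tolerance = 1e-12)
  # full factorial 8x8 grid of quantile cells -> exact independence, MI = 0
  g <- expand.grid(a = 1:8, b = 1:8)
  expect_equal(mutual_information(g$a, g$b, n_bins = 8), 0, tolerance = 1e-12)
  # degenerate input
  expect_error(mutual_information(rep(1, 64), x, n_bins = 8), "constant")
  expect_error(mutual_information(x, x[-1], n_bins = 8), "length")
})

test_that("mutual information matches an independent joint-histogram oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(40:200, 1)
    bins <- sample(2:8, 1)
    rho <- runif(1, -0.95, 0.95)
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_equal(mutual_information(x, y, n_bins = bins),
                 oracle_mi(x, y, bins), tolerance = 1e-12)
  }
})

test_that("mutual information is symmetric and monotone-transform invariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(80)
    y <- 0.6 * x + rnorm(80)
    mi <- mutual_information(x, y, n_bins = 4)
    expect_identical(mi, mutual_information(y, x, n_bins = 4))
    expect_equal(mutual_information(exp(x), y^3 + 2 * y, n_bins = 4), mi,
                 tolerance = 1e-12)
    expect_gte(mi, 0)
  }
})

test_that("the vectorised TF-vs-genes MI path agrees with the scalar estimator", {
  set.seed(11)
  nd <- noise_dataset(n_genes = 30, n = 100, seed = 11)
  vals <- nd$dataset$values
  nb <- default_bins(ncol(vals))
  bins <- t(apply(vals, 1, function(v) {
    as.integer(ceiling(rank(v) * nb / length(v)))
  }))
  fast <- sigmra:::mi_profile_vs_matrix(bins[1, ], bins[-1, ], nb)
  slow <- apply(vals[-1, ], 1, function(v) mutual_information(vals[1, ], v, nb))
  expect_equal(unname(fast), unname(slow), tolerance = 1e-12)
})

test_that("MI null is deterministic, non-negative, and has a spread upper tail", {
  nd <- noise_dataset(n_genes = 40, n = 200, seed = 2)
  null1 <- build_mi_null(nd$dataset, n_perm_pairs = 1000, seed = 7)
  null2 <- build_mi_null(nd$dataset, n_perm_pairs = 1000, seed = 7)
  expect_identical(null1$null_mis, null2$null_mis)
  expect_true(all(null1$null_mis >= 0))
  expect_false(is.unsorted(null1$null_mis))
  q <- quantile(null1$null_mis, c(0.5, 0.995))
  expect_gt(q[2], q[1])
  expect_error(build_mi_null(nd$dataset, n_perm_pairs = 10), "1000")
})

test_that("the significant-MI network keeps planted edges and controls noise edges", {
  # strong-coupling planted dataset: essentially all true edges retained
  cfg <- sim_config(n_case = 120, n_control = 30, n_tf = 8, n_diff_tf = 4,
                    targets_per_tf = c(8, 12), coupling = 2, noise_sd = 1,
                    n_background_genes = 60, seed = 21)
  retained <- numeric(0)
  for (seed in 1:3) {
    cfg$seed <- seed + 20L
    sim <- generate_dataset(cfg)
    null <- build_mi_null(sim$dataset, n_perm_pairs = 2000, seed = seed)
    net <- build_mi_network(sim$dataset, sim$truth$tf_genes, null = null)
    key <- paste(net$gene_a, net$gene_b)
    truth <- sim$truth$regulons
    hit <- paste(truth$tf, truth$target) %in% key |
           paste(truth$target, truth$tf) %in% key
    retained <- c(retained, mean(hit))
  }
  expect_true(all(retained >= 0.99))

  # pure-noise dataset: retained fraction of tested pairs <= 2 * alpha
  nd <- noise_dataset(n_genes = 100, n_tf = 10, n = 150, seed = 31)
  null <- build_mi_null(nd$dataset, n_perm_pairs = 4000, seed = 1)
  net <- build_mi_network(nd$dataset, nd$tfs, alpha = 0.005, null = null)
  n_tested <- 10 * 90 + choose(10, 2)
  expect_lte(nrow(net) / n_tested, 2 * 0.005)

  expect_error(build_mi_network(nd$dataset, c("NOPE1", "NOPE2"), null = null),
               "no TF")
})

test_that("DPI removes the weakest triangle edge exactly as specified", {
  tri <- function(m1, m2, m3) {
    structure(data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                         mi = c(m1, m2, m3), p_value = 1e-4,
                         stringsAsFactors = FALSE),
              class = c("mi_network", "data.frame"))
  }
  # 0.1 < 0.8*0.4 and 0.1 < 0.8*0.5 -> the 0.1 edge goes
  out <- apply_dpi(tri(0.5, 0.4, 0.1), tolerance = 0.2)
  expect_equal(nrow(out), 2L)
  expect_false(0.1 %in% out$mi)
  # 0.4 >= 0.8*0.45 -> nothing removed
  out2 <- apply_dpi(tri(0.5, 0.45, 0.4), tolerance = 0.2)
  expect_equal(nrow(out2), 3L)
})

test_that("DPI agrees with exhaustive triple enumeration on random small graphs", {
  set.seed(77)
  for (i in 1:500) {
    n_nodes <- sample(3:6, 1)
    nodes <- LETTERS[seq_len(n_nodes)]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.7
    if (!any(keep)) next
    edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                        mi = runif(sum(keep), 0.01, 1), p_value = 1e-4,
                        stringsAsFactors = FALSE)
    tol <- runif(1, 0, 0.9)
    got <- apply_dpi(structure(edges, class = c("mi_network", "data.frame")),
                     tolerance = tol)
    want <- oracle_dpi(edges, tol)
    expect_equal(paste(got$gene_a, got$gene_b),
                 paste(want$gene_a, want$gene_b))
  }
})

test_that("DPI limiting tolerances behave as pruning bounds", {
  set.seed(8)
  nodes <- LETTERS[1:5]
  pairs <- t(combn(nodes, 2))
  edges <- structure(
    data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
               mi = runif(nrow(pairs), 0.1, 1), p_value = 1e-4,
               stringsAsFactors = FALSE),
    class = c("mi_network", "data.frame"))
  # tolerance ~1: nothing removed
  out_keep <- apply_dpi(edges, tolerance = 0.999999)
  expect_equal(nrow(out_keep), nrow(edges))
  # tolerance 0 on a complete graph: every strict-minimum edge of every
  # triangle must be gone
  out0 <- apply_dpi(edges, tolerance = 0)
  key <- function(df) paste(df$gene_a, df$gene_b)
  for (t in seq_len(ncol(combn(nodes, 3)))) {
    tr <- combn(nodes, 3)[, t]
    sub <- edges[edges$gene_a %in% tr & edges$gene_b %in% tr, ]
    weakest <- sub[which.min(sub$mi), ]
    if (sub$mi[which.min(sub$mi)] < sort(sub$mi)[2]) {
      expect_false(key(weakest) %in% key(out0))
    }
  }
  # output edges are always a subset with unchanged MI values
  expect_true(all(key(out0) %in% key(edges)))
  expect_equal(out0$mi, edges$mi[match(key(out0), key(edges))])
})
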