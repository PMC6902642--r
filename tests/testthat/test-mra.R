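test_that("enrichment score hits the single-member extremes", {
  z <- c(A = 3, B = 2, C = -2, D = -3)
  expect_equal(gsea_es(z, "A"), 1.0)
  expect_equal(gsea_es(z, "D"), -1.0)
  expect_error(gsea_es(z, "NOPE"), "empty")
  expect_error(gsea_es(z, names(z)), "whole")
})

test_that("enrichment score equals a position-by-position running-sum oracle", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    z <- setNames(rnorm(n), sprintf("g%02d", sample(99, n)))
    m <- sample(1:(n - 1), 1)
    members <- sample(names(z), m)
    w <- if (runif(1) < 0.5) NULL else setNames(runif(m, 0.1, 1), members)
    expect_equal(gsea_es(z, members, w), oracle_gsea(z, members, w),
                 tolerance = 1e-12)
  }
})

test_that("enrichment score is bounded and responds monotonically to member scores", {
  set.seed(66)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    z <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    members <- sample(names(z), sample(2:(n - 2), 1))
    es <- gsea_es(z, members)
    expect_gte(es, -1); expect_lte(es, 1)
  }
  # adding +delta to the z of a positive-mode member never decreases ES+
  z <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  members <- c("g03", "g07", "g11")
  base <- gsea_es(z, members)
  z_up <- z; z_up["g07"] <- z_up["g07"] + 1.5
  expect_gte(gsea_es(z_up, members), base)
})

test_that("regulon scores combine the mode-split parts with the documented sign convention", {
  z <- setNames(c(3, 2, 1, -1, -2, -3), sprintf("g%d", 1:6))
  # all-positive-mode regulon collapses to the plain enrichment score
  expect_equal(regulon_es(c("g1", "g2"), c(0.9, 0.5), z),
               gsea_es(z, c("g1", "g2")))
  # flipping every mode and every z leaves the combined score unchanged
  tg <- c("g1", "g2", "g5", "g6")
  md <- c(0.8, 0.6, -0.7, -0.9)
  expect_equal(regulon_es(tg, md, z), regulon_es(tg, -md, -z),
               tolerance = 1e-12)
  # permuting target order changes nothing
  set.seed(9)
  perm <- sample(4)
  expect_equal(regulon_es(tg[perm], md[perm], z), regulon_es(tg, md, z))
  # up-shifted positive-mode targets mean an active TF: positive score
  expect_gt(regulon_es(c("g1", "g2"), c(1, 1), z), 0)
  # repressed targets up + activated targets down: inactivated TF, negative
  expect_lt(regulon_es(c("g1", "g5"), c(-1, 1), z), 0)
})

test_that("the fast ranking-based ES path agrees with the reference implementation", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    z <- setNames(rnorm(n), sprintf("g%03d", sample(500, n)))
    m <- sample(2:10, 1)
    tg <- sample(names(z), m)
    md <- runif(m, -1, 1)
    w <- runif(m, 0.2, 1)
    rkp <- sigmra:::prep_ranking(z)
    rkn <- sigmra:::prep_ranking(-z)
    pos <- md >= 0
    fast <- sigmra:::regulon_es_fast(rkp, rkn, tg[pos], tg[!pos],
                                     w[pos], w[!pos])
    slow <- regulon_es(tg, md, z, weights = w)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("NES standardisation and its Gaussian-tail p behave as documented", {
  # exactly standardised null -> nes is the raw score
  null <- as.numeric(scale(rnorm(5000)))
  res <- nes_and_p(-4.12, null)
  expect_equal(res$nes, -4.12, tolerance = 1e-9)
  expect_equal(res$p, 2 * pnorm(-4.12), tolerance = 1e-6)
  # es at the null mean -> nes 0, p 1
  res0 <- nes_and_p(mean(null), null)
  expect_equal(res0$nes, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  # large standard-normal null: es = 1.96 gives p ~ 0.05
  set.seed(123)
  big <- rnorm(1e5)
  expect_equal(nes_and_p(1.96, big)$p, 0.05, tolerance = 0.005)
  expect_error(nes_and_p(1, rep(0.5, 200)), "zero variance")
  expect_error(nes_and_p(1, rnorm(50)), "100")
})

test_that("the size filter and ranking rules of the analysis are enforced", {
  set.seed(88)
  genes <- sprintf("G%03d", 1:60)
  z <- setNames(rnorm(60), genes)
  sig <- structure(z, class = "molecular_signature")
  null <- matrix(rnorm(60 * 120), 60, 120, dimnames = list(genes, NULL))
  # TF_BIG has 25 signature targets, TF_SMALL only 19
  regs <- regulon_set(
    c(rep("TF_BIG", 25), rep("TF_SMALL", 19)),
    c(genes[1:25], genes[26:44]),
    runif(44, -1, 1), runif(44, 0.5, 1))
  fit <- run_mra(regs, sig, null, min_targets = 20)
  expect_equal(fit$table$regulon, "TF_BIG")
  expect_false("TF_SMALL" %in% fit$table$regulon)
  expect_error(run_mra(regs, sig, null, min_targets = 30), "no regulon")
  # table invariants
  expect_equal(fit$table$rank, seq_len(nrow(fit$table)))
  expect_true(all(fit$table$fdr >= 0 & fit$table$fdr <= 1))
  # methods
  expect_named(coef(fit), fit$table$regulon)
  expect_output(print(fit), "TF_BIG")
})

test_that("coverage of ranked regulons equals a brute-force set union", {
  # 10 disjoint regulons of 10 signature targets over a 100-gene signature
  sig_genes <- sprintf("S%03d", 1:100)
  tf <- rep(sprintf("TF%02d", 1:10), each = 10)
  regs <- regulon_set(tf, sig_genes, rep(0.5, 100), rep(1, 100))
  tab <- data.frame(regulon = sprintf("TF%02d", 1:10), size = 10, es = 0,
                    nes = 0, p_value = 0.5, fdr = 0.5, rank = 1:10,
                    stringsAsFactors = FALSE)
  cov <- coverage_curve(tab, regs, sig_genes)
  expect_equal(cov$fraction, (1:10) / 10)
  expect_equal(cov$covered, seq(10, 100, 10))
  # random overlapping instances against the union oracle
  set.seed(14)
  for (i in 1:20) {
    n_tf <- sample(3:8, 1)
    tfs <- sprintf("R%02d", seq_len(n_tf))
    edges <- do.call(rbind, lapply(tfs, function(f) {
      data.frame(tf = f, target = sample(sig_genes, sample(5:30, 1)),
                 stringsAsFactors = FALSE)
    }))
    regs <- regulon_set(edges$tf, edges$target,
                        rep(0, nrow(edges)), rep(1, nrow(edges)))
    tab <- data.frame(regulon = tfs, size = 1, es = 0, nes = 0,
                      p_value = 0.5, fdr = 0.5, rank = seq_len(n_tf),
                      stringsAsFactors = FALSE)
    cov <- coverage_curve(tab, regs, sig_genes)
    acc <- character(0)
    for (k in seq_len(n_tf)) {
      acc <- union(acc, intersect(edges$target[edges$tf == tfs[k]], sig_genes))
      expect_equal(cov$covered[k], length(acc))
    }
    expect_false(is.unsorted(cov$covered))
    expect_lte(max(cov$fraction), 1)
  }
})
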