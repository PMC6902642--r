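# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is stored on disk.

# minimal 3-gene x 4-sample dataset
tiny_dataset <- function() {
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                2, 2, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("TP53", "GLI2", "MYC"),
                              c("s1", "s2", "s3", "s4")))
  expression_dataset(m, c("case", "case", "control", "control"))
}

# write tiny expression + label TSVs; returns the two paths
write_tiny_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mpath <- file.path(dir, "expr.tsv")
  lpath <- file.path(dir, "labels.tsv")
  writeLines(c(
    "gene\ts1\ts2\ts3\ts4",
    "tp53\t1\t2\t3\t4",
    "GLI2\t4\t3\t2\t1",
    "MYC\t2\t2\t3\t3"
  ), mpath)
  writeLines(c("s1\tcase", "s2\tcase", "s3\tcontrol", "s4\tcontrol"), lpath)
  list(matrix = mpath, labels = lpath)
}

# i.i.d. noise dataset with named TFs
noise_dataset <- function(n_genes = 60, n = 150, n_tf = 6, seed = 1) {
  set.seed(seed)
  genes <- c(sprintf("TF%02d", seq_len(n_tf)),
             sprintf("G%03d", seq_len(n_genes - n_tf)))
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  list(dataset = expression_dataset(m, rep(c("case", "control"),
                                           c(n - 30, 30))),
       tfs = genes[seq_len(n_tf)])
}

# a random small signature (named z vector)
random_signature <- function(n, seed) {
  set.seed(seed)
  stats::setNames(rnorm(n), sprintf("G%03d", sample.int(999, n)))
}

# regulon fixture whose top-10 union covers exactly `covered` of a
# `sig_size`-gene signature (the coverage-arithmetic fixture)
coverage_fixture <- function(covered = 421, sig_size = 1395, n_regulons = 10,
                             seed = 5) {
  set.seed(seed)
  sig_genes <- sprintf("SIG%04d", seq_len(sig_size))
  chosen <- sample(sig_genes, covered)
  # distribute the covered genes over the regulons with overlap
  assignment <- split(chosen, rep(seq_len(n_regulons), length.out = covered))
  tfs <- sprintf("MR%02d", seq_len(n_regulons))
  tf <- character(0); target <- character(0)
  for (i in seq_len(n_regulons)) {
    tg <- assignment[[i]]
    # each regulon also carries some already-covered genes (overlap) and
    # some genes outside the signature
    overlap <- if (i > 1) sample(unlist(assignment[seq_len(i - 1)]), 5) else character(0)
    outside <- sprintf("OUT%02d_%02d", i, 1:7)
    tg <- unique(c(tg, overlap, outside))
    tf <- c(tf, rep(tfs[i], length(tg)))
    target <- c(target, tg)
  }
  regs <- regulon_set(tf, target, rep(0.5, length(tf)), rep(1, length(tf)))
  table <- data.frame(regulon = tfs, size = 30, es = -0.5, nes = -3,
                      p_value = 1e-3, fdr = 1e-2, rank = seq_len(n_regulons),
                      stringsAsFactors = FALSE)
  list(table = table, regulons = regs, signature_genes = sig_genes)
}

# planted-pathway dataset for PDS: case samples shifted along one gene axis
shifted_pathway_dataset <- function(n_case = 60, n_control = 30,
                                    n_genes = 10, shift = 3, seed = 42) {
  set.seed(seed)
  n <- n_case + n_control
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("PG%02d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  labels <- rep(c("case", "control"), c(n_case, n_control))
  m[1, labels == "case"] <- m[1, labels == "case"] + shift
  list(dataset = expression_dataset(m, labels),
       pathway = gene_set_collection(list(SHIFTED = rownames(m))))
}

# full synthetic pipeline at the default study configuration
run_default_pipeline <- function(seed, n_signature_perms = 500) {
  sim <- generate_dataset(default_study_config(seed = seed))
  fit <- suppressMessages(master_regulators(
    sim$dataset, sim$truth$tf_genes, sim$truth$pathways,
    n_signature_perms = n_signature_perms, seed = seed
  ))
  list(sim = sim, fit = fit)
}
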