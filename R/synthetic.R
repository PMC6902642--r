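# Synthetic two-condition expression data with planted regulatory ground
# truth: TF latent activities drive target expression through signed modes,
# a subset of TFs is activity-shifted in case samples, and pathway gene sets
# are assembled to overlap the planted targets. Every downstream stage of
# the pipeline can therefore be validated against known truth.

#' Simulation configuration
#'
#' Parameters of the synthetic-data generative model. The default values
#' (see [default_study_config()]) emulate, at desk scale, a tumour/normal
#' expression study with strongly unbalanced groups and a transcription
#' factor census much larger than the set of truly differential regulators.
#'
#' @param n_case,n_control Sample counts per class.
#' @param n_tf Number of transcription factors.
#' @param targets_per_tf Integer range `c(lo, hi)`: each TF receives a
#'   uniformly drawn number of targets in this range.
#' @param frac_repressed Probability that a TF-target edge is repressive
#'   (mode -1 rather than +1).
#' @param n_diff_tf Number of planted differential TFs (must be <= `n_tf`).
#' @param activity_shift Non-negative shift `delta` (standardised activity
#'   units) subtracted from planted TFs' latent activity in case samples;
#'   the downward direction mirrors regulators whose activity is lost in
#'   the case phenotype.
#' @param coupling Non-negative coefficient `beta` scaling TF activity in
#'   target expression.
#' @param noise_sd Positive observation noise standard deviation `sigma`.
#' @param n_background_genes Number of unregulated background genes.
#' @param n_pathways Number of pathway gene sets to assemble.
#' @param pathway_size Integer range `c(lo, hi)` of pathway sizes.
#' @param pathway_planted_fraction Fraction of each pathway drawn from the
#'   planted TFs' target pool (the rest from background genes).
#' @param regulon_overlap Probability that a target is additionally wired to
#'   a second, randomly chosen TF (0 = disjoint regulons, the default, which
#'   keeps ground-truth rankings unambiguous).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_case = 120L, n_control = 30L,
                       n_tf = 50L, targets_per_tf = c(10L, 30L),
                       frac_repressed = 0.3, n_diff_tf = 10L,
                       activity_shift = 2, coupling = 1, noise_sd = 1,
                       n_background_genes = 300L,
                       n_pathways = 25L, pathway_size = c(20L, 60L),
                       pathway_planted_fraction = 0.5,
                       regulon_overlap = 0, seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_tf = as.integer(n_tf),
    targets_per_tf = as.integer(targets_per_tf),
    frac_repressed = frac_repressed, n_diff_tf = as.integer(n_diff_tf),
    activity_shift = activity_shift, coupling = coupling,
    noise_sd = noise_sd,
    n_background_genes = as.integer(n_background_genes),
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    pathway_planted_fraction = pathway_planted_fraction,
    regulon_overlap = regulon_overlap,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_case >= 1L, cfg$n_control >= 1L, cfg$n_tf >= 1L,
    length(cfg$targets_per_tf) == 2L,
    cfg$targets_per_tf[1L] >= 1L,
    cfg$targets_per_tf[1L] <= cfg$targets_per_tf[2L],
    cfg$frac_repressed >= 0, cfg$frac_repressed <= 1,
    cfg$n_diff_tf >= 0L, cfg$n_diff_tf <= cfg$n_tf,
    cfg$coupling >= 0, cfg$noise_sd > 0,
    cfg$n_background_genes >= 1L, cfg$n_pathways >= 1L,
    length(cfg$pathway_size) == 2L, cfg$pathway_size[1L] >= 1L,
    cfg$pathway_size[1L] <= cfg$pathway_size[2L],
    cfg$pathway_planted_fraction >= 0, cfg$pathway_planted_fraction <= 1,
    cfg$regulon_overlap >= 0, cfg$regulon_overlap <= 1
  )
  if (cfg$activity_shift < 0) {
    stop("activity_shift must be >= 0 (the shift direction is fixed by construction)")
  }
  invisible(cfg)
}

#' Default desk-scale study configuration
#'
#' 120 case vs 30 control samples (the same 4:1 imbalance as a large
#' tumour/normal cohort), 50 TFs of which 10 are planted differential
#' regulators, and 25 pathway gene sets.
#'
#' @param seed Integer seed stored in the configuration.
#' @return A [sim_config].
#' @export
default_study_config <- function(seed = 1L) {
  sim_config(seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("sim_config: %d case / %d control; %d TFs (%d planted, delta=%g), ",
           "targets/TF %d-%d, beta=%g, sigma=%g; %d background genes; ",
           "%d pathways (%d-%d genes, planted fraction %g); seed %d\n"),
    x$n_case, x$n_control, x$n_tf, x$n_diff_tf, x$activity_shift,
    x$targets_per_tf[1L], x$targets_per_tf[2L], x$coupling, x$noise_sd,
    x$n_background_genes, x$n_pathways, x$pathway_size[1L],
    x$pathway_size[2L], x$pathway_planted_fraction, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic two-condition dataset with ground truth
#'
#' Generative model (deterministic given `config$seed`; draw order is fixed
#' as listed):
#' 1. each TF `f` is assigned a target count uniform in `targets_per_tf`,
#'    its targets drawn disjointly from the target gene pool (plus optional
#'    second-TF wiring with probability `regulon_overlap`);
#' 2. each edge receives a mode sign, -1 with probability `frac_repressed`;
#' 3. the first `n_diff_tf` TFs are the planted differential regulators;
#' 4. latent activities `a[f, s] ~ N(0, 1)`, with `activity_shift` subtracted
#'    in case samples for planted TFs;
#' 5. TF expression `x[f, s] = a[f, s] + N(0, noise_sd)`;
#' 6. target expression `x[t, s] = sum_f coupling * mode[f, t] * a[f, s] +
#'    N(0, noise_sd)`;
#' 7. background genes are i.i.d. `N(0, 1)`;
#' 8. each pathway draws `round(size * pathway_planted_fraction)` members
#'    from the planted TFs' target pool and the rest from background genes.
#'
#' @param config A [sim_config].
#' @return List with elements `dataset` (an [expression_dataset]), and
#'   `truth`: a list with `regulons` (true edges as a [regulon_set], weight
#'   1, mode the planted sign), `diff_tfs` (planted differential TFs),
#'   `tf_genes` (all TF symbols) and `pathways` (a [gene_set_collection]).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_case + config$n_control
    labels <- rep(c("case", "control"), c(config$n_case, config$n_control))
    tf_names <- sprintf("TF%03d", seq_len(config$n_tf))

    # 1. regulon wiring
    n_targets <- sample_int_range(config$targets_per_tf[1L],
                                  config$targets_per_tf[2L], config$n_tf)
    total_targets <- sum(n_targets)
    target_names <- sprintf("TG%05d", seq_len(total_targets))
    edge_tf <- rep(tf_names, n_targets)
    edge_target <- target_names
    if (config$regulon_overlap > 0) {
      extra <- which(stats::runif(total_targets) < config$regulon_overlap)
      for (t in extra) {
        other <- sample(setdiff(tf_names, edge_tf[t]), 1L)
        edge_tf <- c(edge_tf, other)
        edge_target <- c(edge_target, target_names[t])
      }
    }
    # 2. edge mode signs
    edge_mode <- ifelse(stats::runif(length(edge_tf)) < config$frac_repressed,
                        -1, 1)
    # 3. planted regulators
    diff_tfs <- tf_names[seq_len(config$n_diff_tf)]

    # 4. latent activities with case-side shift for planted TFs
    activity <- matrix(stats::rnorm(config$n_tf * n), config$n_tf, n,
                       dimnames = list(tf_names, NULL))
    if (config$n_diff_tf > 0L && config$activity_shift > 0) {
      activity[diff_tfs, labels == "case"] <-
        activity[diff_tfs, labels == "case"] - config$activity_shift
    }

    # 5. TF expression
    x_tf <- activity + matrix(stats::rnorm(config$n_tf * n, sd = config$noise_sd),
                              config$n_tf, n)
    # 6. target expression through the wiring matrix
    wiring <- matrix(0, total_targets, config$n_tf,
                     dimnames = list(target_names, tf_names))
    wiring[cbind(match(edge_target, target_names), match(edge_tf, tf_names))] <-
      config$coupling * edge_mode
    x_tg <- wiring %*% activity +
      matrix(stats::rnorm(total_targets * n, sd = config$noise_sd),
             total_targets, n)
    # 7. background genes
    bg_names <- sprintf("BG%04d", seq_len(config$n_background_genes))
    x_bg <- matrix(stats::rnorm(config$n_background_genes * n),
                   config$n_background_genes, n,
                   dimnames = list(bg_names, NULL))

    values <- rbind(x_tf, x_tg, x_bg)
    colnames(values) <- sprintf("S%04d", seq_len(n))

    # 8. pathway gene sets
    planted_pool <- unique(edge_target[edge_tf %in% diff_tfs])
    sets <- vector("list", config$n_pathways)
    names(sets) <- sprintf("PW%02d", seq_len(config$n_pathways))
    for (p in seq_len(config$n_pathways)) {
      size <- sample_int_range(config$pathway_size[1L],
                               config$pathway_size[2L], 1L)
      n_planted <- round(size * config$pathway_planted_fraction)
      n_planted <- min(n_planted, length(planted_pool))
      n_bg <- size - n_planted
      if (n_bg > length(bg_names)) {
        stop(sprintf(
          "pathway %d requests %d background genes but only %d are available",
          p, n_bg, length(bg_names)
        ))
      }
      sets[[p]] <- c(
        if (n_planted > 0L) sample(planted_pool, n_planted),
        if (n_bg > 0L) sample(bg_names, n_bg)
      )
    }

    dataset <- expression_dataset(values, labels)
    truth <- list(
      regulons = regulon_set(edge_tf, edge_target, edge_mode,
                             rep(1, length(edge_tf))),
      diff_tfs = diff_tfs,
      tf_genes = tf_names,
      pathways = gene_set_collection(sets)
    )
    list(dataset = dataset, truth = truth)
  })
}
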