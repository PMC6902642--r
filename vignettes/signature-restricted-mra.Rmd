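---
title: "Signature-restricted master-regulator analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-restricted master-regulator analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmra)
```

## The problem

Two-condition expression studies (tumour vs adjacent normal tissue being
the motivating case) often ask not just *which genes* change, but *which
transcription factors (TFs) drive* the change. A transcriptional master
regulator is a TF whose regulon — the TF together with its inferred
transcriptional targets — is maximally enriched with the most
differentially expressed genes between the two phenotypes. `sigmra`
implements a signature-*restricted* variant of this analysis: the
differential-expression signature is confined to a chosen gene universe
(canonically, the genes of signal-transduction pathways), so the ranking
answers "which TFs most strongly control the deregulated part of these
pathways", while the regulons themselves are inferred from the whole
transcriptome.

The pipeline has five statistical stages, each exposed as a documented
function and orchestrated by `master_regulators()`:

1. **Network inference** (`build_mi_network()`, `apply_dpi()`): pairwise
   mutual information between every TF and every gene, thresholded by a
   pooled permutation null at p < 0.005, then pruned by the data
   processing inequality (DPI) at tolerance 0.2.
2. **Regulons** (`build_regulons()`): direction is imposed TF → target;
   the mode of regulation is the Spearman correlation of the two profiles
   (positive = activation, negative = repression); the weight is the edge
   MI max-normalised within each regulon.
3. **Molecular signature** (`compute_signature()`): per-gene Welch t
   statistics (case − control) over the restriction universe, mapped to
   Z-scores.
4. **Null model** (`build_null_model()`): the same signature recomputed
   under case/control label permutations.
5. **Master-regulator ranking** (`run_mra()`): a weighted
   Kolmogorov–Smirnov (GSEA) enrichment score per regulon, normalised
   against its own permutation-null distribution into an NES, with a
   Gaussian-tail p-value and Benjamini–Hochberg FDR.

Two companion analyses operate on the same data structures: per-sample
principal-curve pathway deregulation scores (`compute_pds()`) and
hypergeometric over-representation analysis (`run_ora()`).

## Models and estimators

### Mutual information

`mutual_information()` is the plug-in estimator on an equal-frequency
(rank-quantile) grid: both profiles are ranked (average ranks on ties),
cut into `n_bins` cells of near-equal occupancy, and
\(\hat I = \sum_{ab} \hat p_{ab} \log (\hat p_{ab} / \hat p_a \hat p_b)\)
in nats. The default bin count is `max(2, floor(sqrt(n/5)))` so each of
the \(B^2\) joint cells keeps several observations at the study's sample
sizes. Rank-based binning makes the estimate invariant under strictly
monotone transforms of either profile, deterministic, and exactly
checkable: a one-to-one profile pair attains \(\log B\); a full factorial
grid of quantile cells attains exactly 0. Constant profiles are an error
(a degenerate gene should be filtered upstream, not silently scored 0).

Edge significance uses a *pooled* null: MI values of randomly chosen gene
pairs after permuting the sample order of one member. Per-pair permutation
at the 0.005 level is infeasible at transcriptome scale; pooling is the
standard practice for this family of estimators. The empirical p-value
uses the add-one correction \((1 + \#\{null \ge mi\})/(1 + \#null)\) so
reported p-values are never 0.

### DPI pruning

For every triangle of retained edges, edge \((i,j)\) is marked when
\(mi_{ij} < (1-\varepsilon)\,mi_{ik}\) **and**
\(mi_{ij} < (1-\varepsilon)\,mi_{jk}\) for some common neighbour \(k\)
(tolerance \(\varepsilon = 0.2\) by default): the clearly weakest edge of
a triangle is the most likely indirect interaction. All marks are
computed on the input network and removed simultaneously, so the result
does not depend on edge processing order. TF–TF edges are allowed — they
are required for triangles spanning two TFs and a shared target and they
put each TF into the other's regulon.

### Signature Z-scores

The per-gene test is Welch's (unequal variances): with strongly
unbalanced designs (the motivating study had a 780 : 101 imbalance) the
pooled-variance t statistic is the wrong default. Z-normalisation is the
quantile transform \(z = \mathrm{sign}(t)\,\Phi^{-1}(1 - p/2)\), which is
*exactly* standard normal under the null regardless of the per-gene
degrees of freedom — this is what makes Z-scores comparable across genes.
\(|z|\) is clamped at 8 to avoid infinities when p underflows. Genes with
zero variance in both groups and equal means score \(t = 0, p = 1\);
unequal means with zero variance is an error rather than an infinite
statistic.

The restriction is the union of all sets in the supplied collection: the
motivating study pools 25 curated signal-transduction pathways into one
signature universe. The permutation count defaults to
`n_signature_perms = 1000`.

### Regulon enrichment, NES and p

`gsea_es()` is the classic two-set weighted running-sum statistic: walk
the signature ranked by z descending (ties broken by gene symbol so
rankings are reproducible), step up at member genes proportionally to
\(|z|\) (optionally scaled by the regulon's MI-derived weights — on by
default, switchable with `use_weights`), step down by \(1/(n-m)\)
elsewhere; the ES is the signed deviation of maximum magnitude, with the
earlier position winning a (numerical) magnitude tie.

`regulon_es()` folds in the mode of regulation: positive-mode targets are
scored on the z-descending ranking, negative-mode targets on the reversed
ranking, and the two scores are combined as a size-weighted average. The
sign convention is: positive combined ES ⇔ the targets moved the way an
*active* TF predicts; negative ⇔ the TF looks *inactivated* in cases. A
regulator whose activity is lost in tumours therefore shows a negative
ES/NES.

Each regulon's observed ES is standardised against the ES of the *same*
regulon recomputed on every null-signature column:
\(NES = (ES - \mu_{null})/\sigma_{null}\), and
\(p = 2(1 - \Phi(|NES|))\). The Gaussian-tail form is what links the
published NES and p columns of this analysis family (e.g. NES −4.12 ↔
p ≈ 3.8 × 10⁻⁵), and we keep it for that reason. Regulons need at least
`min_targets = 20` signature-restricted targets to be tested; ranking is
by ascending p, ties by descending |NES|, then TF symbol.

**Known conservatism.** The signed maximum-deviation ES has a *bimodal*
null distribution — a running-sum extreme is bounded away from zero, so
the null piles up around \(\pm\mathbb E|ES|\) with little mass near 0
(empirically, kurtosis ≈ 1.5). Its standard deviation therefore
overstates the spread of the bulk, \(|NES|\) rarely exceeds ≈ 1.7 under a
true null, and the Gaussian-tail p is conservative: on null data
(`activity_shift = 0`) essentially no regulon reaches p < 0.05. This is
the safe direction (no type-I inflation) and does not affect the NES
*ranking*, which is what the analysis reports; but absolute p-values for
strongly co-expressed regulons should be read as upper bounds on
evidence, not calibrated tail probabilities. An empirical rank-based p
would be calibrated, at the price of breaking the NES↔p arithmetic above.

### Pathway deregulation scores

`compute_pds()` scores each sample's position along the main nonlinear
trend of a pathway's expression. Per pathway: genes are standardised
against the *control* samples (mean 0, sd 1 in controls; zero-variance
genes dropped), PCA retains the fewest components reaching
`var_fraction = 0.8` of the variance (capped at `max_components = 10`), a
principal curve is fitted to all samples, every sample is projected to
its arc length \(s_i\), the curve is oriented so the control median
precedes the case median, and
\(PDS_i = (s_i - \mathrm{median}(s_{control}))/L\) with \(L\) the total
curve length. Controls thus have median PDS exactly 0, and scores are
signed and length-normalised so they are comparable across pathways. A
clipped-to-[0, 1] variant for heatmap display is a trivial
post-transformation (`pmin(pmax(pds, 0), 1)`).

The curve fitter is the Hastie–Stuetzle alternation: initialise arc
lengths on the first principal component; smooth each coordinate against
arc length with a cubic smoothing spline; re-project all points onto the
resulting polyline (exhaustive segment search — sample counts here are
desk-scale); stop when the total squared projection distance improves by
less than `tol` relatively, or fails to improve (the previous curve is
kept, so the recorded distance trace is non-increasing by construction).

A genuinely open numerical choice: the spline's flexibility. A
GCV-chosen penalty looks natural but interacts badly with the
self-consistency loop — re-projection feeds the smoother its own noise,
GCV then undersmooths, and the curve starts chasing individual points.
That *lowers* the projection distance while corrupting the arc-length
ordering (on a 3σ-shifted test pathway, case/control AUC fell to
0.73–0.94 across seeds). We therefore fix a modest effective
`df = 5` for the coordinate smoothers — the classic principal-curve
regularisation — and keep GCV available via `df = NULL`. Separation also
degrades as uninformative pathway dimensions are added (the planted axis
is diluted across the retained components), which is worth remembering
when interpreting PDS for very large pathways.

### Over-representation analysis

`run_ora()` is the one-sided hypergeometric test
\(P(X \ge k)\) for overlap \(k\) between a query list and each set,
within a user-supplied reference universe (canonically the expression
matrix's gene list), with Benjamini–Hochberg FDR across sets and
enrichment ratio \((k/s)/(M/N)\). Tail probabilities are computed in log
space. Web-service enrichment tools embed their own (version-dependent)
reference universes, so numeric agreement with published FDR/ratio tables
is not expected; the arithmetic itself is exactly reproducible and
oracle-tested.

## The synthetic-data generator

`generate_dataset()` plants a fully known regulatory structure so every
stage can be validated against ground truth. Each TF has latent activity
\(a_{f,s} \sim N(0,1)\); planted differential TFs have \(\delta\)
subtracted in case samples (activity *loss* in cases — matching the
predominance of repressed master regulators in the motivating study, and
the reason planted TFs come out with negative NES). TF expression is
activity plus noise; each target reads
\(x_{t,s} = \sum_f \beta\, g_{ft}\, a_{f,s} + \varepsilon\) with mode
sign \(g_{ft} \in \{+1,-1\}\) (repressive with probability
`frac_repressed`); background genes are i.i.d. \(N(0,1)\); pathway sets
mix planted-TF targets with background genes. The shift is applied to
*activity*, not to target expression directly, so TF and targets co-move
coherently — which is exactly the assumption regulon enrichment makes.

Defaults (`default_study_config()`): 120 case / 30 control (the 4 : 1
imbalance of a large tumour/normal cohort at desk scale), 50 TFs of which
10 planted, 10–30 targets per TF, 30% repressive edges, δ = 2, β = 1,
σ = 1, 300 background genes, 25 pathways of 20–60 genes with half their
members from the planted target pool. Regulons are disjoint by default
(unambiguous ground-truth ranking); `regulon_overlap` wires a fraction of
targets to a second TF. Everything is driven by one seed with a fixed
draw order, so datasets are bit-reproducible.

What the generator deliberately does **not** emulate: count-level
sampling noise (every downstream statistic is rank- or mean-based, so a
negative-binomial layer adds nothing testable — a `log2(x+1)` import flag
handles real count matrices), batch effects, correlated background
structure, and TF–TF regulatory cascades. Passing tests therefore show
the *estimators* recover planted structure under Gaussian co-expression;
they do not certify behaviour under real RNA-seq artefacts, which are
assumed to be handled upstream.

## Problem sizes and determinism

The shipped tests exercise: the full pipeline at the default
configuration (~1,300 genes × 150 samples; network inference, 10,000-pair
MI null, 500–1,000 signature permutations) in a few seconds per seed;
estimator-vs-oracle comparisons on hundreds of small random instances at
1e−12 tolerance; and calibration experiments of a few hundred pooled
regulons / 20,000 ORA set-tests. These sizes were chosen as the smallest
at which the recovery and calibration properties are stable across seeds.
All randomness flows through explicit seeds; library code saves and
restores the caller's RNG state.

## Known limitations

- Absolute regulon p-values are conservative for strongly co-expressed
  regulons (see above); rankings and NES magnitudes are the primary
  output.
- The MI estimator's fixed grid trades some efficiency for exactness and
  monotone invariance; kernel or adaptive-partition estimators are out of
  scope.
- Mode is the raw Spearman correlation, not a three-state
  activation/repression/undetermined decomposition; an exactly-zero mode
  is treated as activation (relevant only for synthetic ties).
- PDS values are comparable within a pathway across samples; comparing
  magnitudes *across* pathways inherits the usual caveats of
  length-normalised arc positions.
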