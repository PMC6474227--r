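---
title: "Cross-kingdom co-expression analysis with dualcoexp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom co-expression analysis with dualcoexp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`dualcoexp` analyses dual RNA-seq experiments in which a host plant and a
fungal root symbiont are sequenced together across a crossed genotype ×
genotype design: several host cultivars, each inoculated with different
fungal isolates or left as a mock-inoculated control. The question the
pipeline addresses is whether the transcriptomes of the two organisms are
coordinated: do groups of host genes and groups of fungal genes co-vary
across biological samples, which gene groups track measured growth traits,
and which individual genes sit at the interface?

The pipeline has five stages.

1. **Normalisation and filtering.** Counts become
   `log2((count + prior) / (library + 2 prior) * 1e6)` (log2-CPM with a
   prior of 0.5 keeping zeros finite). Genes below 1 CPM in fewer than 3
   samples are dropped. Mock samples are removed from the symbiont matrix
   entirely — the fungus is not present in those roots, and the trace
   counts that do appear are cross-contamination, not expression.

2. **Response classification.** For every gene, a two-factor linear model
   of log2-CPM on cultivar, fungal treatment and their interaction is
   fitted, each term is F-tested, and p-values are BH-adjusted per term
   across genes (level 0.05). Classes are assigned with the priority:
   significant interaction → *interaction* (the genotype × genotype
   class); else significant treatment → *mycorrhiza-conserved* or
   *isolate-conserved*, decided by whichever single-df contrast (mock vs
   pooled AMF, or isolate A vs B) carries the smaller p-value; else
   significant cultivar → *cultivar-only*; else *none*. Because the
   factorial design is balanced, the sequential sums of squares used in
   the shared-QR implementation coincide with the usual partial tests.

3. **Module construction.** Within each organism, genes are clustered by
   weighted co-expression: unsigned adjacency `|cor|^12`, topological
   overlap, average-linkage clustering of `1 − TOM`, a dynamic branch cut
   (below), eigengene computation, and merging of modules whose eigengenes
   are closer than 0.1 in correlation dissimilarity. Host modules are
   built only from the pool of genes responsive to the fungal treatment
   (conserved or interaction classes); symbiont modules use all retained
   genes, since a fungus growing only in planta offers no uninfected
   baseline to select against.

4. **Cross-kingdom network.** Every host-module eigengene is correlated
   with every symbiont-module eigengene over the inoculated samples;
   pairs with two-sided p < 0.001 (t transform of Pearson r) are edges of
   a bipartite module network. Within each correlated pair, genes in the
   top 10% of |gene significance| (correlation with the partner
   eigengene) that also have kME > 0.8 in their own module are *key
   genes*. A random relabelling control reassigns genes to modules
   uniformly while preserving module sizes, recomputes eigengenes, and
   counts edges; the observed edge count is compared against this null.

5. **Trait association.** Module eigengenes of both organisms are
   correlated with quantitative traits (e.g., root colonization, biomass)
   with the same t-based p-values, and the key-gene rule is reapplied
   with the trait in the role of the partner eigengene.

# Parameters that matter

| parameter | default | role |
|---|---|---|
| `power` | 12 | soft threshold; suppresses weak correlations geometrically |
| `min_size` | 50 genes | smallest reportable module |
| `merge_cut` | 0.1 | eigengene dissimilarity below which modules merge |
| `edge_alpha` | 0.001 | raw-p threshold for cross-kingdom edges |
| `quantile`, `kme_min` | 0.90, 0.8 | key-gene selection |
| `de_alpha` | 0.05 | per-term BH-FDR for response classes |
| `fc_host`, `fc_symbiont` | 2, 4 | per-cultivar \|log2FC\| gene-set cuts |
| `prior` | 0.5 | log2-CPM prior count |
| `gap_frac` | 0.25 | stringency of the dynamic branch cut |

# The dynamic branch cut

Soft thresholding at power 12 compresses all between-module merge heights
into a thin shelf just below the maximum dissimilarity, while
within-module merges spread over a wide height range. Absolute
height-gap rules are degenerate on such trees, so `dynamic_cut()` scores
every candidate branch (each internal node with at least `min_size`
leaves) by

> q = median within-branch similarity / median off-diagonal similarity,

where similarity is the TOM itself. Medians on both sides make the score
immune to the heavy upper tail that `|r|^12` gives chance correlations —
a property that matters at small sample sizes, where a handful of inflated
pairs would dominate a mean. A branch qualifies when `q > 2 / gap_frac`
(8 at the default). Qualifying branches are resolved bottom-up: an
enclosing branch replaces the qualifying branches nested inside it when
its own score retains at least `1 − gap_frac` of the best nested score,
so modules keep their peripheral members while a diluted super-branch
cannot swallow a tight module. On i.i.d. noise no branch clears the
threshold and all genes stay unassigned; on two ideal blocks the cut is
exact.

# Eigengenes and numerical conventions

The eigengene is the first principal component of the gene-standardized
module submatrix, computed from the sample × sample cross-product (always
a 45 × 45 eigenproblem regardless of module size), scaled to unit
variance over samples and sign-anchored so the mean correlation with the
module's member genes is positive; PCA signs are otherwise arbitrary.
Variance explained is the leading eigenvalue share. A one-gene module's
eigengene is its standardized profile. Correlation p-values use
`t = r sqrt((n−2)/(1−r²))` with n − 2 df; |r| = 1 maps to p = 0. The
key-gene quantile uses linear interpolation and ties at the boundary are
included (≥). Zero-variance genes are dropped before adjacency with a
warning; zero library sizes are an error naming the sample. Merging
iterates until no eigengene pair is closer than the cut, so it is
idempotent and can only reduce the module count.

# The synthetic-data generator

Real dual RNA-seq of this design is not publicly deposited, so validation
rests on a generative model that reproduces the statistical structure the
analysis assumes:

* a full-factorial design (5 cultivars × {2 isolates, mock} × 3
  replicates = 45 samples, blocks assigned round-robin after a seeded
  shuffle);
* one latent factor per planted module, carrying a design-driven mean
  (cultivar effects, mock-vs-AMF shifts, isolate contrasts, or
  non-additive cell effects) plus unit sample noise, standardized per
  factor. Each deterministic treatment-contrast profile is used by at
  most one module per organism, and only in the host: two modules sharing
  a fixed ±pattern would be correlated by construction, planting
  cross-kingdom links beyond the ones configured;
* cross-links: a symbiont factor is a signed mixture
  `s·γ·z_host + sqrt(1−γ²)·z_private`, with both components standardized
  and orthogonalized **on the inoculated samples** — the only samples
  where symbiont expression exists and hence the subspace in which link
  strength γ is defined. The realized factor correlation equals γ
  exactly;
* genes: `z_g = sqrt(w_g)·factor + sqrt(1−w_g)·noise` on the log scale
  with amplitude σ = 1.2; counts are negative-binomial (dispersion 0.05,
  modelling residual technical overdispersion — biological covariance
  already lives in the factor layer) around library-scaled means, with
  libraries drawn uniformly from 0.5–2 million reads;
* the per-gene latent weight `w_g` is inflated by the predicted
  count-noise attenuation `a_g = σ²/(σ² + dispersion + 1/μ_g)`, so the
  realized within-module log2-CPM correlation matches the configured
  target (0.6) rather than a value eroded by shot noise;
* a constant background mass (80% of each library) represents the
  unsimulated remainder of the transcriptome in the normalisation
  denominator. Sequencing is compositional; without this term a module's
  coordinated swing would shift the per-sample total and CPM
  normalisation would partially cancel the module's own signal — an
  artifact of simulating only a small gene panel, not a feature of real
  libraries;
* mock symbiont columns are sparse Poisson contamination (mean 0.1
  counts/gene), not structural zeros;
* background genes receive planted response classes at paper-scale
  fractions (35% cultivar-only, 5% interaction, 2% conserved) with fresh
  random effect draws per gene; the rest are null;
* traits are loading-weighted sums of module factors plus Gaussian noise;
  a trait named `colonization` is forced to 0 in mock samples.

Default cross-links attach to host modules with genotype-driven variance
among inoculated samples (interaction and isolate classes). A link
routed through a mock-vs-AMF module would be unobservable in principle —
that module's factor is nearly constant across the inoculated subset — so
such defaults would test nothing about the method.

# Validation datasets and problem sizes

Validation uses three deliberately different problem sizes:

* **Recovery benchmark** (module recovery and cross-network): 5 planted
  modules of 60–100 genes per organism, within-module correlation 0.6,
  1500 genes per organism, 45 samples, background classes set to 0 —
  planted-truth comparisons (adjusted Rand index, planted vs spurious
  edges) are only defined when background genes are null, because
  same-class background genes co-express for real. Ten independent
  seeds; median ARI and link recovery are reported.
* **Permutation control**: the same design at 6000 genes per organism, so
  module genes are a small minority of the transcriptome, as in real
  data. This matters: a randomly relabelled 80-gene module drawn from a
  module-dominated matrix still contains enough co-regulated genes for
  its first principal component to align with the planted factors
  (the spiked-eigenvalue detection threshold at 30 samples sits near 4
  genes per factor), which would make even a random network look real.
  At realistic dilution the relabelled eigengenes are noise summaries and
  the control reproduces the expected "no network" behaviour.
* **Default pipeline demonstration** (`run_all()`): 1200 host and 1000
  symbiont genes with paper-scale background fractions. At this desk
  scale the host DE pool concentrates module genes, so the in-pipeline
  permutation control is anticonservative and per-gene classification
  power at 3 replicates limits the pool; both effects are scale
  artifacts discussed above, not method properties.

# What passing tests do and do not show

The generator plants exactly the structure the method looks for:
log-linear factors, balanced designs, NB counts, Gaussian-ish factor
noise. Passing recovery at ARI ≥ 0.9 therefore shows the implementation
is correct and well-calibrated under its own model assumptions. It does
not show robustness to batch effects, outlier samples, unbalanced
designs, count-model misspecification, or the read mis-assignment that
in-silico separation of mixed reads can produce — none of which the
generator emulates.

# Known limitations

* The per-gene response classifier is an OLS ANOVA on log2-CPM, not a
  count-model test with dispersion shrinkage; at 3 replicates its
  gene-level power is modest, which shrinks the host module pool.
* The dynamic cut is a background-relative branch selector, not the
  dynamic hybrid algorithm with its PAM stage; unassigned rates are
  accordingly higher, which is intentional (precision over recall).
* Cross-network correlations use the inoculated samples only; with 30
  samples the p < 0.001 threshold corresponds to |r| > 0.57.
* The permutation control is meaningful only when modules are a minority
  of the analysed gene set (see above).
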