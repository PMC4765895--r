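---
title: "Methods: combined connectivity and metabolic screening for drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined connectivity and metabolic screening for drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Expression-based drug repositioning asks: which existing drugs induce a
transcriptional response that *reverses* a disease's expression
signature? Screens of this kind have a well-known failure mode — the
treated cell lines are usually not derived from the diseased tissue, so
a significant negative correlation between a drug profile and a disease
signature need not be biologically meaningful. `metconnect` implements a
combined screen that requires a second, mechanistically independent line
of evidence: the drug must also touch the disease's metabolic core,
either by targeting a predicted key enzyme-coding gene or through a
compound that is a substrate or product of a key enzyme's reaction.

The pipeline has four stages, each usable on its own:

1. differential expression over several case/control datasets
   (`normalize_expression()`, `differential_expression()`);
2. connectivity screening of the resulting signatures against
   drug-induced gene rank profiles (`screen_instances()`,
   `puds_per_dataset()`, `puds_overall()`);
3. key-enzyme prediction from a co-expression network overlaid with a
   metabolic enzyme-link network (`met_express()`,
   `kpc_intersection()`);
4. candidate selection and supporting statistics
   (`select_candidates()`, `overlap_randomization()`,
   `fisher_enrichment()`).

# Differential expression

Datasets are gene × sample matrices with `normal`/`cancer` labels.
Normalization applies `log2(v + 1)` only when the overall median
expression exceeds 16 — a scale heuristic separating linear-scale
intensities from already-logged values; genes missing in more than 20 %
of samples are dropped, and remaining gaps are imputed with the gene's
per-class mean so that downstream correlation and AUC computations see a
complete matrix.

Significance uses a moderated two-sample t-statistic: each gene's pooled
variance is shrunk toward the across-gene mean variance with prior
weight `d0` (default 4 prior degrees of freedom),

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},
  \qquad t_g = \frac{\bar x_{g,\mathrm{cancer}} -
  \bar x_{g,\mathrm{normal}}}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with p-values from a t distribution on `d0 + n1 + n2 − 2` degrees of
freedom. At `d0 = 0` this is exactly the ordinary equal-variance t-test
(a tested limit case); at small sample sizes the shrinkage stabilizes
the denominator the same way empirical-Bayes moderation does in the
established microarray tools. The signature keeps genes with BH-adjusted
p below 0.01 **and** fold change above 2 (`|log2FC| > 1`), split into
up- and down-regulated sets. All datasets are analyzed unpaired: the
matched-pair structure some cohorts have is deliberately ignored because
the screen only consumes group-level signatures.

# Connectivity scoring

A rank profile is a permutation of the gene universe; **rank 1 is the
most drug-up-regulated gene**. Public rank data exist in both
orientations, so `invert_rank_profiles()` flips a compendium recorded
the other way around (`r → n + 1 − r`).

For a gene set with sorted positions $V_{(1)} < \dots < V_{(t)}$ among
$n$ genes,

$$a = \max_j \left(\frac{j}{t} - \frac{V_{(j)}}{n}\right), \quad
  b = \max_j \left(\frac{V_{(j)}}{n} - \frac{j-1}{t}\right), \quad
  \mathrm{KS} = \begin{cases} a & a > b\\ -b & \text{else,}\end{cases}$$

so positive values mean concentration toward the top. The connectivity
score is `KS_up − KS_down` when the two statistics disagree in sign and
0 otherwise; the same-sign-zero rule discards profiles that move both
signature halves the same way, which is noise for the reversal question.

**Null model.** The named test family fixes the statistic but not the
null, so the p-value is a one-sided permutation test: random disjoint
gene sets of sizes `|up|`, `|down|` are drawn without replacement from
the profile's universe, and
`p = (1 + #[null ≤ observed]) / (1 + n_perm)` (the `+1` keeps p
positive). An important simplification makes screens fast: under this
null, a random gene set has uniformly random positions in *any* fixed
permutation, so the null distribution depends only on
`(|up|, |down|, n)`. `screen_instances()` therefore draws one null
sample per screen and shares it across all instances — distributionally
identical to per-profile draws, and it makes p monotone in the score by
construction. Two numerical caveats follow from the construction and are
covered by tests rather than hidden: the same-sign rule puts a
probability atom at score 0, so one-sided p-values are super-uniform
(conservative) globally and uniform only conditional on a negative
score; and the `j/t` vs `(j−1)/t` asymmetry means rank reversal negates
the statistic only up to a `1/t + 1/n` discretization term.

Signature genes absent from the profile universe are dropped with a
warning by default (platform differences are expected); `on_missing =
"error"` makes this strict. BH adjustment runs across all instances of a
screen, and `fdr < 0.1` with a negative score flags an instance. A drug
is a PUD for one dataset when **strictly more than half** of its
instances are flagged, and overall when that holds in at least two
datasets (both cutoffs taken verbatim from the screening design this
package operationalizes). `overlap_randomization()` checks that the
per-dataset drug sets agree more than size-matched random draws from the
screened universe would.

# Key-enzyme prediction

The co-expression network joins genes with `|Pearson r| ≥ 0.7` across
all samples (default; the classical "strong correlation" cutoff —
at 60 samples, independent genes cross it with probability well below
10⁻³, a tested property). Constant genes cannot be correlated and are
excluded from edges with a warning; an exact-collinearity tolerance of
10⁻¹² keeps a threshold of 1.0 meaningful in floating point. Modules
come from greedy agglomerative modularity maximization
(`igraph::cluster_fast_greedy`), which is deterministic, preserves
connected components, and leaves isolated genes as singleton modules.
Any modularity-based partitioner would serve; the algorithm is not the
scientific content here.

Module cancer specificity is the ROC AUC of per-sample module-median
expression, computed by midranks (equivalent to pair counting with ties
worth ½) and oriented as `max(AUC, 1 − AUC)`: a consistently
down-regulated module is as cancer-specific as an up-regulated one, and
the orientation makes 0.5 mean "uninformative" on a `[0.5, 1]` scale.

The metabolic side links two enzyme-coding genes whenever a product of a
reaction catalyzed by one is a substrate of a reaction catalyzed by the
other. A configurable currency-compound exclusion list (empty by
default) prevents ubiquitous carriers like ATP from connecting
everything; it is empty by default because the synthetic reactions
contain no currency metabolites, and real reaction tables should set it
explicitly.

Each enzyme gene `g` with `d_in` of `d_tot` links inside its own module
(module share `K` of `N` scored enzymes) scores

$$\mathrm{score}(g) = \mathrm{AUC}_{m(g)} \times
  \left(-\log_{10} P\!\left[X \ge d_{in}\right]\right),
  \qquad X \sim \mathrm{Hypergeom}(N, K, d_{tot}).$$

This product form is this package's concrete instantiation of "module
cancer-specificity × within-module link enrichment"; the original
formulation lives in prior literature and is only sketched in the work
this design follows, so the combination rule here is an explicit,
documented approximation. `d_tot` counts links to *scored* enzymes so
the hypergeometric urn is internally consistent. Genes scoring
**strictly above the median** are key enzymes (ties at the median are
excluded; with all scores equal the set is empty), and the cross-dataset
key set is the plain intersection.

# Candidate selection

For every PUD, the target route (`targets ∩ key enzymes ≠ ∅`) takes
priority over the compound route (a drug compound appearing among the
substrates or products of a key enzyme's reactions); the two rationale
categories are mutually exclusive, mirroring how such predictions are
reported. Selection is order-invariant and idempotent, and PUDs missing
from the annotation table are dropped with a warning. Fisher gene-set
enrichment (one-sided toward over-representation, BH-adjusted at 0.1) is
provided for annotating the resulting enzyme sets.

# The synthetic-data generator

The generator exists so that every stage has a testable ground truth
without any external download. It emulates, in order:

* **Expression** — a latent-factor model on the log2 scale: baseline
  gene means `~ N(8, 1.5²)`, per-module per-sample factors `~ N(0, 1)`
  (mean `delta = 2` in cancer samples for cancer-specific modules),
  loadings `~ U(0.5, 1.5)`, residual noise `sigma = 0.3`, planted DE
  genes outside the modules shifted by `±Delta = 3` in cancer samples,
  and entries removed completely at random (`missing_rate = 0.01`).
  Defaults: 2,000 genes, 3 datasets of 30+30 samples, 8 modules of
  30–80 genes. `sigma = 0.3` is chosen once so that within-module
  correlations of even low-loading genes sit clearly above the 0.7 edge
  threshold — i.e. the planted modules are modules under the pipeline's
  own default — while per-gene signal-to-noise stays in the range
  typical of array data.
* **Rank profiles** — per instance, gene scores `ε ~ N(0,1)`; reverser
  drugs add `−beta·s_g` (`s_g = ±1` on the signature) before ranking by
  descending score, giving a tunable reversal strength (`beta = 2`, 200
  drugs × 5 cell-line instances, 10 reversers). Acting on scores rather
  than swapping ranks keeps the effect size continuous.
* **Metabolic model** — planted key enzymes inside cancer-specific
  modules receive ~6 product→substrate chains to co-module enzymes;
  background enzymes chain across modules, so within-module degree is
  the planted discriminator (200 enzymes, 20 planted keys).
* **Drug annotations** — 6 planted candidates among the reversers, half
  via a key-enzyme target, half via key-enzyme-adjacent compounds; all
  other drugs get non-enzyme targets and compounds outside the model, so
  false selections indicate real pipeline errors.

The shared biology (gene universe, module layout, baseline means,
loadings, planted DE sets) is drawn once per seed and reused across
datasets and generators; factors and noise are dataset-specific. Every
generator is bit-reproducible given the seed.

What the generator does **not** emulate: probe-level structure, batch
effects, matched-pair correlation, heavy-tailed noise, partially
overlapping gene universes, currency metabolites, or drugs with
off-model pharmacology. Passing tests therefore demonstrate that the
pipeline recovers the structure it is designed to detect under its own
assumptions — not that those assumptions hold for any particular real
dataset.

# Numerical choices and degenerate inputs

* Ties in rank construction are broken by first occurrence
  (`ties.method = "first"`), keeping every profile an exact permutation.
* Empirical p-values always carry the `+1` correction.
* `d_in = 0` maps to enrichment 0 (not `−log10 1 = 0` by accident but as
  the intended "no evidence" value); hypergeometric tails are computed
  with `phyper` on the log-safe side.
* Degenerate inputs fail loudly: empty signatures, single-class
  datasets, classes with fewer than 2 samples, non-permutation rank
  columns, reactions without substrates or products, and p-values
  outside `[0, 1]` are all errors; constant genes, absent signature
  genes, absent enzymes and zero-instance drugs are warnings with a
  defined fallback.

# Problem sizes used in validation

The test-suite and acceptance-script simulations run at the study's
nominal scale — 2,000 genes, 3 datasets of 30+30 samples, 1,000 rank
profiles — for planted-signal recovery (once at a fixed seed plus ten
replicate seeds for end-to-end candidate recovery), and at a reduced
scale (200–600 genes) for calibration loops that need 25–50 replicates.
Exhaustive oracles (all subsets for the KS statistic, all sample pairs
for the AUC, hypergeometric enumeration for Fisher tests) run on
universes small enough to enumerate completely.

# Known limitations

* The importance-score combination rule is a documented approximation;
  rankings could shift under the original formulation.
* The key-enzyme set deliberately includes densely linked co-module
  partners of true key enzymes (they carry the same kind of evidence);
  sensitivity is the designed-for metric, not specificity.
* PUD significance inherits the conservativeness of the one-sided
  permutation p at score 0; extremely weak reversers near the FDR
  boundary are the first to be lost.
* Inter-dataset correlation is computed on per-gene mean profiles; other
  readings of "expression profile of the common genes" (medians,
  concatenated samples) would give different values.
* No IC50 / 4PL fitting in the assay module — raw inhibition summaries
  only, matching how such validation data are typically reported.
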