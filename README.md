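# metconnect

Computational drug repositioning for cancer by combining two independent
lines of evidence:

1. **Connectivity screening.** A disease signature — the up- and
   down-regulated differentially expressed (DE) gene sets of a
   case/control expression dataset — is scored against drug-induced gene
   rank profiles (Connectivity-Map-style data). For a gene set with
   sorted positions `V(1) < … < V(t)` in a ranked list of `n` genes, the
   signed Kolmogorov–Smirnov enrichment statistic is

   ```
   a = max_j ( j/t − V(j)/n ),   b = max_j ( V(j)/n − (j−1)/t )
   KS = a  if a > b,  else  −b
   ```

   and the connectivity score is `KS_up − KS_down` when the two
   statistics have opposite signs (0 otherwise). A significantly
   *negative* score means the drug pushes the disease's up-genes down
   and its down-genes up — the reversal pattern of therapeutic interest.
   Significance comes from a permutation null (random gene sets of the
   same sizes) with Benjamini–Hochberg adjustment across the screen. A
   drug is a *potentially useful drug* (PUD) when a majority of its
   cell-line instances are significant in at least two datasets.

2. **Key-enzyme prediction.** Enzyme-coding genes are scored by
   overlaying a gene co-expression network (edges at `|PCC| ≥ 0.7`,
   partitioned into modules by greedy modularity maximization) with a
   metabolic enzyme-link network (two enzymes are linked when a product
   of one's reaction is a substrate of the other's). Each enzyme gene
   `g` in module `m` receives

   ```
   score(g) = AUC(m) × (−log10 P_hyper[ X ≥ d_in ])
   ```

   where `AUC(m)` is the ROC AUC of per-sample module-median expression
   for separating cancer from normal samples (oriented to `[0.5, 1]`)
   and the hypergeometric tail measures the enrichment of `g`'s
   metabolic links inside its own module (`d_in` of `d_tot` links,
   module share `K` of `N` scored enzymes). Genes scoring strictly above
   the median in **every** dataset are the key cancer enzymes.

A PUD becomes a **candidate drug** when one of its annotated targets is
a key enzyme (`target_of_kpc`), or one of its compounds is a substrate
or product of a reaction catalyzed by a key enzyme
(`substrate_or_product_of_kpc`).

The package is aimed at computational biologists who want to run, test,
or extend this combined screen. Because the real inputs are large
external resources, a fully seeded synthetic-data generator with planted
ground truth (DE genes, signature-reversing drugs, key enzymes,
candidate drugs) makes every stage testable offline. Dose–response (MTT)
inhibition summaries and Fisher gene-set enrichment utilities round out
the downstream validation steps.

## Worked example

Simulate a small study with planted structure and run the whole
pipeline:

```r
library(metconnect)

cfg <- simulation_config(n_genes = 600, n_normal = 15, n_cancer = 15,
  n_modules = 4, module_size_range = c(20, 40), n_drugs = 40,
  instances_per_drug = 3, n_reversers = 5, n_enzymes = 60,
  n_reactions = 100, n_planted_key_enzymes = 8, n_planted_candidates = 4,
  seed = 7)
study <- simulate_study(cfg)
res <- run_pipeline(study$datasets, study$profiles, study$model,
                    study$drugs, n_perm = 500, seed = 7)
res
#> <repositioning_result>
#>   per-dataset PUDs: 5 / 5 / 5
#>   overall PUDs: 5
#>   per-dataset key enzymes: 23 / 23 / 23
#>   key cancer enzymes (all datasets): 23
#>   candidate drugs: 4 (2 target route, 2 compound route)
res$candidates
#>   drug_id                   rationale  relevant_enzymes relevant_compounds
#> 1 drug003 substrate_or_product_of_kpc       g0150;g0288      c00086;c00099
#> 2 drug006               target_of_kpc             g0172
#> 3 drug019 substrate_or_product_of_kpc g0196;g0288;g0456      c00058;c00104
#> 4 drug024               target_of_kpc             g0172
```

All 5 planted reverser drugs come out as PUDs (each significant in a
majority of its instances in all three datasets), the 23 predicted key
enzymes include all 8 planted ones (plus their densely linked co-module
partners), and the 4 planted candidates are recovered with the correct
rationale: `drug006`/`drug024` target a key enzyme directly, while
`drug003`/`drug019` map to compounds consumed or produced by key-enzyme
reactions.

Summarizing an MTT dose–response (inhibition
`1 − (OD_compound − OD_blank)/(OD_DMSO − OD_blank)`, per replicate, then
averaged):

```r
summarize_dose_response(dose_response(
  "finasteride", "PANC-1", c(0.001, 0.01, 0.1),
  matrix(c(0.93, 0.90, 0.96, 0.78, 0.80, 0.76, 0.52, 0.49, 0.55), 3,
         byrow = TRUE), c(1.01, 0.99, 1.00), 0.10))
#>       drug_id cell_line concentration n_replicates mean_inhibition sd_inhibition
#> 1 finasteride    PANC-1         0.001            3      0.07777778    0.03333333
#> 2 finasteride    PANC-1         0.010            3      0.24444444    0.02222222
#> 3 finasteride    PANC-1         0.100            3      0.53333333    0.03333333
```

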