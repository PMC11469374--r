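# xsconcord

Cross-species transcriptional concordance analysis for case/control
transcriptomics compared against staged exposure models — the setting where
a human post-mortem cohort (e.g. opioid use disorder in the nucleus
accumbens) is compared with rodent self-administration cohorts sampled
during intoxication, acute withdrawal, and prolonged abstinence, separately
by sex.

The package implements, as tested R code with a synthetic-data generator
carrying planted truth:

* **Moderated differential expression** — two-group linear fit per gene,
  empirical-Bayes variance shrinkage toward a scaled inverse-chi-square
  prior (method of moments on log variances, trigamma inversion), moderated
  *t* with `d0 + df` degrees of freedom, BH q-values, and the DE call
  `p < 0.01 & |log2FC| > 0.26` (strict inequalities).
* **Signed rank–rank hypergeometric overlap (RRHO)** — signatures ranked by
  `sign(log2FC) · −log10(p)`, a stratified four-quadrant map of exact
  hypergeometric upper tails over all rank-threshold pairs, quadrant
  maxima, and the concordant overlap gene sets.
* **Co-expression modules** — unsigned `|cor|^β` adjacency with automatic
  soft-threshold selection, topological overlap, average-linkage tree cut
  with eigengene merging, module eigengenes and kME.
* **Module differential connectivity (MDC)** — ratio of summed
  lower-triangular adjacency between case and control networks, tested with
  two permutation schemes (shuffled samples, shuffled genes; conservative
  max combination), BH correction, gain/loss calls at q < 0.05.
* **Enrichment and scoring** — Fisher/hypergeometric enrichment of DE genes
  in modules, GMT-based over-representation analysis with an explicit
  background, ARACNe-style mutual-information networks pruned by the
  data-processing inequality with hub identification, and AUCell-style
  module scoring of cell profiles with rank-sum group comparison.
* **A pipeline** — `run_crossspecies()` orchestrates simulate/load → DE per
  sex and contrast → RRHO → modules → MDC → enrichment → hubs → report,
  deterministically from one seed.

## Worked example

Simulate a paired two-cohort study in which concordant effects are planted
in females only, plus one module that gains connectivity under withdrawal,
then run the whole workflow:

```r
library(xsconcord)

d <- synth_design(
  n_genes = 800, groups = c("control", "withdrawal"), n_per_group = 10,
  sexes = c("F", "M"), frac_concordant_down = 0.15, frac_concordant_up = 0.05,
  de_sexes = "F", ortholog_coverage = 0.9,
  modules = list(module_spec(40, 0.2, 0.6, "withdrawal")), seed = 7)

cfg <- pipeline_config(design = d, n_network_genes = 800, beta = 6,
                       n_perm = 200, seed = 7)
report <- run_crossspecies(cfg)
print(report)
```

```
cross-species concordance run
  contrasts: withdrawal | sexes: F, M | seed 7
  DE counts:
          comparison up down
 a.withdrawal.pooled 29   64
 b.withdrawal.pooled 24   76
      a.withdrawal.F 41  109
      b.withdrawal.F 41  114
      a.withdrawal.M  5    5
      b.withdrawal.M  1    2
  RRHO concordant maxima (down-down / up-up):
    withdrawal.pooled              50.64 /   25.40
    withdrawal.F                   88.64 /   37.34
    withdrawal.M                    1.97 /    1.69
  modules: 1 (beta = 6)
  MDC withdrawal: 1 gain, 0 loss of 1 modules
```

Reading the output: more transcripts are called down than up (the planted
direction); the female–female RRHO concordant maximum (88.6 −log10 units in
the down-down quadrant) dwarfs the male–male one (2.0), recovering the
planted sex-specific concordance; and the planted connectivity gain is
called by the MDC permutation test. `report$rrho[["withdrawal.F"]]` holds
the full map (plot it with `plot()`), `report$mdc$withdrawal` the per-module
table, and `quadrant_genes()` extracts the concordant overlap genes for
enrichment.

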