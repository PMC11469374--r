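---
title: "Methods: cross-species transcriptional concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species transcriptional concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsconcord)
```

# The problem

Post-mortem case/control transcriptomics of a brain disorder — the
motivating application is opioid use disorder in the nucleus accumbens —
cannot say which expression changes reflect acute drug exposure and which
are consequences of chronic use. Rodent self-administration models can:
animals are sacrificed while intoxicated, in acute withdrawal, or after
prolonged abstinence. `xsconcord` implements the comparative machinery for
this design: differential expression in each cohort, a threshold-free
comparison of the two cohorts' ranked signatures, co-expression modules and
their change in connectivity between groups, enrichment statistics, and
cell-profile scoring of module activity. Every stage is exercised on
synthetic data with planted truth, so the statistical behaviour of the
pipeline is testable without access to any particular data set.

# Differential expression with variance moderation

For a contrast between control and one exposure group, each gene is fit by
the two-group linear model: the effect is the difference of group means of
log2 expression (`log2FC`), with pooled residual variance $s_g^2$ on
$d = n_a + n_b - 2$ degrees of freedom. Sex-stratified analyses subset the
samples first; no other covariates are modelled.

Variances are moderated empirically. The gene-wise variances are assumed
exchangeable around a scaled inverse-chi-square prior with hyperparameters
$(d_0, s_0^2)$, estimated by method of moments on $z_g = \log s_g^2$: with
$e_g = z_g - \psi(d/2) + \log(d/2)$,

$$\operatorname{trigamma}(d_0/2) = \operatorname{Var}(e) - \operatorname{trigamma}(d/2),
\qquad
\log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2),$$

where the trigamma inversion is performed by bisection to a tolerance of
1e-8 on the argument. When the observed spread of $e_g$ is no larger than
the sampling noise, $d_0 = \infty$ and every posterior variance equals
$s_0^2$. The posterior variance is the usual precision-weighted compromise
$(d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, and the moderated $t$ uses
$d_0 + d$ degrees of freedom. Genes with $s_g^2 = 0$ (possible in small
synthetic fixtures) are floored at the 1st percentile of the positive
variances before taking logs; if every variance is zero the fit aborts.

A transcript is called differentially expressed when $p < 0.01$ **and**
$|log2FC| > 0.26$, with both inequalities strict, so the boundary values
$p = 0.01$ and $|log2FC| = 0.26$ are not called. The raw $p$ is used for
calling by default; BH-adjusted $q$ values are always reported alongside
and a `use_q` flag switches the rule to them.

# Signed rank-rank hypergeometric overlap

Two signatures on a shared (case-insensitively ortholog-matched) gene
universe are each ranked by the signed score
$\operatorname{sign}(log2FC)\cdot\min(-\log_{10} p,\ 300)$; a zero effect
counts as positive, and ties are broken by placing zero-effect genes after
non-zero ones and then by gene id, so the order is total and deterministic.

The map is stratified ("split") into four quadrants. Down-down and up-up
(concordant) quadrants scan prefixes from the down-most and up-most ends of
both lists; down-up and up-down (discordant) quadrants scan opposite ends.
At rank thresholds $(i, j)$ the overlap $k$ between the two prefixes is
scored by the exact hypergeometric upper tail $P(X \ge k)$, computed in log
space, and the cell stores $-\log_{10}$ of that tail — zero when the
overlap falls below its expectation (only enrichment is scored), capped at
300, and signed negative in the discordant quadrants. The default stride is
$\lfloor\sqrt{N}\rfloor$; `step = 1` gives the exact cell-by-cell map used
by the oracle tests. Each quadrant reports its maximum, the argmax
thresholds, and the genes in the prefix intersection there — the concordant
sets are what downstream enrichment consumes.

# Co-expression modules

The network stage follows the weighted co-expression convention: the top
5000 genes by variance (all genes in smaller simulations) form the analyzed
universe, which is also the enrichment background throughout. Adjacency is
unsigned, $A_{ij} = |\operatorname{cor}(x_i, x_j)|^\beta$. The power
$\beta$ is the smallest one whose degree distribution fits a power law with
$R^2 \ge 0.8$ (negative slope, 10 log-spaced bins) **and** whose mean
connectivity stays at least 1 — without the connectivity floor, high powers
on pure noise shrink all degrees toward zero where a power-law fit is
vacuously good. If no power qualifies, $\beta = 6$ is used with a warning.

The topological overlap matrix is
$\mathrm{TOM}_{ij} = (\sum_{u \ne i,j} A_{iu}A_{uj} + A_{ij}) /
(\min(k_i, k_j) + 1 - A_{ij})$. Modules come from average-linkage
clustering of $1 - \mathrm{TOM}$ with a static height cut, clusters smaller
than 30 genes left unassigned ("grey"), and merging of modules whose
eigengenes correlate above 0.85. The cut is placed at the 0.7 quantile of
the merge heights: in average-linkage TOM trees the highest merges attach
isolated background genes one at a time, so a cut near the top of the tree
would undo only those attachments and leave one giant cluster, while merges
below the 0.7 quantile are dominated by cohesive within-module joins. On
planted four-block data this cut recovers memberships with adjusted Rand
index above 0.95 and is stable over the 0.7–0.8 range; the quantile is a
parameter for data that deviate from this shape. The full dynamic tree cut
is intentionally out of scope — the static cut is deterministic and
adequate for block recovery.

Module eigengenes are the first principal component of the standardized
module expression, unit-norm over samples and sign-oriented to correlate
positively with the mean module profile; kME is the gene–eigengene
correlation.

# Module differential connectivity (MDC)

For a module with adjacency submatrices $A^{case}$ and $A^{ctrl}$ computed
separately from the two groups' samples (with the globally chosen $\beta$),

$$\mathrm{MDC} = \frac{\sum_{i>j} A^{case}_{ij}}{\sum_{i>j} A^{ctrl}_{ij}},$$

so MDC > 1 is a gain and MDC < 1 a loss of connectivity. Significance comes
from two permutation schemes: *shuffled samples* permutes the group labels
over the pooled samples (non-random nodes, random connections); *shuffled
genes* redraws a same-size gene set from the analyzed universe with the
labels intact (random nodes, non-random connections). The p-value is
two-sided on the log ratio with the add-one estimator
$(1 + \#\{|\log r^\ast| \ge |\log r|\})/(1 + B)$, so it is never zero. The
schemes are combined conservatively as their maximum, BH-adjusted across
modules, and a gain/loss call requires $q < 0.05$ with the matching ratio
direction. The permutation count defaults to the conventional 1000;
calibration and power checks in the tests use 100, where the smallest
attainable p (~0.0099) still resolves the 0.05 level. Within permutations
$\beta$ is not re-tuned.

# Enrichment, hubs, and cell-profile scoring

Module/DE enrichment and over-representation analysis share one statistic:
the 2×2 Fisher table over an explicit background with the exact
hypergeometric upper tail — the same tail function the RRHO map uses. The
odds ratio is $ad/bc$; 0.5 continuity is applied (and flagged) only when a
zero *denominator* cell would make the ratio undefined, so disjoint sets
report an odds ratio of 0 rather than a continuity-inflated value. ORA
filters every set to the background before testing, tests only sets with a
non-empty intersection, and BH-adjusts across the tested sets. The
background is always explicit, never inferred from the collection.

Hub genes are the top 11 by intramodular degree in the mutual-information
network (sum of retained-edge MI within the module), falling back to kME
when no MI network is built. MI uses equal-frequency binning with
$\lfloor\sqrt{n}\rfloor$ bins and a permutation-calibrated edge threshold;
the data-processing inequality then removes, within each fully connected
triangle, the weakest edge when it falls below the smaller of the other two
(all violations marked before any removal). "Condition-specific hub" has no
standard operational definition, so this package defines it as a hub of the
case network whose rank in the control network falls outside the top
$2\times 11$ — a rank-displacement rule that is deterministic and easy to
audit.

Cell profiles are scored AUCell-style: genes are ranked per cell, and the
score is the area under the module-gene recovery curve truncated at the top
5% of the ranking, normalized by the maximal achievable area, so a cell
with every module gene at the very top scores exactly 1 and one with no
module gene in the window scores 0. Group differences per cell type use the
rank-sum test (AUC distributions are bounded and skewed), BH-adjusted
across cell types.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: two cohorts
sharing a gene universe, a control group plus up to three exposure stages,
two sexes, and planted cross-cohort effect classes (concordant up/down,
discordant, cohort-unique, null) whose magnitudes are drawn from
$|N(\mu_{effect}, \sigma_{effect})|$ and applied in all non-control groups.
An optional `de_sexes` field restricts the planted effects to one sex,
which is how the headline sex-specific concordance pattern is generated and
tested. Defaults — 10 samples per group per sex, log2 noise SD 0.5, effect
mean 1, biotype mix 89.2% protein coding / 7.5% lncRNA / 3.3% pseudogene —
follow the study conditions where stated and conventional bulk-RNA-seq
magnitudes where not; rodent group sizes are not published, so 10 per group
per sex is the configurable default.

Modules are planted with the equicorrelated latent-factor construction
$x_g = \sqrt{r}\, f_m + \sqrt{1-r}\,\varepsilon_g$ (shared per-sample
factor $f_m$), which yields exactly $r$ expected pairwise correlation and
is therefore analytically checkable; $r$ can differ between the control
samples and one target group, which plants a connectivity gain or loss for
MDC to find. Module genes are drawn from the null-effect pool so
connectivity signal is not confounded with mean shifts. Ortholog maps cover
a configurable fraction of the universe, with upper-case symbols in cohort
a and title-case in cohort b to exercise case-insensitive matching. All
randomness flows through one seed; stage seeds are derived by a stable
string hash so stages rerun independently and reproducibly.

What the generator deliberately does **not** emulate: count-level sampling
and overdispersion (values are Gaussian on the log2 scale), library-size
and batch effects, dropout or zero inflation in the cell profiles,
correlated null genes outside planted modules, and many-to-many ortholog
structure. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under its stated model — not that any biological
conclusion transfers to a particular real data set.

# Numerical choices and degenerate inputs

* Trigamma inversion: bisection, tolerance 1e-8; target $\le 0$ maps to
  $d_0 = \infty$.
* Zero gene variances floored at the 1st percentile of positive variances;
  all-zero variances abort.
* Signed scores capped at 300; $p = 0$ capped with a warning.
* Rank ties broken by gene id (and zero-effect genes ranked after
  non-zero), so every ranking is total and deterministic.
* Zero-variance genes get zero correlation (with a warning) in adjacency;
  merge heights are rounded to 10 decimals and made monotone before
  cutting, guarding against floating-point tie noise in `hclust`.
* A disconnected control module (zero adjacency sum) is an error for MDC,
  not a silent infinity; permutation draws that hit it count as ratio 1.
* Add-one permutation p-values are never 0; an observed ratio of exactly 1
  yields p = 1 by construction.

# Problem sizes used by the tests and acceptance script

Unit and property tests run on 30–600-gene fixtures. The statistical
acceptance checks use: 30-gene exact-oracle RRHO maps; exhaustive
hypergeometric enumeration for all universes up to $N = 12$; 200 null and
100 planted-gain MDC simulations (40-gene module, 20+20 and 30+30 samples,
100 permutations); one 600-gene four-module recovery run; a 5000-gene
hyperparameter-recovery simulation; 50 paired-cohort seeds for the
sex-specific concordance motif; and 100 Gaussian-chain runs for DPI
pruning. The acceptance script reruns the same computations from scratch at
comparable sizes and writes the resulting rates and estimates as JSON.

# Known limitations

Covariate adjustment (age, RIN, batch), voom-style precision weights,
dynamic tree cut, consensus networks across cohorts, bootstrap ARACNe, and
permutation family-wise correction of whole RRHO maps are out of scope.
The MDC sample-shuffling scheme interprets "random connections" as label
permutation; directly permuting adjacency entries is a plausible
alternative reading and would give a different (likely anti-conservative)
null. The condition-specific-hub rule is this package's own definition.
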