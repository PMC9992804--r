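---
title: "Stage-prior-informed joint NMF: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-prior-informed joint NMF: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidnmf)
```

## The problem

Tumour cohorts are increasingly profiled on several axes at once: quantitative
histopathology features extracted from whole-slide images (WSI), miRNA
expression, and mRNA expression, measured on the same patients. Each modality
alone gives a partial view; the joint structure — groups of image features,
miRNAs and mRNAs that co-vary across patients — is where imaging-genetic
associations live. `spidnmf` finds that joint structure by factorizing all
views against a *single* shared sample basis, and then mines the factors for
co-expression modules, which in turn seed survival-based biomarker screening.

## The model family

Given sample-aligned non-negative matrices $X_l \in \mathbb{R}^{n \times p_l}$
(rows = samples, identical row order across views), all three model variants
seek a shared basis $W \in \mathbb{R}^{n \times k}_{\ge 0}$ and per-view
coefficients $H_l \in \mathbb{R}^{k \times p_l}_{\ge 0}$ with
$X_l \approx W H_l$.

**Joint NMF (`jnmf`)** minimizes the plain reconstruction loss

$$\sum_l \lVert X_l - W H_l \rVert_F^2 .$$

**Multi-penalty joint NMF (`mdjnmf`)** adds four regularizers:

$$\alpha \sum_l \lVert H_l H_l^\top - I \rVert_F^2
  \;+\; \gamma_2 \sum_l \textstyle\sum_{ij} (H_l)_{ij}
  \;+\; \gamma_1 \lVert W \rVert_F^2
  \;-\; \lambda_1 \,\mathrm{Tr}(H_1 A_1 H_2^\top)
  \;-\; \lambda_2 \,\mathrm{Tr}(H_1 A_2 H_3^\top),$$

where the orthogonality term discourages redundant factors, the entry-sum
term (an L1 penalty on non-negative entries) sparsifies the loadings, and the
two trace terms *reward* placing correlated cross-modal features on the same
factor. The coupling matrices $A_1$ ($p_1 \times p_2$, image vs miRNA) and
$A_2$ ($p_1 \times p_3$, image vs mRNA) hold absolute Pearson correlations
between feature columns, computed by `build_cross_modal_prior()`; entries lie
in $[0,1]$ and pairs involving a constant column get 0 (their correlation is
undefined), with a warning.

**Stage-prior-informed joint NMF (`spid`)** embeds clinical information about
the samples. Patients are nodes of an undirected graph, connected exactly when
they share a clinical-stage label: $A_{ij} = 1$ iff stage$_i$ = stage$_j$
(including $A_{ii} = 1$; self-loops cancel in the penalty below, so the
convention is harmless). With degree matrix $D_{ii} = \sum_j A_{ij}$ and
Laplacian $L = D - A$, the extra penalty

$$\beta \,\mathrm{Tr}(W^\top L W)
  = \frac{\beta}{2} \sum_{ij} A_{ij} \lVert w_i - w_j \rVert^2$$

pulls the basis rows $w_i$ of same-stage samples together in factor space.
The identity above (rows of $W$, indexed like $A$) is the only dimensionally
consistent reading of the penalty, and it is what the package implements and
tests; it also makes the null space explicit: the penalty is zero exactly
when rows are constant within every stage group.

## Optimization

**Initialization.** Factors are initialized by non-negative double SVD
(NNDSVD): the leading singular triplet of the column-concatenated matrix
$[X_1\,X_2\,X_3]$ enters via absolute values, each later triplet through
whichever of its positive/negative part pairs carries more mass. Exact zeros
are floored at `init_floor` ($10^{-6}$) so multiplicative updates can move
every entry. The initialization is fully deterministic — the same data and
rank always give the same factors — which makes fits, sweeps and module
calls reproducible without seed bookkeeping.

**Multiplicative updates.** One iteration updates $W$ first, then
$H_1, H_2, H_3$, each step using the freshest co-factors (a fixed
Gauss–Seidel order, chosen once for reproducibility):

$$W \leftarrow W \circ
 \frac{\sum_l X_l H_l^\top + \beta A W}
      {\sum_l W H_l H_l^\top + \gamma_1 W + \beta D W}, \qquad
 H_1 \leftarrow H_1 \circ
 \frac{W^\top X_1 + 2\alpha H_1 + \tfrac{\lambda_1}{2} H_2 A_1^\top
       + \tfrac{\lambda_2}{2} H_3 A_2^\top}
      {W^\top W H_1 + 2\alpha H_1 H_1^\top H_1 + \tfrac{\gamma_2}{2} E},$$

with $H_2, H_3$ analogous (each carries its single coupling term) and $E$ the
all-ones matrix. Note the Laplacian split: the gradient contribution
$2\beta L W = 2\beta(D - A)W$ is divided into its attractive part $\beta A W$
(numerator) and its degree part $\beta D W$ (denominator). This is the
standard construction for graph-regularized NMF and the only placement that
keeps the rule multiplicative and sign-safe — $L$ itself has negative
off-diagonal entries, so a naive "$+\beta W L$" in the numerator would break
non-negativity (and is dimensionally inconsistent besides). Denominators are
floored at `eps` ($10^{-10}$), which never perturbs a healthy update (the
floor only binds when a denominator entry underflows toward zero).

With all penalty weights at zero the update collapses *exactly* to the
classical two-factor multiplicative NMF step on the concatenated matrix, and
the package asserts the classical guarantee: the objective is non-increasing
across iterations in that limit. The fully penalized objective carries no
published convergence proof; the package monitors it and asserts
non-negativity of the factors at every step instead. Two exact reduction
identities are also enforced in the tests: `spid` with $\beta = 0$ produces
bit-identical iterates to `mdjnmf`, and `mdjnmf` with all extra weights zero
produces bit-identical iterates to `jnmf`.

**Convergence.** The monitored criterion is the scale-free relative error
$\lVert X - W H \rVert_F / \lVert X \rVert_F$ over the concatenated views
(0 = exact factorization, 1 = the all-zero model; a `squared = TRUE` switch
exposes the raw squared norm for users who prefer the unnormalized form).
Iteration stops when the error changes by less than `tol` ($10^{-6}$), when
it has failed to improve for `patience` consecutive iterations (early
stopping, used by the grid search with patience 5), or at `max_iter` (200 by
default).

## Tunable parameters

| parameter | role | default | notes |
|---|---|---|---|
| `k` | rank / number of modules | — | ~n/10 heuristic; 7 at n ≈ 69 |
| `alpha` | $H_l$ orthogonality | 0.01 | not swept; fixed small value |
| `lambda1`, `lambda2` | cross-modal coupling | 0 | swept over {0.001, 0.01, 0.1, 1} |
| `beta` | stage-graph penalty | 0 | swept over the same grid |
| `gamma1` | $W$ shrinkage | 0 | swept |
| `gamma2` | $H_l$ sparsity | 0 | swept |
| `z_threshold` | module membership | 2.0 | see below |
| `min_days` | survival filter | 90 | strict inequality |
| `p_cutoff` | univariate screen | 0.05 | raw p by default; BH optional |

The five swept weights define the canonical grid: 4 candidate values each,
$4^5 = 1024$ combinations, enumerated in a fixed odometer order
(`lambda1` slowest … `gamma2` fastest) so a combination index identifies its
weights deterministically. `grid_search()` fits every combination with
early stopping and selects the smallest relative error, ties going to the
lowest index.

## Co-expression modules

Each factor yields one module: feature $j$ of view $l$ is a member iff
$H_l[i,j] > \mathrm{mean}(H_l[i,\cdot]) + z \cdot \mathrm{sd}(H_l[i,\cdot])$.
The threshold rule is the per-row z-score criterion standard in the joint-NMF
module literature; the literature it descends from does not pin a constant,
so `z_threshold = 2` is the package default and deliberately prominent in the
API. The rule is scale-invariant (per-row), hence immune to the
$W$-vs-$H$ scale indeterminacy of NMF. It is well-posed only when a minority
of a row is active: for an active fraction $f$ of roughly constant loadings,
mean + 2 sd sits below the active level only when
$f + 2\sqrt{f(1-f)} < 1$, i.e. $f < 0.2$. A zero-variance row contributes no
members. Exactly `k` modules are always produced — note that a report of "one
module per sample" (e.g. 69 modules from 69 samples at k = 7) is not
reproducible under any per-factor definition; this package's module count is
`k` by construction.

Modules are scored per view by the absolute Pearson correlation between the
member columns of $X_l$ and of $W H_l$, both flattened to vectors (one scalar
per module per view, matching how such module screens are reported), and
summarized by the mean over views with members; `select_top_module()` takes
the maximal mean, ties to the lowest factor index. `module_residuals()`
exposes the complementary smallest-residual reading for users who prefer it.

## WSI feature aggregation

Per-nucleus segmentation output (10 cell-level features: `area`, `major`,
`minor`, `ratio`, `rMean`, `gMean`, `bMean`, `distMean`, `distMax`,
`distMin`) is aggregated per patient into 10 histogram fractions plus 5
summary statistics (mean, sd, median, min, max) per feature —
$10 \times 15 = 150$ patient-level features, named `area_bin1` …
`distMin_max`. The 10-bins-plus-5-statistics inventory is the unique
15-per-feature scheme consistent with both the naming convention
(`area_bin1`, `area_mean`) and the total of 150. Bin edges default to
cohort-wide deciles — so `area_bin1` is the fraction of a patient's nuclei in
the cohort's smallest-area decile ("extremely small nuclei") — and can be
supplied explicitly for cross-cohort comparability; decile edges are a
documented default, not a claim about how any particular published cohort
was binned. Fractions sum to 1 per feature by construction, and aggregation
is invariant to nucleus row order. Nuclear segmentation itself is out of
scope: the module starts from the segmented per-nucleus table.

## Prognostic screening

The survival arm owns only the bespoke arithmetic; the proportional-hazards
fitting is delegated to `survival::coxph`, which is the reference
implementation and not something to re-derive. The pipeline is: (1) filter to
samples surviving strictly more than 90 days; (2) univariate Cox screen per
feature, retaining raw $p < 0.05$ (no multiplicity correction by default —
that matches the conventional univariate pre-screen before a multivariate
model — with a BH option for users who want control of the false discovery
rate); (3) multivariate Cox fit over the retained features, giving the linear
risk score $\sum_n \mathrm{coef}_n x_n$; (4) median split of training-cohort
scores, strictly-greater-than going to the high-risk group (so all-tied
scores fall to "low" and distinct scores split to within one sample of
balance). Kaplan–Meier curves and time-dependent ROC belong to standard
survival tooling and are not re-implemented here.

## The synthetic generator

`simulate_multiview()` generates the structure the model assumes, with known
ground truth: a non-negative basis `W_true` with a stage-specific dominant
factor (stages assigned round-robin, so groups are balanced and deterministic),
per-view block-sparse `H_true` with disjoint active blocks per factor, and
observations $X_l = \max(0, W_{\rm true} H_{{\rm true},l} + \mathcal{N}(0,
\sigma))$. Truncation at zero preserves non-negativity while keeping $\sigma$
interpretable as an additive noise level. Design constants, fixed once:

* active blocks cover 12.5% of a view's features per factor with values
  $U(0.9, 1.1)$ — a sub-20% active fraction of near-constant positives, the
  regime in which the z = 2 membership rule is well-posed on the truth
  itself (see the feasibility bound above);
* the stage boost is `stage_strength` $\times\, U(0.75, 1.25)$ on factor
  $((s-1) \bmod k) + 1$, so `stage_strength = 0` removes all stage structure
  (verified by a label-permutation test);
* reference configuration n = 60, p = (50, 80, 100), k = 4, 3 stages,
  $\sigma = 0.05$ — a desk-scale cohort in which a full fit takes well under
  a second, so multi-seed validation stays cheap.

`simulate_survival()` draws exponential event times with log-hazard
`effect_size * W_true[, factor]` and censors via an independent competing
exponential whose rate is set so the censoring probability equals
`censor_rate` exactly.

What the generator does *not* emulate: count-distributed sequencing data
(negative binomial dispersion, library-size effects), correlated noise across
features, overlapping modules, batch structure, or realistic WSI morphology
statistics. Passing the validation suite therefore demonstrates algorithmic
correctness — the solver optimizes what it claims, recovers structure it is
built to recover, and is calibrated where it makes statistical claims — not
biological performance on any real cohort.

## Validation summary

The test-suite and the acceptance script (`scripts/acceptance.R`) recompute,
from scratch, at the problem sizes noted: grid cardinality (1024);
the 150-feature WSI aggregation; objective monotonicity in the classical
limit (20 instances, n = 30, 200 iterations); exact reduction identities and
agreement with a hand-rolled classical multiplicative step ($< 10^{-12}$);
the Laplacian/double-sum identity on 20 random graphs ($< 10^{-10}$);
noiseless planted recovery below 1% relative error and planted-module
recovery (mean Jaccard over 10 seeds) at the reference configuration;
monotone decrease of $\mathrm{Tr}(W^\top L W)$ in $\beta$ over
$\{0, 0.01, 0.1, 1\}$; univariate-screen null calibration (200 replicates,
n = 200) and planted-effect power (n = 300); and the risk-score arithmetic
against independent hand computation.

## Known limitations

* No convergence guarantee for the fully penalized objective; only the
  classical limit is covered by theory.
* The relative-error normalization and the sparsity bookkeeping in the
  monitored objective are package conventions (documented above); they never
  affect the iterates, only reporting.
* Module membership depends on a single unpinned constant (`z_threshold`);
  sensitivity to it should be checked on any real analysis.
* Dense linear algebra only; cohorts beyond a few thousand samples or
  ~10^5 features would need a sparse or chunked backend.
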