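---
title: "Methods: clustered group-LASSO prediction under block-wise missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustered group-LASSO prediction under block-wise missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The setting and the model

The package predicts a continuous outcome that is observed for only a
subset of subjects (the *measured* set) from a wide table of partially
observed predictors, in the regime where missingness is *block-wise*:
whole batteries of measures are absent for whole subject subsets, the
patterns are mutually correlated, and no subject may be complete on all
predictors at once. Nothing here assumes missingness at random; the
procedure instead works around the missingness structure by only ever
fitting on locally complete data.

The elementary learner is the linear group-LASSO. For a design $X$ with
columns partitioned into groups $g = 1, \dots, G$ (each categorical
variable's dummy columns form one group; each continuous variable is a
singleton group), the solver minimizes

$$ \frac{1}{2n}\lVert y - X\beta \rVert_2^2
   + \lambda \sum_g \sqrt{p_g}\, \lVert \beta_g \rVert_2 , $$

the Yuan–Lin weighting with $p_g$ the group size. The group penalty
zeroes whole variables rather than single dummies, which is what makes
the procedure interpretable for the many categorical phenotypes in
biobank tables. Only the linear-Gaussian family is implemented;
binary/ordinal outcomes are out of scope for this version.

## Pipeline stages and their parameters

**General filter.** Drops predictors more than `max_missing_fraction`
missing (default 0.8), observed fewer than `min_observed` times,
schema-excluded (free text, dates, arrays, ICD matrices — these are
declared in the schema, not inferred from names), invariant, or
categorical with a realized level thinner than `min_level_count`
subjects (default 50; sparse levels destabilize dummy fits, and dropping
mirrors how ICD-style matrices are handled rather than collapsing
levels). The outcome is never dropped.

**Balance filter.** For variable $k$,
$\tau_k = (n_{k,\mathrm{measured}}/N_{\mathrm{measured}}) \,/\,
(n_{k,\mathrm{unmeasured}}/N_{\mathrm{unmeasured}})$. The default rule is
symmetric — keep iff $\min(\tau_k, 1/\tau_k) \ge t$, $t = 0.7$ — because
imbalance in either direction is pathological: $\tau \gg 1$ means the
variable is largely absent exactly where predictions are needed, and
$\tau \ll 1$ means the training set barely sees it. A one-sided literal
rule (`symmetric = FALSE`) is available. A variable never observed in
one of the two sets has undefined $\tau$ and is treated as maximally
imbalanced. The filter runs after the general filter, and is skipped when
there are no unmeasured subjects.

**Clustering.** Variables are clustered by UPGMA on Euclidean distances
between rows of the pairwise complete-count matrix. Distances are
computed on raw counts by default (`normalize = TRUE` divides by the
subject count); the count-matrix reading is used rather than distances
between missingness-indicator vectors, and the alternative would change
only the distance scale, not the mechanics. UPGMA is implemented
in-package so that merge ties break deterministically on the
lexicographically smallest active-pair index — reproducibility of the
whole pipeline under a fixed seed depends on it. Merge heights are
non-decreasing, and cutting strictly below a height yields the cluster
assignment; height 0 gives singletons.

**Cut heights.** The cut is an empirical choice made on per-cluster
diagnostics (variable count, mean observed count, complete cases).
`evaluate_cut_heights()` tabulates these for candidate heights. When the
operator does not choose, `choose_cut_height()` applies a conservative
rule: the smallest candidate at which every non-singleton cluster has at
least $\max(100, 2\,p_{\text{cluster}})$ complete cases, falling back to
the candidate whose worst cluster is best. Because distances are counts,
absolute heights are data-scale dependent; when no explicit candidates
are supplied the pipeline derives them from the dendrogram as the
heights that produce `k_targets` clusters (default 4, 6, 8, 10, 12).

**Iterative selection.** Each iteration clusters the current variables,
fits a `cv_k`-fold (default 5) cross-validated group-LASSO per cluster on
that cluster's complete cases within the measured set, and keeps the
union of variables with non-zero group norms at the CV-minimal penalty.
Clusters with fewer than `min_cluster_n` (default 25) complete cases are
dropped with a warning — a cluster with no usable rows cannot contribute,
and its variables leave the running set. The loop stops when the
retained set shrinks by less than 5%, when the retained set's
complete-case count reaches $\max(500, 5p)$, or after 10 iterations; all
three are configurable. The retained-set size is non-increasing by
construction.

**Stepwise final model.** Measured subjects are split into training and
hold-out sets (`holdout_fraction` = 0.2, inside the conventional 10–30%
band). Variables are ordered by ascending missingness in the measured
set; ties break by descending single-variable $R^2$ against the outcome
on training complete pairs, then by name. For each prefix of the
ordering a cross-validated group-LASSO is fit on the training complete
cases, stopping when a prefix has too few complete cases to fit
(fewer than $\max(k, 10)$).

*Hold-out scoring.* Each candidate is scored by the Pearson correlation
between observed and predicted outcome over the **full** hold-out set,
with predictions made by the same missingness-tolerant rule used at
deployment (missing terms contribute their training mean, below). Two
reasons. First, deep prefixes include high-missingness variables, so
their *complete* hold-out subsets can shrink to a handful of subjects,
and a correlation computed on five subjects is noise; scoring everyone on
a common sample keeps the candidates comparable. Second, the final model
is used on subjects with missing predictors, so candidates should be
compared on that task, not on the vanishing complete-case slice. The
winner maximizes the lower Fisher-z confidence bound (one standard
error) of the hold-out correlation, which equals the raw correlation for
large hold-outs and discounts small ones; per-step complete-case counts
are still reported in the trace for audit. The chosen prefix is refit on
*all* measured complete cases, with the penalty re-selected by CV, so
published predictions use every measured subject.

**Prediction.** A fitted model stores original-scale coefficients and
the training mean of every design column. The prediction for subject $i$
is $\bar{y} + \sum_{j\,:\,\text{observed}} \beta_j (x_{ij} - c_j)$:
dropping a centered term is exactly substitution of the training mean,
an unbiased-at-the-mean default. The per-subject count of dropped model
variables is returned, and subjects missing every model variable receive
the training outcome mean with an `all_missing` flag, so heavily imputed
predictions can be filtered downstream.

## Solver numerics

Groups are standardized (mean 0, unit sample SD) and orthonormalized
within groups by QR ($X_g^\top X_g / n = I$), making the block update an
exact group soft-threshold; coefficients are mapped back through the QR
factors and the standardization, so back-transformed coefficients
reproduce internal-scale predictions exactly. Rank-deficient groups are
reduced to their pivoted full-rank columns; columns degenerate in a fit's
row subset (e.g. a dummy constant within a CV fold) are dropped for that
fit and flagged. The path uses 100 log-spaced values from
$\lambda_{\max} = \max_g \lVert X_g^\top y\rVert_2/(n\sqrt{p_g})$ down to
$10^{-4}\lambda_{\max}$, fit by block coordinate descent (C++) with warm
starts; convergence is declared when the largest coefficient change in a
sweep is below `tol` = 1e-7, capped at 10,000 sweeps with a warning.
When a design has at least as many columns as rows, the path floor is
raised to $0.05\,\lambda_{\max}$: the unpenalized limit is not unique
there and chasing it is meaningless. CV folds are assigned by a seeded
permutation; each fold refits including standardization; the selected
penalty minimizes mean held-out squared error, preferring the larger
penalty (sparser model) on ties — the minimal-error rule, not the 1-SE
rule. All randomness in the pipeline flows from one top-level seed
through a deterministic seed stream, so identical configuration and seed
give byte-identical artifacts.

## The synthetic-data generator

`simulate_missingness_grid()` reproduces the complete-case collapse
design: a fully observed indicator matrix (defaults 10,000 × 200) gets
`block_counts` rectangular missing blocks — contiguous column runs of
width 5–15 and contiguous row runs of depth 100–500 (increments of 5) at
uniform offsets, overlaps allowed — then independent cellwise missingness
at each rate (1%–50%), over 100 replicates per grid cell. Rectangles are
the natural reading of "block-wise"; the complete-case statistic is
insensitive to row contiguity, which the closed-form cross-check
$N(1-q)^P$ at 1% confirms.

`simulate_phenotype_dataset()` builds prediction-study data: rows drawn
from a synthesized factor-model covariance
$\Sigma = \Lambda\Lambda^\top + D$ (seeded loadings, positive diagonal,
projected to positive-definiteness by eigenvalue clipping) — a stand-in
for a biobank-derived covariance, giving realistically correlated
predictors; half the predictors converted to categorical by equiprobable
quantile cuts (4 or 6 levels); the outcome built as intercept plus true
effects plus $N(0, \sigma^2)$ noise. A categorical true predictor's
level effects are the cumulative sums of the `beta_increments` offsets
from a zero reference — the increments define the dummy coefficients,
while the per-variable beta is recorded in the truth record; how a
single beta should map onto dummy coefficients is otherwise
underdetermined. Block missingness is imposed with the grid mechanism,
then a random cell rate is tuned by bisection (≤ 20 rounds) toward the
target complete-case proportion; a target of 0 escalates the rate until
no complete case remains. Finally the outcome is masked outside a random
measured subset (default 30% measured, matching the availability of a
typical questionnaire-battery phenotype).

**Default study conditions.** The stock `simulation_spec()` is the
scaled-down study used in the acceptance tests: $N = 2{,}000$, $P = 50$,
ten true effects $(0.5, 2, -2, 5, 5, -5, 7, 7, 7, -7)$, 4-level
categoricals with increments $(1, -4, 3)$, intercept $-10$, noise SD
$\sqrt{2}$, twelve blocks of 2–5 columns × 600–1,400 rows, completeness
tuned to zero complete cases. These sizes keep a full five-seed study in
minutes on one CPU while preserving the defining feature of the
full-scale problem — no subject complete on all predictors — and the
block geometry scales the original row-depth fractions to the smaller
table. The error-variance response checks use a lighter variant
($N = 1{,}200$, $P = 30$, small betas) where the correlation ceiling
$\sqrt{\operatorname{Var}(X\beta)/(\operatorname{Var}(X\beta)+\sigma^2)}$
separates cleanly across $\sigma \in \{1, 2, 3\}$.

**What the generator does not emulate.** Real biobank missingness is
*correlated with content* (who skips a questionnaire depends on who they
are); the generator's blocks are placed independently of the data, so
passing tests demonstrate robustness to the *structure* of block-wise
missingness, not to informative missingness. The synthetic covariance is
a generic factor model, not an estimate from real phenotypes, so
absolute accuracy numbers are not comparable to applications on real
data; tests therefore assert qualitative and relative behaviour
(recovery, orderings, ceilings), and the documented accuracy ranges of
the original full-scale application are not reproduction targets.

## Known limitations

- Linear-Gaussian outcomes only; no logistic/multinomial family.
- No imputation of predictor values; the method *avoids* rather than
  fills missingness, and prediction degrades gracefully (but does
  degrade) as model variables go missing.
- Cut heights live on the scale of pairwise counts, so explicit
  candidate heights do not transfer across datasets; prefer
  `k_targets`/`cut_candidates_for_k()`.
- The stepwise stage refits up to $p$ cross-validated models; with very
  wide retained sets this dominates runtime.
- `upgma()` is quadratic in memory in the number of variables; at
  biobank scale (thousands of variables) the distance matrix is the
  limiting object.
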