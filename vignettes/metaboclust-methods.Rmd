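---
title: "Chemocentric metabolite clustering and trait classification: methods"
author: "metaboclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemocentric metabolite clustering and trait classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`metaboclust` implements a chemocentric workflow for case/control
untargeted metabolomics. The premise is that a single metabolite
association is fragile across cohorts — analytical batch effects and
normalization bias shift individual intensities — but a *group* of
chemically similar metabolites that are jointly associated with the trait
is both more credible biologically and more robust as a classifier. The
workflow therefore:

1. preprocesses intensity tables (non-detect imputation, total quantity
   normalization, log2 transform, covariate adjustment);
2. flags trait-associated metabolites by Monte Carlo permutation t-tests
   with Benjamini–Hochberg control;
3. clusters metabolites by chemical structure (MACCS fingerprints,
   correlated-bit filtering, Soergel distance, average linkage, with the
   number of clusters selected by average silhouette width);
4. tests clusters for enrichment of significant metabolites and of
   pathway members (one-sided Fisher exact and hypergeometric tests);
5. trains single- and multi-metabolite classifiers, tuned by grid search
   under leave-one-out cross-validation (LOOCV) with an ROC-derived
   probability threshold, and validates the frozen models on an external
   cohort.

# Data model and preprocessing

A `MetaboSet` extends `SummarizedExperiment`: the `"intensity"` assay
holds metabolites (rows) by samples (columns), `colData` holds the binary
trait label and covariates, and a state flag enforces the stage order
`raw -> imputed -> normalized -> logged -> (autoscaled |
covariate_adjusted)`. Calling a stage out of order is an error, which
prevents silent double-normalization or logging of already-logged data.

* **Half-minimum imputation** (`imputeHalfMin`). Missing cells are
  non-detects, not zeros: each is replaced by half the smallest observed
  intensity of that metabolite, the standard left-censoring assumption
  for mass-spectrometry detection limits. Empty cells and a configurable
  token (`"NA"`) are read as missing; zeros are detected values.
* **Total quantity normalization** (`totalQuantityNormalize`). Each
  sample is divided by its total signal. We multiply back by the mean
  sample total so values keep their original magnitude; this constant
  cancels after log2 and centering, so it affects display only. The
  operation is idempotent and equalizes all sample totals exactly.
* **Log2 transform** stabilizes multiplicative variance.
* **Auto-scaling** (`autoscale`) centers each metabolite and scales to
  unit standard deviation with the *n−1* denominator; zero-variance
  metabolites are centered only and flagged. Used for the
  between/within-group variance decomposition (`varianceDecomposition`,
  reporting BSS/(BSS+WSS)), which quantifies how much profile variance a
  grouping explains.
* **Covariate adjustment** (`covariateAdjust`) replaces every metabolite
  profile by the residuals of an OLS fit on an intercept plus the named
  covariates (gender, smoking history in the motivating design).
  Categorical covariates become 0/1 indicators with the first-seen level
  as reference; constant covariates are dropped with a warning; a
  rank-deficient design falls back to the least-norm fit with a warning.
  Adjustment operates on logged (not auto-scaled) values, matching the
  differential-analysis path.

Panel alignment (`alignDataset`) retains exactly the metabolites that
have a parsed chemical structure and are detected (non-missing in at
least one sample) in the table and in every companion cohort, so that
training and test cohorts share one metabolite panel. Metabolite ids are
the join key across intensity, structure and pathway files; matching is
exact after whitespace trimming.

# Differential analysis

Per metabolite, the two trait groups are compared with a Welch t
statistic on the covariate-adjusted residuals (a pooled-variance option
exists). Significance comes from label permutations: with `nPerm` random
relabelings, the two-sided Monte Carlo p-value uses the add-one
convention

$$p = \frac{1 + \#\{|t^\ast| \ge |t_{obs}|\}}{n_{perm} + 1},$$

which is always positive and a valid p-value. Two numerical points:

* permuted statistics are computed on the *sorted* pooled values with the
  smaller group permuted, so the realized Monte Carlo draw — and hence p —
  is invariant to swapping the group labels;
* each metabolite receives a fresh permutation set seeded reproducibly
  from the master seed, so Monte Carlo noise is independent across
  independent metabolites (sharing one set would correlate it).

Degenerate cases: zero variance with zero mean difference gives t = 0 and
p = 1; zero variance with a nonzero difference is treated as an infinite
statistic magnitude. Benjamini–Hochberg adjustment is applied across
metabolites and the `significant` flag uses the configured FDR, default
**0.075**. Defaults of `nPerm = 100000` match the motivating analysis;
the simulation studies in the test suite use 999 permutations to keep
desk-scale runtimes.

The displayed fold change is computed from back-transformed normalized
group means when a normalized table is supplied; inference always uses
the adjusted log-scale residuals.

# Chemical structure clustering

Structures enter as `metabolite_id` + SMILES (TSV) or SDF; parsing and
canonicalization use the OpenBabel backend (`ChemmineOB`). Unparseable
entries are collected in a rejects table rather than aborting, but must
be resolved before fingerprinting. Each metabolite is characterized by
its **166-key MACCS fingerprint**. OpenBabel stores MACCS in a 256-bit
container whose 1-based positions are the key numbers; positions 1–166
are retained (water sets exactly keys 139, hydroxyl, and 164, oxygen).

Before distances are computed, redundant keys are removed
(`filterCorrelatedBits`): constant columns first (Pearson r is undefined
on them), then a greedy scan in ascending key order drops any column
whose |r| with a previously retained column exceeds the cutoff (default
**0.9**), so the lower-numbered key of a violating pair survives. The
scan is deterministic and order-stable. The filter is fit once on the
full metabolite panel and reused for all downstream clusterings,
including the significant-metabolite subsets.

Dissimilarity is the **Soergel distance**, `1 − |b_i ∧ b_j| / |b_i ∨
b_j|` — one minus Tanimoto similarity, a true metric on binary vectors.
A pair of all-zero fingerprints gets distance 0 by convention (the 0/0
ratio is undefined). The structure-free alternative
(`correlationDistance`) is 1 − |Spearman ρ| of adjusted profiles, with
zero-variance profiles assigned correlation 0 (distance 1) and a warning.

Agglomeration is UPGMA (average linkage) implemented directly so the tie
rule is fully specified: at each step the pair of clusters with the
smallest average inter-cluster dissimilarity merges, and exact ties are
broken lexicographically by the smallest original member index of each
cluster. The number of clusters k is selected by maximizing the **average
silhouette width**

$$s(i) = \frac{b(i) - a(i)}{\max\{a(i), b(i)\}},$$

where a(i) is the mean distance to co-members and b(i) the smallest mean
distance to another cluster, evaluated at every k in `[2, n−1]` (ASW is
undefined at k = 1 and k = n); ties go to the smallest k. Items in
singleton clusters score s(i) = 0 — the standard convention, needed
because significant-metabolite clusterings routinely produce singletons.
Clusters of size ≥ 2 among the significant metabolites become the
candidate multi-metabolite bins; with fewer than three significant
metabolites an all-singleton assignment is returned with a warning.

# Enrichment tests

Per structure cluster, a one-sided (greater) Fisher exact test asks
whether metabolites inside the cluster are more likely to be
trait-significant than those outside; the identical contract with
"significant" replaced by "pathway member" tests pathway concentration
in clusters. Pathway over-representation among significant metabolites
uses the upper-tail hypergeometric p, `P(X ≥ k)` for X ~ Hypergeom(N, K,
n), after intersecting pathway membership with the analyzed panel.
Benjamini–Hochberg correction is applied within each test family (across
clusters; across pathways), with enrichment FDR default **0.05**. A
cluster covering the whole population gets p = 1 with a warning;
pathways without members in the population are skipped with a warning.

# Classifiers

Class labels are encoded case = 1, control = 0; sensitivity is case
recall. Single-metabolite models are logistic regressions fitted by IRLS
with a small ridge penalty (1e−8) so perfectly separable toy data keep
finite coefficients. Multi-metabolite models come in four families —
RBF-kernel SVM (`e1071`), PLS-DA (`mixOmics`), random forest
(`randomForest`) and gradient boosted trees (`xgboost`). Margin-based
families (SVM, PLS-DA) yield probabilities through a logistic link
fitted to their decision values within each training fold; random forest
and boosted trees emit probabilities directly. Default grids: SVM cost
{0.25, 0.5, 1, 2, 4} with the kernel width set by the median
squared-distance heuristic; PLS-DA components 1..min(5, p); random
forest 500 trees with mtry 1..p; boosted trees depth {1, 2, 3} ×
rounds {50, 150} at learning rate 0.3. All grids are configurable.

**LOOCV and threshold selection.** For each grid point, every sample is
predicted by a model trained on the remaining samples
(`loocvProbabilities`); the probability threshold is then chosen from
the out-of-fold probabilities to maximize accuracy
(`selectThreshold`), with candidates at the midpoints of adjacent sorted
unique probabilities plus guards below and above (so the constant
classifiers are always available); ties prefer higher specificity, then
the lower threshold. A sample is called a case when its probability is
greater than or equal to the threshold. AUC is the rank-based
Mann–Whitney statistic with ties counted half. The grid point with the
highest LOOCV accuracy wins (ties: first in declared order), the final
model is refitted on all training samples, and the *frozen* model and
threshold are applied unchanged to the external cohort
(`externalValidate`). Thresholds and hyperparameters are functions of
training data only.

The model suite (`buildModelSuite`) mirrors the comparison design: one
logistic model per significant metabolite, each requested family on each
multi-metabolite bin, and each family on two baselines (all metabolites;
all significant metabolites). `selectBest` picks by LOOCV accuracy with
ties resolved by internal AUC and then the smaller metabolite set —
external results are never consulted during selection.

The test cohort is preprocessed independently (its own totals for
normalization, its own covariate residualization), mirroring a genuinely
external study; whether to reuse training coefficients is configurable
in principle but the independent treatment is the default and the one
exercised throughout.

# The synthetic cohort generator

`simulateCohortPair` generates a train/test pair with the statistical
and chemical structure the pipeline assumes, so that every stage is
testable without external downloads. Per metabolite, log2 intensities
are normal with baseline mean Unif(10, 20) and SD log-uniform on
[0.3, 1]; planted signal metabolites receive a case-mean shift of
`effect` SDs with the planted sign; binary covariates (gender,
Bernoulli 0.5; smoking, Bernoulli 0.4) add a 0.5 log2-unit effect to a
random 30% of metabolites; values are exponentiated to the raw scale;
the test cohort is multiplied by a per-metabolite batch bias
2^N(0, 0.5); and non-detects are introduced by deleting a Binomial(n,
`missingRate`) count of each metabolite's lowest values — a
left-censoring mechanism chosen so half-minimum imputation behaves as
intended, and one that makes the realized missingness fraction exactly
binomial. All randomness flows from the single config seed.

Structures are drawn without replacement from a bundled library of 40
named metabolites with real SMILES in seven families (amino acids,
mono- and di-saccharides, organic acids, purine and pyrimidine
nucleosides, fatty acids); generated ids encode the family so
clusterings can be scored against ground truth. The default study
conditions are 40 cases and 40 controls per cohort over the full
library, with signal planted in the two chemically tightest families —
five fatty acids shifted up and four disaccharides shifted down by 2
SDs, mixed directions as real volcano plots show — and 5% non-detects.

What the generator does *not* emulate: retention-time drift, correlated
(co-eluting) noise between metabolites, annotation ambiguity, non-normal
intensity distributions, or missingness that depends on the trait.
Passing recovery tests on these simulations therefore shows the
pipeline's statistical machinery is sound under its own assumptions, not
that any particular real-data finding will replicate.

# Numerical choices and edge cases

* Permutation p-values can never be 0 (add-one convention); the smallest
  attainable is 1/(nPerm + 1).
* The preprocessing state machine rejects out-of-order stages rather
  than warning.
* Correlated-bit filtering removes constant columns before the greedy
  scan, and errors only if *everything* is constant.
* UPGMA uses the exact weighted (Lance–Williams) average so cluster
  distances equal the mean over original member pairs; merge heights are
  monotone for a metric input.
* Silhouette: s(i) = 0 for singletons and when a(i) = b(i) = 0.
* Ridge 1e−8 in logistic IRLS; the Platt-style link uses 1e−6 (decision
  values can be large and nearly collinear with the labels).
* Threshold candidates are clamped to (0, 1) open-interval guards
  (1e−12), so a stored threshold is always a usable probability cutoff.
* All writers serialize doubles at 17 significant digits; write→read
  round trips are value-identical, and written tables carry their
  processing state in a comment line.

# Simulation sizes used by the checks

The packaged statistical checks run at desk scale, sized to finish in
minutes while keeping Monte Carlo error useful: calibration uses 25 null
cohort pairs (1000 metabolite tests) at 999 permutations; FDR control
uses 50 null simulations; family recovery uses 50 seeded simulations of
the default planted-signal conditions; the external-superiority
experiment uses 25 seeds with the PLS-DA family on an ncomp {1, 2} grid
(the cheapest family that exercises the full multi-metabolite path).

# Known limitations

* OpenBabel's MACCS SMARTS definitions differ in detail from other
  toolkits' (e.g. RDKit's); fingerprints are internally consistent but
  not bit-for-bit portable across backends.
* Family-level cluster recovery is limited by fingerprint resolution:
  within a real chemical family MACCS often resolves sub-blocks
  (saturated vs unsaturated fatty acids; sucrose vs reducing
  disaccharides), and ASW maximization will legitimately split them —
  exact family recovery fails in a small fraction of simulation draws
  for this reason, which is a property of the method, not a defect of
  the implementation.
* Total quantity normalization propagates strong planted (or real)
  shifts into other metabolites, inflating the significant set beyond
  the truly associated one; the workflow's cluster-enrichment stage is
  precisely the guard against over-reading such spurious singles.
* With ~10–20 significant metabolites the ASW-selected k is variable;
  the multi-metabolite bins should be read as candidate panels, not
  definitive chemical classes.
* Logistic single-metabolite models are intentionally unpenalized in
  effect (ridge 1e−8): they are the paper-faithful baseline, not a
  regularized competitor.
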