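---
title: "Scoring the bioactive potential of a metabolome: models, choices and limits"
author: "MetaboBiP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the bioactive potential of a metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Untargeted metabolomics quantifies hundreds of annotated small molecules
per subject, but offers no direct handle on which of them could act on a
biological target. MetaboBiP ranks metabolites by *predicted* bioactivity:
QSAR classifiers are trained on a public screening library against
nuclear-receptor (NR) and stress-response (SR) cell-line endpoints, the
reliable classifiers are applied to the metabolite structures, and the
predicted activity is combined with the measured abundance into a
*bioactive potential* that can be tested against a clinical outcome such
as hs-CRP, a marker of systemic low-grade inflammation.

The pipeline has five stages, each exposed as package functions:

1. structure curation (`standardizeStructures`, `deduplicateCompounds`,
   `featurizeCompounds`),
2. endpoint dataset assembly and splitting (`assembleEndpoint`,
   `splitTrainTest`),
3. per-endpoint classifier training and gating (`trainEndpointModel`,
   `selectFeaturesPermutation`, `gateModels`),
4. metabolome cleaning and scoring (`prepareMetabolitePanel`,
   `predictProbabilities`, `activeMask`, `sbipTable`),
5. association testing (`preparePredictors`, `prepareOutcome`,
   `fitAssociation`).

## Structure curation

Raw structures arrive as SMILES (or SDF) and pass through twelve
standardization steps in a fixed order: explicit-hydrogen removal,
dearomatization, pi-metal bond conversion, metal disconnection, salt
stripping, fragment removal, diazonium transformation, neutralization,
wedge clean, mesomer/tautomer normalization, aromatization and 2D clean.
OpenBabel performs parsing, Kekulization, neutralization
(`--neutralize`), canonical-tautomer normalization (`obtautomer`) and the
final canonical aromatic SMILES; metal disconnection (single-bonded
alkali metals to O/S) and diazonium spelling normalization are applied on
the SMILES fragments in-package. Wedge clean and 2D clean act on
depictions, not on connectivity, so for SMILES input they are recorded as
no-ops. Steps that alter a structure leave a flag
(`salt_stripped`, `neutralized`, ...) in the curation report.

Two design rules make curation deterministic:

* salt/fragment stripping keeps the largest *organic* fragment by heavy
  atom count, ties broken by molecular weight and then lexicographically;
* among identifier duplicates of one canonical structure, the
  lexicographically smallest identifier survives; label conflicts between
  structural duplicates are resolved later, during endpoint assembly, by
  dropping the conflicted structure entirely (the conservative choice).

Standardization is idempotent: re-standardizing a canonical structure
returns it unchanged, which the test suite asserts on generated
libraries.

### Feature schemes

* `circular_fingerprint` — a radius-2 circular (Morgan-type)
  substructure fingerprint hashed to **5120 bits**. The wide fold reduces
  bit collisions. It is computed in-package on the molecular graph: atom
  invariants are (atomic number, heavy degree, formal charge, bond-order
  sum), neighborhood identifiers are rehashed order-invariantly per
  radius, and all identifiers of radius 0–2 set bits modulo 5120. Two
  spellings of one molecule therefore always give identical vectors.
* `structural_keys` — the 166 MACCS keys, via OpenBabel's SMARTS
  dictionary.
* `descriptors` — a fixed panel of exactly **200 numeric descriptors**:
  nine OpenBabel physicochemical properties (MW, exact mass, logP, TPSA,
  molar refractivity, H-bond donors/acceptors), global graph statistics
  (atoms, bonds, rings, degrees, charges), element counts, bond counts by
  element-class pair and bond order, 24 SMARTS functional-group counts,
  32 hashed radius-1 environment counts, and six composition ratios.
  Non-finite values are imputed as 0 and logged, keeping the matrix
  rectangular. The panel is the package's own; its size matches the
  convention of using ~200 descriptors for random-forest QSAR.

## Endpoint datasets and the split

Assay records carry one binary label per compound and endpoint (twelve
endpoints: seven NR, five SR). Assembly drops missing labels and invalid
structures, collapses agreeing structural duplicates and removes
conflicting ones, and reports the imbalance ratio N(1)/N(0,1) per
endpoint — the positives range from ~3% to ~16% in screening data of this
kind.

The 80/20 train/test split is random but **stratified by label**
(per class, `floor(0.8 * n_class)` compounds go to train). With 3–15%
positives an unstratified 20% test set can be degenerate, which would
make the MCC undefined; stratification is therefore used for the split
and for the cross-validation folds. Identical seeds reproduce identical
splits.

## Training: MCC-penalized random forests

The Matthews correlation coefficient,

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

is the training penalty and the model-selection statistic; balanced
accuracy $\tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right)$ is
reported alongside. A zero denominator (degenerate predictor) maps to
MCC = 0, the standard convention that keeps the optimization objective
finite. Both metrics are verified against brute-force recomputation from
raw label/prediction vectors (for binary vectors the MCC equals their
Pearson correlation, which serves as an independent oracle).

Hyperparameters of a random forest are tuned by Bayesian optimization:
20 evaluations, each scored by the mean MCC over 10 stratified CV folds
on the training partition. The search space is trees 100–1000, maximum
depth 3–20 or unlimited, minimum node size 1–10, feature subsampling
(sqrt, log2, or a 0.1–1.0 fraction), and class weighting — one of
`none`, `balanced` (inverse class frequency) or `balanced_sqrt`
(square-root-damped inverse frequency). Class weighting is essential on
imbalanced endpoints. The optimizer uses a Latin-hypercube initial
design, a Gaussian-process surrogate with a fixed kernel width, and
expected improvement over a seeded candidate pool; the loop is written
in-package because no Bayesian-optimization package is among the
dependencies, and it is fully deterministic given the seed. When both the
fingerprint and the descriptor representation are requested the two are
optimized independently and the better cross-validated MCC wins.

After refitting the best configuration, one round of
permutation-importance feature selection runs on the training partition:
10 seeded permutations per feature, scored by the drop in training MCC;
features with mean importance strictly above zero are kept and the model
is refit. On noise-free, perfectly separable data permutation importance
can be degenerate — redundant features back each other up and every
importance is exactly zero; in that case the single best feature by the
forest's impurity importance is kept, with a warning. Constant feature
columns are removed before optimization.

Models are **gated** for downstream use only if both the cross-validated
and the test MCC strictly exceed 0.30 — above the "fair agreement"
regime, suppressing classifiers that could look acceptable through
imbalance alone. Gating is monotone: raising a threshold never admits an
endpoint.

## Metabolome cleaning

The subjects x metabolites relative-peak-area table passes five steps in
the printed order:

1. metabolites with **more than 33%** missing values are removed (exactly
   33% is kept — the boundary is strict);
2. remaining missing cells are imputed with **1/10 of the per-metabolite
   observed minimum** (a detection-limit assumption); the minimum is
   taken after the missingness filter;
3. min–max scaling to [0, 1] per metabolite; constant metabolites map
   to 0;
4. the `floor(0.1 * m)` metabolites with the smallest variance are
   dropped (ties by name order);
5. pairs with |Pearson r| > 0.90 are pruned greedily: the most
   correlated pair first, dropping the member with the larger mean
   absolute correlation to the remaining metabolites (ties:
   lexicographically larger name).

Each step is a pure function; subjects are never dropped. Note that the
variance filter is a *decile count* filter: re-running the full pipeline
on its own output removes a further decile whenever at least 10
metabolites remain, so the pipeline is meant to run once. (For panels
that leave fewer than 10 metabolites, `floor` makes the second pass a
no-op and the pipeline is exactly idempotent, which the tests assert.)

## Bioactive potential

For metabolite $i$, gated endpoint $t$ and a subject, with scaled
abundance $c_i \in [0,1]$ and predicted activity probability $p_t$:

$$\mathrm{BiP}_{i,t} = c_i \, p_t, \qquad
\mathrm{sBiP}_{i} = \log_{10}\Bigl(\sum_{t=1}^{T} \mathrm{BiP}_{i,t}\Bigr).$$

Probabilities are the random forest's class-1 vote fraction, without
recalibration. A metabolite enters the *active mask* when at least one
probability is strictly above 0.5; sBiP is computed only for masked
metabolites, but the sum runs over **all** gated endpoints (sub-threshold
probabilities are not zeroed). The mask depends only on structures, never
on abundances.

**Flooring.** Min–max scaling maps each metabolite's minimum — typically
exactly the detection-limit-imputed cells — to 0, so zero BiP sums are
unavoidable and the logarithm needs a floor. `computeSbip` floors a zero
sum at a configurable $\varepsilon$ (default $10^{-6}$, giving exactly
−6). At the table level (`sbipTable`) an absolute floor would place
censored cells ~5 decades below the observed sBiP range (roughly
[−1.5, 0]); such leverage points dominate the variance of a regression
predictor and can mask real associations, and an absolute floor also
breaks scale equivariance. `sbipTable` therefore floors zero sums at
**1/10 of the metabolite's smallest positive BiP sum** — the same
detection-limit convention the abundance imputation uses — with
$\varepsilon$ only as a fallback when no positive sum exists. This keeps
censored subjects one decade below the observed range and preserves the
equivariance property (abundances × k shift every sBiP by log10 k),
which the tests verify. The sensitivity of sBiP to the flooring
convention is a genuine limitation of the log-sum score and is inherited
by any analysis downstream.

## Association with the outcome

The sBiP table (subjects x masked metabolites) is column-standardized
and decorrelated with the same greedy rule and the same 0.90 threshold
as the panel cleaning (the threshold at this stage is a package choice).
The outcome (hs-CRP, ng/mL) has missing values imputed with the median
of the observed values on the raw scale and is then log-transformed
(natural log; the base only rescales coefficients). One **joint**
ordinary-least-squares regression of the log outcome on all predictors
plus intercept is fitted — not per-metabolite marginal regressions — and
two-sided t-test p-values are reported. The significance report filters
at p < 0.001, a deliberately strict level given the number of
predictors; the full coefficient table is always emitted alongside.
Rank-deficient predictor matrices are refused with the collinear columns
named. Coefficients are verified against the closed-form normal
equations to 1e-8, and the type-I error at the 0.001 level is checked by
a 200-replicate null simulation.

## The synthetic study

Because the cohort data behind the original analyses are not
distributable, the package ships seeded generators that emulate the two
data types and make every stage testable.

**Library** (`syntheticLibrary`): ~20 small organic scaffolds with up to
three decoration sites are decorated from a fragment pool; a compound is
active if and only if it carries the planted substructure — by default a
sulfonamide, S(=O)(=O)N, chosen because it passes all twelve
standardization steps unchanged and has a crisp fingerprint/descriptor
signature. Labels may be flipped with a configurable noise probability.
The positive fraction (default 10%, matching screening-library
imbalance) is met exactly by construction over unique canonical
structures. An independent SMARTS matcher reproduces the noise-free
labels exactly in the tests.

**Cohort** (`syntheticCohort`): abundances are log-normal within
correlated blocks of six metabolites (latent within-block r = 0.6);
per-metabolite location log(1e4)–log(1e6) and log-scale dispersion
0.4–1.0 give realistically skewed relative peak areas. 12 of 60
metabolites carry the planted substructure and are spread across the
panel so that planted outcome effects (defaults +0.6, −0.6, +0.5 per
standardized latent abundance, on three substructure-bearing metabolites
in distinct blocks) do not share a correlation block. Planted
metabolites get moderate dispersion (0.45–0.65), emulating robustly
quantified biomarkers — a metabolite with an extreme upper tail is
squashed by min–max scaling into the lowest variance decile and would be
removed by the cleaning, which would make a "planted" effect an artifact
of the generator rather than a recoverable signal. The outcome is
exp(intercept + effects + N(0, 0.5)), so the pipeline's log transform
and median imputation are exercised on the measurement scale; 5% of
outcome values are missing. Missingness in the panel is completely at
random at 2% — matching the near-complete observation of annotated
serum metabolites that survive a 33% missingness filter — with a
left-censored variant behind `censoredMissingness = TRUE` for stress
testing the detection-limit imputation. 10% of metabolites are left
unannotated and are carried through cleaning but excluded from scoring.

What passing the synthetic study shows — and what it does not: the
generators exercise imbalance, skew, block correlation, missingness and
label noise, but real screening data add assay noise and chemistry far
from the training domain, and real metabolomes add batch effects,
abundance-dependent missingness and annotation errors. Recovery of
planted effects demonstrates the pipeline's internal correctness, not
clinical validity.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the study at 2000
compounds (10% positive, noise-free), one endpoint, 20 optimization
iterations with 10-fold CV on the descriptor representation, and five
cohorts of 500 subjects x 60 metabolites; these sizes keep a complete
run in the tens of minutes on a single core while leaving all planted
signals comfortably recoverable. The dual fingerprint-vs-descriptor
comparison is exercised at smaller size in the unit tests. Further
numerical conventions, in one place:

* MCC zero-denominator convention: 0; balanced accuracy with an absent
  class: an error.
* All randomness flows from one run-level seed through `childSeed`
  (deterministic 32-bit fan-out per consumer); ranger runs
  single-threaded with a fixed seed.
* Correlation pruning tie-breaks: drop the lexicographically larger
  name; variance-filter ties: name order.
* Descriptor non-finite values: imputed as 0, logged.
* sBiP flooring: see above.
* The decorrelation threshold of the association stage reuses 0.90.

## Known limitations

* OpenBabel's canonical forms differ from other toolkits'; dataset
  counts after curation of a public archive can differ marginally from
  counts produced with proprietary standardizers. The ingest machinery
  reports its own counts per endpoint for comparison.
* The tautomer normalization is OpenBabel's canonical tautomer; no
  custom mesomer rules are applied. Metal disconnection covers
  single-bonded alkali metal-O/S motifs; organometallics are out of
  scope.
* Applicability-domain estimation is not implemented: probabilities for
  structures far from the training chemistry are extrapolations.
* The log-sum sBiP is sensitive to its flooring convention for censored
  (scaled-zero) cells, as discussed above.
* The association model is a single OLS fit without covariates, mixed
  effects or multiplicity correction beyond the strict 0.001 filter.
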