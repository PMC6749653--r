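---
title: "Methods: QSAR modeling of aqueous pKa with pkaqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR modeling of aqueous pKa with pkaqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The acid dissociation constant, expressed as pKa, controls the ionization
state of a chemical at a given pH and with it solubility, membrane
permeability, protein binding and environmental fate. Experimental pKa
collections are heterogeneous: one chemical may appear several times with
diverging values, as a salt or solvate, as one component of a mixture, or
in different tautomeric drawings. `pkaqsar` implements a complete
workflow for turning such a collection into quantitative
structure-activity relationship (QSAR) models of the *strongest acidic*
(minimum) and *strongest basic* (maximum) macroscopic pKa, together with
the routing, reliability-estimation and benchmarking machinery a
deployed predictor needs.

The pipeline mirrors the architecture used by open QSAR suites: a
three-class categorical model decides whether a query is acidic, basic or
amphoteric; separate regressors predict the acidic and basic pKa; every
prediction carries applicability-domain (AD) indices and an accuracy
estimate derived from its nearest training neighbours.

## Curation model

`standardize_structures()` maps a raw SMILES to a *QSAR-ready parent*:

* The input is split into components. Components without carbon
  (counterions, water, inorganic acids) are stripped. A short allow-list
  of solvents and organic counterions (ethanol, methanol, acetone,
  acetonitrile, DMSO, THF, ethers, chlorinated solvents, tosylate,
  mesylate, trifluoroacetate, oxalate, maleate) is stripped only when
  another organic component remains, so a lone solvent molecule is still
  a valid parent.
* Inputs with two or more distinct organic components after stripping
  are rejected as mixtures; carbon-free inputs as inorganic; inputs
  whose organics were all allow-listed as empty-after-stripping.
* The surviving parent is charge-neutralized when its net formal charge
  (read from the InChI charge and protonation layers) is non-zero.
  Zwitterions have net charge zero and are deliberately left unmodified.
* Nitro mesomers are rewritten to the charge-separated form, and
  *terminal* enols (CH2=C(OH)R) are rewritten to their carbonyl
  tautomer. The structure key is the standard InChIKey of the final
  parent; because InChI normalization itself unifies nitro mesomers and
  protomers, deduplication is robust even where the SMILES differ.

The tautomer rule set is deliberately narrow. General tautomer
canonicalization is an open problem and every toolkit draws the line
differently; we normalize the two families that commonly cause
duplicate records (nitro drawings, simple enols) and document that
internal enols and heteroaromatic N-H tautomers are *not* merged. This
is the main place where curated set sizes can deviate between toolkits.

Replicate handling follows three policies, applied per class after
grouping records by structure key (`group_replicates()`; sample SD,
n-1 denominator — the estimator choice is ours, made once):

* **Option 1** admits only groups whose present classes are singletons.
* **Option 2** additionally admits replicate groups with per-class
  SD < 2 pKa units, entering their mean (all replicates are averaged;
  no outlier pre-filtering — a decision we made once where the
  procedure was ambiguous).
* **Option 3** admits every group: mean when SD <= 1, otherwise the
  strongest value (minimum acidic, maximum basic).

For Options 1-2 a combined set is built from the non-amphoteric
admitted groups. The inequalities are strict/inclusive exactly as
stated (`< 2`, `<= 1`); values at the boundary therefore fall to the
strongest-value rule in Option 3.

`split_train_test()` stratifies on 1-pKa-unit bins crossed with the
replicate and amphoteric flags (and class, for combined sets), then
allocates within each stratum by a seeded shuffle with largest-remainder
rounding, so the overall 75/25 split is exact and both sets sample every
region of the pKa distribution.

## Featurization

`compute_features()` produces named, family-prefixed columns through
OpenBabel: ~19 continuous 1D/2D descriptors (`desc_`: MW, logP, TPSA,
molar refractivity, H-bond donor/acceptor counts, element counts, ring
and aromaticity measures), MACCS keys (166 bits), the FP2 path
fingerprint (1024 bits), FP3/FP4 SMARTS-key fingerprints, a curated
30-pattern SMARTS fragment-count table (`frag_`), and topological
atom-pair counts (`ap_<elem>_<elem>_<distance>`, distances 1-6 by BFS
on the heavy-atom graph). Continuous columns containing any missing
value are dropped; structures that fail featurization are excluded and
reported. Column parity with any other descriptor engine is explicitly
not promised; models and their published-scale performance therefore
transfer only approximately.

`reduce_features()` implements a nested reduction ladder: D1 removes
constant columns, D2 additionally removes one of every pair with
|Pearson r| >= 0.95 (keep-first scan order), D3 additionally removes
columns with variance < 0.01. The two thresholds are package defaults
chosen once at conventional values. `fit_scaling()`/`apply_scaling()`
min-max scale training columns to [-1, 1]; zero-range columns map to 0
and test rows may legitimately fall outside the interval.

## Descriptor selection and routing

`ga_select()` evolves binary chromosomes over the continuous
descriptors to maximize fivefold cross-validated multiclass balanced
accuracy (mean of per-class recalls) of a kNN classifier restricted to
the selected columns. Defaults: population 100, 200 generations,
tournament selection (size 3), one-point crossover at 0.8, per-bit
mutation at 1/n, single elitism, and a soft penalty of 0.001 per
selected descriptor that biases toward compact subsets. The CV folds
are fixed before the run and shared by all chromosomes so fitness
comparisons are paired; with elitism the best penalized fitness is
non-decreasing by construction. On pools of up to ~12 features the GA
provably reaches the exhaustive-search optimum on the same folds (this
is a test invariant, not an asymptotic claim).

`fit_router()` is the three-class kNN router: z-scored descriptors,
Euclidean distance, majority vote, ties broken by the class of the
single nearest neighbour (distance ties by lowest row index, making the
router invariant to training-row permutations). `k` defaults to
cross-validated selection over {1, 3, 5, 7, 9}. `is_ionizable()` gates
the whole flow: pKa is only predicted for structures with at least one
hydrogen-bond donor or acceptor site (Lipinski-style OpenBabel typing);
methane-like inputs are reported non-ionizable with no pKa.

## Regression branches

Acidic and basic pKa are always modeled separately. All three branches
consume the same split labels and the same fold maker, so comparisons
between branches are paired.

* **SVM** (`train_svm()`): LibSVM epsilon-regression with an RBF
  kernel via e1071; cost, gamma and epsilon tuned by grid search on
  fivefold-CV RMSE (defaults cost 2^-2..2^10, gamma 2^-10..2^2,
  epsilon {0.01, 0.1, 0.5}). Q2 is computed from the winning
  combination's out-of-fold predictions, never from resubstitution.
* **XGB** (`train_xgb()`): gradient boosting via xgboost, boosted
  linear model by default with an L1/L2 grid, tuned on fivefold CV
  repeated five times; variable importances are exposed.
* **Neural network** (`train_dnn()`): a feed-forward multilayer
  perceptron implemented in the package on base matrix operations —
  three hidden layers (256 units each by default), each followed by
  batch normalization and dropout (rate 0.25), ReLU activations, a
  single linear output, mean-squared-error loss, Adam updates, seeded
  He-normal initialization, mini-batches of 32, and early stopping on
  an internal validation split (patience 20, at most 500 epochs). The
  learning rate is selected from {1e-2, 1e-3, 1e-4} by fivefold-CV
  RMSE using shortened tuning runs. Inference uses running batch-norm
  statistics and no dropout, so predictions are deterministic functions
  of the stored weights; identical data and seed give identical models.

`compute_metrics()` defines RMSE and the coefficient of determination
about the observed mean; with out-of-fold predictions the same formula
is the cross-validated Q2.

## Applicability domain

The global AD is the classical leverage approach: on the centered
training design, h = x (X'X)^-1 x', with a query inside the domain when
h <= h* = 3 p / n (the conventional multiplier; the effective dimension
p is the design rank). When columns outnumber rows the design is first
projected onto principal components retaining 95% of variance, and a
pseudo-inverse backs up an ill-conditioned X'X. Training leverages sum
to p, which the tests verify on hand-computable designs.

The local AD is the mean Jaccard-Tanimoto similarity (|intersection| /
|union| of on-bits; two empty fingerprints count as identical) of the
k = 5 most similar training fingerprints. The per-prediction accuracy
estimate is the similarity-weighted mean absolute residual
(experimental minus predicted) of those neighbours, in pKa units. The
upstream AD framework this mirrors does not publish its exact accuracy
formula, so this estimator is a documented stand-in with the same
contract (continuous, [0, 1] index; residual-based error estimate;
neighbours reported with similarities and experimental values).

## Concordance benchmarking

`pairwise_concordance()` joins two prediction tables on the structure
key and splits the common chemicals into pairs agreeing within a
threshold (default +/-2 pKa units; |delta| exactly 2 counts as
concordant) and pairs beyond it, reporting R2 (first table as
reference), squared Pearson correlation and RMSE.
`build_benchmark()` averages the concordant pair values into a
benchmark table; `range_filter()` restricts a table to a pKa window
(e.g. [0, 14] acidic, [-2, 12] basic, the ranges typically covered by
experimental collections); `bootstrap_ci()` attaches percentile
bootstrap confidence intervals (5000 paired resamples by default,
seeded; the percentile flavour, not BCa, is a package choice made
once). Resamples on which a metric is undefined are redrawn and
counted.

## The synthetic study set

`generate_fixture()` fabricates record collections with the statistical
structure the pipeline assumes, so every stage is testable without any
external download. Structures are drawn from a ~700-member pool built
from 11 templates (benzoic acids, phenols, sulfonamides, aliphatic
acids, amines, anilines, pyridines, imidazoles, amino acids,
aminophenols, anthranilic acids) with up to two ring decorations or a
chain length. A deliberately simple additive group-contribution oracle
(`oracle_pka()`) assigns ground truth: template base value, decoration
effects with electron-withdrawing groups lowering pKa (second site at
60% weight), +0.04 per chain carbon, clamped to [0, 14] acidic and
[-2, 12] basic. Records add Gaussian noise (0.4 pKa units by default),
replicate groups realize their SD band *exactly* (low < 1, mid 1-2,
high > 2 — drawn from bands that avoid the option-rule boundaries),
and salts, mixtures and inorganics are injected in known numbers.

Default composition (25% amphoteric structures, 75% singleton
measurements, mostly sub-unit replicate SDs, ~8% salt records, ~3%
mixtures and inorganics each) was chosen once to mirror the shape of a
typical curated experimental pKa collection. What the fixture does
*not* emulate: real descriptor-activity relationships (the oracle is
additive by construction, so models recover it far more easily than
they recover experimental pKa), structural diversity beyond the
template families, measurement-method biases, and tautomeric ambiguity
beyond the standardizer's rule set. Passing fixture-scale tests
therefore demonstrates correctness of the machinery, not
chemical-space-scale accuracy; published-scale performance checks
require the original curated collection, which is not redistributable
with the package.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at
fixture scale — 150-250 structures, compact hyperparameter grids, a
64-unit three-layer network, GA populations of ~24 over ~15
generations — sizes we chose so the whole suite completes in minutes
while still exercising every code path, including GA-vs-exhaustive and
kNN-vs-brute-force oracle equivalences at sizes where enumeration is
exact. Degenerate inputs are handled explicitly: constant targets and
single-class training sets raise errors; zero-range scaling columns map
to 0; all-zero fingerprints compare as identical; rank-deficient
designs fall back to pseudo-inverses; distance and similarity ties
break toward the lowest row index so results are order-invariant.

## Known limitations

* Only macroscopic strongest-acidic/strongest-basic values are modeled;
  no per-site microscopic pKa, no protonation-state enumeration.
* Tautomer normalization covers nitro mesomers and terminal enols only.
* The descriptor stack is OpenBabel-based; models trained here are not
  numerically interchangeable with stacks built on other engines.
* The MLP is CPU-sized; very wide feature sets train slowly in pure R.
* The local-AD accuracy estimate is a documented stand-in for an
  unpublished upstream formula.
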