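---
title: "Similarity-augmented QSAR modeling with rasarstack: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-augmented QSAR modeling with rasarstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasarstack)
```

## The modeling problem

`rasarstack` builds regression and classification models of acute aquatic
toxicity, expressed as pLC50 = −log10 of the median lethal concentration in
mol/L, from 2D molecular structure. The workflow it implements is the
similarity-augmented QSAR ("q-RASAR") pipeline used for multispecies salmon
ecotoxicity modeling: a conventional descriptor-based QSAR model is enriched
with read-across information (statistics of each compound's most similar
training neighbours), condensed through ARKA supervised dimensionality
reduction, recombined in a hybrid model, and finally stacked into a
one-latent-variable PLS meta-model whose inputs are the four base models'
predictions. Every stage is exposed as an ordinary function returning a
classed S3 object with `print`, `coef`, `predict` and related methods, so the
pipeline can be rearranged or truncated at will.

## Data input and curation

Toxicity records arrive as CSV (columns `id`, `smiles`, optionally `name`,
`lc50_mgL`, `plc50`, `mol_weight`, `species`), one-per-line SMILES, or V2000
SDF. Structures are parsed by OpenBabel (via ChemmineOB); the package reads
OpenBabel's kekulized connection tables directly so that single-atom
molecules (e.g. methane, a unit-test staple) survive the round trip.
Curation applies, in order:

1. **Unparseable structures** are removed and reported, never silently dropped.
2. **Metal-containing structures** — any element outside
   {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I} — are removed. The organic
   element set is a design choice: the source protocol says only "removing
   the salts and metals" without enumerating elements.
3. **Multi-fragment structures** (salts, mixtures) are removed whole rather
   than desalted, matching a removal (not neutralization) protocol.
4. **LC50 conversion**: records with `lc50_mgL` gain
   `pLC50 = −log10(lc50 / (1000 · MW))`, molecular weight computed from the
   structure when absent. Records carrying both representations are checked
   for consistency to 1e−6 and flagged on disagreement.
5. **Duplicates** (same canonical SMILES) whose pLC50 range is at most
   `duplicate_merge_max_range` (default 1.0 log unit) merge into one record
   with the arithmetic-mean pLC50; wider groups are all retained and flagged
   for manual review. The 1.0 log-unit default quantifies "numerical values
   close to each other", which the protocol leaves unspecified; it is a
   policy parameter, not a constant.

Curation is idempotent, and a write/read round trip preserves ids, canonical
SMILES and pLC50 to 1e−9.

## The six structural descriptors

Only the six descriptors entering the published salmon equations are
computed (the full commercial 0–2D descriptor pool is out of scope):

* **H-053** — count of hydrogen atoms on an sp3 carbon that itself bears only
  C/H neighbours while its neighbouring carbons carry exactly two halogen
  substituents in total. Two readings of the original atom-centred-fragment
  scheme exist ("X" = halogen vs any heteroatom); the halogen reading is the
  default and `x_is_heteroatom = TRUE` selects the other.
  "Exactly two" (not "at least two") follows fragment semantics.
* **NsssCH** — E-state atom-type count: carbons with one hydrogen and three
  single bonds to heavy atoms.
* **B02[N-N]**, **B02[S-S]**, **B03[N-O]** — binary 2D atom-pair descriptors:
  1 iff two atoms of the stated elements sit at topological distance exactly
  2 (or 3) on the heavy-atom graph. Binary presence/absence (not a count) is
  forced by the "B" atom-pair semantics.
* **LOGP99** — the Wildman–Crippen (1999) atom-contribution octanol/water
  logP, delegated to OpenBabel's implementation of the published scheme.

Distances are shortest-path bond counts on the heavy-atom graph (hydrogens
excluded); aromatic perception and kekulization are OpenBabel's standard
model. All six descriptors are invariant under SMILES atom reordering, and
the binary descriptors are verified in the test suite against a brute-force
double loop over atom pairs and against independent (igraph) shortest paths.

## Pretreatment, division and feature selection

`pretreat()` removes near-constant columns (variance < 1e−4) and then breaks
inter-correlated pairs (|r| > 0.95), dropping from each pair the column with
the larger mean absolute correlation to everything else — the tie-break is a
package convention, since the original tooling names only the thresholds.

`split_data()` implements four division schemes. The activity-based scheme
sorts by response and strides every k-th compound (k = round(1/test
fraction)) into the test set with the response extremes forced into
training; on 106 compounds at test fraction 26/106 this yields the 80/26
pattern of the original study. Kennard–Stone is the classical max–min
algorithm on standardized descriptors; the Euclidean scheme strides the
distance-to-centroid ranking; the k-medoid scheme is plain PAM
(`cluster::pam`) with one test compound drawn per cluster in rotation — the
"modified" k-medoid variant of the original workflow is unspecified, so
standard PAM is implemented and labelled as such.

Feature selection offers exhaustive best-subset search (`best_subset_selection`,
OLS per combination, ranked by leave-one-out Q² computed through the hat
matrix, ties by LOO MAE; capped at 200,000 fits) and a genetic algorithm
(`genetic_selection`) with fixed-length chromosomes, tournament selection,
one-point crossover, per-gene mutation and single-member elitism, so the
best fitness trace is non-decreasing. GA defaults (population 100,
generations 100, crossover 0.8, mutation 0.05) are package choices; the
original protocol fixes only the chromosome length (6) and, for
classification, the MCC fitness.

## Read-across and the RASAR block

Read-across predicts a query as the similarity-weighted mean of its
`n_close` most similar training compounds, with distances measured on
z-scored descriptors (training statistics only). Three similarity kernels
are provided; the source names the kernels without printing formulas, so
the conventional forms are used:

* Gaussian: s = exp(−d²/2σ²)
* Laplacian: s = exp(−d/γ)
* Euclidean-distance similarity: s = 1/(1+d)

All equal 1 iff d = 0 and decrease strictly in d. Ties in similarity break
toward the lower source id; sources with similarity below 1e−12 are dropped
as numerical dust; a training query always excludes itself from its own
sources, making training-set read-across a leave-one-out quantity. Whether
the original tool weights the close-source mean by similarity is not
documented; the weighted mean is the default and `weighted = FALSE` gives
the plain mean. Hyperparameters are optimized on a 75/25 activity-based
sub-split of the training set by sub-test RMSE (ties: higher Q²F1, then
fewer close sources); the default grid (σ, γ ∈ {0.5, …, 3}, n_close 2–10,
all kernels) contains the published optimum (Gaussian, σ = 2, 10 sources).

The RASAR block condenses each query's close-source neighbourhood into 18
named descriptors: the read-across prediction itself, similarity mean / SD /
CV, source-response SD / CV / standard error, class-conditional similarity
maxima and means (classes from thresholding the training response at its
mean), the Banerjee–Roy coefficients sm1 = MaxPos − MaxNeg and
sm2 = PosAvg − NegAvg, the concordance bit gm = 1 iff the most similar class
is active, its composites gm·AvgSim and gm·SDSim, and the active fraction.
The original tool's exact 18-descriptor composition is not published; this
set reconstructs the five descriptors named in the published equations plus
the standard similarity/error measures of the RASAR literature, and every
column is exported by name so any subset can be selected downstream. When a
close-source set contains only one class, the conditional columns are 0 and
the row is flagged. "Data fusion" (`fuse`) is column-wise concatenation of
the QSAR and RASAR blocks with id checking.

## ARKA supervised reduction

ARKA (arithmetic residuals in K-groups analysis, K = 2) is described
conceptually but not algebraically in its source; the implementation here is
the construction that reproduces every stated property. Training compounds
are classed by thresholding the response at the training mean. Each
z-scored descriptor joins group G1 if its mean z over actives exceeds that
over inactives, else G2 (ties to G2). ARKA_1 and ARKA_2 are the per-compound
means of the z-scores over G1 and G2. Consequences, all asserted in tests:
actives average positive ARKA_1 and negative ARKA_2 by construction;
duplicating a descriptor changes nothing; scores of a compound at the
training means are (0, 0); and the two-descriptor OLS model fitted on ARKA
scores has its intercept at the training response mean — matching the
published ARKA equation, whose intercept equals the reported training-mean
pLC50 of 5.424. Whether the original tool z-scores or range-scales, and
whether group means are weighted, is not recoverable from the source;
z-scoring and equal weights are the package's choice, documented here.

On the ARKA plane, compounds outside a ±0.5 buffer around both axes are
diagnosed: an active in quadrant 2 (ARKA_1 < −0.5, ARKA_2 > 0.5) or an
inactive in quadrant 4 is a potential activity cliff; quadrant 1 or 3
placement marks a less-confident data point; everything inside the buffer is
left unflagged.

## Models

* **PLS** (`fit_pls`): single-response NIPALS on autoscaled X and centred y
  (the convention of the chemometrics software used in the original study),
  collapsed to original-scale coefficients, with X-residuals after the final
  component retained for DModX. At full rank PLS equals OLS (tested to
  1e−8), and predictions match an independent reference implementation
  (mixOmics) to 1e−6.
* **MLR** (`fit_mlr`), used for the ARKA and hybrid equations.
* **LDA** (`fit_lda`): Fisher discriminant through `MASS::lda` with equal
  priors (priors are not stated in the source), classification threshold at
  the midpoint of the projected class means, and Wilk's λ computed as
  within-group over total sum of squares of the discriminant scores.
* **Bagged trees** (`fit_bagged_trees`): a randomForest ensemble with the
  stated defaults (bag size 100%, unlimited depth, automatic feature
  subsampling, 100 trees, seed 1) and a stratified 10-fold CV report.
* **Stacking** (`stack_models`): one-latent-variable PLS of the training
  response on the four base-model columns (QSARpred, RASARpred, ARKApred,
  Hybridpred). Training rows carry fitted values and test rows predictions,
  as in the original design. With four identical input columns the
  coefficients are exactly equal and sum to the single-copy regression
  slope — the near-equal 0.255-pattern of the published stacking equation is
  this symmetry showing through.

## Validation

`regression_metrics` implements R², Q²(LOO), Q²F1 (train-mean denominator),
Q²F2 (test-mean denominator), MAE, RMSEp and Lin's CCC. The printed CCC
formula in the source carries a typesetting artifact (a minus where Lin's
concordance has a product); the standard product form is implemented, which
is the form consistent with the cited 0.85 threshold. All metrics agree
with independent brute-force evaluations to 1e−10 on 1,000 random vector
pairs, and Q²F1 = Q²F2 exactly when the test mean equals the train mean.

`y_randomization` follows the validate-plot convention of the chemometrics
software cited for this step: R² and Q² of response-scrambled refits are
regressed on the absolute correlation between scrambled and true response
(unpermuted point included), and the intercepts are compared with 0.3 / 0.05.

`dmodx` computes each row's X-residual SD after the A latent variables,
normalized by the pooled training residual SD s0 with the (N−A−1)(K−A)
degrees of freedom, so the training mean squared normalized DModX is
(N−A−1)/N ≈ 1. The 99% critical value is sqrt of the F quantile with
(K−A, (N−A−1)(K−A)) degrees of freedom. The "D-crit 0.009999" printed in
the source is read as the software's significance setting (α = 0.01), not as
a critical distance; the implementation exposes α and reports the F-based
critical value. Note that DModX measures *off-plane* distance: a
displacement lying inside the latent plane is a score (Hotelling T²)
outlier, not a DModX outlier, which is why the outlier-detection simulation
in the test suite uses a descriptor pool (10) comfortably wider than twice
the latent dimension, so an injected 10-SD single-descriptor displacement
always has residual mass.

`prediction_quality` categorizes query predictions as good / moderate / bad
by a three-rule composite — (a) inside the DModX domain, (b) the mean
absolute LOO error of the 10 most similar training compounds is below the
training MAE, (c) the prediction lies within the training mean ± 3 SD; all
three → good, exactly two → moderate, else bad. The tool this emulates is
closed source; the composite is this package's own documented definition.

## The frozen published predictor

`published_model` / `predict_published` expose the six published salmon
equations (global QSAR, q-RASAR, ARKA, hybrid, stacking, LDA) with their
printed coefficients verbatim, and `predict_from_smiles` scores a new
compound through the QSAR and LDA routes directly from structure. The
similarity-dependent routes (q-RASAR, hybrid, stacking) are exposed only
through user-supplied inputs because they require the original training set
as a similarity source, and that dataset is not public — the package is
explicit about what is reproducible without it. The LDA equation is printed
without its score cut-point; 0 is used and documented. For the regression
route, the toxic/non-toxic boundary is the published pLC50 = 5.424.

## Synthetic study conditions

Because the 106-compound descriptor/response table is available only on
request, the package generates data with the statistical structure the
framework assumes, and the test suite plus `scripts/acceptance.R` run on
those conditions:

* `gen_regression_dataset`: i.i.d. standard-normal descriptors, linear
  response with Gaussian noise. Defaults n = 106 and p = 6 mirror the study
  dimensions; noise SD 0.3 gives the strong-but-imperfect fits typical of a
  curated ecotoxicity dataset; the intercept 5.4 sits at a typical
  training-mean pLC50.
* `gen_two_class_dataset`: symmetric class separation `offset` (default 1.5)
  per descriptor across a G1/G2 split of p = 20 descriptors — a realistically
  sized reduced pool; with ~10 descriptors per group the group-mean scores
  place ≥95% of each class in its expected ARKA quadrant at that offset.
  Injected activity cliffs are actives relocated to the empirical inactive
  centroid.
* `fixture_compounds`: eleven named pesticides/industrial chemicals whose
  descriptor presence/absence patterns carry the published mechanistic
  interpretation; SMILES curated once from public registries and shipped as
  plain text.

What these generators deliberately do **not** emulate: discrete/zero-inflated
descriptor distributions (real count and binary descriptors), inter-descriptor
correlation, nonlinear structure–activity relationships, and measurement
heteroscedasticity. Passing tests on synthetic data therefore demonstrate
algorithmic correctness — formulas, invariants, recovery under the assumed
model — not predictive performance on real ecotoxicity data.

Simulation sizes in the tests (e.g. 100 seeds for coefficient recovery, 50
seeds for Y-randomization, 1,000 random pairs for the metric oracle) are
chosen to make the property estimates stable at desk scale.

## Numerical conventions

* Leave-one-out for OLS-type fits uses the hat-matrix identity
  (residual/(1−h)), avoiding n refits; PLS LOO refits explicitly.
* Rank-deficient OLS pools degrade through the pseudo-inverse and rank to
  the bottom of best-subset rankings rather than erroring.
* All stochastic steps (k-medoid sampling, GA, bagged trees, generators,
  Y-randomization) take explicit seeds and are deterministic given them.
* Zero-variance columns error early with the offending column named;
  `pretreat()` is the expected remedy.

## Known limitations

* The published Table-1 statistics (R² 0.713, Q²LOO 0.697, …) cannot be
  reproduced without the original 106-compound table; the acceptance script
  reports the same statistics computed on the synthetic study conditions
  instead, plus the exact evaluations of the frozen published equations.
* OpenBabel's Wildman–Crippen atom typing differs from other
  implementations on some heteroatom environments (amide N, thiophosphates);
  values agree closely on hydrocarbons and simple molecules, and all
  mechanistic orderings used by the models hold under either typing.
* H-053 neighbour counting follows the "exactly two halogens, summed over
  neighbouring carbons" reading; the alternative per-neighbour convention of
  the original descriptor software is not recoverable from its documentation.
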