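---
title: "Ion-ratio fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-ratio fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiomics)
```

## The problem

Untargeted ("shotgun") mass-spectrometry fingerprints of complex samples —
wines, plasma, plant extracts — contain thousands of ion peaks whose
absolute intensities drift from injection to injection: source conditions,
ionization suppression and injection volume all scale whole spectra by
unpredictable factors. `ratiomics` implements a discrimination workflow
built on a simple observation: a *ratio* of two ion intensities measured in
the same spectrum cancels any such per-injection factor exactly. The
workflow takes raw multi-scan spectra to a small panel of ion-intensity
ratios that separates sample classes (e.g. geographic origins), selected by
a genetic algorithm (GA) with cross-validated linear discriminant analysis
(LDA) as its fitness, validated on an independent sample set, and
benchmarked against random forests.

## Preprocessing model

Each injection is acquired as many scans on a shared m/z grid. The scans in
a configurable window (default 240–295, the elution range of interest) are
summed elementwise; summing concentrates signal and averages scan noise.

The baseline is estimated by robust locally weighted regression
(`stats::lowess`, four robustness iterations) with a smoother window
spanning a fraction `baseline_bandwidth` (default 0.1) of the m/z range,
then subtracted and floored at zero. Robust reweighting keeps narrow peaks
from inflating the local baseline; a constant or slowly varying chemical
background is absorbed essentially exactly, while a peak a few grid steps
wide loses at most a few percent of its height (both properties are tested).

Peak detection follows a validated-local-maximum scheme with parameters
`span = 5`, `sm_span = 1`, `zerothrsh = 20000`, `son = 1.5`,
`mad_mult = 1.64`:

1. the summed, baseline-corrected spectrum is smoothed by a moving average
   over the `span` nearest grid points;
2. every local maximum of the smoothed signal within its span window is a
   candidate, ties between adjacent equal maxima keeping the lowest m/z;
3. a candidate of smoothed height *h* is validated iff *h* ≥ `zerothrsh`,
   *h* ≥ `son` × local noise, and *h* > `mad_mult` × MAD of the smoothed
   signal in the window.

Two points were genuinely open and are fixed here as package policy. The
*local noise* is the MAD of the smoothing residual (raw − smoothed) over
the window's other points, excluding the candidate and its `sm_span`
neighbours on each side — a robust spread of exactly the points the rules
designate as "noise". Peak *height* is the smoothed intensity at the apex,
because the validation rules are phrased on the smoothed signal. The
absolute floor `zerothrsh` is applied after baseline subtraction (the
alternative ordering is defensible; applying it after makes the floor a
property of analyte signal rather than of background level). `area_w` is
accepted and stored for interface fidelity but deliberately unused: nothing
downstream consumes peak areas. Centroided input still works — detection
only needs a locally gridded signal — but the pipeline is designed for
profile-mode data.

## Alignment

Peaks pooled over all injections are clustered on m/z by complete-linkage
hierarchical clustering and the tree is cut at a height `cutoff`; each
cluster becomes one consensus feature (m/z = mean of members). Complete
linkage is the right linkage here because it bounds the m/z spread of every
feature by the cut height — a guarantee single or average linkage do not
give, and one the test suite asserts.

Distance is absolute m/z difference in Th (not ppm): the simplest metric
consistent with a cut height quoted in Th. For tractability at tens of
thousands of peaks, the pooled sorted list is first split wherever a gap
between consecutive m/z values exceeds the cutoff; complete linkage can
never merge across such a gap at or below the cut height, so clustering the
segments separately is exact, not an approximation (tested against full
`hclust` on pooled data).

The cutoff is chosen by the workflow's own objective: the number of
clusters containing two or more peaks *from the same spectrum* — distinct
ions that should never merge — minimized over a candidate grid
(logarithmic, 0.001–0.5 Th, 20 points by default; the original candidate
set is not recorded anywhere, so the grid is a package default). Ties break
toward the larger cutoff, which splits fewer genuine features. If two peaks
of one spectrum do land in one cluster, their heights are summed — the
event is exactly what the objective counts and penalizes, and summing keeps
the matrix well defined even at the optimum.

Technical replicates are averaged arithmetically per feature after
alignment, giving one row per biological sample.

## Annotation

Features are matched against a compound database by exact mass with the
signed relative error `(theoretical − experimental) / theoretical × 1e6`
ppm, i.e. an experimental mass below the theoretical one gives a positive
error; the opposite convention is also in circulation, so the sign is fixed
and documented. Default tolerance is 10 ppm, a customary bound for a
well-calibrated TOF. All matches within tolerance are reported; multiple
matches are flagged ambiguous rather than resolved, because resolving them
needs information (isotopes, MS/MS) outside this workflow's scope.

## Ratio features and the size of the search space

From *p* features the package builds all *p·(p−1)* ordered ratios; both
orientations are kept as distinct features throughout (72 features give
exactly 5112 ratios, which is the ordered count). Zeros (missing peaks) are
imputed with half the smallest positive value of their column before
division, keeping every ratio finite and positive. Ratios are used raw by
default; `log_ratios` exists because log-ratios are symmetric in
orientation, but the default matches the count semantics above.

`count_subsets()` computes the number of ratio subsets of sizes 1–10 in
exact arbitrary-precision integer arithmetic (hand-rolled base-1e7 digit
vectors — adequate for binomial sums and dependency-free). From 5112 ratios
there are about 3.3 × 10³⁰ such subsets; from the ~1.9 × 10⁸ ratios of an
unfiltered 13699-peak fingerprint, far more. Exhaustive search is
hopeless, which is the entire motivation for a heuristic selector.

## The discriminant and its cross-validation

LDA with equal class covariances: class means, pooled within-class
covariance (denominator n − g) and empirical priors. A relative ridge
`1e-8 · trace(S)/d` on the covariance diagonal guards invertibility for
tiny panels; at the 1–10 feature scale used here its effect is far below
any decision boundary's resolution, and it can be disabled. Prediction is
the argmax of the usual linear score, with exact ties going to the earlier
class label so that behaviour is fully specified.

Cross-validation is stratified: with 30 samples in 3 classes, unstratified
2-fold splits can lose a class from a training fold entirely, making the
fit ill-posed. Fold accuracies are averaged per repeat and then across
repeats. The fold loop is implemented in C++ (RcppArmadillo) because
wrapper selection performs tens of thousands of small CV fits; the compiled
path is asserted to agree with the R-level fit/predict to 1e-12.

## The genetic algorithm

Individuals are variable-length *sets* of ratio indices, sizes bounded by
`subset_size_range` (default 1–10). A fixed-length binary string over all
ratios would be absurdly sparse at these sizes; the set encoding is
standard for subset selection. Operators:

* **selection** — tournament of size 3, plus 2 elites copied unchanged
  (elitism makes the best fitness monotone per generation, an invariant the
  tests assert);
* **crossover** (probability 0.8) — the child samples, without
  replacement, from the union of both parents' ratios, at a size drawn
  uniformly between the parent sizes, which preserves the size bounds by
  construction;
* **mutation** (probability 0.2 per individual) — replace one ratio with a
  uniformly random new one, add one, or drop one, chosen with equal
  probability among the moves the bounds allow.

Fitness is stratified 2-fold CV-LDA accuracy of the subset's columns, on
one fixed split per run: the same split for every subset makes comparisons
fair, fitness deterministic, and caching by sorted index set exact. The
original tuning values for population size, generation count and operator
rates are not recorded in the available text, so the defaults (population
100, 200 generations, 5 runs) are package policy and fully configurable;
tests and the acceptance study pass smaller explicit configurations sized
to their problems (stated below).

Runs are independent with seeds `seed + run`. Selection of the final
fingerprint then proceeds in stages over all distinct final-generation
solutions: re-score by 30-repeat stratified 2-fold CV on the learning set
(same folds for all candidates); keep solutions above 80% CV accuracy; fit
each survivor on the full learning set and score the held-out validation
set; return the solution with the highest validation accuracy, ties broken
by fewest distinct features (molecules), fewest ratios, highest CV
accuracy, and finally the lexicographically smallest index set. The last
tie-break is a canonical resort absent from the original description; it
makes the selection a deterministic function of the candidate pool, without
which "the GA found the same answer as exhaustive enumeration" is not even
well defined. If nothing clears 80%, the best-by-CV solution is returned
with a prominent warning rather than an error, so pipelines degrade
loudly but gracefully.

## Random-forest benchmark

`rf_full()` fits a forest on all ordered ratios, tuning the number of trees
(250/500/1000) and per-split candidate count (√p, p/10, p/3) by out-of-bag
accuracy, and ranks ratios by out-of-bag permutation importance (the
canonical forest importance, and univariate in spirit — which is precisely
the property the comparison interrogates). `rf_reduced()` refits on the
top-k ratios. Both report learning, repeated-2-fold-CV and validation
accuracies, mirroring the three-accuracy comparison of the GA panel.

## The synthetic cohort generator

No public spectra accompany the original wine study, so the generator
produces data with the statistical properties the workflow assumes, with
the planted ground truth returned alongside (never hidden), so recovery can
be asserted. Per injection r of biological sample s in class c:

I_rp = μ_p · e_c(p) · f_r · g_rq(p) · ε_rp

* μ_p — cohort-level base intensity of peak p (log-uniform, 10^4.5–10^6);
* e_c(p) — the planted class effect: `ratio_effect_size`^(c−1) if p is the
  numerator of a planted pair, 1 otherwise (geometric steps across
  classes);
* f_r — per-injection log-normal scale (sdlog `injection_scale_sd`,
  default 0.5): cancels in every ratio, which is the premise of the whole
  method;
* g_rq — a log-normal fluctuation (sdlog `pair_coupling_sdlog`, default
  0.5) shared by the two peaks of planted pair q. This term is what makes
  the planted *pair* identifiable: without it, a ratio of the shifted
  numerator against *any* stable peak carries identical signal and the
  "true" denominator would be statistically meaningless. With it, the
  planted ratio cancels the fluctuation while every alternative pairing
  retains it — the generator's expression of "abundances fluctuate, ratios
  are stable";
* ε_rp — mean-one multiplicative log-normal noise with CV
  `intensity_noise_cv` (default 0.15).

Everything is multiplicative and log-normal, so intensities stay positive
and ratio invariance under the injection factor is exact. The ground truth
records the planted pairs and the exact expected per-class ratio means
(including the log-normal ratio bias 1 + cv²).

What the generator does **not** emulate: chromatographic retention-time
structure, isotope patterns, adducts, detector saturation, correlated
(non-planted) biology, and class-dependent injection effects. Passing
tests on this generator therefore demonstrate that the algorithms do what
they claim under the stated statistical model — not that the workflow will
discriminate any particular real cohort.

Default cohort geometry mirrors the original design: 3 classes, 20
biological samples per class (split 10 learning + 10 validation per class
in the studies below), technical triplicates averaged.

## Study sizes used by the tests and the acceptance script

* **GA vs exhaustive enumeration** — 8 peaks (56 ordered ratios), 1
  planted pair, effect 2.5, noise CV 0.15, pair coupling 1.0, subset sizes
  1–2, GA population 60 × 80 generations × 4 runs; 20 replicate cohorts.
  The strong coupling makes the planted ratio the identifiably unique
  optimum; at weaker coupling many solutions become observationally
  equivalent on a 30-sample validation set and "the" best subset is a tie,
  which tests the tie-break rather than the search.
* **Planted recovery at full design scale** — 72 peaks (5112 ratios), 2
  planted pairs, effect 2.5, noise CV 0.15, default coupling 0.5,
  GA population 100 × 100 generations × 3 runs; 20 replicate cohorts; a
  selected fingerprint counts as a recovery if it contains a planted pair
  in either orientation.
* **Permutation nulls** — 100 independent label shuffles of balanced
  3-class data (one stratified 2-fold split each) for both CV-LDA and the
  forest's validation accuracy.
* **Overfit gap** — 20 cohorts at 12 peaks; the forest's learning accuracy
  is compared with its validation accuracy.

These sizes are the package's own choices for replicable desk-scale
studies; every number they produce is computed at run time by the test
suite or by `scripts/acceptance.R`, never stored.

## Numerical and degenerate-input policy

* Zero/missing intensities: half-minimum imputation per feature column
  before ratio formation.
* Ratios under per-sample scaling are invariant to the last bit for
  power-of-two factors and to ~1 ulp otherwise (floating-point division
  does not cancel arbitrary common factors bitwise).
* `detect_peaks` on an empty or flat spectrum returns an empty table, not
  an error; an empty compound database annotates nothing with a warning.
* All stochastic entry points (`simulate_*`, `cross_validate`, `run_ga`,
  `rf_*`, `run_pipeline`) take explicit integer seeds and restore the
  caller's RNG state.
* A class with fewer samples than folds, mismatched dimensions, and
  out-of-range scan windows raise errors naming the offending field.

## Known limitations

* The alignment metric is Th, not ppm; at very wide m/z ranges a single
  cutoff in Th is coarser at high m/z than low.
* LDA assumes shared class covariances; strongly heteroscedastic classes
  would favour quadratic or regularized variants, which are out of scope.
* The GA ranks only final-generation solutions (as the workflow it
  implements prescribes); a solution visited and lost before the last
  generation is not considered. Elitism makes this loss rare but possible.
* Raw (non-log) ratios make LDA sensitive to the orientation of each pair;
  the selector compensates by treating both orientations as distinct
  candidate features.
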