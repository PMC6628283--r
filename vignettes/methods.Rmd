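---
title: "Inducing Mamdani fuzzy classifiers from clinical tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inducing Mamdani fuzzy classifiers from clinical tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzydx)
```

## The model

`fuzzydx` builds Mamdani-type fuzzy inference classifiers directly from a
numeric table of clinical measurements plus one categorical class column.
A Mamdani system is a set of linguistic rules

> IF *x₁* is *A₁* AND … AND *xₚ* is *Aₚ* THEN *y* is *C*

whose antecedent sets *Aⱼ* and consequent set *C* are fuzzy sets: piecewise-
linear membership functions mapping a crisp value to a degree in [0, 1].
Inference follows the classical min/max operator family: the firing strength
of a rule is the minimum of its antecedent degrees (maximum for OR rules),
scaled by a rule weight; each rule's consequent set is clipped at the firing
strength (min implication); the clipped sets are superposed pointwise by max;
and the aggregate is collapsed to one crisp value by centre-of-gravity
defuzzification. The crisp output is decoded to a class label by evaluating
every output membership function at it and taking the class attached to the
highest-degree set (ties to the lower index, i.e. the lower-coded class).

What distinguishes this estimator from a hand-designed fuzzy system is that
*both* halves of the knowledge base are induced from data:

1. **Knowledge database (fuzzification).** Every selected input and the
   outcome are clustered one dimension at a time — agglomerative Ward
   clustering on the 1-D Euclidean distances by default, k-means for very
   large tables — and each cluster's raw minimum and maximum become the
   plateau breakpoints *b* and *c* of one membership function. A cluster
   whose minimum equals its maximum becomes a triangle peaked there;
   otherwise the set is trapezoidal.
2. **Knowledge rule base (pivot tables).** Each training row is mapped to
   its vector of cluster indices, and the *sorted unique rows* of that
   clustered table become the rules (weight 1, AND connector). Duplicate
   observations therefore collapse into one rule, and the rule count is
   bounded by both the number of training rows and the product of cluster
   counts.

## Sizing the fuzzy sets

The number of clusters per variable is bounded by the pivot-table rule: with
*u* distinct observed values, use *u* itself when *u* ≤ 20, otherwise
round(√*u*) (half away from zero), never fewer than 2 and never more than 20.
The cap exists because the rule count grows with the product of the
per-variable set counts; √*u* keeps systems with hundreds of distinct
biomarker values interpretable. Rounding half away from zero is pinned by
the worked sizings: 110 → 10, 113 → 11 (10.63 rounds up), 51 → 7,
116 → 11.

## Membership-function feet and the Ruspini property

Clustering determines only the plateau [*b*, *c*] of each set. The feet are
a design choice: `fuzzydx` places the left foot of cluster *i* at the
previous cluster's maximum and the right foot at the next cluster's minimum
(outermost feet coincide with the plateau, giving shoulder-like edge sets).
Two neighbouring sets then ramp across the same inter-cluster gap in
opposite directions, so degrees sum to exactly 1 at every point of the
variable's range (a Ruspini partition). This guarantees the coverage the
inference engine needs: no in-range value can fuzzify to all-zero degrees.
The property is verified on a dense grid at 1e-9 tolerance in the test
suite. Identical raw values always share a cluster (Ward merges zero-
distance pairs first), so plateaus of adjacent sets never touch and the
partition stays exact.

Categorical (nominal) features bypass distance-based clustering entirely:
each observed code becomes its own singleton cluster, i.e. a triangular set
peaked at the code. Distances between arbitrary category codes are
meaningless, so clustering them would manufacture structure.

## Numerical choices

* **Defuzzification grid.** Each output range is sampled at 1001 evenly
  spaced points (configurable via `resolution`). The centroid is the ratio
  of the discretised integrals of *µ(z)·z* and *µ(z)*, both computed with
  trapezoid-rule weights (half weight at the two endpoints). For a
  piecewise-linear aggregate sampled at its breakpoints this quadrature is
  exact; a plain unweighted sum would bias the centroid by ~3·10⁻⁴ of the
  range whenever the aggregate is non-zero at a range end, which cluster-
  derived shoulder sets routinely are.
* **Rows that fire no rule.** A validation row whose cluster combination was
  never observed in training can fire no rule. Rather than abort batch
  evaluation, inference returns the midpoint of the output range and flags
  the row (`fired = FALSE`); the per-candidate flag count is carried in the
  search results. The midpoint is maximally non-committal between the two
  class sets.
* **Out-of-range inputs** are clamped to the variable's training range, so
  validation folds that exceed the training extremes still fuzzify inside
  the covered range.
* **Vertical edges.** Zero-width ramps (a = b or c = d) evaluate to degree 1
  at the breakpoint, so degenerate sets from single-value clusters never
  open measure-zero coverage gaps.
* **Tie-breaks** are all deterministic: class decoding prefers the lower
  membership index; model selection prefers, in order, higher selection
  metric, fewer input variables, fewer rules, lower iteration index;
  majority resolution of contradictory rules (off by default) prefers the
  lower consequent index.

## The design loop

`fis_search()` drives the iterative construction: rows are first permuted
(seeded), then partitioned either by a single random-sampling split (70%
training / 30% validation by default) or by 10-fold cross-validation. A
candidate model is a feature subset paired with one cluster count per
selected feature; subsets are enumerated exhaustively per size
(`choose(n, k)` of them), cluster counts sweep 2 … `optimal_cluster_count`
per feature, and the default budget caps evaluation at 3000 candidates.

The enumeration order is a genuine design choice, since a budget that
truncates the stream makes the order part of the estimator. `fuzzydx` orders
candidates by ascending subset size, then ascending *product of cluster
counts* — the upper bound on the rule-base size — with a seeded shuffle
inside each complexity stratum. The search therefore spends its budget on
parsimonious systems first, which is the stated goal of the framework:
maximal effectiveness with a reduced rule count. When a size's candidate
grid exceeds an enumeration cap (50,000 pairs), candidates are sampled
uniformly with the same seed and then complexity-ordered; this keeps memory
bounded on wide continuous tables. Within every candidate, clustering,
membership ranges, rules and class codes derive from that candidate's
training rows only; the sweep *ranges* come from unlabelled unique-value
counts of the full table, which involves no class information.

Under cross-validation a configuration's reported metrics are fold averages,
and the winning configuration is refitted on the full dataset to yield the
single deliverable model; under random sampling the winner is refitted on
the training split (its metrics already refer to the untouched validation
split).

## Evaluation suite

Candidates are scored with the standard binary diagnostic metrics read off
the 2×2 confusion matrix — accuracy, sensitivity (= recall), specificity,
precision, F-measure — plus Cohen's kappa and a rank-based AUC. Kappa is the
usual chance-corrected agreement (pₒ − pₑ)/(1 − pₑ) from the matrix
marginals. The AUC is the Mann–Whitney probability that a random positive
instance outranks a random negative one, with half credit for ties; the
ranking score is the continuous defuzzified output, oriented so that larger
means more positive. Any 0/0 metric (e.g. precision of a model that never
predicts positive) is reported as 0 with a structured warning rather than
NaN, so report tables stay comparable. AUC values are labelled with the
conventional bands — ≥ 0.9 excellent, 0.8–0.9 good, 0.7–0.8 fair, 0.6–0.7
poor, 0.5–0.6 failure — each band closed at its lower edge; below 0.5 the
label is "worse than chance". The positive class defaults to the higher
class code (e.g. malignant = 2 when benign = 1), which fixes the orientation
of sensitivity and specificity; with the opposite convention the two simply
swap.

## Preprocessing and interchange

`read_dataset()` reads header-first delimited text (comma, semicolon or tab,
auto-detected), types columns numerically, and assigns integer codes to
nominal columns in first-appearance order (stable across locales), recording
a code book. `preprocess()` replaces missing cells — read in from a missing
token such as `"?"` — with a configurable imputation value and applies
per-column recodes (e.g. a class coded 2/4 mapped onto 1/2). The default
imputation value 0 deliberately lies *outside* the usual 1–10 clinical code
range, so imputed cells form their own low cluster rather than contaminating
an observed code's cluster; if that is not wanted, set `impute` to a
within-range value.

Fitted systems serialise to the sectioned plain-text `.fis` interchange
dialect (`[System]`, `[InputN]`, `[OutputN]`, `[Rules]`), with triangular
sets as `trimf` and trapezoidal as `trapmf`, rule weights in parentheses and
connector code 1 for AND / 2 for OR. The formatting is canonical —
write∘read∘write is byte-stable — and reading back reproduces crisp outputs
to 1e-12.

## What the synthetic generator does and does not emulate

`generate_fuzzy_data()` plants known structure: informative features draw
from class-specific value bands (truncated-normal bands for continuous
biomarkers, contiguous code blocks for 1–10 integer codes), noise features
draw identically for all classes, and an optional fraction of informative
cells is knocked out as missing. `separation` is the gap between class bands
in units of the within-band spread; any positive separation makes the bands
disjoint, while `separation = 0` draws informative features from the same
pooled distribution as noise (class-conditionally indistinguishable, the
honest null). `generate_wbcd_like()` specialises this to a nine-feature
1–10-coded table with ≈ 65/35 class prevalence, five informative features
and laboratory-style dropouts on one feature.

The generator reproduces the *shape* of the benchmark clinical tables —
band-structured classes, bounded integer codes, heavy-tailed continuous
markers, missing tokens — but none of their real correlation structure,
measurement error or label noise. Passing the recovery tests therefore shows
that the induction machinery finds planted, separable structure under the
stated conditions; it does not certify accuracy on any real dataset.

Default study conditions used by the test suite and examples: recovery runs
use n = 300 rows, 2 informative + 3 noise features, separation 3, a 70/30
split, a budget of 200 candidates and 5 seeds; the distributional null check
uses 2000 rows. These sizes were chosen so that every stochastic check is
comfortably powered while the whole suite stays desk-scale.

## Known limitations and open ends

* The crisp-to-class decoding rule (argmax of output-set degree at the
  centroid) is this package's documented choice; nothing in the framework's
  description fixes it, and near the midpoint between two class sets the
  decoded label is sensitive to the rule-base composition.
* Whether cluster ranges should come from the full dataset or the training
  split is ambiguous in the framework's description (clustering is presented
  before splitting); this implementation clusters the training split only,
  the leakage-free reading.
* Contradictory rules (identical antecedents, different consequents) are
  kept by default, faithful to unique-row semantics; both then fire equally
  and the centroid lands between their consequents. `resolve_contradictions
  = TRUE` switches to majority resolution.
* Only binary outcomes get the full metric suite; accuracy and kappa would
  extend to more classes, but sensitivity/specificity/AUC as implemented are
  two-class.
* Sugeno-type systems, product/probabilistic operator families, Gaussian or
  generalised-bell membership shapes, fuzzy C-means and metaheuristic rule
  tuning are out of scope.
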