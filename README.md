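# fuzzydx

Interpretable, data-driven Mamdani fuzzy classifiers for tabular clinical
data.

Clinical decision support often has to trade accuracy against
interpretability: a clinician can audit "IF Bare Nuclei is *high* AND Cell
Size is *high* THEN *malignant*", but not a deep network. `fuzzydx` induces
complete Mamdani-type fuzzy inference systems — membership functions *and*
rule base — directly from a table of measurements plus a class column, for
binary diagnostic problems of the kind found in the UCI breast-cancer, wart-
treatment and caesarean-section benchmarks.

The estimator has two data-driven halves:

* **Knowledge database.** Each variable is clustered on its own axis (Ward
  hierarchical clustering by default, k-means for very large tables). A
  cluster's raw minimum and maximum become the plateau `[b, c]` of one
  triangular/trapezoidal membership function; feet are placed at the
  neighbouring clusters' extremes so the family is a Ruspini partition
  (degrees sum to 1 everywhere). The number of sets per variable follows
  the pivot-table rule: `u` distinct values give `u` sets when `u ≤ 20`,
  otherwise `round(√u)`, never fewer than 2.
* **Knowledge rule base.** Each training row maps to its vector of cluster
  indices; the sorted unique rows become the IF–THEN rules (weight 1, AND
  connector).

Inference is classical Mamdani — min firing/implication, max aggregation,
centre-of-gravity defuzzification

$$Z = \frac{\int \mu_C(z)\, z \, dz}{\int \mu_C(z)\, dz}$$

— and a crisp output is decoded to the class of the highest-degree output
set. A wrapper search (`fis_search()`) sweeps feature subsets × per-variable
cluster counts under an iteration budget, with a 70/30 random-sampling split
or 10-fold cross-validation, and ranks candidates by accuracy (or kappa);
the metric suite covers accuracy, sensitivity, specificity, precision,
recall, F-measure, Cohen's kappa and Mann–Whitney rank AUC with the usual
verbal bands (≥ 0.9 "excellent classification", …). Fitted systems
round-trip through the plain-text `.fis` interchange format.

## Worked example

Plant separable two-class structure (two informative features among five),
search 200 candidate systems on a 70/30 split, and inspect the winner:

```r
library(fuzzydx)

gen <- generate_fuzzy_data(n_rows = 300, n_informative = 2, n_noise = 3,
                           separation = 3, seed = 11)
ctl <- fz_search_control(max_iterations = 200, subset_sizes = c(2, 3))
s   <- fis_search(gen$data, "class", control = ctl, seed = 11)
glance(s)
#> # A tibble: 1 × 7
#>   n_candidates partition       selection_metric best_features       best_ks best_n_rules best_metric
#>          <int> <chr>           <chr>            <chr>               <chr>          <dbl>       <dbl>
#> 1          200 random_sampling accuracy         feature_1,feature_2 2,2                2           1

best <- select_best(s)
best$kb
#> <fz_kb> 2 feature(s) [feature_1, feature_2], 2 rule(s), method=ward, trained on 210 row(s)
tidy(best$kb$system)$statement
#> [1] "IF feature_1 is MF1 AND feature_2 is MF1 THEN class is MF1"
#> [2] "IF feature_1 is MF2 AND feature_2 is MF2 THEN class is MF2"
```

The search recovered exactly the two planted informative features, clustered
each into its two class bands (`best_ks = 2,2`), and compressed 210 training
rows into two auditable rules with validation accuracy, kappa and AUC all
1.0 (`best_metric` is the validation accuracy). `write_fis(best$kb$system,
"model.fis")` saves the system; `autoplot(best$kb$system)` draws every
membership function; `write_report(s, "report.csv")` dumps the full ranked
candidate table.

Real datasets enter through `read_dataset()` + `preprocess()` (missing-token
imputation, class recodes, nominal coding); a thin command-line wrapper with
`simulate` / `build-kb` / `search` / `evaluate` subcommands lives in
`inst/cli/fuzzydx.R`.

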