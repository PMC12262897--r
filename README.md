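# bimmknee

Prediction of clustered binary outcomes — two knees per person — with the
**Binary Mixed Model (BiMM)**: an iterative coupling of a classification
random forest and a Bayesian logistic mixed-effects model. Standard
classifiers treat every knee as an independent observation; in bilateral
joint data the two knees of a person are correlated (left–right phi
coefficients around 0.3 are typical in knee-pain cohorts), and ignoring
that correlation misstates both uncertainty and signal. BiMM represents it
explicitly through a per-person random intercept while keeping the forest's
ability to model non-linear covariate effects.

The package is aimed at biostatisticians and epidemiologists working with
paired-organ or otherwise clustered binary outcomes (knees, hips, eyes, MRI
sub-regions within a joint).

## The model

For person *i*, knee side *t* ∈ {1, 2}, covariates X<sub>it</sub> and
binary outcome Y<sub>it</sub>:

    logit P(Y_it = 1) = β0 + β1 · RF(X_it) + b_i,   b_i ~ N(0, σ_b²)

where RF(X<sub>it</sub>) is the forest's class-1 probability and b<sub>i</sub>
a person-level random intercept. BiMM iterates: fit forest → fit mixed model
→ extract posterior probabilities Q<sub>it</sub> → update the working
outcome through a split function Y\* = h(Y + Q) → refit, until the change
in posterior log-likelihood drops below a tolerance (default 0.5). Three
split functions are provided: h1 (flips only 0→1, sensitivity-preserving),
h2 (flips only 1→0, specificity-preserving) and h3 (stochastic in the
middle band); the function and its threshold constant are chosen by grid
search on a validation split.

Because real bilateral cohorts of this kind are access-controlled, the
package includes a calibrated synthetic cohort generator (person- and
knee-level covariates, controllable prevalence and left–right phi) so the
entire pipeline is testable end to end. See the methods vignette
(`vignettes/bimm-methods.Rmd`) for the inference details and design
rationale.

## Worked example

```r
library(bimmknee)

# calibrated bilateral cohort: 500 persons, prevalence 0.27, phi ~ 0.30
cfg <- default_cohort_config(n_persons = 500, prevalence = 0.27,
                             target_phi = 0.30, seed = 42)
cohort <- generate_cohort(cfg)
sprintf("prevalence %.3f, phi %.3f", mean(cohort$outcome), empirical_phi(cohort))
#> "prevalence 0.287, phi 0.311"

# select the split function on a validation split carved from training
outer <- partition_by_individual(cohort, 0.7, seed = 1)
inner <- partition_by_individual(outer$train, 0.7, seed = 2)
gs <- grid_search_split(inner$train, inner$test,
                        rf_params = list(num_trees = 150, class_weight = 0.37),
                        k1_grid = c(0.25, 0.5, 0.75, 0.9),
                        k2_grid = c(1.1, 1.5, 1.9), seed = 3)
gs
#> Split-function grid search over 8 candidates
#> Best AUC: 0.6115
#> Split function h1 (k1 = 0.75)

# repeated person-level 70/30 holdout: BiMM vs plain random forest
ex <- run_experiment(cohort, gs$spec,
                     rf_params = list(num_trees = 150, class_weight = 0.37),
                     n_partitions = 10, threshold = 0.5, seed = 4)
ex
#> Repeated-holdout evaluation: 10 person-level partitions
#>
#> BiMM  AUC 0.600 ± 0.033 | iter 2.80 ± 1.23 | sens 0.056 | spec 0.973 | acc 0.729 | FPR 0.027
#> RF    AUC 0.595 ± 0.040 | iter NA | sens 0.048 | spec 0.976 | acc 0.729 | FPR 0.024
#>
#> AUC difference (BiMM - RF): 0.0051, t = 0.312, p = 0.759, 95% CI [-0.0295, 0.0397]
#> Unique top-20 variables: BiMM 15, RF 15
```

Reading the output: the cohort generator hit its calibration targets; the
grid search picked the sensitivity-preserving split h1 with constant 0.75;
over ten person-level partitions BiMM's mean test AUC is 0.600 against the
plain forest's 0.595 — a difference of +0.005 that the Welch t-test does
not distinguish from zero, as expected in this weak-correlation regime. The
`class_weight = 0.37` setting down-weights the majority (no-pain) class so
the minority class carries ≈2.7× influence during forest training.

`write_outputs(ex, "results/")` exports per-partition metrics, summary
tables, an AUC box plot and a checksum manifest. A command-line wrapper for
the same pipeline (subcommands `simulate`, `tune-split`, `fit`, `evaluate`)
lives at `inst/cli/bimm.R`.

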