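# elscape

Energy-landscape analysis of task-state fNIRS brain dynamics, with a
depression-detection pipeline and a fully synthetic test cohort.

## The problem

Functional near-infrared spectroscopy (fNIRS) records cortical
oxygenated-haemoglobin (HbO) time series from a few dozen optodes while a
participant performs a task — here, listening to emotional audio (happy,
calm, fear, white-noise trials in a block design). Classical functional
connectivity summarises such recordings by pairwise channel correlations,
which ignores how the *joint* activation pattern of all channels moves
through its state space. Energy-landscape (EL) analysis addresses that:
binarize each channel, treat the C-channel pattern at each sample as one of
2^C brain states, fit a pairwise maximum-entropy model (pMEM), and study
the resulting energy function on the hypercube of states — its attractors
(local minima), their basins, and the dwell statistics of a random walker.
Differences in those attractor statistics between clinical groups (e.g.
individuals with major depressive disorder, MDD, versus healthy controls,
HC) are candidate markers of constrained, low-degree-of-freedom brain
dynamics.

`elscape` implements the complete channel-level pipeline:

1. **io** — TSV + JSON recordings, zero-phase 0.01–0.2 Hz band-pass,
   stimulus segmentation (happy / calm / fear / full);
2. **chansel** — CANDECOMP/PARAFAC (CPD) decomposition of the
   time × channel × participant tensor by alternating least squares, with
   Pearson-correlation ranking of the channel factor matrix and top-k
   selection;
3. **pmem** — mean-threshold binarization, empirical state statistics,
   pMEM fitting (pseudo-likelihood or exact-gradient moment matching), the
   independent-MEM baseline, and the accuracy index *r*;
4. **landscape** — local/global minima, steepest-descent basins,
   20,000-step Metropolis walks, dwell features, major states;
5. **stats** — Shapiro–Wilk-gated Kruskal–Wallis / two-way ANOVA group
   comparisons with Tukey post-hoc contrasts, plus demographics tests;
6. **classify** — RBF-kernel maximum-margin classifier (own SMO solver)
   with leave-one-out cross-validation and nested grid search, comparing
   *connectivity* features (the couplings J) against *energy* features
   (state energies + landscape features);
7. **synth** — a two-group synthetic cohort generator with planted
   landscape differences, so every stage is testable without clinical data.

## The model

With spins σ_m ∈ {−1, +1} (displayed as 0/1), a state
s = (σ_1 … σ_C) has energy

    E(s) = − Σ_m h_m σ_m − ½ Σ_{m≠n} J_mn σ_m σ_n

and Boltzmann probability P(s) ∝ exp(−E(s)). The fields h and symmetric
couplings J are chosen so the model's activation rates ⟨σ_m⟩ and
co-occurrences ⟨σ_m σ_n⟩ match their empirical values (learning rate 0.1,
stopping threshold 5×10⁻⁶). Fit quality is scored by the accuracy index

    r = (K1 − K2) / K1,

where K1 and K2 are base-2 Kullback–Leibler divergences of the empirical
state distribution from the independent (J = 0) and pairwise fits: r = 1
when the pairwise model is exact, r = 0 when couplings add nothing.

The landscape features per participant × stimulus are: the number of local
minima (n_LM), the mean energy gap E(LM) − E(GM) over non-global minima,
the standard deviation of basin sizes, and the occupancy of the global
minimum's basin during a 20,000-step Metropolis walk (`gm_duration`).

## Worked example

```r
library(elscape)

## 1. Simulate a small two-group cohort (state-level fast path)
cfg <- cohort_config(n_per_group = 10, seed = 42)
cohort <- generate_cohort(cfg, continuous = FALSE)

## 2. Analyse one participant under the fear stimulus
states <- cohort$truth[[11]]$categories$fear$states   # an HC participant
ana <- analyze_states(states, n_steps = 20000, seed = 1)
ana$acc
#> accuracy index r = 0.7057 (K1 = 0.4860, K2 = 0.1430 bits)
ana$landscape
#> energy_landscape: C = 7 | 2 local minima | GM = 1111000
str(ana$features[c("n_LM", "mean_gap", "basin_size_sd", "gm_duration")])
#> $ n_LM         : int 2
#> $ mean_gap     : num 2.68
#> $ basin_size_sd: num 53.7
#> $ gm_duration  : int 18062
```

The pairwise couplings explain ~71% of the divergence the independent
model leaves unexplained (r = 0.71); this healthy-control participant has
the two planted attractors (`1111000` and its complement), a large energy
gap, and a skewed basin split, and the walker spends 18,062 of 20,000
steps in the global minimum's basin.

```r
## 3. Cohort-level features and group statistics
cf <- cohort_features(cohort, n_steps = 20000, seed = 42)
run_group_tests(cf$table)
#> n_LM           [nonparametric] group p = 4.839e-06
#> mean_gap       [nonparametric] group p = 3.146e-14
#> basin_size_sd  [parametric] group p = 6.909e-06
#> gm_duration    [nonparametric] group p = 6.924e-09

## 4. Depression detection from energy features (fear stimulus)
labels <- vapply(cohort$truth, `[[`, character(1), "group")
fe <- build_features(cf$analyses$fear, labels, "energy")
loocv_classifier(fe, grid_C = 10^seq(-2, 4, 2), grid_gamma = 10^seq(-4, 0, 2),
                 inner_folds = 3, n_repeats = 3, seed = 1)
#> classification_report ( energy , nested )
#>        Acc Pre   Rec Spec   F1
#> mean 96.67 100 93.33  100 0.96
#> sd    2.89   0  5.77    0 0.03
```

The synthetic MDD group has more local minima, smaller gaps and smaller
basin-size spread than HC (all group effects significant above), and a
leave-one-out SVM on the energy features separates the groups at ~97%
accuracy on this 20-participant toy cohort.

## Command line

A thin CLI wraps the main stages:

```sh
inst/cli/elscape simulate   --out cohort/ --n-per-group 5 --seed 1
inst/cli/elscape preprocess --in cohort/hc001.tsv --band 0.01 0.2 --segment fear
inst/cli/elscape fit-pmem   --states states.tsv --mode exact --out model.json
inst/cli/elscape landscape  --model model.json --steps 20000 --seed 1
```
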