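# cytocycle

Label-free cell-cycle analysis for imaging flow cytometry.

Imaging flow cytometers photograph every cell in flow in a brightfield
(transmitted light) and a darkfield (90-degree side scatter) channel —
neither needs a stain. `cytocycle` reconstructs cell-cycle state from those
two channels alone:

* **Preprocessing** — reshape variably sized single-cell tiles to 55x55 px
  (background-sampled padding / centre cropping), tile them into 15x15
  montages of up to 225 cells, and segment the cell in the brightfield tile
  by edge enhancement + thresholding (the darkfield is deliberately used
  whole-frame: side scatter is not registered to the cell outline).
* **Features** — a fixed, versioned 213-feature profile per cell: 130
  brightfield-object features (17 shape scalars, 30 Zernike moment
  magnitudes of degree <= 9, 16 intensity, 12 radial-distribution, 39
  Haralick texture, 16 granularity-spectrum) and 83 darkfield full-frame
  features (16 + 12 + 39 + 16).
* **Learning** — DNA content is predicted by least-squares gradient
  boosting (`fit_lsboost`), the rare mitotic phases (prophase, metaphase,
  anaphase, telophase; a few percent of cells combined) by boosting with
  per-stage random undersampling (`fit_rusboost`) to counter the class
  imbalance. Stratified 10-fold cross-validation with fivefold internal
  early stopping; leave-one-feature-out importance.
* **Cell-cycle fractions** — per-cell DNA content (measured or predicted)
  is histogrammed and deconvolved by the Watson pragmatic algorithm
  (`fit_watson`): Gaussians are fitted to the outer halves of the G1 and G2
  peaks — the regions S phase cannot contaminate — and the unexplained
  counts between the peaks are assigned to S, yielding fractions
  fG1 + fS + fG2M = 1.
* **Synthetic ground truth** — a seeded generator (`generate_population`)
  renders brightfield/darkfield/stain image triplets with known DNA content
  and phase, so the entire workflow is testable without instrument data.

The intended user workflow: train on a stained, annotated subset; score
arbitrarily many unstained cells. `demo_block_experiment()` reproduces that
transfer end to end on synthetic data — train a DNA-content regressor on a
stained untreated population, score two unstained arms (control and
mitotically blocked), and recover the induced G2/M shift from predicted DNA
content alone.

## Worked example

```r
library(cytocycle)

# a 600-cell synthetic population with stain ground truth
pop <- generate_population(population_config(n_cells = 600, seed = 11))
ft  <- feature_table(pop, seed = 11)       # segment + 213 features per cell
fm  <- feature_matrix(ft$features)

# label-free DNA content: 5-fold cross-validated boosted regression
cv <- cross_validate(fm$X, fm$meta$stain_integrated, k = 5,
                     task = "regression", params = boost_params(M = 60),
                     seed = 2)
print(cv)
#> 5-fold cross-validation (pearson_r)
#>   Pearson r = 0.979 +/- 0.003 (s.d. over folds)

# cell-cycle fractions from the out-of-fold predictions
fit <- fit_watson(build_histogram(cv$predictions, n_bins = 64,
                                  source = "predicted"))
print(fit)
#> Watson pragmatic fit (n = 600 cells, predicted intensities)
#>   G1: mu = 202, cv = 0.017 | G2: mu = 397 (ratio 1.97)
#>   fractions: G1 53.4%, S 20.7%, G2/M 25.9%
```

The Pearson r of 0.98 says the 213 label-free features carry nearly all of
the stain's information about DNA content in this synthetic population. The
fitted fractions (53.4 / 20.7 / 25.9%) recover the generator's composition
(55% G1, 20% S, 25% G2 + mitotic) from predictions alone; the fitted
G2:G1 peak ratio of about 2 reflects DNA doubling.

Mitotic phases, with G1/S/G2 merged into one interphase class (single-axis
DNA content cannot separate them — that is the regression's job). Rare
classes need a larger population for stable rates; at the default study
size of 3000 cells (a few minutes of feature extraction):

```r
pop3k <- generate_population(population_config(n_cells = 3000, seed = 42))
fm3k  <- feature_matrix(feature_table(pop3k, seed = 42)$features)
cv_phase <- cross_validate(fm3k$X, merge_phase_labels(fm3k$meta$phase),
                           k = 10, task = "classification",
                           params = boost_params(M = 40), seed = 5)
round(cv_phase$mean, 3)
#>   anaphase interphase  metaphase   prophase  telophase
#>      0.967      0.964      0.867      0.903      0.933
```

A command-line wrapper over the same functions is installed at
`inst/cli/cytocycle` (subcommands `simulate`, `features`, `train`,
`predict`, `cellcycle`, `demo-block`, `run`).

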