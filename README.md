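# copdct

Quantitative CT biomarkers and diagnostic models for chronic obstructive
pulmonary disease (COPD), aimed at the lung-cancer-screening setting where
CT is acquired routinely but spirometry is not.

Spirometrically, COPD is prebronchodilator FEV1/FVC < 0.70. `copdct`
extracts three imaging surrogates from paired inspiratory/expiratory chest
CT and evaluates how well they diagnose COPD on top of demographics:

* **Emphysema index** IN₋₉₅₀ = 100 · |{v ∈ lung : HU(v) < −950}| / |lung|,
  on the inspiratory scan (strict inequality).
* **Air trapping** E/I-ratio_MLD = MLD_exp / MLD_insp, the ratio of
  expiratory to inspiratory mean lung density.
* **Bronchial wall thickness** Pi10: over all measurable bronchial
  cross-sections (72-ray perpendicular wall measurements at 1-mm spacing
  along the airway centerline, after excluding trachea, main bronchi,
  branching regions and failed sections), fit √WA = a + b·Pi by ordinary
  least squares and report Pi10 = a + 10·b — the square root of wall area
  of a hypothetical airway with a 10-mm lumen perimeter.

The diagnostic ladder fits eight nested logistic models — demographics
(age, BMI, packyears, smoking status) plus every subset of
{log IN₋₉₅₀, E/I-ratio, Pi10} — and for each reports bootstrap
optimism-corrected discrimination (C-statistic with DeLong CI), shrunken
coefficients (mean bootstrap calibration slope), the optimal-accuracy
cutoff with its confusion table, and Net Reclassification Indices versus
the baseline and, for models using the expiratory scan, versus the
inspiratory-only counterpart.

A synthetic-data module generates CT phantoms (airway tubes and emphysema
clusters with closed-form ground truth) and subject cohorts with a known
generating model, so the entire pipeline is testable without clinical
data. See the methods vignette (`vignettes/copdct-methods.Rmd`) for the
models, assumptions and design decisions.

## Worked example

```r
library(copdct)

# a study-sized synthetic cohort with known generating model
cohort <- generate_cohort(cohort_config(n = 1140, seed = 1))
mean(cohort$copd)                      # 0.387  (38.7% prevalence)

ladder <- run_model_ladder(cohort, B = 100, seed = 1, stratify = FALSE)
print(ladder)
#> Diagnostic model ladder (n = 1140, B = 100)
#> id model                                           appC  corrC    acc NRIvs1
#> 1  baseline                                       0.604  0.595   63.7      -
#> 2  baseline + emphysema                           0.740  0.736   69.9   16.0
#> 3  baseline + air trapping                        0.716  0.714   69.1   18.4
#> 4  baseline + wall thickness                      0.687  0.680   66.7    7.1
#> 5  baseline + wall thickness + air trapping       0.773  0.770   72.0   23.9
#> 6  baseline + emphysema + air trapping            0.812  0.808   75.2   31.4
#> 7  baseline + emphysema + wall thickness          0.798  0.792   74.6   29.4
#> 8  baseline + emphysema + wall thickness + air trapping  0.864  0.859   80.3   42.8
```

Each biomarker improves on the demographic baseline (apparent C 0.60) and
the full model reaches C = 0.86 with 80% accuracy at its
optimal-accuracy cutoff, reclassifying a net 42.8% of subjects correctly
relative to the baseline.

Densitometry on a noiseless phantom with 10% emphysema and parenchymal
attenuation −875/−700 HU recovers the ground truth exactly:

```r
ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64), spacing = 0.5,
                                    emphysema_fraction = 0.10, noise_sd = 0),
                       seed = 1)
compute_density_metrics(ph$insp, ph$exp, ph$mask, ph$mask)
#> Density metrics
#>   emphysema index (<-950 HU): 10.00 %
#>   MLD insp/exp: -887.5 / -710.0 HU
#>   E/I-ratio: 0.800
#>   lung volume insp/exp: 0.03 / 0.03 L
```

Airway wall measurement on the standard three-tube phantom, against the
closed-form oracle (regressing (2πr, √(π((r+t)²−r²))) gives 3.244 mm):

```r
phw  <- generate_phantom(standard_wall_phantom(), seed = 1)
tree <- airway_tree_from_polylines(lapply(phw$truth$tubes, `[[`, "centerline"))
secs <- measure_sections(phw$insp, sample_cross_sections(tree, 1.0))
filt <- filter_cross_sections(secs)
compute_pi10(filt$valid, filt$tally)
#> Pi10 = 3.177 mm  (sqrtWA = 1.409 + 0.1768 * Pi; 63 sections)
```

A thin command-line front end with subcommands `simulate-cohort`,
`simulate-phantom`, `quantify`, `airways`, `fit` and `run-all` is
installed at `inst/cli/copdct.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/copdct.R", package = "copdct"))')" \
    run-all --seed 1 --out demo-run
```

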