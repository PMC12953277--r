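# tumorfd

3D box-counting fractal dimension of segmented tumor volumes, and the
downstream evaluation of that number as an imaging biomarker for
microvascular invasion (MVI) in hepatocellular carcinoma.

## Who this is for

Quantitative-imaging researchers who want (a) a tested, deterministic
Minkowski–Bouligand (box-counting) dimension estimator for 3D binary masks
on CT, and (b) the full statistical scaffolding that a biomarker study of
this kind requires — cohort simulation calibrated to published summary
statistics, univariable screening, multivariable logistic modelling, ROC
analysis with DeLong comparisons, Youden cut-off selection,
Hosmer–Lemeshow calibration, decision-curve analysis, inter-reader ICC,
and Kaplan–Meier risk stratification with log-rank tests.

## The core statistic

Cover the mask foreground with cubic boxes of edge `s` voxels (anchored at
the foreground bounding-box corner) and count occupied boxes `N(s)` over a
schedule of scales; the fractal dimension is the OLS slope

```
FD = -d log N(s) / d log s ,
```

i.e. the slope of `log N` against `log(1/s)`. For a solid cube FD = 3
exactly, for a one-voxel slab FD = 2, and for a level-3 Menger sponge
FD = log 20 / log 3 ≈ 2.7268 with r² = 1 — the package's analytic test
oracles. Patients' lesions are preprocessed to isotropic 1 mm voxels
(trilinear for CT, nearest-neighbour for masks) and cropped to the lesion
bounding box before counting.

## Worked example

```r
library(tumorfd)

# exact self-similar phantom: level-3 Menger sponge
m <- make_phantom("menger", 3)
curve <- boxcount_curve(m, box_size_schedule(dim(m$data), "ternary"))
print(curve)
#>   size count
#> 1    1  8000
#> 2    3   400
#> 3    9    20
#> 4   27     1
fit_fractal_dimension(curve, "all")
#> <fractal_result> fd = 2.7268 (r2 = 1.0000, 3 scales: 1,3,9)
```

The counts fall by a factor of 20 per 3-fold coarsening, so the fitted
slope is log 20 / log 3; the saturated `N = 1` tail is excluded from the
fit.

```r
# simulated cohort calibrated to the published training-set summaries
cohort <- simulate_cohort(sim_config(), n = 406, seed = 1)
mean(cohort$mvi)                                  # 0.328 (target 0.298)
fit_multivariable(cohort,
                  c("afp_high", "size_gt5", "multiple_tumors", "fd"))
#> <logistic_fit> mvi ~ afp_high + size_gt5 + multiple_tumors + fd (n = 406)
#>                    OR    95% CI        p
#> afp_high         2.23 1.26-3.94  0.00604
#> size_gt5         5.31 2.98-9.49 1.59e-08
#> multiple_tumors  2.43 1.00-5.91  0.05052
#> fd               1.0e8 ...       1.30e-13
```

(The enormous per-unit FD odds ratio is genuine, not divergence: the
simulated class-conditional FD distributions are tightly separated on a
0.2-wide gap, so the logistic slope per *unit* FD is steep. The `converged`
flag distinguishes this from separation.)

```r
# full study replica: simulate, screen, model, evaluate, stratify
rep <- run_study(run_config(n_train = 1000, n_test = 1000, seed = 1))
print(rep)
#> <study_report> simulate_table, seed 1, hash 2b72df79
#>   AUC: fd 0.827 / clinical 0.729 / combined 0.886
#>   DeLong combined vs clinical: p = 2.389e-31
#>   RFS log-rank p = 7.65e-05, OS log-rank p = 0.0005543
```

The combined (clinical + FD) model beats the clinical model on the
independent simulated test cohort, and patients above the training-set
Youden cut-off have worse recurrence-free and overall survival — the
qualitative orderings the real study reports (its test-set AUCs were
0.795 vs 0.752). Median RFS in this run: 35.9 months (high-risk) vs 53.9
(low-risk).

## Command line

```sh
inst/cli/tumorfd simulate --mode table --n 406 --seed 1 --out cohort.csv
inst/cli/tumorfd fd --mask lesion.nii.gz --schedule pow2 --out fd.csv
inst/cli/tumorfd fit-model --cohort cohort.csv --model combined
inst/cli/tumorfd run-study --seed 1 --out results/
```

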