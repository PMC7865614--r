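# hemiAsym

Hemispheric asymmetry mapping and classification for 2D brain-slice images.

Structural asymmetry between the left and right cerebral hemispheres changes
with degenerative dementia: slices from subjects with early (amnestic) mild
cognitive impairment (EMCI) tend to be *more* bilaterally symmetric than
those of normally-ageing controls (NC), while Alzheimer's disease (AD)
markedly *increases* asymmetry. hemiAsym turns this observation into a
measurable, classifiable quantity. It is aimed at researchers in medical
image analysis who want a transparent, fully classical (non-deep-learning)
asymmetry pipeline that runs on commodity hardware and is testable end to
end without access-controlled clinical data.

## What it computes

Given a grayscale slice `I`, the pipeline:

1. standardizes it (256×256, intensities min-max rescaled to [0, 255]) and
   strips the skull with an intensity band + largest-component rule;
2. aligns the brain to its axis of reflective symmetry: the binarized
   brain-mask centroid is translated to the image center, then the in-plane
   rotation `θ* = argmin_θ mean[(I_θ − mirror(I_θ))²]` (over the union
   support) is found by exhaustive grid search (±15°, 0.5° steps);
3. extracts the **asymmetry map** by saturating two-way subtraction of the
   aligned slice `A` and its vertical mirror:

   `D = clip0(A − mirror(A)) + clip0(mirror(A) − A) = |A − mirror(A)|`

   so bilaterally symmetric pixels are exactly 0;
4. derives the fixed 10-statistic feature vector
   (MSE, Mean, Std, Entropy, RMS, Variance, Smoothness, Kurtosis, Skewness,
   IDM) — MSE directly from the aligned slice vs. its mirror, the other nine
   from the Haar-DWT approximation subband of `D` — plus an optional
   bag-of-visual-words histogram (SURF-like detector/descriptor + K-Means
   codebook);
5. evaluates eight classical binary classifiers (Gaussian NB, linear
   discriminant, linear/quadratic/cubic/medium-Gaussian SVM, 1-NN Euclidean,
   10-NN cosine — all at fixed default hyperparameters) on the three
   dementia datasets EMCI vs. NC, AD vs. NC, AD vs. EMCI under 10 runs of
   stratified 10-fold cross-validation, reporting accuracy, sensitivity,
   specificity and ROC/AUC.

A synthetic phantom generator (`generatePhantom()`, `generateCohort()`)
renders brain-like slices whose *only* asymmetry is a known set of
unilateral lesions, with class amplitudes ordered EMCI < NC < AD, plus
controlled pose perturbation and noise — every stage of the pipeline is
validated against this ground truth.

## Worked example

```r
library(hemiAsym)

co  <- generateCohort(10, seed = 7)                 # 30 phantoms, 10/class
cfg <- pipelineConfig(runs = 2, folds = 5, seed = 7)
out <- runPipeline(co, cfg, out_dir = "results")

out$pareto
#>   label total_mse cumulative_pct
#> 1    AD  37.71995       36.42227
#> 2    NC  33.35099       68.62588
#> 3  EMCI  32.49195      100.00000

out$reports[["AD vs. NC | C-SVM"]]
#> CVReport C-SVM on AD vs. NC (2 runs x 5 folds)
#>   accuracy 100.0% (sd 0.0)  sensitivity 100.0%  specificity 100.0%  AUC 1.000
```

The Pareto table is the class-level summary of hemispheric asymmetry: total
mirror-MSE per class, ordered descending, with each class's cumulative share
of the grand total. At the default study conditions the ordering is
AD > NC > EMCI — dementia increases asymmetry, early impairment reduces it.
The absolute differences look modest because additive image noise
contributes a common mirror-MSE floor to every class; the class-dependent
lesion signal rides on top of that floor, and it is what the classifiers
exploit (the synthetic pairs classify essentially perfectly; performance on
clinical MRI is a different, data-access-dependent question).

`runPipeline()` also writes `features.csv` (one row per image: source id,
label, the 10 named statistics), `alignment.csv` (recovered pose and
symmetry score per image), `metrics.csv` / `auc.csv` (datasets × models
grids) and `config.json` (full provenance). Reruns with the same config and
seed are byte-identical.

A command-line front end with subcommands `simulate`, `preprocess`,
`align`, `features`, `evaluate` and `run` is installed at
`inst/cli/hemiasym.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hemiasym.R", package="hemiAsym"))')" \
    simulate --n-per-class 30 --out cohort --seed 7
```

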