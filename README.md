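# nacresp

Early prediction of pathological response to neoadjuvant chemotherapy (NAC)
in advanced breast cancer from paired baseline/interim PET and
diffusion-weighted MRI — as a fully seeded, testable R pipeline.

Clinical studies of this question compare two predictor families on small,
imbalanced cohorts (order of 6 responders vs 50 non-responders, responders =
Miller–Payne grades 4–5):

* **Conventional imaging parameters.** From FDG-PET inside an ellipsoid VOI:
  SUVmax; metabolic tumour volume `MTV = (# voxels with SUV ≥ 2.5) · v_voxel`;
  total lesion glycolysis `TLG = MTV · mean(SUV ≥ 2.5)`. From DWI at b = 0
  and 800 s/mm²: the mean apparent diffusion coefficient inside a circular
  ROI, with `ADC = ln(S_b0 / S_b800) / 800` per voxel. Each parameter is
  measured at baseline (X0) and interim (X1) and summarized as
  `ΔX(%) = (X1 − X0) · 100 / X0`; responders vs non-responders are scored by
  ROC analysis (Mann–Whitney AUC, DeLong 95% CI, Youden-optimal cutoff).
* **A compact CNN** on 64×64 crops of the lesion's largest cross-section
  (PET0/PET1/MRI0/MRI1): two 5×5 conv layers of 32 filters with 2×2
  max-pooling, two fully-connected layers with dropout, softmax
  cross-entropy, Adam; class imbalance handled by rotating each responder
  image 7 times in 45° steps (6 → 48 responder images in a 98-image set);
  80/20 patient-level split with 3-fold cross-validation, test metrics from
  the fold-ensemble mean probability. Pre- vs post-augmentation fold metrics
  are compared with a Mann–Whitney U test.

Because such cohorts are private, the package ships a seeded **phantom
generator** (ellipsoidal tumours in 3-D voxel grids; quadratic SUV profiles
with multiplicative Gaussian noise; monoexponential DWI pairs with Rician
noise; class-specific longitudinal effect sizes; optional responder-only
intratumoral texture) with per-patient ground truth, so the whole analysis is
reproducible and every stage is validated against exhaustive-enumeration
oracles. See the methods vignette (`vignettes/nac-response-methods.Rmd`) for
the model, the defaults and every recorded design choice.

## Worked example

```r
library(nacresp)

cfg <- cohort_config(n_responders = 5, n_nonresponders = 15,
                     grid_shape = c(32L, 32L, 32L), voxel_spacing = c(2, 2, 2),
                     tumor_radius_range = c(6, 10), seed = 42)
cohort <- generate_cohort(cfg)
params <- extract_cohort_parameters(cohort)
head(params[, c("patient_id", "suv0", "suv1", "dsuv", "adc0", "adc1", "dadc")], 4)
#>   patient_id      suv0      suv1      dsuv      adc0     adc1     dadc
#> 1       P001 15.150982 7.2285465 -52.28991 0.8852851 1.258903 42.20312
#> 2       P002  4.780273 0.9377501 -80.38292 1.0642621 1.538845 44.59269
#> 3       P003  8.365031 2.8756049 -65.62350 0.9806370 1.393942 42.14660
#> 4       P004 12.277084 9.9417481 -19.02191 1.0930067 1.603850 46.73746

labels <- classify_response(vapply(cohort, function(s) s$grade, integer(1)))
roc_analysis(params$dsuv, labels)
#> ROC: AUC 0.853 (95% CI 0.590-1.000), p = 0.00846
#>   cutoff -50.9 (responder_low): sensitivity 80%, specificity 93% (n = 5/15)

crops <- build_dataset(cohort, "PET1", augment = TRUE)
length(crops)                                            # 15 + 8 * 5 crops
#> [1] 55
sum(vapply(crops, function(cr) cr$responder, logical(1)))
#> [1] 40
```

Reading the output: baseline SUVmax values sit in the 5–15 range and drop
sharply for responders; ADC rises after the first cycle. The ΔSUV ROC is
oriented `responder_low` (responders have the larger metabolic *decline*), so
patients at or below the −50.9% cutoff are called responders, catching 4 of
the 5 responders (80% sensitivity) while misclassifying 1 of 15
non-responders (93% specificity). Augmentation bookkeeping: each of the 5
responder crops gains 7 rotated copies, giving 55 crops of which 40 carry the
responder label.

The full pipeline — quantification, ROC per parameter and molecular-subtype
subgroup, CNN per modality/timepoint pre/post augmentation, augmentation
comparison, JSON report — runs from one config:

```r
report <- run_pipeline(pipeline_config(output_dir = "run1"))
```

or from a shell via the thin front end `inst/cli/nacresp`
(`nacresp run --config cfg.yaml`, plus `simulate` / `quantify` / `roc` /
`cnn` stage commands sharing the manifest CSV contract).

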