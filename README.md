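# ftvdce

Functional tumor volume (FTV) analysis for dynamic contrast-enhanced (DCE)
breast MRI, for imaging scientists evaluating early response to neoadjuvant
systemic therapy (NAST) in triple-negative breast cancer. Roughly half of
patients reach a pathologic complete response (pCR) at surgery; a
volumetric imaging marker measured after 2 or 4 treatment cycles (C2, C4)
that separates future pCR from non-pCR patients would let non-responders be
redirected early. This package implements the full analysis chain on 4D
DCE series, plus a ground-truth synthetic cohort generator so every stage
is testable without patient data.

## The model

Per voxel, with `S_E`, `S_P`, `S_L` the early (1 or 2.5 min
post-injection), pre-contrast, and late (7 min) signal intensities:

    PE  = (S_E - S_P) / S_P x 100        (wash-in, percent)
    SER = (S_E - S_P) / (S_L - S_P)      (wash-out; capped where S_L -> S_P)

Volumetrics from three orthogonal tumor diameters (AP, CC, TR, in cm) and a
binary tumor mask:

    LD  = max(AP, CC, TR)
    TV  = 4/3 pi (AP/2)(CC/2)(TR/2)
    ETV = voxel volume x #(segmented voxels)
    FTV(tPE, tSER) = voxel volume x #(segmented voxels with PE > tPE and SER > tSER)

FTV is computed over a fixed grid of thresholds (PE 0–220% by 5%, SER 0–2
by 0.05; 1845 pairs). For each timepoint (BL, C2, C4) and relative change
(%C2/BL, %C4/BL), the cohort AUC for discriminating pCR from non-pCR is
evaluated at every pair, and the AUC-maximal pair (minimum PE-then-SER on
ties) defines the reported FTV. AUCs come with DeLong 95% confidence
intervals, Mann–Whitney group comparisons, and Youden best cutoffs;
categorical patient characteristics use the r×c (Freeman–Halton) Fisher
exact test.

## Worked example

```r
library(ftvdce)

cfg <- cohort_config(n_patients = 12, grid_shape = c(32, 32, 32),
                     spacing_mm = c(2, 2, 2), radius_mm_mean = 9,
                     radius_mm_sd = 2, seed = 20230206)
cohort <- generate_cohort(cfg)
cohort
#> <synthetic_cohort> 12 patients (7 pCR / 5 non-pCR), grid 32x32x32

report <- analyze_cohort(cohort, refine = FALSE)  # synthetic masks are exact
report
#> <cohort_report> 12 patients analyzed (0 excluded), 7 pCR / 5 non-pCR
#>   best FTV AUC 1.00: FTV at 1 min C4 at PE 0%, SER 0.00

ftv1 <- report$table_ftv[report$table_ftv$measurement == "FTV at 1 min", ]
ftv1[, c("timepoint", "pe", "ser", "auc", "ci_low", "ci_high", "p_value")]
#>  timepoint  pe  ser   auc ci_low ci_high p_value
#>         BL 210 1.80 0.643  0.361   0.924 0.33598
#>         C2 200 1.45 0.800  0.439   1.000 0.09952
#>         C4   0 0.00 1.000  1.000   1.000 0.00568
#>     %C2/BL   0 0.00 1.000  1.000   1.000 0.00253
#>     %C4/BL   0 0.00 1.000  1.000   1.000 0.00253
```

Reading the table: each row is one analysis. At baseline the best threshold
pair over the whole grid only reaches AUC 0.64 (CI spanning 0.5, p = 0.34)
— baseline FTV cannot tell future responders apart, because the generator
encodes response as on-treatment volume shrinkage, not a baseline
signature. After 4 cycles the arms separate completely (AUC 1.0 at this
desk-scale effect size): the pCR arm's enhancing volume has shrunk to ~2%
of baseline versus ~45% for non-pCR. `p_value` is the Mann–Whitney
comparison of the 5 non-pCR vs 7 pCR FTV values at the selected pair.

The same pipeline runs from an on-disk cohort (`analyze_cohort("dir/")`,
one directory per patient with `{BL,C2,C4}.nii.gz`, `*_mask.nii.gz`, and
timing sidecars `*.json`, plus `cohort.csv`), or streamed patient-by-patient
straight from a `cohort_config` for large simulations. The numbered scripts
under `analysis/` run the full workflow (simulate → measure → threshold
search → report) and write their tables under `results/`.

Fisher's exact test on a published patient-characteristics table (overall
clinical stage; pCR column 7/34/8, non-pCR column 3/34/14):

```r
fisher_exact_rxc(matrix(c(7, 34, 8, 3, 34, 14), ncol = 2))
#> [1] 0.2231739
```

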