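# tmascreen

Automated screening of immunostained tissue microarrays (TMAs) for loss of
a nuclear marker — built around MLH1 immunohistochemistry in colorectal
cancer, where absent nuclear MLH1 marks mismatch-repair-deficient (dMMR)
tumours relevant to Lynch-syndrome screening and immunotherapy eligibility.

Given a brightfield H-DAB whole-slide image of a TMA, the pipeline

1. **deconvolves** the RGB image into haematoxylin and DAB optical-density
   channels (Beer–Lambert: `OD_c = Σ_s conc_s · v_{s,c}`, inverted per pixel
   against unit stain vectors);
2. **detects cells**: nucleus segmentation on the haematoxylin OD channel
   (Gaussian smoothing σ = 1.5 µm, 8 µm opening-based background
   subtraction, 0.1 OD threshold, watershed splitting, 10–400 µm² area
   gate), 5 µm cell expansion, and a single-threshold positive/negative
   call at nucleus DAB OD mean ≥ 0.2;
3. adds **Gaussian-smoothed neighbourhood features** (FWHM 25 µm, restricted
   to the same positive/negative base class) and classifies every cell into
   normal epithelium / tumour / immune infiltrate / stroma with a
   **random forest** trained on a handful of annotated 500 × 500 µm regions;
4. **dearrays** the slide into labelled cores (A1–I18 on a 9 × 18, 0.9 mm
   grid; a core is valid iff tissue covers ≥ 5% of its 105%-scaled disc);
5. **certifies** each valid core: histology and MLH1 status each certify
   only when ≥ 75% of the relevant cells agree (MLH1 fractions use
   epithelial cells only); any uncertain axis **flags the core for manual
   review** instead of forcing a call;
6. **evaluates** calls against reference review: sensitivity and specificity
   with exact Clopper–Pearson intervals and Cohen's κ with a Wald interval.

Because TMA scans are rarely shareable, the package includes a full
synthetic TMA generator (`render_tma()`) with per-cell ground truth —
staining physics via Beer–Lambert mixing, hard-core nucleus placement,
class-specific morphology, and the five real-world ambiguity patterns
(scant tissue, atypical tumour morphology, heavy immune infiltrate,
normal-only mucosa, weak/patchy staining) — so every stage is testable
end to end without external data.

## Worked example

Agreement statistics on the bundled 74-core validation table (17 true
positives, 1 false positive, 0 false negatives, 56 true negatives):

```r
library(tmascreen)
print(agreement_report(reference_confusion()))
#> Agreement on 74 classified cores (positive = MLH1DeficientTumour)
#>   sensitivity: 100.00% (95% CI 80.49, 100.00)
#>   specificity: 98.25% (95% CI 90.61, 99.96)
#>   Cohen's kappa: 0.963 (95% CI 0.890, 1.035), p < 0.001
```

All 17 deficient tumours are recovered (the exact one-sided 95% bound for
17/17 is 80.49%), one proficient tumour is over-called (56/57 = 98.25%
specific), and chance-corrected agreement is near-perfect.

A complete synthetic screen — render a 9 × 18 TMA, train the classifier on
14 simulated annotated regions, run every stage, and compare with the
generator's ground truth:

```r
spec  <- tma_sim_spec(pixel_size = 1, scenarios = tma_study_layout(seed = 1), seed = 1)
img   <- render_tma(spec)
cfg   <- pipeline_config(detection = detection_params(requested_pixel_size = 1))
model <- train_pipeline_classifier(simulate_training_regions(14, pixel_size = 1, seed = 2), 1, cfg)
res   <- run_pipeline(img, model, cfg)
print(res$calls)
#> Core calls: 74 certified, 25 flagged (histology 16, marker 8, both 1), 63 invalid
```

Of the 99 cores with enough tissue, the unambiguous 74 certify with the
correct histology and MLH1 status and the 25 deliberately ambiguous cores
are flagged for review, split by reason exactly as designed (16 histology,
8 marker, 1 both); the 15 orientation blanks and 48 scant cores are
invalidated by the dearrayer. Run time is a few minutes on one CPU.

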