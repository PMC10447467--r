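# tmesurv

Multi-task deep learning for tumor-microenvironment (TME) classification and
survival prediction from CT in gastric cancer — with the complete downstream
statistical evaluation and a seeded synthetic phantom-cohort generator.

## What it is for

The immune and stromal microenvironment of a gastric tumor is prognostic and
predicts treatment benefit, but it is normally measured by
immunohistochemistry (IHC) on resected tissue. `tmesurv` implements a
noninvasive alternative: a multi-task network that reads five tumor-centered
CT slices and jointly predicts

* the tumor's TME class — four classes defined by the quadrants of the
  gastric-cancer ImmunoScore
  (`IS_GC = 0.149 CD3_IM + 0.021 CD3_CT + 0.044 CD8_IM + 0.096 CD45RO_CT − 0.173 CD66b_IM`)
  and the periostin (POSTN) stromal score (intensity × extent averaged over
  five fields), each dichotomized at its training-cohort median — and
* a scalar survival risk (the deep learning survival score, DLS), trained
  with the negative log Cox partial likelihood
  `−Σ_{i:E_i=1} [ĥ_i − log Σ_{T_j≥T_i} exp(ĥ_j)]` (Breslow ties).

Per-slice backbone features are refined by two leaky-ReLU FC layers and
pooled across slices by gated attention,
`A = softmax(w3(tanh(w1 f + b1) ⊙ σ(w2 f + b2)) + b3)` (softmax across
slices, one attention row per task); the classification head reads `M[1,]`,
and the survival head reads `M[2,]` concatenated with the predicted class
probabilities. The package also contains the study's surrounding machinery:
CT preprocessing (trilinear resampling to 0.75×0.75×2.5 mm, [−150, 150] HU
windowing, tumor-centered 160×160 5-slice stacks, training-time
augmentation), IHC labeling, Kaplan–Meier/log-rank/Cox analyses,
time-dependent ROC with DeLong comparisons, C-index, calibration, continuous
NRI, IPCW Brier/IBS with .632+ prediction-error curves, chi-square variable
importance, an integrated clinical+DLS model with frozen 8-quantile risk
strata, propensity-matched chemotherapy-benefit analysis with interaction
tests, CPS categorization, and a CART decision tree for immunotherapy
response. Audience: researchers in imaging biomarkers and methods
reviewers; everything runs at desk scale on synthetic phantoms (no patient
data are included or required).

## Worked example

```r
library(tmesurv)

# score an IHC panel (densities in cells per field)
panel <- list(cd3_im = 18, cd3_ct = 30, cd8_im = 12, cd45ro_ct = 25, cd66b_im = 4)
compute_is_gc(panel)                                  # 5.548
compute_postn_score(c(2,1,2,3,2), c(3,2,4,4,3))       # 6.8

# a seeded phantom cohort (statistics-only; add out_dir= for NIfTI volumes)
gen <- generator_config(n_subjects = 400, seed = 1)
co  <- generate_cohort(gen, generate_images = FALSE)

# TME labels from IHC, thresholds at the cohort medians
thr <- fit_tme_thresholds(co$is_gc, co$postn_score)
co$tme_class <- assign_tme_class(co$is_gc, co$postn_score, thr)
table(co$tme_class)                                   # 92 108 106 94

# prognosis and class-dependent chemotherapy effect
log_rank_test(co$time, co$event, co$true_class)       # chisq 209.8, p 3.3e-45
e1 <- with(co[co$true_class == 1, ],
           stratum_treatment_effect(time, event, chemo))
e1$hr                                                 # 0.301 (CI 0.140-0.647)

# immunotherapy response: TME class + CPS decision tree
rr <- response_report(data.frame(predicted_class = co$true_class,
                                 cps = co$cps, response = co$response))
rr$orr_by_class     # 0.596 0.587 0.188 0.188   (overall 0.388)
rr$auc              # cps 0.625, tme 0.713, composite 0.741
```

The class-wise response rates and the class-1 chemotherapy hazard ratio track
the generator's configured effects (marginal response rates 69/53/18/17% and
per-class chemo HRs 0.258/0.691/0.831/1.669 at infinite n); at n = 400 they
are recovered within sampling error. The log-rank test shows the designed
hazard ordering across classes. The composite (tree) model outperforms CPS
alone because response depends on both features by construction.

The imaging arm runs through `run_pipeline()` (or the thin CLI at
`inst/cli/tmesurv_pipeline.R`): simulate → preprocess → train → predict →
evaluate → chemo-benefit → immuno-response, writing per-stage artifacts and
a reproducibility manifest:

```r
cfg <- default_run_config(out_dir = "run1", seed = 313, n_subjects = 60,
                          epochs = 12, pec_B = 15)
run_pipeline(cfg)   # ~2 minutes on one CPU
```

See `vignettes/tmesurv-methods.Rmd` for the model, the phantom generator's
assumptions (and what it deliberately does not emulate), numerical
conventions, and design decisions.

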