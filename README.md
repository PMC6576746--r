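# winoccf

Genome-scale drug off-target prediction from positive-only
chemical–protein association data, by **w**eighted **i**mputed
**n**eighborhood-regularized **O**ne-**C**lass **C**ollaborative
**F**iltering — plus the downstream analytics an off-target campaign
needs: kinome-panel evaluation, dose-response parameter extraction
(Kd, EC50, IC50, GI50, activity area), and drug-sensitivity
differential-expression statistics.

It is written for computational pharmacologists and cheminformaticians
who have (i) bioactivity records from heterogeneous sources, (ii)
structure-based off-target screens (binding-site similarity + docking),
and (iii) chemical and protein similarity matrices, and who want ranked
off-target hypotheses with a reproducible evaluation protocol.

## The model

Observed positive associations form a sparse chemicals × proteins matrix
*R*; a structure screen contributes putative positives *Q* for unobserved
cells. Nonnegative low-rank factors *U*, *V* are obtained by iteratively
minimizing

```
min_{U,V >= 0}  Σ_ij w_ij (R_ij + Q_ij − U_i·V_j)²
                + α(||U||² + ||V||²)
                + β tr(Uᵀ(D_C − C)U) + γ tr(Vᵀ(D_T − T)V)
```

where the sum runs over **all** cells with class-dependent confidence
weights (w_obs on R, w_imp on Q, w_zero on the unobserved background), C
and T are chemical–chemical and protein–protein similarity graphs with
degree matrices D_C, D_T, and predictions are P_ij = U_i · V_j. The
background term is handled implicitly — nothing dense is ever formed — and
optimization uses monotone multiplicative updates (objective
non-increasing at every iteration, seeded and bitwise reproducible).

Around the solver, the package standardizes activity records into R
(IC50 ≤ 10 µM, Ki ≤ 5 µM, pKi ≥ 5, percent-inhibition converted via
Ki = conc × (100 − %inh)/%inh, confidence < 9 excluded), builds Q with the
dual screen filter (site-similarity p < 2e-3 **and** docking score < −7.5,
both strict), and evaluates rankings against kinome panels (binder ⇔
percent control < 30 at 100 µM; top ceiling(2.5% × panel) flagged).

## Worked example

```r
library(winoccf)

## 1. Structure screen on the packaged PDE3B off-target table
fx <- offtarget_screen_fixture()
hits <- filter_offtarget_candidates(fx$sites, fx$docks)   # p < 2e-3 & score < -7.5
table(hits$chemical_key)
#>     amrinone   anagrelide    enoximone levosimendan    milrinone
#>            1            7            4           16            5
Q <- build_imputation_matrix(hits[hits$chemical_key == "levosimendan", ])
#> Imputation matrix Q: 16 putative pair(s)
```

Levosimendan retains 16 putative off-targets (including the RIOK1
structure 4OTP at p = 1.45e-3, score = −7.6); scores of exactly −7.5 are
rejected by the strict threshold.

```r
## 2. Factorization on the seeded synthetic benchmark
sim <- simulate_interaction_data(seed = 42)   # 200 x 100, rank 5, 5% positives
fit <- winoccf(sim$R, Q = sim$Q, chem_sim = sim$C, prot_sim = sim$T,
               rank = 5, alpha = 0.1, beta = 0.1, gamma = 0.1,
               weights = weight_scheme(1, 0.5, 0.1),
               max_iter = 500, tol = 1e-7, seed = 42)
fit
#> Weighted imputed neighborhood-regularized one-class factorization
#>   200 chemicals x 100 proteins, rank 5
#>   observed entries: 800, imputed entries: 60
#>   alpha = 0.1, beta = 0.1, gamma = 0.1; w = (1, 0.5, 0.1)
#>   500 iteration(s), objective 818.813 -> 326.518 (max_iter reached)
rank_targets(fit, "CHEM0001", top = 3)
#>   protein_key     score
#> 1    PROT0012 0.8890461
#> 2    PROT0020 0.8536458
#> 3    PROT0017 0.8438939
```

Held-out positives from this benchmark are retrieved with rank-AUC ≈ 0.997
(see `tests/testthat/test-acceptance.R`).

```r
## 3. Dose-response characterization of a validated hit
d <- simulate_dose_response("hill",
       params = list(background = 0, signal = 100, kd = 0.82),
       doses = half_log_doses(100, 12), noise_sd = 0)
fit_hill(d)
#> Hill binding fit: Kd = 0.82 uM (signal 100 -> background -1.314e-08), RSS = 4.99e-16

## 4. Panel evaluation metrics (percent, 3 significant figures)
signif(precision_recall_fpr(4, 8, 408, 32), 3)
#> precision    recall       fpr
#>     33.30     11.10      1.92
```

The Hill fitter recovers the binding constant of a noise-free curve to
machine precision; with realistic noise (sd = 2 on a 12-point curve) the
median relative Kd error over 200 replicates stays below 10%. The
confusion-count example converts (TP, FP, TN, FN) = (4, 8, 408, 32) on a
452-kinase panel into precision 33.3%, recall 11.1%, FPR 1.92%.

A thin command-line front-end over the same functions is installed at
`system.file("cli", "dti_tools.R", package = "winoccf")` with subcommands
`simulate`, `build-matrix`, `screen`, `fit`, `rank`, `evaluate`,
`dose-hill`, `dose-sigmoid`, `sensitivity`, `config`.

## Package layout

- `R/activity.R` — activity standardization and interaction-matrix assembly
- `R/screen.R` — structure-screen filter and imputation matrix Q
- `R/winoccf.R`, `R/winoccf-methods.R` — the factorization model and its
  S3 methods (`print`, `summary`, `coef`, `predict`, `fitted`,
  `residuals`, `plot`, `rank_targets`)
- `R/dose_response.R` — %control, Hill and sigmoid fits, EC50/IC50/GI50,
  activity area
- `R/sensitivity.R` — cell-line classification, pooled t-tests, fold
  change and q-values as printed, gene selection, hypergeometric ORA
- `R/evaluation.R` — kinome-panel truth, top-k% cut, confusion metrics
- `R/simulate.R` — seeded generators for every input class
- `R/io.R` — Matrix Market / TSV-triple / GMT / report readers and writers
- `vignettes/drug-target-prediction.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
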