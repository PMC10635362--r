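# blastarrest

Subpopulation-level analysis of treatment-resistant T-cell acute
lymphoblastic leukemia (T-ALL) for computational biologists working with
single-cell and bulk transcriptomes. Leukemic blasts in ETP-ALL arrest along
normal hematopoietic development: the immature, bone-marrow-progenitor-like
(**BMP-like**) compartment — blasts resembling HSPC/LMPP/CLP/ETP stages — is
the treatment-resistant one, while **T-specified** blasts respond. The
package turns that observation into a reproducible pipeline:

1. **Projection** — map blasts onto a two-branch (myeloid/T) healthy
   reference by PCA latent space + k-nearest-neighbour plurality transfer,
   yielding per-cell stage label, confidence (fraction of the k neighbours
   voting for the label), and unified pseudotime `t ∈ [−1, 1]` (myeloid
   mapped to `−t_raw`, T to `+t_raw`, shared HSPC root at 0).
2. **Arrest spectra** — 20-bin histograms of unified pseudotime per group,
   compared by the two-sample Kolmogorov–Smirnov statistic
   `D = sup_t |F̂_A(t) − F̂_B(t)|` and Wilcoxon rank-sum tests (exact by
   enumeration for combined n ≤ 12); samples called BMP-like High iff
   their BMP-like blast fraction exceeds 30% strictly.
3. **Signatures** — per-gene rank-sum differential expression with
   `log2FC = log2((mean_A + 1)/(mean_B + 1))` on counts-per-10k, strict
   filters (FDR < 0.001, log2FC > 0.5), and a consensus rule keeping overlap
   genes with mean log2FC > 0.9 across two comparisons.
4. **Scoring** — the Z-difference statistic
   `score_s = mean_{g∈pos} z_{gs} − mean_{g∈neg} z_{gs}` (population-SD
   z-scores across samples) and the recovery-curve AUC over the top 25% of
   ranked genes, normalized by its maximum; cohorts binarized by sign or
   median split.
5. **Survival** — Kaplan–Meier curves and Cox proportional-hazards fits
   (Breslow ties, likelihood-ratio p) with MRD/CNS covariates, plus NOTCH1
   mutation-dosage analysis (bins 0/1/2+, per-patient total variant allele
   fraction) and recurrence filters for mutations (≥ 5 samples, mean
   VAF > 0.05) and fusions (≥ 2 samples).
6. **Target ranking** — a 0–8 consensus score per gene: three drug-target
   databases + connectivity-screen filter + dependency-screen filter (0–5)
   plus three tiered differential-expression components (0–3).
7. **Drug nomination** — IC50 activity categories across four ETP models
   (strict < 1000 nM) and the three-comparison rule nominating compounds
   with strictly lower BMP-high median IC50 in every comparison.

Because the originating patient cohorts are not publicly available, a
first-class synthetic-data module (`make_reference()`, `make_blasts()`,
`make_cohort()`, `make_evidence_fixtures()`, `make_ic50_fixture()`)
simulates every input with planted ground truth — trajectory, mixtures,
survival hazards (`h(t) = h0 · exp(γ · BMP fraction)`), mutation dosage,
and evidence databases — so every stage of the pipeline is testable.

## Worked example

```r
library(blastarrest)

cfg <- trajectory_config(n_genes = 800, n_cells_per_stage = 100,
                         effect_log2fc = 1, n_signature_genes = 30)
ref <- make_reference(cfg, seed = 1)
lat <- fit_latent(ref$counts, n_dims = 15)

bl <- make_blasts(c(HSPC = .2, ETP = .3, ProT = .3, DP = .2), 400, cfg,
                  seed = 2, sample_id = "P001")
proj <- transfer_labels(bl$counts, ref, lat, k = 25, sample_id = "P001")
state_proportions(proj)
#> # A tibble: 1 × 9
#>   sample_id n_cells bmp_like post_commit pro_t pre_t myeloid_other bmp_fraction bmp_class
#> 1 P001          400    0.575        0.18 0.245     0             0        0.575 High
```

The planted mixture put 50% of blasts in BMP-like states (HSPC + ETP); the
projection recovers a BMP-like fraction of 0.575 and calls the sample High
(> 30%). On a simulated 200-patient cohort with planted log-hazard effect
γ = 1:

```r
cc <- cohort_config(n_samples = 200, hazard_log_effect = 1)
ch <- make_cohort(cc, cfg)
fit <- cox_fit(ch$cohort, c("bmp_fraction_true", "mrd_status"))
tidy(fit)
#> # A tibble: 2 × 7
#>   term               estimate std_error statistic p_value conf_low conf_high
#> 1 bmp_fraction_true    1.14       0.604     1.88   0.0602  -0.0486     2.32
#> 2 mrd_statuspositive   0.0664     0.267     0.248  0.804   -0.457      0.590
```

The BMP-fraction coefficient estimate (1.14, 95% CI −0.05–2.32) covers the
planted γ = 1; at n = 200 with ~32% events the interval is wide, which is
why the calibration checks below use n = 500 and replication.
`plot_spectrum()`, `plot_km()`, `plot_ledger()`, and `autoplot()` methods
render the spectra, survival curves, evidence rankings, and Cox forests.

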