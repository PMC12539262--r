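# circaphase

Unsupervised circadian phase inference for proteomic (and other omics) time
courses.

Many proteomic datasets — postmortem brain tissue, biobanked urine or
plasma — carry no collection-time labels, which makes circadian analysis
impossible with standard rhythmometry. `circaphase` assigns each sample a
position on the 24-hour cycle from the expression matrix alone: no time
labels, no seed set of known rhythmic proteins. It is aimed at researchers
who want to order unlabeled samples in circadian time and then call
rhythmic and ultradian proteins against the inferred phases.

## Method at a glance

1. **Normalize**: per-protein z-scoring (population SD); matrices with
   ≥ 5000 proteins are reduced to a cap by raw-scale variance (or seeded
   k-means cluster selection).
2. **Pretrain**: a stack of shallow tanh autoencoders, trained greedily
   layer by layer, compresses each sample to a two-unit bottleneck
   \((s_i, c_i)\); the initial phase is
   \(\phi_i^0 = \operatorname{atan2}(s_i, c_i)\).
3. **Fine-tune**: each protein is modelled as
   \(\hat{x}_{ip} = L_p + A_p\cos(\omega_p\hat\phi_i + \psi_p)\)
   (mesor, amplitude, acrophase, free period), and the encoder plus all
   cosine parameters are optimized jointly under the robust loss
   \(\tfrac1m\sum_i \tfrac1n\sum_p |x_{ip}-\hat{x}_{ip}|^q + \lambda R(\Theta)\)
   with defaults \(q=1\), \(\lambda=0\).
4. **Screen**: samples/proteins whose signed mean fitting residual deviates
   more than 2 SD from the population are flagged; high-amplitude proteins
   are rescued; the network is retrained on the cleaned data.
5. **Call and evaluate**: cosinor refits on the original scale give
   per-protein statistics (BH-FDR, relative amplitude rAMP, \(R^2\));
   rhythmic calls use FDR < 0.05, rAMP ≥ 0.1, \(R^2\) ≥ 0.1 and ultradian
   (12-h) calls use FDR < 5e-4, rAMP ≥ 0.2, \(R^2\) ≥ 0.6. When collection
   times are known, predictions are aligned over rotation/reflection and
   scored by the normalized area under the error-threshold curve (nAUC;
   1 = perfect, 0.5 = random).

See `vignettes/methods.Rmd` for the full model description, parameter
reference and limitations.

## Worked example

```r
library(circaphase)

# a synthetic two-day time course with known truth: 16 samples, 300 proteins,
# 30% rhythmic, noise at half the median planted amplitude
ds  <- generate_synthetic(synthetic_spec(m = 16, n = 300, rhythmic_fraction = 0.3,
                                         phase_sampling = "two_day_grid", seed = 42))
fit <- run_pipeline(run_config(seed = 42), ds$matrix)
fit
#> circaphase_fit: 16 samples, 300 proteins; 53 rhythmic call(s); 0 outlier protein(s), 0 outlier sample(s)
#>   aligned mean circular error 1.17 h, nAUC 0.903

head(fit$sample_table, 3)
#>   sample_id phase_radians phase_degrees phase_hours outlier_flag
#> 1       S01      4.028999      230.8446    15.38964        FALSE
#> 2       S02      5.159446      295.6145    19.70763        FALSE
#> 3       S03      6.101605      349.5962    23.30642        FALSE

write_results(fit, "results/")   # sample/protein tables, outlier report, loss trace
```

The sample table gives each sample's inferred clock position (here recovered
to within 1.2 h of the planted times on average, after alignment); the protein
table carries one row per input protein with its cosine geometry, FDR, rAMP,
\(R^2\) and outlier flag. `call_ultradian()` refits at the 12-h period, and
`anchor_to_reference()` re-expresses acrophases relative to a chosen
protein.

A thin CLI over the same functions is shipped in `inst/cli/circaphase`
(subcommands `run`, `normalize`, `simulate`, `evaluate`, `rhythmic`).

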