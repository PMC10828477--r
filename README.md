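# methylRate

Cross-tissue comparison of DNA methylation ageing rates.

## The problem

DNA methylation (DNAm) clocks — sparse linear models $\hat y =
c_0 + \sum_j c_j \beta_j$ mapping CpG beta values to age — are widely used
to ask whether tissues age at different rates. Naively comparing DNAm ages
across tissues is unreliable: a clock underestimates any tissue that was
under-represented in its training data, for reasons unrelated to ageing.
`methylRate` is for epigenomics researchers who have (or simulate) two
tissues measured on the **same subjects** and want a symmetric, testable
rate comparison:

1. a covariate-adjusted age EWAS per tissue
   ($\beta_i \sim w_{1i}\,\mathrm{Age} + \mathrm{Sex} + \mathrm{Batch} +
   \mathrm{Disease} + c_0$, Bonferroni-corrected $p \le 0.01$),
2. selection of the CpGs age-associated in **both** tissues,
3. elastic-net clocks
   ($\tfrac{1}{2n}\sum_i w_i (y_i - c_0 - x_i^\top c)^2 + \lambda \sum_j
   \gamma_j[\tfrac{1-\alpha}{2} c_j^2 + \alpha |c_j|]$, $\lambda$ by
   internal CV) trained on each tissue restricted to that shared set,
4. reciprocal application: the slope of DNAm age on chronological age in
   the *other* tissue reads off the relative ageing tick rate — slope
   $> 1$ in one direction and $< 1$ in the reverse direction consistently
   identify the slower tissue.

The package also provides the surrounding machinery: a synthetic
paired-tissue cohort generator with ground truth (for calibration and
parameter-recovery testing), intensity-to-beta conversion
($\beta = M/(M+U+100)$), sex and beta-density QC, probe filtering,
fixed-reference quantile normalization, leave-one-dataset-out and k-fold
cross-validation, RMSD/MAD/correlation/slope accuracy metrics, age
acceleration (difference and residual modes), and plain-text clock
serialization. Data containers are Bioconductor-style S4
(`BetaSet` extends `SummarizedExperiment`).

## Worked example

```r
library(methylRate)

cfg <- simulationConfig(nSubjects = 200, seed = 11, noiseSd = 0.01,
  cpgCounts = c(shared_age = 60L, tissueA_only = 40L, tissueB_only = 120L,
                null = 600L, sex_linked = 40L))
study <- generateCohort(cfg)
qcFilter(tissueA(study))$report
ewasA <- fitAgeEwas(tissueA(study))
ewasB <- fitAgeEwas(tissueB(study))
part  <- partitionCpgs(ewasA, ewasB)
rates <- compareRates(study, part$shared, transform = "identity",
                      config = enetConfig(alpha = 0.2, seed = 1))
```

Output:

```
QC report: 200 samples in, 200 retained
  excluded: sex_mismatch=0, abnormal_density=0 (density threshold 0.50)
CpG partition [CBL vs MTG]: 40 | 60 shared | 120
  shared = 60.0% of CBL significant, 33.3% of MTG significant
Ageing-rate comparison [CBL vs MTG], 60 shared CpGs
  CBL-trained clock on MTG: slope 1.967, intercept 16.92
  MTG-trained clock on CBL: slope 0.493, intercept -8.21
  verdict: CBL has the smaller ageing tick rate (both directions agree)
```

Reading the numbers: the generator gave tissue B (MTG) per-year effects
twice tissue A's (CBL) on the shared CpGs. The clock trained on CBL, applied
to MTG, sees age-related methylation change accumulating twice as fast and
returns slope ≈ 2; the MTG-trained clock applied to CBL returns slope ≈ 0.5.
Both directions agree, so CBL is reported as the tissue with the smaller
ageing tick rate on the shared CpGs — recovering the configured ground
truth. `rates$selfCV` carries each tissue's leave-one-dataset-out accuracy
(here r ≈ 0.99, MAD ≈ 1.1 years), and `rates$tallies` the supporting
fractions (CpGs gaining methylation in both tissues, lower-methylated in A,
smaller absolute effect in A).

A complete simulate → QC → EWAS → partition → train → rate-comparison run
with deterministic TSV outputs and a JSON manifest:

```r
runPipeline(system.file("extdata", "demo_config.yaml", package = "methylRate"))
```

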