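# itvcv

Low-bias estimation of intraspecific trait variation (ITV) with the
coefficient of variation.

## The problem

Ecologists quantify ITV — how much a functional trait (specific leaf area,
height, body dimensions, ...) varies among conspecific individuals — with
the coefficient of variation, CV = σ/μ, because it is dimensionless and
comparable across traits and species. Nearly every study uses the plug-in
estimator

    CV1 = s / x̄

which **underestimates** the population CV at the 10–50 individuals per
species that field campaigns typically afford, by an amount that depends on
the skewness and kurtosis of the trait distribution — so the bias differs
among traits and species even at identical sample size. `itvcv` provides
bias-aware estimators, the data normalizations that interact with them, a
realistic trait-pool simulator, and a resampling engine that measures the
bias directly.

## Estimators

With N the sample size, g1 the plug-in skewness and g2 the plug-in excess
kurtosis:

| estimator | formula | idea |
|---|---|---|
| `cv1` | s/x̄ | plug-in |
| `cv2` | cv1·(1 + 1/(4N)) | removes the normal-theory bias −CV/(4N) |
| `cv3` | cv1 / [1 − (cv1/N)(3·cv1 − 2·g1)] | skewness-aware correction |
| `cv4` | cv1 − cv1³/N + cv1/(4N) + cv1²·g1/(2N) + cv1·g2/(8N) | skewness + kurtosis correction |
| `cv5`, `cv6` | (cv3+cv4)/2, (cv2+cv4)/2 | arithmetic composites |
| `cv7`, `cv8` | √(cv3·cv4), √(cv2·cv4) | geometric composites |

`cv4` combined with a natural-log normalization (with an add-one shift when
any value is below 1) is the recommended default for right-skewed trait
data: on simulated contaminated-gamma pools it reaches the ±5% accuracy
band by 10–20 samples, where `cv1` on raw data can need hundreds.

## Worked example

```r
library(itvcv)
set.seed(42)
x <- rgamma(20, shape = 4, scale = 12)   # one trait sample, n = 20
estimate_cv(x)
#> CV estimates (n = 20):
#>    cv1    cv2    cv3    cv4    cv5    cv6    cv7    cv8
#> 0.5026 0.5089 0.5121 0.5016 0.5069 0.5053 0.5068 0.5052
#> moments: mean 52.211, sd 26.2421, skewness 0.3863, excess kurtosis -1.073
```

The population CV of gamma(shape = 4) is 1/√4 = 0.5: all corrected
estimators land close, while `cv1` alone would be biased low on average
over repeated samples.

Measuring that bias directly against a simulated population:

```r
set.seed(7)
pool <- simulate_pool()   # 9,520 gamma draws + 480 extreme values
pool
#> trait_pool: 10000 values, simulated gamma(9.9, 14.9) + 480 extremes, transform raw, cv_true 0.3539

bp <- bias_profile(pool, grid = c(10, 20, 50, 100), replicates = 1999,
                   estimators = c(1, 4))
bp
#>   estimator   k mean_cv        se       bias         pb
#> 1       cv1  10  0.3365 0.0018613 -1.741e-02 -4.920e-02
#> 2       cv1  20  0.3457 0.0012804 -8.205e-03 -2.318e-02
#> 3       cv1  50  0.3499 0.0007607 -4.055e-03 -1.146e-02
#> 4       cv1 100  0.3528 0.0005108 -1.114e-03 -3.149e-03
#> 5       cv4  10  0.3429 0.0019123 -1.097e-02 -3.098e-02
#> 6       cv4  20  0.3503 0.0013009 -3.654e-03 -1.032e-02
#> 7       cv4  50  0.3520 0.0007636 -1.915e-03 -5.411e-03
#> 8       cv4 100  0.3539 0.0005113 -1.165e-05 -3.293e-05
```

At every sample size `cv1`'s proportional bias (`pb`) is negative —
underestimation — and `cv4`'s is roughly half as large, vanishing by
k = 100. `min_sample_size(bp)` reports the smallest k whose |pb| stays
within ±5%.

For long-format trait tables (columns `species`, `trait`, `value`):

```r
tab <- read_trait_table("traits.csv")
estimate_traits(tab, transforms = c("raw", "log"))        # per-group CVs
evaluate_matrix(tab, transforms = c("raw", "log"))        # bias sweep + k_min
```

## Command line

```sh
Rscript inst/cli/itvcv simulate --pools 20 --seed 1 --out pools.csv
Rscript inst/cli/itvcv evaluate --input pools.csv --transforms raw,log \
    --grid 10:400:5 --replicates 9999 --seed 1 --out-prefix out/run_
Rscript inst/cli/itvcv minsize  --input traits.csv --accuracy 0.05 \
    --seed 1 --out-prefix out/ms_
```

(after installation the script also lives at `system.file("cli/itvcv",
package = "itvcv")`). Outputs are full-precision CSVs plus a JSON summary,
a YAML config echo and a run log; exit codes are 0 (ok), 1 (user error),
2 (internal).

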