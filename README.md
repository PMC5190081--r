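# cnentropy

Quantifies **inter-tumor genomic heterogeneity** from array-CGH copy
number profiles as *DNA copy number entropy*, and relates it to treatment
groups and patient survival. The intended users are cancer-genomics
analysts working with two-channel aCGH (or any probe-level log2-ratio)
data who want a reproducible, fully tested pipeline from raw intensity
tables to survival association — plus a seeded synthetic cohort generator
so every stage can be verified against ground truth without any external
download.

## The statistic

For segmented profiles $x_1,\dots,x_n \in \mathbb{R}^d$ ($n$ samples,
$d$ probes), the package estimates differential entropy with the
first-nearest-neighbour (Kozachenko–Leonenko) estimator. With $\rho_i$
the distance from sample $i$ to its nearest neighbouring profile,

```
full_kl:     h_i = d·log(ρ_i) + log(n−1) + γ + log V_d ,   V_d = π^(d/2)/Γ(d/2+1)
normalized:  h_i = log(ρ_i/√d) + log(n−1)
H = mean(h_i)
```

`full_kl` carries the full constants and is validated against closed-form
Gaussian entropies; `normalized` is the dimension-stabilized cohort
default (the constants diverge at genomic `d`). Tumors that aberrate at
*shared* genomic locations sit close to their neighbours and score low
entropy; tumors aberrant at *dispersed* locations score high. Group
differences are tested by permutation with the entropy difference as the
statistic, genome-wide and per chromosome (Benjamini–Hochberg, q < 0.1),
and entropy is linked to survival via Cox regression and Kaplan–Meier /
log-rank analysis.

## Worked example

A complete synthetic study — simulate a homogeneous (CS-like) and a
heterogeneous (S-like) arm, preprocess, segment, estimate entropy, test
the group difference, and fit survival models:

```r
library(cnentropy)
cfg <- pipeline_config(seed = 1,
                       simulate = list(n_probes = 2200L, n_per_group = 10L),
                       entropy = list(B = 999L))
rep <- run_pipeline(cfg)
rep
#> pipeline_report: 5 stages
#>   simulate   records: 20
#>   preprocess records: 2121
#>   segment    records: 524
#>   entropy    records: 20
#>   associate  records: 20

rep$results$group_test
#> permutation test (monte_carlo): T = -0.458692, p = 0.001 (B = 999, two-sided)
```

The test statistic `T = H(CS-like) − H(S-like) = −0.459` nats: the
shared-pool arm is measurably more homogeneous, and none of 999 label
permutations produced as extreme a difference (p = 0.001). Per-sample
entropy contributions (cohort z-scores; low values = profiles close to
their neighbours):

```r
round(head(rep$results$entropy, 4), 3)
#> CS_like_01 CS_like_02 CS_like_03 CS_like_04
#>     -1.482     -0.931     -0.646     -1.244
```

Survival in this run was generated from the measured entropy with a true
log hazard ratio of log(1.8) per unit; the Cox fit and the median-split
Kaplan–Meier analysis recover a strong effect at n = 20:

```r
rep$results$cox
#> Cox PH: HR 3.862 (95% CI 1.597-9.342), p = 0.002714, n = 20, events = 15
rep$results$km
#>   group  n events    median     ci_low  ci_high
#> 1   low 10      6 11.895062 0.03897541       NA
#> 2  high 10      9  0.537014 0.07567808 2.035604
#> log-rank chisq = 11.010, p = 0.000906
```

High-entropy patients die a median 0.5 years after surgery in this
simulation versus 11.9 years for low-entropy patients — the direction and
rough magnitude the hazard model was told to produce, recovered through
the whole pipeline. `plot(rep$results$km)`, `plot(rep$results$dispersion)`
and `plot_entropy_beans()` draw the standard figures.

A thin command-line wrapper is included for batch use:

```sh
Rscript inst/scripts/run-pipeline.R config.yaml output_dir
```

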