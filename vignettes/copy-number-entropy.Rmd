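---
title: "Quantifying inter-tumor heterogeneity as DNA copy number entropy"
author: "cnentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-tumor heterogeneity as DNA copy number entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnentropy)
```

## The problem

Two tumors can carry the same *amount* of copy-number aberration yet differ
in *where* those aberrations sit. A cohort whose tumors gain and lose the
same genomic regions is homogeneous; a cohort whose tumors are aberrant at
many different locations is heterogeneous. `cnentropy` quantifies this
inter-tumor heterogeneity from array-CGH log2-ratio profiles as the
differential entropy of the cohort's segmented copy-number profiles, and
provides the surrounding machinery — preprocessing, segmentation,
permutation inference, dispersion summaries, survival association, and a
fully seeded synthetic cohort generator that gives every stage a ground
truth.

## The entropy estimator

Let $x_1, \dots, x_n \in \mathbb{R}^d$ be the segmented profiles of $n$
samples over $d$ probes, viewed as draws from an unknown density $f$. The
package estimates the differential entropy $H(f) = -\int f \log f$ with the
classical first-nearest-neighbour (Kozachenko–Leonenko) estimator. With
$\rho_i$ the Euclidean distance from $x_i$ to its nearest other sample,

$$\hat H_{\mathrm{KL}} = \frac{1}{n}\sum_{i=1}^n h_i,\qquad
h_i = d\,\log \rho_i + \log(n-1) + \gamma + \log V_d,$$

where $V_d = \pi^{d/2}/\Gamma(d/2+1)$ is the unit-ball volume and $\gamma
\approx 0.5772$ the Euler–Mascheroni constant. `estimate_entropy(...,
estimator = "full_kl")` implements this form; it is consistent and is
validated in the test suite against closed-form Gaussian entropies at $d
\in \{1, 2\}$.

At genomic dimension ($d \sim 10^4$–$10^5$) the constants $d \log \rho_i$
and $\log V_d$ diverge, while everything scientifically relevant —
which samples are far from their neighbours, which group is more spread
out — lives in the distances. The cohort default (`"normalized"`) is the
dimension-stabilized variant

$$h_i = \log\!\big(\rho_i / \sqrt{d}\big) + \log(n-1),$$

i.e. distances measured per dimension, with the unit-ball term and the
$d$-multiplier dropped. Both variants satisfy exact location invariance
and a deterministic scale law (multiplying the data by $s$ shifts the
normalized $H$ by $\log s$ and the full form by $d \log s$), so every
*group contrast* is invariant to the choice; the tests assert these laws
to $10^{-9}$. Per-sample values $h_i$ are computed with neighbours drawn
from the whole cohort, so each case gets one value against the common
background; the "normalised" per-sample entropy is the cohort z-score of
the $h_i$ (configurable off).

Duplicate profiles give $\rho_i = 0$; such distances are floored at
`tie_epsilon` ($10^{-8}$ by default) with a warning, keeping the logarithm
finite and the computation deterministic. The neighbour count is fixed at
$k = 1$.

## Permutation inference

Group differences are tested with the statistic $T = H(\text{group 1}) -
H(\text{group 2})$, each entropy computed within its group, under label
permutation with group sizes fixed. When the number of distinct label
arrangements is at most 20,000 the null is enumerated exhaustively and the
p-value is the proportion of arrangements with $|T| \ge |T_{\mathrm{obs}}|$
(the observed split is one of them, so $p > 0$); otherwise $B$ Monte-Carlo
permutations are drawn and $p = (1 + \#\{|T_b| \ge
|T_{\mathrm{obs}}|\})/(B+1)$. Type-I error of the Monte-Carlo path is
verified by simulation (500 null cohorts at $\alpha = 0.05$).

The same test applied per chromosome, with Benjamini–Hochberg adjustment
across chromosomes and a significance threshold of $q < 0.1$, localizes
group differences. One property of BH control worth stating plainly:
with 21 truly null chromosomes, the probability that *some* null
chromosome is flagged alongside a strongly significant one is roughly
$1 - (1 - 2 \cdot 0.1/22)^{21} \approx 0.17$ per cohort. That is the false
discovery rate doing what it is designed to do; a workflow that needs
family-wise control should lower the threshold rather than expect BH to
deliver uniqueness.

## Segmentation

Statistical analyses run on segmented data: each probe carries the mean of
its segment. The segmenter is a recursive binary splitter in the
circular-binary-segmentation style, written in C++ for the permutation
scan. Within a window it locates the breakpoint maximizing the two-sample
pooled-$t$ statistic (leftmost maximizer on ties), accepts the split when
the within-window permutation p-value $(1 + \text{exceedances})/(n_{\text{perm}}
+ 1)$ falls below `alpha`, and recurses on both flanks. Defaults:
`alpha = 0.01`, `min_width = 3`, `n_perm = 1000`. A zero-variance step
yields an infinite $t$, so noiseless profiles are recovered exactly —
provided every true segment is at least `min_width` probes wide; the
simulator's overlap resolution (later draw wins) can in principle leave
narrower fragments, which no minimum-width segmenter can isolate, so the
exactness checks use architectures with disjoint candidate segments.
Probe indices are 0-based, intervals half-open and chromosome-local, and
segments never span chromosome boundaries.

## Preprocessing

The raw-table path mirrors standard two-channel practice: control spots
removed (count conservation asserted), background medians subtracted from
foreground medians per channel, ratios floored at one intensity unit to
keep $\log_2$ finite, and per-sample median normalization (the external
package used for the original analyses does not document its method; the
global median is the simplest location correction and is idempotent).

A sample with tumor-cell fraction $c$ mixes tumor and diploid normal
signal, $2^{x} = c\,2^{t} + (1-c)$. `correct_cellularity()` inverts this:
$x_{\text{corr}} = \log_2\!\max\{(2^x - (1-c))/c,\ \text{floor} \cdot
2^x\}$, identity at $c = 1$, exact round-trip on noiseless data for any
$c \in (0.3, 1]$ (asserted to $10^{-9}$), and finite via the floor branch
for deep losses where the de-mixed intensity is nonpositive. Samples with
$c < 30\%$ are dropped with a warning — their signal is too diluted to
de-mix reliably. Note that de-mixing amplifies probe noise by roughly
$1/c$, which is why the quality metric below is taken before correction.

Per-sample quality is the scaled MAD, $1.4826 \cdot \mathrm{median}\,|r -
\mathrm{median}(r)|$, computed on probe-minus-segment residuals when a
segmentation is available (so genuine copy-number structure does not
inflate it) and on raw ratios otherwise; a derivative form
(`method = "diff"`) is also exposed. For Gaussian noise the scaled MAD
estimates the standard deviation, which the tests assert at
$\sigma = 0.30$ within $\pm 0.02$.

## The synthetic cohort generator

The generator emulates a two-arm aCGH study on a configurable platform
(default desk scale: 10,000 probes over 22 chromosomes at ~17 kb spacing;
the full 180,880-feature geometry is supported). Each arm has an
*aberration architecture*: a pool of candidate segments with copy states
in $\{-1, 0, +1, +2\}$, a `concentration` dial giving the fraction of the
pool accessible to the arm, and a per-tumor draw count. A small shared
pool makes tumors reuse the same loci (the homogeneous, low-entropy arm);
the full pool disperses them. The defaults — 100 candidates, 8 segments
per tumor, concentration 0.1 vs 1.0, segment lengths 30–120 probes — make
the shared arm reuse ~80% of its loci between any two tumors, a contrast
strong enough that the downstream permutation test detects it at $p <
0.01$ in essentially every replicate at 20 + 20 samples.

Observed ratios are $\log_2(c\,2^{t} + (1-c)) + \varepsilon$ with
per-sample cellularity $c \sim U(0.3, 0.9)$ (one value per tumor, matching
how cellularity is estimated in practice) and probe noise $\varepsilon \sim
N(0, 0.33^2)$, placing the scaled MAD in the 0.33–0.34 regime of a
good-quality hybridization. Control spots carry pure noise. Survival is
exponential with hazard $\lambda_0 \exp(\beta h_i)$, independent
exponential censoring, and an optional extreme-survivor selection (death
within 1 year, or at least 3 years of follow-up).

What the generator does *not* emulate: intra-tumor subclones, spatial and
wave artifacts, dye-swap effects, platform-specific probe response, or
correlated noise. Passing tests therefore demonstrate correctness of the
pipeline's logic and inference under a clean generative model, not
robustness to every artifact of real arrays.

Randomness is organized as one root seed per run with per-stage child
seeds (`derive_seeds()`), so any stage can be re-run in isolation and the
whole pipeline is byte-identical under a fixed configuration.

## Survival and covariate association

Cox proportional-hazards fits (continuous entropy, optional treatment
interaction), Kaplan–Meier curves with log-log median confidence
intervals, and the log-rank test are delegated to the survival package;
the bespoke pieces are the grouping procedures and permutation tests.
`group_by_entropy()` offers a median split (ties to the low-entropy group,
so sizes differ by at most one) and a tertile-merge: three equal-sized
groups by entropy order, then the two *adjacent* groups whose Kaplan–Meier
curves overlap most — operationalized as the larger pairwise log-rank
p-value — are merged. The visual judgement "curves overlapped
substantially" needs a reproducible surrogate, and the pairwise log-rank
criterion is that surrogate. Associations between entropy and categorical
pathology variables use a permutation test on the mean difference (two
levels) or an ANOVA-style F ratio (more levels); a linear model `entropy ~
group + cellularity` reports the group effect adjusted for tumor-cell
content. Deaths from causes other than cancer are treated as censored.

Cross-study support is limited to probe matching (greedy one-to-one
nearest-midpoint pairing within a tolerance, symmetric in its arguments)
and mean segmented profiles; no formal cross-study statistics are
offered, since differing platforms and resolutions do not support them.

## Dispersion in principal-component space

`pca_dispersion()` projects the column-centered profile matrix on its
first two principal components and reports each group's convex-hull area.
For groups of equal covariance shape the more dispersed group has the
larger hull (asserted over 100 replicates at a 4x spread ratio). One
caveat for architecture-based cohorts: the projection axes are shared, and
a homogeneous arm whose variation concentrates on a few high-amplitude
loci can occupy a *larger* top-2 hull than a heterogeneous arm whose
variation spreads over many axes, because the leading components align
with the concentrated variance. Nearest-neighbour entropy, which works in
the full-dimensional space, is the primary heterogeneity measure; the PCA
hull is a visualization aid.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen to exercise every code path in minutes on a single
core: estimator validation at $n = 5000$, $d \le 2$; calibration at 500
null cohorts of 10 + 10 samples x 1,100 probes; the heterogeneity
contrast at 100 cohorts of 20 + 20 samples x 10,000 probes with full
segmentation; the reference study in the acceptance script at 40 + 35
samples x 10,000 probes. The full 180,880-feature platform is used where
the check concerns platform geometry itself. Other fixed choices:
intensity floor 1 unit at the ratio step, cellularity floor branch at
5% of the observed intensity, `tie_epsilon` $10^{-8}$, exhaustive
enumeration limit 20,000 arrangements, BH threshold $q < 0.1$.

## Limitations

* Entropy here is *inter*-tumor: one profile per tumor. Multi-region or
  single-cell heterogeneity is out of scope.
* The segmenter is a self-contained CBS-style splitter; it does not claim
  numerical agreement with any external segmentation package, only the
  piecewise-constant contract that downstream analyses need.
* The normalized estimator's absolute values are not differential
  entropies of any fixed density; they are comparable within a cohort and
  across groups, which is what the analyses use.
* BH control at $q < 0.1$ bounds the false discovery *rate*; it does not
  make per-chromosome discoveries individually reliable, and occasional
  spurious chromosomes alongside a true one are expected behavior.
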