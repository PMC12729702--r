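---
title: "Models and methods behind phenodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiv)
```

`phenodiv` packages the multivariate workflow classically used to infer
genetic divergence among plant genotypes from replicated phenotype data:
one-way ANOVA with genetic-parameter estimation, Scott–Knott grouping of
means, Mahalanobis/Euclidean distance matrices, Tocher and UPGMA
clustering, Singh's trait-importance decomposition, canonical variates,
Pearson correlations, and seedling-emergence indices. This vignette is the
package's own account of the statistical machinery: the models and their
assumptions, the tunable parameters, the synthetic-data generator used for
validation, and the numerical and design choices a maintainer would want
spelled out.

## The one-way model and its genetic parameters

Everything begins with a balanced completely randomized design:
$$Y_{ij} = \mu + G_i + e_{ij}, \qquad i = 1,\dots,g,\; j = 1,\dots,k,$$
with genotype effects $G_i$ and residuals $e_{ij}$ assumed independent with
variances $\sigma^2_g$ and $\sigma^2_e$ (the replicate-level residual
variance). The per-trait ANOVA yields mean squares with expectations
$E[QM_g] = k\sigma^2_g + \sigma^2_e$ and $E[QM_r] = \sigma^2_e$, which the
estimators in `genetic_parameters()` invert on the genotype-mean basis:

* $\hat\sigma^2_f = QM_g/k$ (phenotypic variance of genotype means),
* $\hat\sigma^2_e = QM_r/k$, $\hat\sigma^2_g = (QM_g - QM_r)/k$,
* broad-sense heritability $h^2 = 100\,(QM_g - QM_r)/QM_g$ (%),
* $CV_g = 100\,\hat\sigma_g/m$ and $CV_e = CV = 100\sqrt{QM_r}/m$, with
  $m$ the trait's grand mean.

Two conventions deserve emphasis. First, **$CV_e$ uses the plot-basis
residual standard deviation $\sqrt{QM_r}$**, not $\sqrt{QM_r/k}$; under this
convention the experiment-wide CV and $CV_e$ are the same quantity, and the
ratio takes the closed form
$CV_g/CV_e = \sqrt{(QM_g - QM_r)/(k\,QM_r)}$. This is the only reading
under which published trial tables we recompute (heritabilities together
with their printed $CV_g/CV_e$ and CV rows) are internally consistent.
Second, when $QM_g < QM_r$ the raw negative $\hat\sigma^2_g$ is **preserved
and flagged** while $h^2$ is floored at zero, so simulation studies can
examine estimator bias rather than having it silently hidden.

A related small-sample fact guides the validation suite: with no genetic
variance the raw estimator $\hat h^2 = 1 - QM_r/QM_g$ has expectation
$1 - \nu_1/(\nu_1 - 2)$ with $\nu_1 = g - 1$ (about $-0.057$ at $g = 38$),
not exactly zero; the tests assert that closed form rather than a naive
zero.

Unbalanced designs are rejected outright. All the estimator algebra above
assumes a common $k$; supporting harmonic-mean replicate counts would trade
exactness for generality the package does not need.

## Scott–Knott grouping

`scott_knott()` recursively partitions the mean-sorted genotypes. At each
node the split maximizing the between-group sum of squares
$B_0 = T_1^2/j + T_2^2/(g-j) - (T_1+T_2)^2/g$ is tested with
$\lambda = \frac{\pi}{2(\pi-2)}\, B_0/\hat\sigma_0^2$, where
$\hat\sigma_0^2 = \big(\sum_i(\bar y_i - \bar y)^2 + \nu s^2_{\bar y}\big)/(g+\nu)$
uses the node's own means, the **global** residual degrees of freedom
$\nu = g(k-1)$ and $s^2_{\bar y} = QM_r/k$ (neither re-estimated per
subgroup). The split is accepted when $\lambda$ exceeds the $\chi^2$
quantile at the fractional degrees of freedom $g/(\pi-2)$, evaluated with
the continuous quantile function (no rounding) — the behavior of the
reference implementations of the method. Ties in the argmax go to the
smallest $j$ for determinism, and letters run from the highest-mean group
("a") downward. Because accepted groups are contiguous runs in sorted
order, the output never shows the overlapping-letter ambiguity of pairwise
tests.

## Distances, Tocher, UPGMA

The **generalized Mahalanobis distance**
$D^2(i,i') = (\bar x_i - \bar x_{i'})^\top S^{-1} (\bar x_i - \bar x_{i'})$
uses the pooled residual covariance $S = E/\big(g(k-1)\big)$ estimated from
the replicate-level data. $S$ is inverted by a numerically stable solve; a
condition-number estimate above $10^{12}$ is an error (no silent
pseudo-inverse), with an optional ridge on the diagonal that is off by
default. The **standardized mean Euclidean distance** centers and scales
each trait to unit standard deviation across genotype means and divides the
squared sum by the trait count, making the metric comparable across trait
sets and invariant to per-trait affine rescaling.

The two metrics serve different stages by convention, and the package keeps
both because the field's software chain does: **Tocher defaults to
Mahalanobis $D^2$** (the metric its threshold rule was formulated for) and
**UPGMA defaults to the standardized Euclidean distance** (the metric
dendrograms of trait means are usually drawn from). Published analyses
sometimes label these inconsistently; `run_pipeline()` exposes
`distance_tocher` and `distance_upgma` so either pairing is a one-line
change.

Tocher clustering computes $\theta = \max_i \min_{j\ne i} D(i,j)$ **once**
from the full matrix, seeds each cluster with the closest unassigned pair,
and admits the candidate with the smallest mean distance to the cluster
while that mean is $\le \theta$ — boundary admits, so a uniform matrix
forms a single cluster. The "increase in average within-cluster distance"
variant of the admission rule exists in the literature but is not
implemented. Ties break by (distance, label order), making the procedure
label-equivariant and order-independent.

UPGMA uses true unweighted (size-proportional) average linkage via
`stats::hclust(method = "average")`; fusion heights are the average
inter-cluster distances themselves, **not halved** — halving appears only
in the exported Newick branch lengths, where each leaf-to-root path is half
the root height so patristic distances equal cophenetic ones. Mojena's
cutoff is $h^* = \text{mean}(h) + c\cdot\text{sd}(h)$ over the $g-1$ fusion
heights (sample sd, denominator $g-2$). The constant defaults to
$c = 1.25$, the value the clustering literature recommends for this rule;
it is a free parameter of the method, never fitted, and with only one
fusion height the rule is undefined and a flagged single group is
returned.

## Singh contributions and canonical variates

Singh's criterion decomposes each pair's $D^2$ through
$c_j = \delta_j\,(S^{-1}\delta)_j$ and sums over pairs. Contributions are
kept **signed**: the per-pair identity $\sum_j c_j = D^2$ then holds
exactly (tested to $10^{-6}$ relative), at the price that an individual
trait's percentage can go negative or exceed 100 under strong trait
correlation. In the data regime the defaults emulate, percentages remain
positive.

Canonical variate analysis solves $Bv = \lambda Wv$ with $B$ the
between-genotype and $W$ the pooled within-genotype sums-of-products
matrices. Rather than forming $W^{-1}B$ (non-symmetric, numerically
fragile), the package whitens with the Cholesky factor $W = U^\top U$ and
eigendecomposes the symmetric $U^{-\top} B\, U^{-1}$, mapping eigenvectors
back by $v = U^{-1}z$. At most $\min(p, g-1)$ roots are non-zero and only
those are returned.

## Emergence indices

From daily counts $n_i$ on days $t_i$ (days after sowing, 90-day window by
default): emergence percentage $SE = 100\sum n_i/\text{sown}$, Maguire's
speed index $ESI = \sum n_i/t_i$, and the Edmond–Drapalla mean emergence
time $MET = \sum n_i t_i / \sum n_i$. A replicate in which nothing emerges
has $SE = ESI = 0$ but an **undefined MET**; such replicates contribute
their zeros to the genotype's SE and ESI means but are excluded from the
MET mean, and the exclusions are reported. When emergence metrics are
merged into a phenotype table (which must stay balanced and finite for the
ANOVA), a missing replicate-level MET is filled with the genotype's mean
over its emerging replicates; a genotype with no emergence at all is an
error rather than a guess. Counts are "newly emerged per day"; a
`cumulative` flag differences cumulative input.

## The synthetic-data generator

`sim_config()` defaults emulate the field trial the package grew around:
38 genotypes in three natural populations (13 + 8 + 17), 4 replicates, and
ten diaspore traits — fruit length/diameter/mass, endocarp
length/width/thickness/mass, and SE/ESI/MET — with grand means (e.g. fruit
length 34.2 mm, endocarp mass 1.46 g, MET 44.8 days) and residual
variances chosen so the implied experimental CVs span the observed range
(about 2% for fruit dimensions up to ~49% for emergence traits), and
target heritabilities from 0.63 (MET) to 0.985 (fruit length).
`sigma_g_for_h2()` converts each target $h^2$ into the genetic variance
$\sigma^2_g = h^2\sigma^2_e/\big(k(1-h^2)\big)$ that makes the expected
heritability estimate hit the target. Genetic correlations default to a
block structure (fruit traits 0.9, endocarp traits 0.6, SE–ESI 0.9,
moderate cross-links, MET tied only to ESI at −0.33) — a positive-definite
idealization of the correlation patterns such trials report. Residuals are
uncorrelated by default. Population labels are assigned but carry no
simulated effect (matching the one-way analysis model); an optional
per-population mean shift enables between-population contrasts.

Emergence kinetics are simulated per genotype: an emergence probability
drawn uniformly from [0.02, 0.50] (population means landing near the
10–30% such trials report, with occasional high-emergence genotypes), a
binomial emerged count per 25-seed replicate, and emergence days from a
lognormal with median 40 days (sdlog 0.3) truncated to the 90-day window —
placing MET values in the late-30s-to-50s-days range.

What the generator does **not** emulate: spatial field heterogeneity,
genotype × environment interaction, non-normal trait distributions
(emergence percentages near the boundary are genuinely non-Gaussian),
measurement rounding, and any real between-population structure. Passing
the validation suite therefore demonstrates that the estimators and
clustering procedures behave correctly under the stated model — not that
field data satisfy that model.

All draws flow from a single RNG stream seeded once per generator call, so
one integer seed makes every output byte-identical across runs.

## Numerical choices and degenerate inputs

* ANOVA sums of squares come from the balanced-design group-total algebra
  (cross-checked in the tests against both a brute-force double loop and
  `stats::lm`); a zero residual mean square reports $F = \infty$, $p = 0$
  with a degeneracy warning.
* Covariance inversions go through `solve()`/Cholesky after an explicit
  SVD-based condition check (threshold $10^{12}$).
* Scott–Knott guards the $0/0$ case ($B_0 = 0$ with zero variance) by
  declaring no split.
* Ties: argmax splits to smallest $j$; Tocher candidate selection by
  (distance, label order); UPGMA tie-breaking follows `hclust`'s
  deterministic ordering.
* CSV output formats numbers with 12 significant digits, so write/read
  round trips preserve values to at least $10^{-10}$ relative.
* Decimal commas are never auto-detected; the reader takes an explicit
  `dec` argument.

## Validation scale

The test suite and acceptance script validate at the emulated design size
(g = 38, k = 4): heritability recovery uses 200 simulated trials per
target (bias at most ${\sim}0.023$, within the ±0.03 assertion), the
expected-mean-square identities use 500 trials at a 2% tolerance,
ultrametricity is checked over more than $10^4$ random triples, and the
oracle equivalences (Scott–Knott split enumeration at $g \le 8$,
generalized-eigenproblem CVA, Singh/D² identity) run on small random
instances with fixed seeds. These sizes were chosen so each property is
measured well inside its tolerance while the whole suite stays fast enough
to run on every change.

## Known limitations

* Only balanced one-way designs; no mixed models, no narrow-sense
  heritability, no multi-environment trials.
* Distance menu is limited to Mahalanobis $D^2$ and standardized mean
  Euclidean (no Gower or marker-based distances).
* The "modified Tocher" sequential variant and alternative linkage rules
  are out of scope.
* No germination-curve model fitting; the emergence module computes
  indices, not dormancy dynamics.
* Reference partitions and mean squares shipped in `inst/extdata` are
  published summary inputs for recomputation checks; the underlying raw
  trial data are not public, so data-dependent results (exact group
  memberships, Singh percentages) cannot be reproduced, only their
  structural properties validated.
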