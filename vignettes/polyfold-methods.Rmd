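---
title: "Methods: CV-corrected normalization and uncertainty-moderated fold changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CV-corrected normalization and uncertainty-moderated fold changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfold)
library(dplyr)
```

polyfold estimates two-group differential expression (DE) from RNA-seq count
matrices. Its two ingredients are a normalization that stays honest when a
large or one-sided fraction of genes is differentially expressed (`qtotal`),
and a fold-change statistic that folds the reliability of each gene's
measurement into the fold change itself (the moderated log2 fold change),
so that a single ranking by fold change is simultaneously a ranking by
significance. This vignette explains the model, the tunable parameters, the
numerical choices, and what the simulation benchmark does and does not show.

## Normalization by CV-corrected totals

Size factors put all libraries on a common scale; normalized expression is
`count / size_factor`, and all factors are rescaled to geometric mean 1 so
normalized values stay on the counts scale.

The total read count of a library confounds two things: sequencing depth and
biology. If many genes are up-regulated in one condition, that condition's
libraries contain more reads at equal depth, and dividing by totals silently
shrinks every other gene. Methods that pick a robust subset of the counts
(upper-quartile sums, median-of-ratios) instead assume that most genes are
*not* DE, which fails on strongly perturbed comparisons.

`qtotal` uses a third signal: the coefficient of variation (CV) of a
sample's count distribution across genes. Multiplying every count in a
sample by a scalar — which is exactly what a depth change does — leaves the
CV unchanged, while genuine DE makes the distribution more (or less)
dispersed and moves the CV. The size factor is therefore a CV-corrected
total,

    f_s = T_s * (CV_ref / CV_s)^beta,

with `T_s` the column sum, `CV_s` the sample's CV computed on winsorized
count proportions, and `CV_ref` the median CV across samples. A sample whose
distribution is more dispersed than typical has its apparent library size
discounted. `beta` (default 1) sets the strength of the correction;
`beta = 0` reduces exactly to totals. The CV is computed on proportions of
the column sum (making it exactly depth-invariant), with the top 5% of
proportions winsorized to the 95th percentile (`winsor_fraction = 0.05`) so
that a handful of extremely high-count genes cannot dominate; the SD uses
the `n - 1` divisor and quantiles interpolate linearly between order
statistics (type 7) — the one quantile convention used throughout the
package. This formula is one concrete realization of CV-corrected totals;
`beta` and `winsor_fraction` are deliberately exposed as its adjustable
surface.

The `total`, `quartile` (sum of counts at or below the per-sample upper
quartile of nonzero counts) and `geometric` (median-of-ratios) baselines are
provided for comparison under the same geometric-mean-1 convention.

## The uncertainty model and moderated fold change

An observed count decomposes into a mean plus an uncertainty. Within a
gene and group with mean `mu` and replicate SD `s`, the SD itself is
estimated from the same few replicates, and its error propagates in
proportion to the gene's CV `s / mu`. Adding the SD and its propagated
error gives a polynomial uncertainty in `s`:

    eps = s + s^2 / mu.

The quadratic term dominates exactly where measurements are least reliable —
low expression and high dispersion. Three stabilizers feed the working SD
`s` before it enters this formula:

* **Outlier winsorization.** Within each gene and group with at least 4
  replicates, values above the Tukey fence `Q3 + 1.5 * IQR` are capped at
  the fence. This is a standard robustification choice and an approximation
  to more elaborate per-count outlier detectors.
* **Trend borrowing.** A mean-SD trend is fitted across genes (20
  equal-count bins of `log(mu + 1)`, per-bin medians, a monotone
  non-decreasing pass, linear interpolation, flat extrapolation), and the
  working SD is `max(s_obs, s_trend(mu))`: a floor, not a shrinkage, because
  the dangerous failure mode at small `m` is an unrealistically *small*
  variance estimate, while genuinely large variances carry real information.
* **Small-sample penalty.** With `m` replicates the working SD is further
  multiplied by `sqrt(1 + 1/(m - 1))`, charging for the uncertainty of the
  SD estimate itself; a group with a single replicate uses the trend value
  times the two-replicate penalty. Removable with `penalty = FALSE`.

The moderated log2 fold change adds the larger of the two group
uncertainties (`eps* = max(eps_ref, eps_alt)`) and a pseudo-count
(`pseudo = 1` on the normalized scale) to both means:

    lfc = log2(mu_alt + eps* + pseudo) - log2(mu_ref + eps* + pseudo).

This preserves the sign of the mean difference, is monotone shrinking in
`eps*`, goes to zero as the uncertainty grows, and reduces to the ordinary
pseudo-count fold change when `eps* = 0`. Low-expression, high-dispersion
genes are pulled toward zero; well-measured genes are nearly untouched.
Implementations in this family differ in exactly how `eps` enters the fold
change; this moderation formula is polyfold's own fixed choice with the
stated qualitative properties, and other realizations of the same idea may
behave differently in detail.

## Significance

Moderated fold changes across genes are compared against a zero-centered
normal with a single global scale `sigma0`:
`p = 2 * (1 - Phi(|lfc| / sigma0))`, followed by Benjamini–Hochberg
adjustment. P-values are therefore a monotone function of `|lfc|`, so
ranking by p-value and ranking by moderated fold change coincide — one
cutoff, one ordering.

Everything hinges on estimating `sigma0` as the scale of the *null* genes
while the vector of fold changes contains the DE genes too. The default,
`trimmed_normal`, fits the zero-mean normal by iterative truncation:
starting from the MAD, genes with `|lfc| > 2.5 sigma` are set aside, the
second moment of the remainder is divided by the truncated-normal
correction `E[Z^2 | |Z| < 2.5] = 1 - 2 c phi(c) / (2 Phi(c) - 1)`, and the
two steps repeat to convergence. On null data this estimator recovers the
plain SD (and with it a raw type I rate near the nominal 0.05); under 10%
DE the plain second moment `sqrt(mean(lfc^2))` is inflated by roughly 40%
(costing most of the method's sensitivity), while the truncated fit moves
by only a few percent because the large DE fold changes fall outside the
truncation. The literal `second_moment` and a plain `robust_mad` mode are
kept available; the second moment is the conservative choice when one
suspects the null fold changes themselves are heavy-tailed.

Degenerate inputs are defined, not special-cased: identical groups give all
`lfc = 0`, `sigma0 = 0`, and all p-values 1; a mean of zero in `eps` is
guarded by a `1e-8` floor; `s = 0` gives `eps = 0` exactly.

## The simulator

`make_param_table()` emulates the marginal structure of a deeply sequenced
human RNA-seq experiment rather than shipping one: baseline means are
log-normal with `log10` median 1.5 and `log10` SD 0.8 (truncated to
`[0.5, 1e5]`), and dispersions follow `phi = (0.05 + 2/mu0) * noise` with
log-normal noise (log-SD 0.5), truncated to `[0.01, 5]` — strongly
overdispersed low expressors, a `~0.05` dispersion floor for high
expressors. Counts are negative binomial with variance `mu + phi mu^2`.
The benchmark design holds 12,500 genes with 10% DE split between up- and
down-regulation; effect sizes are uniform on 1.5–4 fold (log2 0.585–2), a
conventional benchmark range; per-sample library factors are uniform on `[0.7, 1.4]`; random
outliers multiply each cell independently with probability 0.05 by a factor
uniform in `[5, 10]`. `spike_de()` instead plants known fold changes into a
real null comparison, and `n_up = 0` produces the one-sided designs under
which composition-assuming normalization breaks.

What the simulator does *not* emulate: gene-gene correlation, GC/length
bias, batch structure, and sample-specific dispersion. Passing benchmarks
here therefore demonstrates calibration and ranking behaviour under clean
NB noise with outliers — necessary, not sufficient, evidence about any
particular real data set.

## Benchmark behaviour and limitations

`afold_bench()` runs the full protocol (simulate, fit, score) and the test
suite asserts its headline properties at the study conditions: mean AUC
above 0.9 at 10 replicates per group with outliers; a mean raw type I rate
within `[0.005, 0.07]` over 20 null runs; an outlier-induced AUC drop below
0.05 at n = 5; and qtotal beating totals in depth recovery on one-sided
spiked data in at least 8 of 10 replicates. Problem sizes in the test suite
mirror the study conditions (12,500 genes; 10–20 samples; 10–20
repetitions); unit tests use smaller instances of a few hundred genes.

One benchmark property is *not* met and deliberately left failing rather
than tuned away: at n = 5 with effects of 1.5–4 fold, the measured mean
sensitivity at `padj < 0.1` is about 0.52 (FDR about 0.11) against a target
of 0.6. The cause is structural in the surrogate moderation: at the
generator's median expression (`mu ~ 30`, `phi ~ 0.12`) the uncertainty
`eps = s + s^2/mu` is of the same order as `mu` itself, so a true 2-fold
gene is shrunk from `lfc = 1` to about 0.55 while the BH calling threshold
sits near 0.6. The removable options (penalty, sigma0 mode) move
sensitivity by under 0.03. A moderation acting on the standard-error scale
(`s / sqrt(m)`) would be markedly more sensitive, but would no longer be the
stated polynomial in the replicate SD; we keep the formula and report the
conservatism honestly. In exchange the method is strongly calibrated: its
FDR runs far below nominal, and outliers barely move it.

## Worked example

```{r example}
params <- make_param_table(2000, seed = 1)
sim <- simulate_nb(params, n_per_group = 5, n_up = 100, n_down = 100,
                   seed = 2)
noisy <- inject_outliers(sim$counts, prob = 0.05, seed = 3)

fit <- run_afold(noisy$counts, sim$design)
glance(fit)

tidy(fit) |>
  arrange(padj) |>
  select(gene_id, mean_ref, mean_alt, lfc_moderated, padj) |>
  head()

truth <- sim$truth[match(tidy(fit)$gene_id, sim$truth$gene_id), ]
roc_auc(abs(tidy(fit)$lfc_moderated), truth$de_flag)$auc
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(fit)
```
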