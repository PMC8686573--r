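---
title: "A population-dynamics model of pooled CRISPR knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-dynamics model of pooled CRISPR knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenpop)
```

## The model

In a pooled CRISPR knockout screen, cells are infected with a library of
sgRNAs, each directing Cas9 to one target gene, and the relative abundance of
each sgRNA's tagged population is read out by sequencing at one or more late
time points, together with the plasmid library (pDNA) that defines the
starting abundances. Because double-strand-break repair is stochastic, an
sgRNA does not produce a homogeneous knockout population: a fraction of
infected cells lose gene function entirely while the rest keep it. screenpop
models this explicitly as a two-population mixture. For sgRNA $j$ targeting
gene $g$ in cell line $c$, the knocked-out fraction $p_c\,p_j$ of cells grows
at the perturbed rate $R_c (1 + r_{cg})$ after a phenotype-onset delay $d_g$,
and the remainder grows at the line's unperturbed rate $R_c$. Dividing out
the common growth, the modelled (unnormalized) relative abundance is

$$Z_{cj}(t) = \nu_{cj}(0)\,\bigl(1 + p_c\,p_j\,(e^{R_c r_{cg} (t - d_g)} -
1)\bigr), \qquad t \ge d_g,$$

with $Z_{cj}(t) = \nu_{cj}(0)$ before the delay, and the predicted read
proportion is $\nu_{cj}(t) = Z_{cj}(t) / \sum_j Z_{cj}(t)$. The gene fitness
effect $r_{cg}$ — the fractional change in growth rate on complete knockout —
is the quantity of interest. This mixture reproduces the saturation
characteristic of CRISPR depletion curves: a fully essential gene's sgRNA
does not vanish but asymptotes at its non-knockout fraction $1 - p_c p_j$,
which is what makes knockout efficacy identifiable and what a single
exponential-decay model cannot represent.

The initial abundances anchor to the data: $\nu_{cj}(0)$ is the median
measured pDNA share of sgRNA $j$ in the line's pDNA batch, times
$e^{\rho_{bj}}$ with free offsets $\rho$ that absorb systematic pDNA
measurement error. The offsets are constrained to mean zero over each gene's
sgRNAs per batch and are quadratically penalized.

## Likelihood

Readcounts are overdispersed relative to Poisson, so observations enter
through the NB2 negative binomial (variance $\mu + \alpha\mu^2$). Keeping
only the $\mu$-dependent terms and shifting so a perfect prediction has zero
cost, each unmasked (sequence, sgRNA) entry contributes

$$\lambda(N, \mu) - \lambda(N, N), \qquad
\lambda(N,\mu) = (N + \alpha^{-1})\ln(1 + \alpha\mu) - N\ln\mu,$$

with $N = 10^6 n$ (observed reads per million) and $\mu = 10^6 \nu$. Working
in RPM makes the cost independent of sequencing depth; the overdispersion
$\alpha$ is a fixed hyperparameter (default 0.05 for every line, or a
user-supplied per-line table — estimating it is out of scope here, and
external estimators can be plugged in through the `alpha` argument).

## Constraints and regularization

The raw model is not identifiable — $R_c$ and $r_{cg}$ trade off exactly, as
do efficacies and effects — so constraints and penalties are applied:

* $p_c$ is estimated before training from the depleted tail of the late
  fold changes (`estimate_cell_efficacy()`): the most-depleted 1% boundary
  $q$ of a line's mean LFCs asymptotes at $\log_2(1 - p_c)$ under the model,
  so $p_c = \mathrm{clip}(1 - 2^q, 0.01, 1)$. It is held fixed during
  training.
* $p_j \in (0,1]$, clipped after every step. The two currently most
  efficacious guides of each gene pay a reciprocal penalty
  $\chi_p \, \mathrm{mean}_g \sum_{j \in \mathrm{top2}(g)} p_j^{-1}$
  ($\chi_p = 0.5$), forcing at least two sgRNAs per gene toward full
  efficacy. This is the mechanism that prevents a single (possibly
  off-target) guide from carrying a gene's fitness call.
* $R_c > 0$ with mean exactly 1 (projection after every step) plus a
  $\chi_R\,\mathrm{mean}(\ln^2 R_c)$ penalty, inert near 1 and large if a
  line's rate collapses.
* the global mean of $r$ is pinned by $\chi_{r1}\,\mathrm{mean}(r)^2$, and a
  smoothed hierarchical kernel couples each $r_{cg}$ to the mean effects of
  genes with similar rank:
  $\mathrm{mean}_{c,g}\sum_h \kappa_{gh} (r_{cg} - \bar r_h)^2$ with
  $\kappa_{gh} = \chi_h \delta_{gh} + \chi_k w_{gh}$, $w$ a rank-distance
  Gaussian (width $\sigma = 5$ ranks, truncated at $3\sigma$, normalized to
  sum 1 over each gene's support). The delta term shrinks per-line effects
  toward the gene mean; the Gaussian term shares information across genes of
  similar essentiality.

Several of these forms are stated here deliberately: the penalty family is
defined so that every term is a chi-weighted *mean* (so magnitudes are
comparable across dataset sizes), the growth-rate and mean penalties are
squared (a signed sum is unbounded below under minimization and would not
regularize), and the kernel's Gaussian decays with rank distance. The
guide-efficacy penalty is normalized per gene; with the weaker per-guide
normalization the penalty no longer suppresses single-guide dominance (we
measured guides up to 0.54 efficacy above all siblings on planted off-target
screens versus 0.13 with the per-gene form, and the design intent is that no
gene rely on one guide).

## Fitting

`screenpop()` minimizes the total cost with hand-coded analytic gradients
and an Adam-style first-order optimizer (moments 0.9/0.999), full-batch,
`epochs = 801` by default. Three scheduling devices matter:

* the core cost is rescaled once, at the first epoch, to 0.67, fixing the
  likelihood:penalty balance regardless of dataset size;
* only the gene-effect parameters move during the first 100 epochs — the
  core cost is convex in them, which stabilizes the optimum before
  efficacies and offsets are released;
* the learning rate ramps geometrically from $10^{-4}$ to $0.02$ over 50
  epochs, avoiding the initial cost explosion of a fixed large step.

Inside the growth exponent, days are multiplied by `time_scale = 0.1`
(time in units of 10 days) for conditioning; reported gene effects are on
that fitted scale. Since the model is scale-degenerate between $R_c$ and
$r_{cg}$, raw effects are only comparable across runs after
`normalize_global()`, which applies one affine map so nonessential and
essential control medians sit at 0 and $-1$.

Exponents are clipped at 50 with a warning; hitting the cap signals runaway
parameters rather than a numerical regime the model should visit.

## Copy-number correction

Cutting toxicity depletes sgRNAs in proportion to locus copy number
independently of the targeted gene, and high copy number also attenuates
knockout of genuinely essential genes, so the bias is non-monotone and
depends on both copy number and the gene's mean effect. `fit_cn_model()`
captures it post hoc as a tensor-product cubic B-spline surface over
(copy number, mean gene effect) — ten knots linear in CN, five knots
pseudo-exponentially spaced so they concentrate at strong negative effects —
scaled per line by a weight $w_c \in (0,1]$ with a $X_w \ln^2 w_c$ penalty
($X_w = 10^{-3}$), minimized by alternating exact least squares in the
spline coefficients with bounded one-dimensional updates of each $w_c$.

Two identifiability safeguards are essential and deliberate. The surface is
fit to per-gene *centered* deviations, because the raw effects are dominated
by each gene's true mean essentiality, which lives exactly on the
mean-effect axis: an unconstrained surface absorbs it wholesale and the
"corrected" matrix comes out mean-centered, destroying the essentiality
structure it is supposed to preserve. And the surface is anchored at normal
ploidy (bias $\equiv 0$ at $cn = 1$ in $\log_2(x{+}1)$ units, which is also
the value imputed for genes missing from the CN matrix). With both in
place, mean gene effects are approximately preserved, the correction is
idempotent to well under 1% of variance, and a planted smooth bias surface
with per-line weights is recovered to better than 80% of its variance in
our tests.

## The simulator

`simulate_screen()` generates readcounts from exactly the two-population
mixture above, which makes every downstream property testable against known
truth. The default conditions describe, once, the kind of screen the package
expects: unperturbed growth 0.25/day (a 2–3-day doubling time), knockout
efficacies Beta(9,2) per guide and uniform (0.7, 1) per line, lognormal
(sdlog 0.5) pDNA abundances sequenced twice, a 3-day phenotype delay,
readouts at days 7 and 14 at 500 reads per sgRNA with NB2 overdispersion
0.05, and a gene mixture of 80% neutral, 15% essential
($r \sim N(-1, 0.2)$, shared across lines) and 5% selectively essential
genes (essential in a random 20% of lines) — the essential prevalence
mirrors the roughly 15% of genes that behave as true dependencies in a
given line. Optional artifacts: clonal-outgrowth spikes (single entries
multiplied by $2^8$), a copy-number bias surface with per-line weights
(`cn_bias_surface()`), and off-target guides carrying an extra depletion.

What the simulator does *not* emulate: per-cell lineage stochasticity
(knockout is a deterministic population fraction), sequence-determined guide
behavior, batch effects between libraries, and real screens' heavier-tailed
count noise. Passing recovery tests on it therefore demonstrates that the
estimator inverts its own generative model at realistic noise, not that it
is robust to everything real data does.

## Measurement scale choices

Scale-free comparisons with simulated truth (Pearson, Spearman) use raw
fitted effects. Scale-bearing comparisons (RMSE, deviation bounds) first put
both the fit and the truth on the control scale via `normalize_global()`
with the simulator's truth-derived control sets; this is the only scale on
which different fits are comparable, because of the $R_c$–$r_{cg}$
degeneracy. Guide-efficacy recovery is measured over guides targeting genes
with a nonzero true effect: the likelihood is flat in $p_j$ when
$r_{cg} = 0$, so efficacies of neutral-gene guides are structurally
unidentifiable and would only add initialization noise to the comparison.

For the multi-time-point comparison, the three-point subset of the
seven-day timecourse is {7, 16, 25}: spread across the design, including
the early regime where the dynamics of strong essentials are still
informative. By day 13 and later, $e^{R r t}$ is far below the escaped
fraction $1 - p$ and essential-gene magnitudes are set by regularization
rather than data.

## Problem sizes

The bundled scenarios are desk-scale by design: 20 lines x 250 genes x 4
guides for standard recovery, one line over seven time points for the
timecourse, 60 lines x 200 genes for copy-number work (per-gene correlation
medians need enough lines that the null width $\sim 1/\sqrt{C-1}$ sits well
below the decision threshold), and 25 lines with spike rate $2 \times
10^{-4}$ for outgrowth detection. These sizes exercise every code path while
keeping a full test run in minutes.

## Known limitations

* With a single late time point, $r$ and $p$ are partly confounded; the
  tail-quantile $p_c$ estimator is biased slightly low (by roughly the
  top guides' $p_j < 1$), and compensating $p_j$ values accumulate at the
  boundary 1. Rank recovery of guide efficacy is therefore capped — by
  design, since the top-2 penalty deliberately saturates two guides per
  gene.
* The gene-effect-only warm start can lock in part of a *strong*,
  consistent off-target signal before the efficacy machinery can discount
  it: a guide depleting like a full essential in every line is
  indistinguishable from a real dependency with one good guide. Partial
  off-target depletion (the common case) is rejected; total-dropout
  artifacts leave a residual effect of roughly half the artifact's
  magnitude on the worst-hit genes.
* The fixed likelihood:penalty rescale (0.67 at epoch 0 regardless of data
  size) means fits with more observations are proportionally more
  regularized per observation. Joint multi-time-point fits improve control
  separation consistently in our measurements, but their whole-matrix RMSE
  against truth can trail a median-of-single-fits ensemble, whose implicit
  shrinkage flatters that particular metric.
* Conditions where most cells are dying (cytotoxic treatments) violate the
  model's assumption that the unperturbed population grows; behavior there
  is untested.
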