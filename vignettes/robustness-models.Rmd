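---
title: "Quantifying robustness in multi-environment breeding programs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying robustness in multi-environment breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

robustgen quantifies two components of robustness in a fish breeding program
whose stock is disseminated across countries:

* **macro-environmental sensitivity** (genotype-by-environment interaction,
  G×E), measured by treating harvest body weight in each environment as a
  different trait of the same genotype and estimating the cross-environment
  additive genetic correlation $r_g$; values well below 1 mean genotypes
  re-rank across environments (below ~0.8 re-ranking is practically
  relevant);
* **micro-environmental sensitivity**, measured as genetic heterogeneity of
  the residual variance of the trait: some genotypes are inherently noisier
  than others, and the log residual variance is itself given a linear mixed
  model with additive genetic and common-environment effects.

This vignette explains both models, the simulator used to validate them, the
samplers, their numerical choices, and the design decisions where the design
was genuinely open.

## Data structure

The motivating design is a tilapia program: a nucleus population selected on
harvest body weight (BW, grams) for 13 generations, with subsets of 60
full-sib families shipped after five and nine generations to found satellite
programs (three and four further generations of selection). Each full-sib
family is reared in its own *hapa* (a net enclosure within a pond), so full
sibs share a common environment on top of their genetic relatedness. Records
are harvest body weights with sex, spawning season (coinciding with the
generation), line (selection vs. control, nucleus only), rearing system and
harvest age as systematic effects.

All analyses work on the square-root scale, $y = \sqrt{\mathrm{BW}}$. The
transformation makes the normality assumptions of both models tenable (on
the raw scale the double hierarchical model fails to converge in practice)
and the simulator generates phenotypes on the square-root scale and squares
them, so the transformation is exactly model-consistent.

## The multi-trait animal model for G×E

With $t$ environments,
$$ y = Xb + Za + Wc + e, \qquad
\mathrm{Var}\begin{pmatrix}a\\c\\e\end{pmatrix} =
\begin{pmatrix} A\otimes G & 0 & 0\\ 0 & I\otimes C & 0\\
0 & 0 & I\otimes R\end{pmatrix}, $$
where $A$ is the pedigree numerator relationship matrix over *all* animals
in the joint pedigree and $G$ the $t\times t$ additive genetic covariance.
$C$ and $R$ are diagonal: no animal and no hapa is ever recorded in two
environments, so cross-environment residual and common-environment
covariances are not identifiable and are fixed at zero by design. The G×E
measure is $r_{g,kl} = G_{kl}/\sqrt{G_{kk}G_{ll}}$.

Fixed effects per environment: the nucleus model has rearing system, a
combined sex × spawning × line factor and a separate harvest-age slope per
spawning × line cell; satellite models have rearing system, sex × spawning
and a single age slope. Combined factors use observed level combinations
only, the first level is absorbed as reference (corner constraint), and age
is centred within environment. Fitted values are invariant to the reference
choice; a test verifies this.

To monitor how G×E develops after a transfer, the model is refitted on
reduced datasets pairing each post-transfer generation of a satellite with
the full nucleus data (`reduce_by_generation()`, `gxe_trend()`).

## The genetically structured environmental variance model

Per environment, the GSEVM is a double hierarchical animal model:
$$ y \mid b,a,c \sim N(Xb + Za + Wc,\ \mathrm{Diag}(\sigma^2_{e,i})),
\qquad \ln\sigma^2_{e,i} = x^{*\prime}_i b^* + a^*_{z(i)} + c^*_{w(i)}, $$
with
$$ \begin{pmatrix}a\\a^*\end{pmatrix} \sim
N\!\left(0,\ G_2 \otimes A\right), \qquad
G_2 = \begin{pmatrix}\sigma^2_a & \rho\sigma_a\sigma_{a^*}\\
\rho\sigma_a\sigma_{a^*} & \sigma^2_{a^*}\end{pmatrix}, $$
and independent hapa effects $c\sim N(0, I\sigma^2_c)$,
$c^*\sim N(0, I\sigma^2_{c^*})$ on the two levels. A covariance between $c$
and $c^*$ is deliberately not modelled. By default the variance-level design
$X^*$ equals the mean-level design; `variance_design = "intercept"` reduces
it to an intercept.

$\sigma_{a^*}$ has a direct breeding interpretation: shifting the dispersion
breeding value by one SD multiplies the residual variance by
$\exp(\pm\sigma_{a^*})$ (`variance_response()`), so e.g.
$\sigma_{a^*} = 0.58$ predicts a $1-\exp(-0.58) \approx 44\%$ drop in
residual variance per downward genetic SD — selection for uniformity.

## Inference

Both models share one Bayesian engine (Rcpp): Metropolis-within-Gibbs with
single-site updates of breeding values using the sparse $A^{-1}$ (built
directly from the pedigree by Henderson's rules with inbreeding-adjusted
Mendelian sampling variances; inbreeding by the Meuwissen–Luo algorithm).
The multi-trait model is fully conjugate (normal conditionals for $b$, $a$,
$c$; inverse-Wishart for $G$; scaled-inv-$\chi^2$ for the scalar variances).
In the GSEVM the location parameters have exact heteroskedastic normal
conditionals, while the dispersion parameters ($b^*$, $a^*$, $c^*$) use
single-site random-walk Metropolis–Hastings with proposal scales adapted
toward ≈0.3 acceptance during burn-in only (frozen afterwards, preserving
detailed balance).

Two further move types proved essential. Variance components and their
effect vectors form the classic "funnel": single-site updates plus conjugate
variance draws leave $\sigma^2_{a^*}$ (and $\sigma^2_a$ in the multi-trait
model) practically immobile. Both samplers therefore add *interweaving*
(centred/non-centred) re-updates after the conjugate draws: the genetic
covariance Cholesky factor is re-proposed by random-walk MH with the
whitened breeding values held fixed (moving $(G, a, a^*)$ jointly, with
exact Jacobian terms), and the hapa variances are re-proposed on the log
scale with the whitened family effects held fixed. These moves cut the
potential scale reduction factor for the dispersion variance from >3 to
≈1.0 at desk scale.

Correctness of the kernels is tested by Geweke-style successive-conditional
simulation (sample data given parameters, then parameters given data, and
compare against direct prior draws) on a 30-animal pedigree including family
effects; all moments agree within $|z| < 3$ (in long runs, within ≈1).

**Priors.** Flat on $b$ and $b^*$; inverse-Wishart on $G$ and $G_2$;
scaled-inv-$\chi^2(\nu = 3)$ on the hapa variances. Two default choices
matter and are worth their rationale:

* *Degrees of freedom.* For $G_2$ the default is $\nu = d + 1 = 3$, the
  smallest proper choice; it implies a *uniform* marginal prior on $\rho$
  and a heavy-tailed variance prior. A seemingly innocuous $\nu = 4$ puts
  only a few percent of its mass above dispersion variances of ~0.3: with
  single records per animal the per-record information about $a^*_i$ is
  weak (Fisher information 1/2 per record on the log-variance scale), the
  posterior for $\sigma^2_{a^*}$ then shrinks toward the prior mode and
  $\rho$ compensates toward $\pm 1$, because the cross-moment
  $\rho\sigma_a\sigma_{a^*}$ is the directly identified quantity.
* *Scales.* Mean-level prior scales default to $0.1\,\mathrm{var}(y)$ (the
  trait's phenotypic variance), so the prior is invariant to the trait's
  measurement unit; a fixed absolute scale cannot be a sensible default for
  weights recorded in grams and kilograms alike, and when the likelihood is
  weak it silently dominates the mean-level variance. The log-variance
  level is dimensionless and keeps the absolute scale 0.1.

All prior constants remain one `prior` argument away.

**Chains.** Defaults: multi-trait 3 chains × 50,000 iterations (10,000
burn-in, thin 10); GSEVM 3 × 30,000 (5,000, thin 10), from dispersed starts
(multiplicative factors on the initial covariances; initial effect fields
drawn at the matching scale). A `preset = "paper"` runs 10^6 iterations with
10^5 burn-in. Convergence is summarised by the Gelman–Rubin PSRF (original
between/within-chain form; split-chain optional) — fits flag, but do not
error on, PSRF > 1.1 — and uncertainty by shortest-window HPD intervals
computed exactly on the sorted draws (no smoothing).

## The simulator

`simulate_gift()` generates the whole design: founders carry one
$(t+1)$-variate normal breeding-value vector (one mean-level value per
environment plus one dispersion value $u^*$), with cross-environment
correlations from the configured $r_g$ matrix and per-environment
mean–dispersion correlations $\rho_e$; descendants follow
$u_{\mathrm{child}} = \tfrac12(u_s + u_d) + m$ with Mendelian variance
$\left(\tfrac12 - \tfrac14(F_s + F_d)\right)\Sigma$. Families are produced
by nested mating (each selected sire serves `dams_per_sire = 2` dams by
default), each family gets one hapa with effects $c$ and $c^*$ on the two
levels, and phenotypes are
$t = \mu_E + \mathrm{fixed} + \beta(\mathrm{age} - \bar a) + u_E + c + e$
with $e \sim N(0, \exp(\log\sigma^2_{e,E} + u^* + c^*))$, squared to grams.
Selection is between- and within-family (top families by mean, then best
individuals round-robin across the selected families), mass, or random;
ties break by animal id and all randomness derives from one seed, so output
is byte-reproducible. Transfers copy offspring of randomly chosen
selection-line families into a satellite environment, where they found the
local program.

Defaults emulate the published design: three environments with 13/3/4
generations, 87/71/54 families per generation, mean family sizes 41/32/52,
grow-out 230/344/232 days, mean BW 222/244/313 g, transfers of 60 families
at generations 5 and 9, a 10% control line in the nucleus, and generative
variance components set to the published point estimates (mean level from
the multi-trait table, dispersion level from the GSEVM table; Malaysia's
dispersion variance 0.34 is used as the single $u^*$ variance since one
dispersion effect per animal cannot carry three environment-specific
variances).

Two design decisions deviate from the simplest reading of the design and
deserve their rationale here:

* **Nested mating instead of strict pair mating.** With one dam per sire,
  sire, dam and hapa are the same grouping (1:1:1), so additive and hapa
  variances are separated only by cross-generation links — an REML sire-dam
  fit on pair-mated data is degenerate, and desk-scale posteriors for
  $\sigma^2_a$ are very wide. Two dams per sire restores the paternal
  half-sib structure that actual tilapia programs use and that variance
  component estimation needs.
* **A single dispersion effect per animal.** The alternative — one $u^*$
  per environment — would require assumptions about cross-environment
  dispersion correlations that nothing in the motivating study informs.

What the generator deliberately does not emulate: mortality, sex-ratio
distortion, water-quality covariates, genomic data, maternal effects, and
dominance. Passing recovery tests on this generator therefore shows the
estimators are correct *under the stated model*, not that real data meet
the model.

## Numerical choices and degenerate inputs

* Unknown parents are founders from one non-inbred base population; animals
  with a single known parent get the adjusted Mendelian variance
  $0.75 - 0.25\,F_p$.
* Pedigrees are topologically sorted at construction; cycles (including
  self-ancestry) and parents missing from the animal list are errors.
* Dense $A$ is used only at desk scale; model fitting touches $A$ only
  through its sparse inverse.
* MH proposals that would push a log residual variance beyond $\pm 40$ are
  rejected outright; retained draws are checked finite.
* Non-positive body weights are errors naming the record; the simulator
  truncates analysis-scale phenotypes at 0.05 (an event of order $10^{-9}$
  at the default intercepts).
* Single-level factors are dropped with a warning; aliased design columns
  are removed by QR pivoting; one-record environments are errors.
* Empty generations, satellite-free `reduce_by_generation()` calls, and
  fits where trait blocks share no pedigree ancestry (then $r_g$ is
  prior-identified) are errors or warnings, as appropriate.

## Problem sizes used in the tests

The test-suite and acceptance runs use desk-scale versions of the study
conditions, chosen as the smallest sizes at which the checked property is
informative: recovery experiments run at 100–200 families × 40 offspring
over one to two generations (6,000–8,000 records) with 2–3 chains ×
8,000–30,000 iterations, and the cross-environment correlation is reported
as the mean over three replicate programs (one replicate's estimate still
carries sampling noise of about ±0.1); the HPD-coverage experiment uses 20
replicates at 50 families × 40 with two chains of 6,000 iterations each;
oracle tests (A-inverse against dense
inverses, likelihood against brute-force sums, HPD against exhaustive
window search, PSRF against the hand formula, GLS and ANOVA closed forms,
grid posteriors, Geweke joint-distribution checks) run on instances of 5 to
a few hundred animals. Recovery experiments use random mating: under
selection the base-population parameters are no longer the distribution
from which later-generation effects are drawn, so coverage of the nominal
truth is only well defined without selection.

## Known limitations

* Cross-environment dispersion genetics (a multi-trait GSEVM) is out of
  scope — as is any genomic relationship information.
* With single records per animal, $\sigma^2_{a^*}$ and especially $\rho$
  are weakly identified at desk scale; their posteriors remain noticeably
  prior-sensitive below ~10,000 records. The package reports HPD intervals
  and PSRF so this is visible rather than hidden.
* The AI-REML standard errors of the original software are replaced by
  posterior standard deviations and HPD intervals; point estimates are
  posterior means under weak priors, which approximate REML but are not
  identical to it.
* Phenotypic variance in derived ratios is an explicit input
  (`heritability(va, vp)`), because published component tables do not
  always satisfy $V_P = V_A + V_C + V_R$ exactly.
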