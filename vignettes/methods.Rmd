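---
title: "Two-stage Bayesian SNP selection for non-Gaussian GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian SNP selection for non-Gaussian GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momgwas)
```

# The problem

Genome-wide association studies regress a phenotype on each of a very
large number of SNPs (allele counts 0/1/2), with two complications that
the classical Gaussian LMM toolchain does not address together: the
phenotype may be binary or a count, and the samples are correlated
through relatedness and population structure. `momgwas` models such data
with a generalized linear mixed model (GLMM) and performs Bayesian
variable selection over the SNPs in two stages, with explicit
false-discovery control at each stage.

# The GLMM

Conditional on random effects, observations are exponential-family with
canonical link,

$$f(y_i \mid \eta_i) = \exp\{T(y_i)\eta_i - B(\eta_i) + C(y_i)\},
\qquad \mu_i = B'(\eta_i),\; v_i = B''(\eta_i),$$

$$g\!\left(E(\mathbf y \mid \boldsymbol\alpha_1, \boldsymbol\alpha_2)\right)
 = \text{offset} + X_c\boldsymbol\beta_c + X_s\boldsymbol\beta_s
   + \boldsymbol\alpha_1 + \boldsymbol\alpha_2,$$

with a kinship random effect
$\boldsymbol\alpha_1 \sim N(\mathbf 0, \kappa_1\Sigma)$ ($\Sigma$ a known
positive semi-definite kinship matrix, or the genomic relationship matrix
of the genotypes themselves) and an i.i.d. overdispersion random effect
$\boldsymbol\alpha_2 \sim N(\mathbf 0, \kappa_2 I)$ that absorbs
extra-Poisson (or extra-binomial) variability. Two families are supported
for data analysis — Bernoulli/logit and Poisson/log — plus a
Gaussian/identity family with unit variance used for degenerate-limit
testing. When the count phenotype is a total over $r_i$ replicates,
$\log r_i$ enters as a per-sample offset.

# Pseudo-likelihood fitting and the P3D approximation

The GLMM likelihood integrates over the random effects and has no closed
form; repeated numerical integration across hundreds of thousands of
models is not viable. `pql_fit()` therefore uses penalized
quasi-likelihood (PQL, the Breslow–Clayton / Wolfinger–O'Connell working
scheme): at each iteration the model is linearized around the current
fit, producing *adjusted observations*

$$\mathbf y^\star = \widehat V^{-1}(\mathbf y - \widehat{\boldsymbol\mu})
 + X\widehat{\boldsymbol\beta} + \widehat{\boldsymbol\alpha}_1
 + \widehat{\boldsymbol\alpha}_2,$$

which follow the working LMM
$\mathbf y^\star = X\boldsymbol\beta + \boldsymbol\alpha_1 +
\boldsymbol\alpha_2 + \widehat V^{-1}\boldsymbol\epsilon$ with
$\mathrm{Var}(\widehat V^{-1}\boldsymbol\epsilon) \approx \widehat V^{-1}$
(for the canonical links used, $d\mu/d\eta = v$, so this is the textbook
working response). Each iteration estimates $(\kappa_1, \kappa_2)$ by
REML on the working model, then fixed effects by GLS and random effects
by their BLUPs, and repeats until the largest absolute change in
$(\boldsymbol\beta, \kappa_1, \kappa_2)$ falls below the tolerance.

REML rather than ML is used because it is the standard choice for GWAS
mixed models (the EMMAX lineage); whether the two differ materially here
is immaterial since only the frozen $(\widehat\kappa_1, \widehat\kappa_2)$
enter downstream. Random effects are updated through the working-LMM
solve (Henderson form); a BLUP-per-iteration variant would coincide at
convergence.

The P3D (population parameters previously determined) device then makes
per-model fitting cheap: a stage's *baseline* model — no SNPs for
screening, all $k$ candidates for selection — fixes
$\widehat{\boldsymbol\beta}_c, \widehat\kappa_1, \widehat\kappa_2,
\widehat V$ and $\mathbf y^\star$. The frozen covariance
$H = \widehat\kappa_1\Sigma + \widehat\kappa_2 I + \widehat V^{-1}$ is
eigendecomposed once, $H = PDP^\top$, and every model in the stage is
fitted in the rotated coordinates
$\tilde{\mathbf y} = P^\top(\mathbf y^\star - X_c\widehat{\boldsymbol\beta}_c)$,
$\tilde{\mathbf x} = P^\top \mathbf x$, where the covariance is the
diagonal $D$.

## Numerical choices in the fitter

* Convergence tolerance $10^{-4}$ on the maximum absolute parameter
  change; at most 50 iterations. Non-convergence returns the last state
  with a warning, never silently; a non-finite working response (e.g.
  separation in the Bernoulli model) is an error carrying iteration
  diagnostics.
* $v_i$ is floored at $10^{-6}$ so fitted probabilities near 0/1 cannot
  blow up $V^{-1}$.
* REML is maximized by bounded quasi-Newton (L-BFGS-B) on
  $(\log\kappa_1, \log\kappa_2) \in [\log 10^{-8}, \log 10^{4}]^2$,
  warm-started across PQL iterations and initialized at
  $0.1\,\mathrm{var}(\mathbf y^\star)$; estimates at the lower bound are
  reported as exact zeros (the boundary is a legitimate estimate).
* Missing genotypes are mean-imputed per SNP and the minor allele
  frequency (MAF) filter at 0.01 is applied after imputation.
* **SNP columns are mean-centered in every estimation-side design**
  (screening summaries, selection designs, PQL SNP blocks), while the
  phenotype simulators use raw 0/1/2 counts. This matters: the screening
  estimator regresses $\tilde{\mathbf y}$ — which has the baseline GLS
  fit of $X_c$ removed, hence is $D^{-1}$-orthogonal to the rotated
  intercept — on a lone SNP column. With raw coding the column's mean
  component inflates the denominator
  $\tilde{\mathbf x}^\top D^{-1}\tilde{\mathbf x}$ and attenuates
  $\widehat\beta_s$ by roughly $n\bar x^2 / \mathbf x^\top\mathbf x$;
  centering removes the attenuation without changing what the estimator
  means (slopes are identical in any design containing an intercept).

# Stage 1: screening

Each SNP's GLS summary in the rotated coordinates is

$$\widehat\beta_s = (\tilde{\mathbf x}_s^\top D^{-1}\tilde{\mathbf x}_s)^{-1}
   \tilde{\mathbf x}_s^\top D^{-1}\tilde{\mathbf y}, \qquad
  \sigma_s^2 = (\tilde{\mathbf x}_s^\top D^{-1}\tilde{\mathbf x}_s)^{-1},$$

an $O(n)$ operation per SNP once the decomposition exists. The prior on
the effect is a spike/nonlocal mixture

$$p(\beta_s \mid \tau, \pi_0) = \pi_0\,\delta_0(\beta_s)
 + (1-\pi_0)\,\frac{\beta_s^2}{n\tau\sigma_s^2}
   N(\beta_s \mid 0, n\tau\sigma_s^2),$$

a product-moment (pMOM) nonlocal density that vanishes at zero —
evidence for a truly null SNP accumulates faster than under any local
prior. Marginalizing $\widehat\beta_s \sim N(\beta_s, \sigma_s^2)$ gives
the closed-form predictive used throughout
(`mixture_predictive()`); multiplying over SNPs (approximate
independence given the hyperparameters) and adding log hyperpriors gives
the objective whose mode defines the empirical-Bayes estimates
$(\widehat\tau, \widehat\pi_0)$.

Three hyperprior schemes for the scale $\tau$ are available:

| scheme | prior on $\tau$ | default |
|---|---|---|
| `uniform` | improper flat prior on $(0,\infty)$ (contributes 0 to the log posterior; only the mode is used) | recommended default |
| `invgamma` | $IG(0.55/0.022 + 1,\; 0.55)$: prior mean exactly 0.022, $P(\tau > 0.01) = 0.999$, keeping $\tau$ away from the numerically unstable neighbourhood of zero | |
| `fixed` | point mass | 0.022, the GWAS effect-size scale at which the pMOM prior puts probability 0.01 on a standardized effect in $(-0.05, 0.05)$ |

$\pi_0$ always gets a uniform prior on $(0,1)$. The optimizer works on
$(\log\tau, \operatorname{logit}\pi_0)$ with L-BFGS-B, initialized at
$\tau = 0.022$ and $\pi_0 = 1 - 10/p$ clipped to $[0.5, 1-10^{-6}]$.
$\pi_0$ is *constrained* to $[0.5, 1-10^{-6}]$: a genome-wide scan always
has a null majority, and without the bound the optimum can collapse to
$\pi_0 \to 0$ with a tiny $\tau$, because the pMOM predictive dominates
the null density pointwise whenever the summaries are even slightly
overdispersed ($z_s^2 > 1$ on average). A boundary estimate at the top is
clipped with a warning. $\tau$ is bounded in $[10^{-6}, 100]$.

Each SNP then gets the posterior inclusion probability
$P(\beta_s \ne 0 \mid \cdot) = 1 - \widehat\pi_0
N(\widehat\beta_s\mid 0,\sigma_s^2) / p(\widehat\beta_s \mid
\widehat\tau, \widehat\pi_0)$, and candidates are selected by the direct
posterior-probability Bayesian FDR rule: sorting the null probabilities
$q_s = 1 - P(\beta_s \ne 0\mid\cdot)$ ascending, keep the largest $m$
whose running mean is at most $\alpha$ (default 0.05). Ties are broken by
original SNP index, for determinism. Among the Bayesian FDR variants in
circulation this is the posterior-expected-FDR procedure; the choice
matters little because candidate inclusion probabilities are typically
near 0 or 1.

# Stage 2: model selection

The $k$ screened candidates define a space of $2^k$ GLMMs. The baseline
for this stage is the *full* model with all $k$ candidates (using the
full model's adjusted observations for every submodel is the standard
recommendation for GLMM model comparison), refitted by PQL, with a fresh
spectral context. Under model $M_m$ with $p_m$ SNPs the rotated adjusted
observations are $\tilde{\mathbf y} \sim N(\widetilde X_m
\boldsymbol\beta_m, D)$, the prior on $\boldsymbol\beta_m$ is the
multivariate pMOM with Gaussian kernel covariance
$\widehat\tau n (\widetilde X_m^\top D^{-1}\widetilde X_m)^{-1}$ (the
rotated form equals the $X^\top H^{-1} X$ prose form exactly), and with

$$C_m = \widetilde X_m^\top D^{-1}\widetilde X_m\,(1 + (\widehat\tau n)^{-1}),
\quad \tilde{\boldsymbol\beta}_m = C_m^{-1}\widetilde X_m^\top D^{-1}\tilde{\mathbf y},
\quad R_m = \tilde{\mathbf y}^\top D^{-1}\tilde{\mathbf y}
 - \tilde{\mathbf y}^\top D^{-1}\widetilde X_m\tilde{\boldsymbol\beta}_m,$$

the log marginal likelihood is

$$\log m(\tilde{\mathbf y}\mid M_m) = -\tfrac n2\log 2\pi
 - \tfrac12\log|D| - \tfrac{p_m}2\log(1+\widehat\tau n) - \tfrac{R_m}2
 + \log E_2 - \log E_1,$$

where $E_2 = E\prod_i \beta_{mi}^2$ under
$N(\tilde{\boldsymbol\beta}_m, C_m^{-1})$ and $E_1$ is the same
expectation under $N(\mathbf 0, (1+\widehat\tau n)C_m^{-1})$. The pMOM
normalizing constant never appears: it cancels into $E_1$. Both
expectations are approximated from the *same* 2000 draws (common random
numbers): draws from $N(\tilde{\boldsymbol\beta}_m, C_m^{-1})$ feed $E_2$
directly and their rescaled residuals feed $E_1$, so the ratio is stable.
Each model draws from its own substream derived from the master seed and
the (sorted) model indicator, making scores reproducible and independent
of enumeration order; repeated evaluations of one indicator are cached.
For $p_m = 1$ the Bayes factor against the null reduces algebraically to
the ratio of the screening predictive's nonnull and null components at
$(\widehat\beta_s, \sigma_s^2)$ — the two stages are mutually consistent,
and the test suite verifies the identity numerically.

The model prior is exchangeable-Bernoulli,
$P(M_m) = \widehat\pi_0^{\,k-p_m}(1-\widehat\pi_0)^{p_m}$, reusing the
screening $\widehat\pi_0$ (and $\widehat\tau$) without re-estimation so
the selection stage's false-discovery control is as strict as the
screening stage's.

For $k < 16$ the space is enumerated and the posterior normalized
exactly. For larger $k$ a binary-encoded genetic algorithm maximizes
log prior + log marginal: population 50, up to 200 generations,
rank-based selection, one-point crossover at rate 0.8, per-bit mutation
at rate 0.1, elitism 2, early stop after 50 stagnant generations —
R/GA-like settings at this scale. The null, full, and all single-SNP
models are always evaluated, and the best model seen anywhere is
returned. Cached fitness under common random numbers means a duplicate
individual is never re-scored with fresh noise.

# The single-marker baseline

`sma_scan()` is the frequentist comparator: the same PQL working model
and frozen spectral context, per-SNP Wald statistics
$z_s = \widehat\beta_s/\sigma_s$ referred to the standard normal (not a
$t$: sample sizes are large and this matches EMMAX-style practice), and
Bonferroni selection at family level $\alpha = 0.05$, i.e.
$p_s < \alpha/p$. Screening and baseline share identical summaries by
construction.

# The simulators and what they do (not) emulate

`simulate_genotypes()` draws Balding–Nichols structured genotypes: an
ancestral MAF per SNP uniform on $[0.05, 0.5]$, three subpopulations with
divergence $F = 0.01$ perturbing it through a beta model, binomial(2)
allele counts, SNPs with realized MAF < 0.01 redrawn, and positions on
one synthetic chromosome at 1 kb spacing so the 5 kb detection buffer
spans $\pm 5$ SNPs. The defaults were chosen once to induce a non-trivial
kinship structure comparable to real panels while keeping the generator
simple. What this does **not** emulate: linkage-disequilibrium blocks
(SNPs are independent given the structure), realistic MAF spectra (real
panels are skewed toward rare variants), relatedness beyond three-way
structure, and genotyping error. Consequently the detection buffer never
fires through LD proxies here, and passing tests say nothing about LD
fine-mapping behaviour on real data.

The phenotype builders reproduce the two study designs used throughout
the package's tests:

* **binary**: 20 evenly spaced causal SNPs — 10 at a varying $\beta$, 5
  at 0.2, 5 at $-0.2$ — intercept $\beta_0 = -0.5$, kinship variance
  $\kappa_1 = 0.15$, Bernoulli-logit sampling;
* **count**: 10 evenly spaced causal SNPs — 5 at a varying $\beta$, 5 at
  0.2 — intercept $\beta_0 = 1$, $\kappa_1 = 1$, $\kappa_2 = 0.3$,
  12 replicates per sample entering as a $\log 12$ offset,
  Poisson-log sampling;

plus null (no-causal) variants of both. These parameter values *are* the
study conditions; they are constructor defaults, not tuning knobs.

# Evaluation

`match_detections()` scores causal-centrically with a 5000 bp buffer: a
causal SNP with at least one detection within the buffer on the same
chromosome counts one true positive (several nearby detections still
count once); a detection not within any causal buffer is one false
positive; a detection inside two buffers credits both causal SNPs.
`detection_metrics()` reports FDR $= FP/(TP+FP)$ (0/0 defined as 0 — no
discoveries, no false discovery) and F1 $= 2TP/(2TP+FP+FN)$ with
$FN = n_\text{causal} - TP$, i.e. false negatives are unmatched causal
SNPs, not unmatched detections.

# Problem sizes used in the included studies

The packaged null-robustness studies (`null_fp_study()`, also driven by
`scripts/acceptance.R` and the acceptance tests) run 100 data sets per
scenario at n = 150, p = 5000 for the count design (all three $\tau$
schemes plus the single-marker baseline) and n = 500, p = 10000 for the
binary design (single-marker baseline); these sizes keep a full
replication within a desktop-scale compute budget while leaving the
binomial standard errors small enough for the calibration comparisons to
bite. Monte-Carlo marginal likelihoods use the default 2000 draws per
model; verification tests raise this to $10^5$–$10^6$ where an identity
is checked to fixed precision.

# Known limitations

* PQL is a first-order approximation; for Bernoulli data with small
  cluster information its variance components are known to be biased
  toward zero. The package's tests verify recovery in the Poisson
  replicate-offset regime, where the approximation is accurate.
* The screening predictive treats per-SNP summaries as independent given
  the hyperparameters; strong LD (not simulated here) would violate this
  more severely than population structure does.
* A third, design random effect (e.g. experimental batches with a known
  covariance) is not implemented, though the P3D machinery would admit it.
* The empirical-Bayes $\widehat\tau$ under the improper uniform prior can
  sit at the lower numerical bound when the data carry no signal; the
  inclusion probabilities are then effectively null everywhere, which is
  the intended behaviour, but $\widehat\tau$ itself should not be
  interpreted in that regime.
* Survival phenotypes, biobank-scale $n$, and MCMC over the model space
  are out of scope.
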