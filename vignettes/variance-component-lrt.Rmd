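---
title: "Permutation-based variance component LRT for SNP-set association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based variance component LRT for SNP-set association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vclrt)
```

## The testing problem

In a case-control study, a gene groups $K$ SNPs into a set
$\mathbf{Z} = [Z_1, \dots, Z_K]$ of additive dosages (0/1/2 copies of the
minor allele).  Testing the $K$ SNP effects jointly with a fixed-effects
logistic regression costs $K$ degrees of freedom and breaks down under
linkage disequilibrium (LD): nearby SNPs are strongly correlated, so the
design is near-collinear.  The standard remedy treats the SNP effects as
exchangeable random effects with one shared variance component,

$$
\operatorname{logit}\,\mu_i = \mathbf{x}_i'\boldsymbol\alpha +
\mathbf{z}_i'\boldsymbol\beta, \qquad
\beta_k \sim N(0, \tau^2),
$$

so the gene-level null "no SNP in the set matters" is the one-dimensional
boundary hypothesis $H_0\!: \tau^2 = 0$.  `vclrt` implements a
likelihood-ratio test of this hypothesis whose null distribution is
obtained by permutation, together with the comparators a practitioner
would want alongside it: the chi-square-mixture reference distributions
and the score-based (SKAT-style) variance-component test.

## Working model and the LRT statistic

The binary-response likelihood of the mixed model has no closed form.
The package therefore fits the model by penalized quasi-likelihood
(PQL): each iteration linearizes around the current estimates, producing
the working response and weights

$$
Y'_i = \eta_i + \frac{y_i - \mu_i}{\mu_i(1 - \mu_i)}, \qquad
R = \operatorname{diag}\!\left(\tfrac{1}{\mu_i(1-\mu_i)}\right),
$$

and fits the working linear mixed model
$\mathbf{Y}' = X\boldsymbol\alpha + Z\boldsymbol\beta + \mathbf{e}$ with
$\boldsymbol\beta \sim N(0, \tau^2 I_K)$ and
$\mathbf{e} \sim N(0, \sigma^2 R)$.  Its quasi log-likelihood, up to a
constant, is

$$
L(\tau^2, \sigma^2) = -\tfrac{1}{2}\left[\log |V| +
(\mathbf{Y}' - X\hat{\boldsymbol\alpha})' V^{-1}
(\mathbf{Y}' - X\hat{\boldsymbol\alpha})\right], \qquad
V = \tau^2 Z Z' + \sigma^2 R,
$$

with $\hat{\boldsymbol\alpha}$ the GLS estimate
$(X'V^{-1}X)^{-1}X'V^{-1}\mathbf{Y}'$.  The test statistic is twice the
profile gap at the converged working response:

$$
T = 2\left[\sup_{\tau^2 \ge 0} L(\tau^2, \hat\sigma^2(\tau^2)) -
L(0, \hat\sigma^2(0))\right].
$$

Both terms share the same converged $\mathbf{Y}'$ and $R$, so $T \ge 0$
by construction (evaluating the null term with a different working
response — e.g. the null logistic model's own — produces negative
statistics in the majority of null datasets; we verified this directly,
which is why the shared-working-response form is used).

Two design choices deserve emphasis:

* **The residual scale $\sigma^2$ is estimated, not fixed at 1.**
  The working model is an ordinary LMM, and the standard LMM machinery
  (e.g. `nlme::lme`, which `MASS::glmmPQL` drives) always estimates a
  residual variance alongside $\tau^2$.  Fixing $\sigma^2 = 1$ makes the
  null distribution of $T$ markedly lighter-tailed: in our null
  calibration runs the 0.50:0.50-mixture rejection rate at the 5% level
  drops by roughly half relative to the free-scale statistic, moving the
  mixture comparators away from their classical behaviour.  The
  free-scale profile is both the standard LMM likelihood and the variant
  whose comparator behaviour matches the literature, so it is the
  package default throughout.
* **REML inside the loop, ML for the statistic.**  Variance parameters
  inside the PQL iterations are estimated by the REML form of the
  working likelihood (the LMM default, less biased for variance
  components); the statistic $T$ itself is always the ML profile gap on
  the converged working response, i.e. an (unrestricted) LRT, not a
  restricted LRT.  `pql_control(reml = FALSE)` switches the loop to ML.

## Null distribution: why permutation

Under $H_0$, $\tau^2$ lies on the boundary of its parameter space, so
$T$ is not asymptotically $\chi^2_1$.  The classical approximations
refer $T$ to a mixture $w_0\chi^2_0 + w_1\chi^2_1$ with
$(w_0, w_1) = (0.50, 0.50)$, or $(0.65, 0.35)$ as suggested for some
longitudinal designs.  Both are known to be unreliable: the correct
mixture weight depends on the design (through the LD structure of $Z$),
and for strongly correlated SNP sets the point mass at zero is far
larger than 0.5 — in our null simulations around 90% of fits give
$\hat\tau^2 = 0$ exactly.  The mixtures are therefore provided as
comparators (`mixture_pvalue()`), not as the recommended test.

The recommended null is resampling (`permutation_test()`):

1. compute $T^{\mathrm{obs}}$ on the original data;
2. permute the rows of $(\mathbf{y}, X)$ jointly, keeping $Z$ fixed
   (this assumes no correlation between $X$ and $Z$, which holds by
   construction in the simulation designs); or, in bootstrap mode,
   redraw $\mathbf{y}$ from the fitted null logistic model;
3. refit the full PQL model from cold start and record $T^{*b}$;
4. repeat $B$ times; the Monte-Carlo p-value is the proportion of
   $T^{*b} \ge T^{\mathrm{obs}}$, ties included.

Because the statistic has a large null atom at zero, the permutation
p-value inherits an atom at exactly 1 (whenever $T^{\mathrm{obs}} = 0$,
every tie counts).  The p-value is valid — sub-uniform, with rejection
rates at conventional levels matching the nominal level — but its full
distribution is far from Uniform(0,1), so distribution-level uniformity
diagnostics (e.g. a Kolmogorov–Smirnov test against the uniform) reject
for any faithful implementation of the tie-inclusive rule.  The add-one
estimate $(\#+1)/(B+1)$ is also reported; the plain proportion is the
default.  Non-converged refits keep their last-iterate statistic (with a
warning) so that the null sample always has exactly $B$ draws.

## The score comparator

The score test (`score_statistic()`) needs only the null logistic fit:
$Q = (\mathbf{y} - \hat{\boldsymbol\mu}_0)' Z Z'
(\mathbf{y} - \hat{\boldsymbol\mu}_0)$, referred to its asymptotic null
$\sum_j \lambda_j \chi^2_{1j}$ with $\lambda_j$ the eigenvalues of
$Z' P_0 Z$.  The kernel is unweighted linear (all SKAT weights 1),
matching a common-variant model with one shared $\tau^2$; beta-MAF
weights would change the comparator.  No small-sample moment adjustment
is applied — the mild conservatism of the unadjusted test at small $n$
is part of what the simulations document.  Tail probabilities come from
numerical inversion of the characteristic function (Imhof/Davies
integral, target accuracy $10^{-6}$), with a Liu-type moment-matching
fallback when the inversion reports insufficient accuracy or an answer
at its own resolution; each p-value records which algorithm produced it.

## Synthetic data

`simulate_sim1()` draws correlated common-variant genotypes: latent
Gaussian rows with AR correlation $0.5^{|k-k'|}$, thresholded at
$\pm\Phi^{-1}(0.75) \approx 0.674$ so dosages 0/1/2 occur with
probabilities 0.25/0.50/0.25 (Hardy–Weinberg at MAF 0.25), plus
covariates $X_1 \sim \mathrm{Bernoulli}(0.5)$, $X_2 \sim N(0,1)$,
effects $\beta_k \sim N(0, \tau^2)$ and phenotypes from the logistic
model with baseline $-(1 + 0.5X_1 + 0.5X_2)$.  The latent AR recursion
is exact for this correlation structure and costs $O(nK)$.

`simulate_sim2_standin()` covers the non-normal-effects regime: only
$m$ of $K$ SNPs are causal, with effects drawn $U[0.60, 1.10]$ (all
positive; no sign flipping), causal positions chosen uniformly at
random per replicate.  Its genotypes come from `gen_haplotype_pool()`, a
configurable haplotype-pool generator (Markov copying on a latent
uniform; exact marginal allele frequencies, LD decaying geometrically
with the copying probability) standing in for coalescent-simulator
output.  It reproduces the structure of that regime — sparse non-normal
effects on LD-correlated genotypes — but not any particular
population-genetic demography, so published power values for
coalescent-simulated genotypes are not reproduction targets; the
package's own checks for this design are structural (the $m = 0$
configuration must be calibrated).  Defaults: per-site MAF drawn from
the argument `maf` (default 0.25), copying probability 0.8, pool of 500
founders — values chosen once as a plausible common-variant gene region.

Setting $\tau^2 = 0$ or $m = 0$ reproduces the exact null of the
phenotype model, so type-I-error and power studies share one code path.

What passing tests on these generators do *not* show: behaviour under
population stratification, rare variants (MAF $\ll$ 0.25), missing or
mis-called genotypes, or $X$–$Z$ correlation (which the joint
permutation scheme explicitly assumes away).

## Numerical choices

* Each working-model fit standardizes by $R^{-1/2}$ and takes one thin
  SVD of the standardized $Z$; every $\tau^2$ evaluation then costs
  $O(\min(n,K)\,p^2)$, and $\log|V|$ is a sum over singular values.  The
  efficient path is tested to $10^{-9}$ against dense linear algebra.
* The profile over the variance ratio $\tau^2/\sigma^2$ is maximized on
  a 64-point log-spaced grid on $[10^{-5}, 100]$ (plus the boundary 0)
  refined by golden section; the estimate is tested to $10^{-5}$
  against an independent dense-grid oracle.  A ratio at the upper bound
  raises a boundary warning.
* PQL iterates to a $10^{-6}$ max-absolute-change tolerance with at most
  50 iterations, starting from the null logistic fit and
  $\tau^2 = 0.1$.  Fitted probabilities are clipped to
  $[10^{-6}, 1 - 10^{-6}]$ before weights are formed.
* $T$ is clamped to zero when it is negative within $10^{-10}$
  (floating-point noise at the boundary); larger negative values are an
  internal error, not silently absorbed.
* Permutations and bootstrap responses are drawn in R (so seeding is
  plain `set.seed()`); the $B$ refits run in compiled code.  Experiment
  replicates use independent L'Ecuyer-CMRG streams derived from one
  master seed, so results are identical at any worker count.

## Monte-Carlo study sizes

The bundled studies use the full published design at desk scale where
the method is cheap (score and mixture type-I cells: 2000 null
replicates at $n = 400$, $K = 20$) and a reduced scale where each
replicate embeds a full permutation null (300 replicates with $B = 500$
for the permutation cells; 200 replicates with $B = 200$ for the
reduced null-calibration and sparse-design checks).  $B$ in the 200–500
range is known to behave well at the 5% level; the package default for
single-dataset analysis is $B = 1000$.

A note on effect scales: with $K = 20$ LD-correlated SNPs, per-SNP
effects $\beta_k \sim N(0, \tau^2)$ at $\tau^2 = 0.15$ put a variance of
roughly 1.5 on the logit scale — a very strong gene-level signal at
which every calibrated test rejects almost surely for $n \ge 400$
(measured power 0.95–0.98 for all four methods).  Method comparisons
are only informative on the steep part of the power curve, so the
bundled paired-ordering study (permutation $\ge$ score $\ge$
0.50:0.50 mixture) runs at $\tau^2 = 0.01$, where power is near 0.3;
this variance was chosen from a power scan of the score comparator, not
from the ordering outcome itself.

## Known limitations

* PQL variance-component estimates are biased downward for binary
  responses; the permutation null inherits the same bias, so type-I
  error is controlled, but power is somewhat below what an exact-
  likelihood LRT could achieve.  Bias-corrected PQL is out of scope.
* One variance component only; no probit/Poisson links, no REML-based
  restricted LRT statistic, no SKAT weights or SKAT-O, no small-sample
  SKAT adjustments.
* The joint $(\mathbf{y}, X)$ permutation is invalid when covariates
  correlate with genotypes (e.g. ancestry); bootstrap mode relaxes this
  at the cost of trusting the null logistic model.
* Reconstructed comparator details (the exact working-likelihood
  variant inside the original PQL software, its convergence tolerances
  and starting values) are underdetermined; the chi-square-mixture
  comparator cells are reproduced to Monte-Carlo accuracy but can sit
  at the edge of tight reproduction bands, slightly on the conservative
  side.
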