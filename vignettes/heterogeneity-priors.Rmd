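---
title: "Informative priors for multiple heterogeneity variances in network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informative priors for multiple heterogeneity variances in network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetnma)
```

## The model

`hetnma` fits the contrast-based random-effects consistency model for
arm-level binary data. With $b_j$ the baseline treatment of study $j$
(the lowest-indexed treatment present),

$$r_{jk} \sim \mathrm{Bin}(\pi_{jk}, n_{jk}), \qquad
\mathrm{logit}(\pi_{jk}) = \mu_j + \delta_{jb k}\,[k \neq b_j],$$

and the vector of study contrasts with the overall reference treatment is
exchangeable, $\boldsymbol\delta_j \sim N(\mathbf d, \boldsymbol\Sigma)$.
The baselines $\mu_j$ are unrelated fixed effects with vague $N(0, 10^4)$
priors, as are the basic parameters $d_{01}, \dots, d_{0p}$; all other
contrasts follow from consistency, $d_{kl} = d_{0l} - d_{0k}$
(`functional_contrasts()`). Heterogeneity variances are
$\tau_{kl}^2 = \Sigma_{kk} + \Sigma_{ll} - 2\Sigma_{kl}$. Multi-arm trials
contribute a correlated vector of contrasts: the network-level
$\boldsymbol\Sigma$ is re-based to the trial's own baseline
(`trial_contrast_covariance()`), and the joint normal is handled through
its sequential conditional factorization (`conditional_factors()`), each
component conditioned on the ones before it.

Coherence of the heterogeneity variances across any treatment triple
(*second-order consistency*, equivalently the triangle inequality for the
$\tau_{kl}$) holds exactly when $\boldsymbol\Sigma$ is positive
semidefinite, and each of the four prior schemes below guarantees or
enforces this.

## The four heterogeneity prior schemes

**Approach 1 — common variance.** $\Sigma = \tau^2 P$ with $P_{kk} = 1$,
$P_{kl} = 1/2$; every comparison shares $\tau^2$. $P$ has eigenvalues
$(p+1)/2$ and $1/2$, so $\Sigma$ is always valid. The prior is either
$\tau \sim U(0, 2)$ (vague; the bound is on the SD scale, appropriate for
log odds ratios) or a catalogued log-normal on $\tau^2$.

**Approach 2 — proportional variances.**
$\tau^2 \sim \text{log-}N(0, s^2)$ and
$\tau_{kl}^2 = \tau^2 e^{m_{kl}}$, so every $\log\tau_{kl}^2$ has variance
$s^2$ and mean $m_{kl}$. `proportional_spec()` fills the offsets from the
comparison-type catalog and pools $s$ as the study-count-weighted average of
the catalogued SDs. The off-diagonals of $\Sigma$ are recovered by
inverting the contrast-variance identity; validity now depends on the
offsets, so the constructor checks positive semidefiniteness once (it is
scale-invariant in $\tau^2$) and the sampler gives zero mass to invalid
states of the vague variant. For the vague two-level pattern (offset 0
against the reference, a common sampled $m$ between active treatments)
the check has a closed form: $\Sigma/\tau^2$ is compound symmetric and is
valid iff $e^m \le 2 + 2/(p-1)$.

**Approach 3 — arm-based variances.** Latent arm effects give
$\tau_{kl}^2 = \tau_k^2 + \tau_l^2 - 2\rho_{kl}\tau_k\tau_l$ with a
between-arm correlation matrix $R$ written through its upper-triangular
Cholesky factor in spherical coordinates, $R = L^TL$: column $j$ of $L$
uses the angle cosines $c_{1j}, \dots, c_{(j-1)j}$ in that order. The
construction makes $R$ valid for any angles. Cosine priors
$c_{kl} \sim \mathrm{Beta}(a, b)$ are catalogued by network size
(`angle_prior()`); they keep the implied correlations near mean $0.5$,
variance $0.07$ — the moments of a $U(0,1)$ correlation conditioned on
validity, and the value $\rho = 0.5$ is exactly the common-variance model.
The published 3-treatment closed form fixes only the first column
ordering; for larger networks the angle-to-pair assignment is a
convention, and we use lexicographic order and document that derived
(non-first-row) correlations then have slightly different implied
distributions than first-row ones (see *Reporting choices* below).

**Approach 4 — scaled inverse Wishart.** $\Sigma^{-1} = M/\lambda$,
$M \sim \mathrm{Wishart}(S, t)$,
$\log\lambda \sim N(m_\lambda, s_\lambda^2)$. We pin the Wishart
convention by the marginal it must induce:
$\Sigma_{kk} \sim IG\big((t-p+1)/2,\ S_{kk}/2\big)$ at $\lambda = 1$ (the
rate convention of the BUGS family; in R this is
`rWishart(df = t, Sigma = solve(S))`). Using
$E[\log IG(a,b)] = \log b - \psi(a)$ and
$\mathrm{Var}[\log IG(a,b)] = \psi_1(a)$, matching
$\log\Sigma_{kk} \sim N(m_D, s_D^2)$ gives the closed form
$$m_\lambda = m_D - \log(S_{kk}/2) + \psi\!\big(\tfrac{t-p+1}{2}\big),
\qquad s_\lambda^2 = s_D^2 - \psi_1\!\big(\tfrac{t-p+1}{2}\big).$$
This also resolves the grouping of the $\log(S_{kk}/2)$ term: the
requirement $E[\log\Sigma_{kk}] = m_D$ admits only this form, and a unit
test asserts the self-consistency. $t = p+1$ is the smallest feasible
choice ($t = p$ would need $s_D^2 > \psi_1(1/2) = \pi^2/2$, larger than any
catalogued value; $t=p+1$ needs $s_D^2 > \pi^2/6 \approx 1.645$, satisfied
by all of them) and implies the least borrowing of heterogeneity
information across comparisons. $S_{kk} = 1$ (its scale is absorbed by
$m_\lambda$) and $S_{kl} = S_{kk}/2$, which makes the implied prior for a
non-reference contrast variance
$\Sigma_{kk}+\Sigma_{ll}-2\Sigma_{kl}$ identical to that of a reference
contrast — a property the acceptance suite verifies distributionally.

## Moment matching for the arm-based model

The catalog provides target priors for *contrast* variances,
$\tau^2_{kl} \sim \text{log-}N(m_D, s_D^2)$, while approach 3 needs priors
for *arm* variances. With $\tau_k^2, \tau_l^2$ iid log-normal$(m, s^2)$
independent of $\rho_{kl}$ (mean $m_\rho$, variance $s_\rho^2$), log-normal
moments $E[(\tau_k^2)^a] = e^{am + a^2s^2/2}$ give

$$E[\tau_{kl}^2] = 2e^m e^{s^2/4}\big(e^{s^2/4} - m_\rho\big),$$
$$\mathrm{Var}[\tau_{kl}^2] = 2e^{2m}e^{s^2}(e^{s^2}-1)
 + 4s_\rho^2 e^{2m}e^{s^2}
 + 4m_\rho^2 e^{2m}e^{s^2/2}(e^{s^2/2}-1)
 - 8 m_\rho e^{2m}e^{3s^2/4}(e^{s^2/2}-1).$$

The variance expression is derived in-package from first principles and is
checked against a large Monte-Carlo oracle in the test suite before the
solver that depends on it is trusted; only the first two moments of
$\rho_{kl}$ enter. `match_arm_prior()` then solves the two equations for
$(m, s)$ by a damped Newton iteration in $(m, \log s)$ coordinates
(unconstrained), starting at $(m_D - 0.5, \log s_D)$, declaring convergence
when both relative residuals fall below $10^{-10}$, and restarting from
jittered points (up to 5 times) on failure; non-convergence raises an error
carrying the residuals. The whole catalog solves in well under a second.
One caveat a user should know: the bundled second-column catalog reproduces
the solver's output to the printed two decimals for every outcome type
except all-cause mortality, where the exact solution $(-4.8361, 1.6960)$
sits a half-unit beyond the catalogued rounding; the catalog stores the
published decimals verbatim and the tests compare at one unit in the last
printed digit.

## The sampler

`nma_fit()` runs a seeded, component-wise adaptive random-walk
Metropolis-within-Gibbs sampler:

* $\mu_j$ — vectorized random-walk Metropolis across studies (each study's
  acceptance is independent given $\delta$);
* $\delta_{jbk}$ — vectorized random-walk updates for two-arm studies;
  multi-arm components are updated one at a time against their exact
  conditional prior given the study's other contrasts;
* $\mathbf d$ — drawn from its exact Gaussian full conditional
  ($\boldsymbol\delta_j$ are normal in $\mathbf d$ given $\Sigma$, and the
  prior is normal), which mixes far better than a random walk and is exact;
* heterogeneity parameters — component-wise random walks on transformed
  scales: $\log\tau^2$ for variances, the constrained SD scale for vague
  uniform variants, $\mathrm{logit}(c_{kl})$ for angle cosines, $\log$
  diagonal plus free off-diagonal entries of the Cholesky factor of $M$
  (with the appropriate Jacobians) and $\log\lambda$ for the scaled
  Wishart. Proposals landing outside a support, or producing a
  non-factorizable $\Sigma$, are rejected.

Step sizes adapt every 50 iterations towards an acceptance rate of 0.44,
during burn-in only, so the post-burn-in chain is a fixed Markov kernel.
Defaults are 4 chains of 100 000 sampling iterations after 20 000 burn-in
iterations; `iterations` always means *post-burn-in* draws. All randomness
derives from `mcmc_config(seed = )`: chain streams are drawn from the seed,
and identical configurations reproduce draws bit-for-bit.

Correctness is established three ways in the test suite: (i) on a
two-treatment toy posterior the sampled median of $d$ agrees with a fine
numeric integration of the same posterior (baselines and random effects
integrated on grids); (ii) with the likelihood switched off
(`prior_only = TRUE`, where $\mu$ and $\delta$ are then drawn exactly from
their conditionals) the marginal $\tau_{kl}$ draws reproduce the forward
Monte-Carlo prior for both the common and arm-based structures; (iii)
simulated 40-study networks recover their generating basic parameters
within two posterior SDs at the nominal rate. Convergence is summarized by
split-$\widehat R$ (flagged above 1.01) and an
initial-positive-sequence effective sample size; `convergence()` reports
both, and one test cross-checks $\widehat R$ against an independent
implementation.

## Prior Monte Carlo and reporting choices

`prior_monte_carlo()` forward-samples only the heterogeneity block and
reports, per comparison, quantiles of $\tau_{kl}$ and the Pearson
correlation matrix of $\log\tau_{kl}^2$. Two reporting conventions are
worth stating explicitly, because the spherical parameterization makes
pairs non-exchangeable in the tail ordering:

* *Correlations.* A single "shared-treatment" correlation is reported as
  the average over all comparison pairs sharing a treatment (and likewise
  for disjoint pairs). Under approach 3 with four treatments the
  individual shared-pair correlations span roughly 0.37–0.39; the average
  is the single-number summary the package reports.
* *Implied medians.* Under vague arm-based priors the implied
  $\tau_{kl}$ prior differs slightly by pair position (first-row pairs are
  widest); the package reports pooled quantiles across all comparisons,
  which for the 8-treatment vague configuration reproduces the
  published-style summary (median ≈ 1.21, 95% range ≈ 0.25–2.08, as the
  acceptance suite recomputes).

For the vague proportional variant, forward draws are conditioned on the
positive-semidefinite region, matching the sampler's rejection rule, so
prior and posterior refer to the same distribution.

## The synthetic-data generator

`simulate_network()` draws data from exactly the model above: study
baselines $\mu_j \sim N(\mathrm{logit}(0.3), 0.5^2)$ by default (the model
treats baselines as unrelated fixed effects, so any dispersed choice is
valid; the default centres event risks near 30% with realistic spread),
contrast vectors from the re-based $N(\mathbf d, \boldsymbol\Sigma)$
restriction, and binomial counts at a configurable per-arm size. It
returns the generating truth alongside the data for recovery tests, and is
deterministic given a seed. What it deliberately does **not** emulate:
baseline risk related to treatment effects, non-exchangeable or skewed
random effects, inconsistency between direct and indirect evidence, or
outcome misclassification — so passing recovery tests demonstrate internal
correctness of the fitting machinery, not robustness of the model on messy
real data.

The bundled prostate-cancer fixture (17 two-arm trials, 8 treatments) is
shipped as plain CSV with pinned checksums; observational management is
encoded as a control-type treatment and the rest as nonpharmacological,
which is what selects the bundled comparison-type priors for that context.
The smoking-cessation example ships as a design skeleton only (treatments,
per-comparison study counts, the two three-arm trials); its outcome counts
are not bundled and must be supplied by the user.

## Numerical choices and problem sizes

* Positive semidefiniteness: symmetric eigendecomposition with relative
  tolerance $-10^{-8}$ (strictness would reject boundary cases created by
  rounding); the sampler uses Cholesky failure as its rejection criterion.
* Quantiles: type 7 (linear interpolation of order statistics) everywhere,
  because published-style two-decimal intervals are sensitive to the
  convention.
* Solver: relative residuals $< 10^{-10}$; catalog values are stored as the
  exact printed decimals and never re-rounded.
* Degenerate inputs: $r = 0$ and $r = n$ arms are accepted (the binomial
  likelihood needs no continuity correction); $\tau^2 = 0$ yields the
  zero matrix, which is handled by the pseudo-inverse path of the
  conditional factorization.
* Test problem sizes were chosen to keep the full suite near five minutes:
  prior Monte-Carlo checks use $10^6$ draws where a published correlation
  or median is asserted and $2\times10^5$ for internal consistency checks;
  the bundled-network fits in the acceptance tests use 4 chains × 30 000
  iterations (the acceptance *script* uses the full 4 × 100 000 after
  20 000 burn-in); recovery uses 20 seeded replicates of 40-study
  networks.

## Known limitations

* Inconsistency models, network meta-regression, exchangeable-variance
  models, rank probabilities and truncated priors are out of scope.
* Approach 2 with arbitrary offset patterns can be invalid for larger
  networks; the package checks and refuses rather than silently fitting.
* Approach 4 cannot target *different* priors for different comparisons
  (one matched distribution applies across the network), and approach 3
  deliberately borrows almost no heterogeneity information across
  comparisons, so comparisons with little data lean on the prior.
* The catalogued angle priors cover 4–10 treatments; a 3-treatment network
  needs a user-supplied Beta prior for its single derived angle (a
  moment-matched choice near Beta(0.93, 0.93) keeps the implied
  correlation moments at (0.5, 0.07), but no catalogued value exists).
* The sampler is a general-purpose random-walk scheme; for very large
  networks the arm-based and Wishart blocks update one component at a
  time and will be slower per effective draw than specialized samplers.
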