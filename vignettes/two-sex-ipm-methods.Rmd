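---
title: "Methods: a two-sex integrated population model for long-term raptor monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-sex integrated population model for long-term raptor monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hawkipm)
```

## The population model

`hawkipm` implements a pre-breeding-census, two-sex, stage-structured
stochastic population model for a territorial raptor such as the goshawk
(*Accipiter gentilis*), monitored annually over decades.  Each sex is
divided into stages: 1-year-old non-breeders and breeders (stages 1, 2),
2-year-old non-breeders and breeders (stages 3, 4), and breeders aged 3 or
more (stage 5); males have an additional stage 6 holding the current year's
immigrant breeders, who are assumed to arrive as 3y+ breeders and join
stage 5 thereafter.  All individuals aged 3+ are assumed to breed, and
immigration is male-only (female immigration into a large study area of
this kind is typically negligible, and a female-immigration variant is out
of scope here).

Writing $N_{a,s,t}$ for the abundance of stage $a$, sex $s$ in year $t$,
the female transitions are

$$
\begin{aligned}
N_{1,f,t+1} &\sim \text{Poisson}\big(F_{f,t}\, s_{1,f,t}\, (1-\alpha_{1,f,t+1})\big)\\
N_{2,f,t+1} &\sim \text{Poisson}\big(F_{f,t}\, s_{1,f,t}\, \alpha_{1,f,t+1}\big)\\
N_{3,f,t+1} &\sim \text{Binomial}\big(N_{1,f,t},\, s_{2,f,t}(1-\alpha_{2,f,t+1})\big)\\
N_{4,f,t+1} &\sim \text{Binomial}\big(N_{1,f,t},\, s_{2,f,t}\alpha_{2,f,t+1}\big)
  + \text{Binomial}\big(N_{2,f,t},\, s_{2,f,t}\big)\\
N_{5,f,t+1} &\sim \text{Binomial}\big(N_{3,f,t}+N_{4,f,t}+N_{5,f,t},\, s_{3,f,t}\big)
\end{aligned}
$$

with female fledgling production
$F_{f,t} = \sum_{a} N_{b(a),f,t}\,\eta_{a,t}\,\rho_{a,t}\,\xi_{a,t}$ summed
over the three breeding female classes $b(a) \in \{2, 4, 5\}$.  Males are
analogous with $1-\xi$ in place of $\xi$, the immigrant stage pooled into
the adult survival pool
($N_{5,m,t+1} \sim \text{Binomial}(N_{3}+N_{4}+N_{5}+N_{6},\, s_{3,m,t})$),
and $N_{6,m,t+1} \sim \text{Poisson}(\omega_{t+1})$.

The parameters are: age- and sex-specific annual survival $s_{a,s,t}$
(ages 1, 2, 3+), maternal-age-specific breeding success $\eta_{a,t}$
(probability a brood fledges at least one young), productivity $\rho_{a,t}$
(mean fledglings per successful brood), fledgling sex ratio $\xi_{a,t}$
(proportion female), sex- and age-specific recruitment $\alpha_{a,s,t}$
(probability of first breeding at ages 1 and 2; recruitment at the arrival
year is indexed $t+1$, so the projection carries a one-step lookahead), and
the expected number of male immigrants $\omega_t$.

Two modelling points deserve emphasis:

* **Stage indexing.** Stage 3 is the 2-year-old non-breeder and stage 4 the
  2-year-old breeder; descriptions that label stage 4 as "3 years old"
  conflict with the transition structure above, which is authoritative
  here.
* **Conserving stochastic splits.** The two binomial draws out of stage 1
  (recruit vs. not) are generated in the simulator as a multinomial
  "survive, then recruit" split, so survivors can never exceed the source
  pool; the margins are exactly the binomials above.  The fitted likelihood
  keeps the two binomial nodes, matching the printed model.

### Productivity parameterization

$\rho$ is defined as the *mean* number of fledglings of a successful brood,
because that is the quantity that multiplies through the projection and
yields the interpretable composite $\eta_a \rho_a$ = fledglings per
initiated brood.  A successful brood has at least one fledgling, so its
size is modelled as a zero-truncated Poisson.  A truncated Poisson with
rate $\lambda$ has mean $\lambda/(1-e^{-\lambda}) > \lambda$, so rate and
mean must not be conflated: the simulator draws brood sizes with the rate
solved numerically so that the mean equals $\rho$, and the Bayesian model
parameterizes the annual rate $\lambda_{a,t}$ (identity link) and derives
$\rho_{a,t} = \lambda_{a,t}/(1-e^{-\lambda_{a,t}})$ for the projection.
`loglik_productivity()` exposes both conventions
(`parameterization = "mean"` is the internally consistent default; `"rate"`
treats $\rho$ directly as the truncated-Poisson rate).  The temporal random
effect sits on the mean in the simulator and on the rate in the fitted
model; the map between the two scales is monotone with slope ≈ 0.9 at the
default values, so the difference is far below the resolution of the data.

### Temporal random effects

Every demographic and observation rate carries independent annual random
effects on a link scale: logit for probabilities, identity for
productivity, log for immigration, i.e.
$g(\theta_t) \sim \text{Normal}(\mu_\theta, \sigma_\theta^2)$.  Link-scale
values are clamped to $(-20, 20)$ before back-transformation (probabilities
of exactly 0 or 1 are representable in direct simulation but have no
finite link value), drawn productivity means are floored just above 1, and
the log-scale immigration mean is capped in the sampler to keep the Poisson
mean finite during burn-in.

## The seven data sets and the joint likelihood

The observation layer mirrors a real territory-monitoring programme:
occupied territories are counted annually; moulted feathers collected at
nests identify individual breeders (with sex and age class 1 / 2 / 3+);
broods are followed for success, fledgling counts and fledgling sex; and
ringed nestlings are reported dead by the public.  The seven data sets and
their likelihood components are:

1. **Territory counts** — Poisson observation of the true number of
   breeding pairs (breeding females, stages 2 + 4 + 5).  The count survey
   is nearly a census, and a Poisson census with optional exact-count or
   normal alternatives (switchable) is the standard state-space choice.
2. **Sex- and age-specific breeder counts** — binomial thinning of the true
   class sizes with the sex- and year-specific resighting probability
   $p_{s,t}$, shared with the capture-recapture component because both
   derive from the same feather collection.
3. **Brood success** — Bernoulli($\eta_{a,t}$) per brood.
4. **Fledgling counts of successful broods** — zero-truncated Poisson (see
   above).
5. **Brood sex composition** — Binomial($\xi_{a,t}$) over sexed fledglings;
   partial sexing is allowed.
6. **Adult capture-recapture** — Cormack-Jolly-Seber likelihood conditioned
   on first identification, with the age class advancing along the history
   (a 1-y bird survives its first interval with $s_2$, older birds with
   $s_3$) and sex/year-specific $p$.  First-year survival never enters the
   CJS: breeders are aged 1+.
7. **Dead recoveries of ringed nestlings** — Seber-style recovery
   likelihood: death in interval $k$ with the age-appropriate survival
   chain ($s_1$, then $s_2$, then $s_3$), reported with sex- and
   year-specific $r$; never-recovered birds contribute the complementary
   probability.  Recoveries are what identify first-year survival, and as
   true survival (emigration does not masquerade as death).

The joint likelihood is the product of the seven components with the
latent state-space transition densities.  Every component is implemented
twice on purpose: as a pure R function tested against enumeration oracles
(all outcome probabilities summing to one on small instances, closed-form
spot values, per-individual vs m-array agreement), and inside the JAGS
model used for inference.  Impossible data under a latent state return
$-\infty$, never an error, so samplers can reject.

## Bayesian inference

`fit_ipm()` fits the joint model with JAGS.  Capture-recapture and
recovery data enter as multinomial m-arrays (the age-2 and age-3+ release
classes have identical cell probabilities and are pooled exactly); brood
data are aggregated to (year, age-class) binomial and sufficient-statistic
cells; the zero-truncated Poisson uses the standard zeros trick.  Latent
abundances are sampled as discrete Poisson/binomial nodes — pair counts of
30-70 are far too small for a normal approximation.

Priors are vague and deliberately simple: logistic(0, 1) on logit-scale
means (uniform on the probability scale, which also makes single-component
reductions exactly conjugate-checkable), Normal(0, 10) on the identity-link
productivity rate, Normal(0, sd ≈ 3.2) on the log immigration mean (vague
over 0.04-25 immigrants/year while keeping burn-in excursions finite),
Uniform(0, 10) on all temporal SDs, and a discrete uniform on the initial
stage abundances over 0 to three times the first territory count.

The default `ipm_config()` is desk-scale (2 chains x 4000 iterations,
burn-in 1500, thinning 5), sized for simulation experiments;
`ipm_config_paper()` is the production configuration (3 chains x 110,000,
burn-in 10,000, thinning 50, posterior sample 6000).  Convergence is
reported as split R-hat per monitored scalar with a warning above 1.05;
the immigration mean is the slowest-mixing parameter (it is informed only
through the male breeder-count surplus) and generally needs the long
configuration for R-hat < 1.05.

Estimands in simulation experiments are the *realized temporal means* of
the annual rates (e.g. $\overline{s}_{1,f} = \tfrac1T\sum_t s_{1,f,t}$),
not the hyperparameter $\mu$: over a finite study window the data identify
the realized history, and the posterior of the temporal mean is the
matched comparison for the generator's realized truth.

## The synthetic monitoring study

`simulate_individuals()` is an individual-based realization of the model:
every bird carries sex, cohort, survival outcomes, recruitment year and
per-year brood outcomes, so aggregation reproduces a stage-structured
trajectory exactly (this is tested).  `observe()` thins it into the seven
data sets.  The default `goshawk_hyper()` preset emulates the study
system: 47 annual occasions, ~40 initial pairs fluctuating between roughly
30 and 70, male-biased fledgling sex ratio weakening with maternal age
(overall proportion of females ≈ 0.46), female first-year survival above
male, productivity increasing with maternal age
($\eta_a\rho_a \approx 1.16,\ 1.80,\ 2.10$ fledglings per initiated
brood), earlier female recruitment, and moderate male immigration (~3
males/year, ≈ 8% of male breeders).  First-year survival means (0.30
female, 0.23 male) were calibrated once so that the deterministic two-sex
model with immigration is near-stationary at ~45 pairs; stochastic
half-century runs then show a CV of pair counts around 20%, matching the
magnitude of fluctuation such populations display.  Temporal SDs put most
environmental variation into first-year survival and breeding success, the
rates that drive dynamics in this system.  Observation defaults: breeder
resighting 0.65 (females) / 0.45 (males), recovery probability 0.11 for
both sexes (a 47-year run rings roughly 2,000-4,500 nestlings and recovers
roughly 300-500), 75% of fledglings ringed, all broods recorded, Poisson
territory-count noise (exact census switchable).

What the generator does *not* emulate: feather misidentification,
individual heterogeneity beyond age/sex/stage (territory quality,
senescence), within-season structure, spatial variation in recovery
probability, and non-independence between the breeder-count and
capture-recapture data streams beyond their shared $p$ (in both the
generator and the model the two components use the same detection events,
mirroring the practice of treating them as independent likelihood terms).
Passing tests therefore demonstrate self-consistency of model and
inference under these idealizations, not robustness to the structured
heterogeneity of real data.

## Prospective and retrospective analyses

The realized growth rate is written as
$\lambda(\theta, n, N) = \sum_i n_i\, c_i(\theta) + \omega/N$ over the 11
relative stage abundances $n_i$ (all individuals aged 1+), where the
per-capita contribution $c_i$ of a breeding female class adds
$\eta_a \rho_a (\xi_a s_{1,f} + (1-\xi_a) s_{1,m})$ fledglings surviving
to the next census on top of her own survival, and every other class
contributes survival only.  Recruitment moves individuals between breeder
and non-breeder classes without changing the total, so it carries no
direct sensitivity and is excluded from the elasticity/LTRE component set.

* **Transient elasticities** are evaluated analytically at the temporal
  means of rates and structure, per posterior draw.  For structure
  components the realized-structure convention is used: the elasticity of
  $n_i$ is $n_i (c_i - \lambda)/\lambda$, so classes whose per-capita
  contribution exceeds the current growth rate (breeding females) come out
  positive and below-average classes (males, non-breeding females) come
  out negative.  A finite-difference oracle through the expected one-step
  projection verifies every component to $10^{-3}$ relative error.
* **Transient LTRE**: $\text{var}(\lambda_t)$ is decomposed to first order
  as $\sum_{ij} S_i S_j \text{cov}(x_{i}, x_{j})$ over the annual series of
  the 16 rates, the 11 structure proportions and the total size (whose
  only effect is through $\omega/N$), with sensitivities at temporal means
  and covariances over years, per draw.  Contributions are reported
  relative to the summed total; the rates aggregate (direct effects) and
  the structure aggregate (delayed effects) add to one.  Individual
  relative contributions can be slightly negative when covariances are
  negative — that is a property of first-order LTREs, not an error.  On
  low-variation expected-mode simulations the first-order total matches
  the realized variance within 10%.
* **Environmental vs demographic stochasticity**: per draw, the expected
  (demographic-noise-free) trajectory is propagated from the realized
  starting state under the realized annual rates; its growth rates isolate
  the environmental component and the log-scale residual is the
  demographic component.  The environmental share is the variance fraction
  of the environmental component.  With constant rates this share
  collapses towards zero (up to the initial transient of the stage
  structure, which is attributed to the environmental side by
  construction); with a deterministic trajectory as "actual" the
  demographic share is exactly zero.

## Density dependence

The population-level test is a Dennis-Taper style regression calibrated
against a simulated null.  `dd_slope()` supports two conventions that
differ by exactly 1: levels (log $N_{t+1}$ on log $N_t$; no feedback gives
≈ 1) and growth (log $\lambda_t$ on log $N_t$; no feedback gives ≈ 0).
The growth convention is the default and the one in which reported values
like an observed slope of about −0.2 against a null of about −0.1 are
interpretable.  Because the same noise enters both regression variables,
the null slope is biased negative even without feedback; `dd_test()`
therefore compares the posterior of the observed slope (computed per draw
from the latent female trajectory) against slopes of matched
density-independent replicates simulated from each draw's own
hyperparameters (same length, same starting state, fitted process noise,
one replicate per draw), reporting $P(b_{obs} < b_{null})$.

`fit_ipm_dd()` fits the mechanistic variant: the link-scale mean of any
selected rate becomes $\mu_\theta + \beta_\theta Z_t$ with $Z_t$ the
standardized total number of females.  Applied literally to the
arrival-year-indexed rates this would be circular ($\alpha_{t+1}$ and
$N_{t+1}$ determine each other), so recruitment and immigration respond to
the female total of the year the transition starts from; all other rates
use their own year.  $Z_t$ is centered and scaled with constants (by
default the mean and SD of the territory counts) rather than
posterior-dependent quantities, for a well-defined model;
$\beta$ is reported on the standardized scale (divide by the scale
constant for the per-female slope) and `dd_beta_summary()` tabulates which
95% CRIs exclude zero.  Density dependence on immigration is not offered:
without a mechanism for how immigrants respond to local density, such a
link is not interpretable.

## Numerical choices and limitations

* Problem sizes: simulation experiments in the test-suite use 20-year
  studies of ~40 pairs with 2-chain desk MCMC and 8 replicate fits for
  parameter-recovery coverage; the density-dependence calibration uses 100
  replicate trajectory-level experiments with 100 nulls each; Monte-Carlo
  projection checks use $10^5$ draws.  The end-to-end acceptance run fits
  the full 47-year study at a reduced chain length (2 x 2600); its R-hat
  warning for the slow immigration parameter is expected at that length.
* The convolution in the stage-4 transition density is evaluated exactly;
  all discrete pmfs are used directly (no normal approximations), because
  pair counts are small.
* Ties in posterior-predictive p-values count 1/2.  The Freeman-Tukey
  discrepancy is used for all components.
* `dd_test()` excludes draw pairs whose null replicate went extinct; with
  the near-stationary preset this is rare.
* Known limitations: no mating function (male immigration is not
  identifiable jointly with one), no senescence or territory-quality
  heterogeneity, no misidentification, recovery probability assumed
  spatially homogeneous.  These match the scope of the monitoring design
  the package targets.
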