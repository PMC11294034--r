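# hawkipm

Two-sex integrated population models (IPMs) for long-term raptor
monitoring.

## The problem

Territorial raptors such as the goshawk (*Accipiter gentilis*) are
monitored for decades by checking nesting territories, collecting moulted
feathers that identify individual breeders, following broods, and ringing
nestlings that are later reported dead by the public.  Each of these data
streams alone gives a partial, noisy view of the population.  An
integrated population model analyzes them jointly through a shared
stage-structured population process, yielding coherent estimates of
survival, recruitment, productivity, fledgling sex ratio, immigration and
stage-specific population sizes — and, from those, answers to the
questions such monitoring programmes are run for: what drives the
population's ups and downs, do the sexes contribute differently, and is
the population density-regulated?

`hawkipm` is for quantitative population ecologists who want a tested,
reusable implementation of this analysis: an individual-based simulator of
the whole monitoring process with known truth, the seven component
likelihoods, the joint Bayesian fit, and the downstream population
analyses.

## The model

The core is a pre-breeding-census, two-sex stochastic projection with
stages {1y non-breeder, 1y breeder, 2y non-breeder, 2y breeder, 3y+
breeder} for each sex plus an immigrant-breeder stage for males.  With
female fledgling production
F_f,t = Σ_a N_breeder(a),t · η_a,t · ρ_a,t · ξ_a,t,

    N1,f,t+1 ~ Poisson(F_f,t · s1,f,t · (1 − α1,f,t+1))
    N2,f,t+1 ~ Poisson(F_f,t · s1,f,t · α1,f,t+1)
    N3,f,t+1 ~ Binomial(N1,f,t, s2,f,t (1 − α2,f,t+1))
    N4,f,t+1 ~ Binomial(N1,f,t, s2,f,t α2,f,t+1) + Binomial(N2,f,t, s2,f,t)
    N5,f,t+1 ~ Binomial(N3,f,t + N4,f,t + N5,f,t, s3,f,t)

and analogously for males (with 1 − ξ, the immigrant stage pooled into
adult survival, and N6,m,t+1 ~ Poisson(ω_t+1)).  Every rate carries
temporal random effects on its link scale (logit for probabilities,
identity for productivity, log for immigration).  The joint likelihood
combines seven data sets: territory counts (Poisson census), sex- and
age-specific breeder counts (binomial thinning), brood success
(Bernoulli), fledgling counts of successful broods (zero-truncated
Poisson), brood sex ratios (binomial), adult capture–recapture
(age-structured Cormack–Jolly–Seber) and dead recoveries of ringed
nestlings (Seber-style, the component that identifies first-year
survival).  Fitting is MCMC via JAGS; the analyses are transient
elasticities, a transient LTRE (variance decomposition of the realized
growth rate), an environmental-vs-demographic stochasticity split, and
Dennis–Taper-style density-dependence tests with a simulated
exponential-growth null.  The methods vignette
(`vignettes/two-sex-ipm-methods.Rmd`) documents every formula and design
choice.

## A worked example

```r
library(hawkipm)

# simulate a 20-year goshawk-like monitoring study with known truth
sim <- simulate_goshawk(years = 20, seed = 5)
print(sim$data)
#> Monitoring data over 20 years
#>   territory counts:    20 years, mean 28
#>   identified breeders: 758 breeder-years
#>   broods (success):    564
#>   successful broods:   444
#>   sexed broods:        444
#>   CR histories:        271 individuals
#>   ringed nestlings:    797 ( 73 recovered )

# fit the integrated model (desk-scale MCMC, ~1 min)
fit <- fit_ipm(sim$data, ipm_config(seed = 3))
round(coef(fit)[c("s1_f", "s1_m", "eta_3", "xi_3", "omega")], 3)
#>  s1_f  s1_m eta_3  xi_3 omega
#> 0.234 0.195 0.812 0.485 1.113

# is female first-year survival higher than male?
prob_greater(rate_mean_draws(fit, "s", 1, "f"),
             rate_mean_draws(fit, "s", 1, "m"))
#> [1] 0.448

# population analyses
transient_elasticities(fit)        # prospective: what would move lambda
ltre_contributions(fit)            # retrospective: what did move lambda
stochasticity_decomposition(fit)   # environment vs demographic chance
dd_test(fit)                       # density dependence vs simulated null
```

In this run the generator's realized temporal means were first-year
survival 0.283 (f) / 0.256 (m), adult breeding success 0.842, adult
fledgling sex ratio 0.456 and mean immigration 3.4 males/year: the
posterior means above sit within their (wide) credible intervals, the
sex difference in first-year survival is not resolvable from 20 years of
data at this detection effort (P(f > m) = 0.45), and immigration is the
least precise parameter because it is informed only through the male
breeder-count surplus.  The half-century acceptance run below shows the
same machinery at full study length.

A command-line pipeline over the same functions is installed at
`inst/cli/hawkipm.R` (`simulate`, `fit`, `analyze` subcommands).

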