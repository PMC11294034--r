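# Shared fixtures.  Everything is generated in code; the one moderately
# expensive JAGS fit is cached and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

# empty component tables, for assembling small monitoring_data objects
empty_broods <- function() {
  list(
    brood_success = data.frame(year = integer(0), age_class = integer(0),
                               success = integer(0)),
    brood_fledglings = data.frame(year = integer(0), age_class = integer(0),
                                  count = integer(0)),
    brood_sex = data.frame(year = integer(0), age_class = integer(0),
                           n_female = integer(0), n_male = integer(0)),
    adult_cr = list(history = matrix(0L, 0, 0), sex = character(0),
                    age_first = integer(0), id = integer(0)),
    recoveries = data.frame(id = integer(0), sex = character(0),
                            ring_year = integer(0),
                            recovery_year = integer(0)))
}

tiny_monitoring_data <- function(years = 2, counts = rep(5L, years),
                                 brood_success = NULL) {
  e <- empty_broods()
  e$adult_cr$history <- matrix(0L, 0, years)
  if (!is.null(brood_success)) e$brood_success <- brood_success
  monitoring_data(years = years, territory_counts = counts,
                  breeder_counts = array(0L, c(years, 2, 3)),
                  brood_success = e$brood_success,
                  brood_fledglings = e$brood_fledglings,
                  brood_sex = e$brood_sex, adult_cr = e$adult_cr,
                  recoveries = e$recoveries)
}

# rates with every block constant at given values (no temporal variation)
flat_hyper <- function(s = matrix(0.5, 3, 2), eta = rep(0.5, 3),
                       rho = rep(2, 3), xi = rep(0.5, 3),
                       alpha = matrix(0.5, 2, 2), omega = 0,
                       p = c(0.5, 0.5), r = c(0.1, 0.1)) {
  ipm_hyper(list(s = s, eta = eta, rho = rho, xi = xi, alpha = alpha,
                 omega = omega, p = p, r = r))
}

# one cached moderate JAGS fit on 14 years of goshawk-like data, shared by
# the method/ppc/density tests
cached_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  sim <- simulate_goshawk(14, seed = 401)
  fit <- fit_ipm(sim$data, ipm_config(seed = 11, n_chains = 2,
                                      n_iter = 1800, n_burnin = 600,
                                      thin = 3))
  .fixture_env$sim <- sim
  .fixture_env$fit <- fit
  fit
}

cached_sim <- function() {
  cached_fit()
  .fixture_env$sim
}

# finite-difference elasticities through the expected one-step projection —
# an oracle independent of the analytic gradient used by the package
fd_elasticities <- function(v, n, Ntot, hrel = 1e-4) {
  state_from <- function(nn, tot) {
    out <- matrix(0, 6, 2, dimnames = list(hawkipm:::.STAGES,
                                           c("f", "m")))
    out[1:5, 1] <- nn[1:5] * tot
    out[, 2] <- nn[6:11] * tot
    out
  }
  rates_from <- function(v) {
    list(s = matrix(v[c("s1_f", "s2_f", "s3_f", "s1_m", "s2_m", "s3_m")],
                    3, 2, dimnames = list(NULL, c("f", "m"))),
         eta = unname(v[paste0("eta_", 1:3)]),
         rho = unname(v[paste0("rho_", 1:3)]),
         xi = unname(v[paste0("xi_", 1:3)]),
         alpha = matrix(0.3, 2, 2, dimnames = list(NULL, c("f", "m"))),
         omega = unname(v["omega"]))
  }
  lam_of <- function(v, n, tot) {
    st <- state_from(n, tot)
    r <- rates_from(v)
    nx <- expected_next_state(st, r, r)
    sum(nx) / sum(st)
  }
  lam0 <- lam_of(v, n, Ntot)
  er <- sapply(names(v), function(nm) {
    v1 <- v; v2 <- v
    v1[nm] <- v1[nm] * (1 + hrel); v2[nm] <- v2[nm] * (1 - hrel)
    (lam_of(v1, n, Ntot) - lam_of(v2, n, Ntot)) / (2 * hrel * lam0)
  })
  es <- sapply(seq_along(n), function(i) {
    n1 <- n; n2 <- n
    n1[i] <- n1[i] * (1 + hrel); n2[i] <- n2[i] * (1 - hrel)
    # raw perturbation of one stage abundance changes the total too
    (lam_of(v, n1, Ntot) - lam_of(v, n2, Ntot)) / (2 * hrel * lam0)
  })
  list(rates = er, structure = es, lambda = lam0)
}

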