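test_that("analytic elasticities agree with finite differences", {
  tr <- project_trajectory(goshawk_initial_state(), goshawk_hyper(), 30,
                           seed = 301)
  el <- transient_elasticities(tr)
  ctx <- hawkipm:::.analysis_contexts(tr)[[1]]
  cm <- hawkipm:::.context_means(ctx)
  fd <- fd_elasticities(cm$v, cm$n, cm$Ntot)
  for (nm in hawkipm:::.RATE_NAMES) {
    got <- el$mean[el$component == nm]
    want <- unname(fd$rates[nm])
    if (abs(want) > 1e-8)
      expect_lt(abs(got - want) / abs(want), 1e-3)
    else expect_lt(abs(got - want), 1e-8)
  }
  for (i in seq_along(hawkipm:::.STRUCT_NAMES)) {
    nm <- hawkipm:::.STRUCT_NAMES[i]
    got <- el$mean[el$component == nm]
    want <- unname(fd$structure[i])
    if (abs(want) > 1e-8)
      expect_lt(abs(got - want) / abs(want), 1e-3)
    else expect_lt(abs(got - want), 1e-6)
  }
})

test_that("closed-form single-stage reduction: e(s) = s / (s + f)", {
  # all abundance in adult breeding females, all-female offspring:
  # lambda = s3f + eta3 * rho3 * s1f
  v <- stats::setNames(rep(0, 16), hawkipm:::.RATE_NAMES)
  v["s3_f"] <- 0.8; v["s1_f"] <- 0.4
  v["eta_3"] <- 0.9; v["rho_3"] <- 2; v[paste0("xi_", 1:3)] <- 1
  v[c("eta_1", "eta_2")] <- 0; v[c("rho_1", "rho_2")] <- 0
  n <- c(0, 0, 0, 0, 1, rep(0, 6))
  gr <- hawkipm:::.lambda_grad(v, n, 100)
  f <- 0.9 * 2 * 0.4
  lam <- 0.8 + f
  expect_equal(gr$lambda, lam, tolerance = 1e-12)
  expect_equal(unname(v["s3_f"] * gr$rates["s3_f"] / lam), 0.8 / lam,
               tolerance = 1e-12)
})

test_that("a rate absent from every transition has elasticity zero", {
  # no immigration: omega elasticity is exactly 0
  m <- hyper_means(goshawk_hyper()); m$omega <- 0
  tr <- project_trajectory(goshawk_initial_state(), ipm_hyper(m), 12,
                           mode = "expected", seed = 1)
  el <- transient_elasticities(tr)
  expect_equal(el$mean[el$component == "omega"], 0)
  # recruitment does not enter the realized growth rate at all
  expect_false(any(grepl("alpha", el$component)))
})

test_that("LTRE contributions normalize and match first-order variance", {
  h <- goshawk_hyper()
  # small temporal variation so the first-order expansion is accurate;
  # expected mode removes demographic noise
  for (nm in names(h$sigma)) h$sigma[[nm]][] <- 0.06
  tr <- project_trajectory(goshawk_initial_state(), h, 47,
                           mode = "expected", seed = 302)
  lt <- ltre_contributions(tr)
  expect_equal(sum(lt$contributions$mean), 1, tolerance = 1e-9)
  ag <- lt$aggregates
  expect_equal(ag$mean[ag$component == "rates_share"] +
                 ag$mean[ag$component == "structure_share"], 1,
               tolerance = 1e-9)
  v1 <- ag$mean[ag$component == "var_firstorder"]
  v2 <- ag$mean[ag$component == "var_realized"]
  expect_lt(abs(v1 - v2) / v2, 0.10)
})

test_that("a rate with no temporal variation contributes nothing", {
  h <- goshawk_hyper()
  for (nm in names(h$sigma)) h$sigma[[nm]][] <- 0.10
  h$sigma$xi[] <- 0           # freeze the fledgling sex ratio
  tr <- project_trajectory(goshawk_initial_state(), h, 40,
                           mode = "expected", seed = 303)
  lt <- ltre_contributions(tr)
  xi_rows <- grepl("^xi_", lt$contributions$component)
  expect_true(all(abs(lt$contributions$mean[xi_rows]) < 1e-10))
})

test_that("contribution aggregates are stable under rate relabeling", {
  tr <- project_trajectory(goshawk_initial_state(), goshawk_hyper(), 30,
                           seed = 304)
  lt <- ltre_contributions(tr)
  # permuting the report rows cannot change the aggregate shares
  perm <- lt$contributions[sample(nrow(lt$contributions)), ]
  expect_equal(sum(perm$mean[perm$type == "rate"]),
               lt$aggregates$mean[lt$aggregates$component == "rates_share"],
               tolerance = 1e-9)
})

test_that("stochasticity decomposition honours its limiting cases", {
  # expected projection as "actual": no demographic residual at all
  h <- goshawk_hyper()
  tr <- project_trajectory(goshawk_initial_state(), h, 30,
                           mode = "expected", seed = 305)
  sd0 <- stochasticity_decomposition(tr)
  expect_equal(sd0$mean[sd0$component == "dem_share"], 0, tolerance = 1e-9)
  expect_equal(sd0$mean[sd0$component == "env_share"], 1, tolerance = 1e-9)
  # shares sum to one
  expect_equal(sd0$mean[sd0$component == "env_share"] +
                 sd0$mean[sd0$component == "dem_share"], 1)

  # no environmental variation: the environmental share collapses
  h0 <- ipm_hyper(hyper_means(h))  # sigma = 0
  # start at the deterministic stage structure so transients are negligible
  warm <- project_trajectory(goshawk_initial_state(), h0, 40,
                             mode = "expected", seed = 1)
  init0 <- ipm_state(round(warm$N[1:5, 1, 40]), round(warm$N[, 2, 40]))
  set.seed(306)
  shares <- replicate(8, {
    trs <- project_trajectory(init0, h0, 40)
    s <- stochasticity_decomposition(trs)
    s$mean[s$component == "env_share"]
  })
  expect_lt(mean(shares), 0.15)
})

test_that("derived summaries match a hand-computed toy trajectory", {
  rates <- mean_rates(flat_hyper(eta = rep(1, 3), rho = rep(2, 3),
                                 xi = rep(0.5, 3)), 3)
  N <- array(0, c(6, 2, 3))
  N[, 1, 1] <- c(2, 1, 1, 1, 5, 0); N[, 2, 1] <- c(2, 1, 1, 1, 5, 0)
  N[, 1, 2] <- c(2, 1, 1, 1, 5, 0) * 2; N[, 2, 2] <- c(2, 1, 1, 1, 5, 0) * 2
  N[, 1, 3] <- c(2, 1, 1, 1, 5, 0); N[, 2, 3] <- c(2, 1, 1, 1, 5, 0)
  tr <- structure(list(N = N, recruits2y = matrix(0, 2, 3),
                       rates = rates, years = 3),
                  class = "ipm_trajectory")
  ds <- derived_summaries(tr)
  g <- function(nm) ds$mean[ds$component == nm]
  expect_equal(g("lambda_geomean"), 1, tolerance = 1e-12)   # 20 -> 40 -> 20
  expect_equal(g("pct_change"), 0)
  # eta = 1, rho = 2: two fledglings per initiated brood in every class
  expect_equal(g("fledglings_per_brood_age1"), 2)
  expect_equal(g("fledglings_per_brood_age3"), 2)
  expect_equal(g("adult_sex_ratio_m"), 0.5)
  expect_equal(g("prop_female_fledglings"), 0.5)
  # pairs 7, 14, 7: cv = sd/mean
  pairs <- c(7, 14, 7) * 1  # female stages 2+4+5
  expect_equal(g("cv_pairs"), 100 * sd(pairs) / mean(pairs),
               tolerance = 1e-9)
  # composition proportions sum to one
  expect_equal(g("prop_fledglings") + g("prop_floaters") + g("prop_breeders"),
               1, tolerance = 1e-12)
  expect_equal(g("prop_first_time_f") + g("prop_experienced_f"), 1,
               tolerance = 1e-12)
})

test_that("posterior analyses run on a fitted model and propagate draw-wise", {
  fit <- cached_fit()
  el <- transient_elasticities(fit)
  expect_true(all(el$lower <= el$upper))
  expect_gt(el$mean[el$component == "s3_f"], 0)
  lt <- ltre_contributions(fit)
  expect_equal(
    lt$aggregates$mean[lt$aggregates$component == "rates_share"] +
      lt$aggregates$mean[lt$aggregates$component == "structure_share"], 1,
    tolerance = 1e-9)
  sdp <- stochasticity_decomposition(fit)
  ev <- sdp$mean[sdp$component == "env_share"]
  expect_gt(ev, 0); expect_lt(ev, 1)
  ds <- derived_summaries(fit)
  expect_true(all(is.finite(ds$mean)))
})
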