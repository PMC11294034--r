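test_that("aggregating individuals reproduces the trajectory exactly", {
  sim <- simulate_goshawk(12, seed = 101)
  ind <- sim$individuals
  N <- ind$trajectory$N
  by <- ind$breeder_years
  for (t in c(1, 4, 8, 12)) {
    bt <- by[by$year == t, , drop = FALSE]
    for (sx in c("f", "m")) for (a in 1:3) {
      st <- c(2, 4, 5)[a]
      truth <- N[st, sx, t] + if (a == 3) N[6, sx, t] else 0
      expect_equal(sum(bt$sex == sx & bt$age_class == a), truth)
    }
  }
  # fledgling table totals equal brood totals
  fl <- ind$fledglings; br <- ind$broods
  expect_equal(nrow(fl), sum(br$n_fledged))
  expect_equal(sum(fl$sex == "f"), sum(br$n_female))
  # one brood per breeding female per year
  expect_equal(nrow(br), sum(breeding_pairs(ind$trajectory)))
})

test_that("perfect detection yields complete data sets", {
  sim <- simulate_goshawk(10, seed = 102,
                          obs = obs_params(p = c(f = 1, m = 1),
                                           r = c(f = 1, m = 1),
                                           sigma_p = 0, sigma_r = 0,
                                           ring_frac = 1,
                                           counts_model = "exact"))
  ind <- sim$individuals; md <- sim$data
  # every breeder-year appears in the capture histories
  expect_equal(sum(md$adult_cr$history), nrow(ind$breeder_years))
  # breeder counts equal the true class sizes
  N <- ind$trajectory$N
  cls <- hawkipm:::.breeder_class_sizes(N)
  expect_equal(as.numeric(md$breeder_counts), as.numeric(cls))
  # exact census
  expect_equal(md$territory_counts, as.integer(breeding_pairs(N)))
  # every ringed bird dying within the horizon is recovered
  di <- ind$individuals$death_interval[match(md$recoveries$id,
                                             ind$individuals$id)]
  should <- !is.na(di) & di <= ind$years - 1
  expect_equal(!is.na(md$recoveries$recovery_year), should)
  # all broods recorded
  expect_equal(nrow(md$brood_success), nrow(ind$broods))
})

test_that("zero detection yields empty feather data", {
  sim <- simulate_goshawk(8, seed = 103,
                          obs = obs_params(p = c(f = 0, m = 0), sigma_p = 0))
  expect_equal(nrow(sim$data$adult_cr$history), 0)
  expect_true(all(sim$data$breeder_counts == 0))
})

test_that("observed breeder counts never exceed the true class sizes", {
  sim <- simulate_goshawk(15, seed = 104)
  cls <- hawkipm:::.breeder_class_sizes(sim$individuals$trajectory$N)
  expect_true(all(sim$data$breeder_counts <= cls))
})

test_that("recovery thinning matches the recovery probability", {
  # fixed r = 0.5: the fraction of first-winter deaths recovered is 0.5
  # within binomial error over thousands of deaths
  set.seed(105)
  sim <- simulate_goshawk(25, obs = obs_params(r = c(f = 0.5, m = 0.5),
                                               sigma_r = 0, ring_frac = 1))
  ind <- sim$individuals; md <- sim$data
  di <- ind$individuals$death_interval[match(md$recoveries$id,
                                             ind$individuals$id)]
  first_winter <- !is.na(di) & di == md$recoveries$ring_year
  n <- sum(first_winter)
  got <- sum(!is.na(md$recoveries$recovery_year[first_winter]))
  expect_gt(n, 1000)
  expect_lt(abs(got / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("pooled fledgling sex ratio recovers the xi mixture", {
  set.seed(106)
  sim <- simulate_goshawk(30)
  br <- sim$individuals$broods
  rates <- sim$individuals$trajectory$rates
  sb <- br[br$success == 1, ]
  # expected proportion of females given each brood's maternal age and year
  pf_exp <- sum(sb$n_fledged * rates$xi[cbind(sb$age_class, sb$year)]) /
    sum(sb$n_fledged)
  pf_obs <- sum(sb$n_female) / sum(sb$n_fledged)
  expect_lt(abs(pf_obs - pf_exp), 3 * sqrt(0.25 / sum(sb$n_fledged)))
  expect_lt(pf_obs, 0.5)  # male-biased preset
})

test_that("the default half-century preset matches the study's scale", {
  set.seed(107)
  rings <- replicate(3, nrow(simulate_goshawk(47)$data$recoveries))
  # same order as a real ringing programme of ~3500 nestlings
  expect_gt(median(rings), 1200)
  expect_lt(median(rings), 8000)
})

test_that("simulation and observation are seed-reproducible end-to-end", {
  s1 <- simulate_goshawk(10, seed = 108)
  s2 <- simulate_goshawk(10, seed = 108)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$trajectory$N, s2$truth$trajectory$N)
})

test_that("extinction truncates the output with a warning", {
  h <- flat_hyper(s = matrix(0.01, 3, 2), eta = rep(0.1, 3),
                  rho = rep(1.2, 3), xi = rep(0.5, 3),
                  alpha = matrix(0.1, 2, 2), omega = 0)
  init <- ipm_state(f = c(0, 0, 0, 0, 2), m = c(0, 0, 0, 0, 2, 0))
  expect_warning(out <- simulate_individuals(h, init, 30, seed = 109),
                 "extinct")
  expect_true(out$extinct)
  expect_lt(out$years, 30)
})

test_that("zero survival makes every ringed death available immediately", {
  h <- flat_hyper(s = matrix(0, 3, 2), eta = rep(0.8, 3), rho = rep(2, 3),
                  xi = rep(0.5, 3), alpha = matrix(0.5, 2, 2), omega = 0)
  init <- ipm_state(f = c(0, 0, 0, 0, 20), m = c(0, 0, 0, 0, 20, 0))
  suppressWarnings(ind <- simulate_individuals(h, init, 5, seed = 110))
  fl <- ind$fledglings[ind$fledglings$year == 1, ]
  di <- ind$individuals$death_interval[match(fl$id, ind$individuals$id)]
  expect_true(all(di == 1))
})

test_that("monitoring data round-trips through CSV", {
  sim <- simulate_goshawk(9, seed = 111)
  d <- withr::local_tempdir()
  write_monitoring_csv(sim$data, d, manifest = list(seed = 111))
  md <- read_monitoring_csv(d)
  expect_identical(md$territory_counts, sim$data$territory_counts)
  expect_identical(md$breeder_counts, sim$data$breeder_counts)
  expect_identical(md$adult_cr$history, sim$data$adult_cr$history)
  expect_identical(md$adult_cr$age_first, sim$data$adult_cr$age_first)
  expect_equal(md$recoveries$recovery_year, sim$data$recoveries$recovery_year)
  expect_error(read_monitoring_csv(file.path(d, "nope")), "missing data file")
})

test_that("validation names the offending data set and rule", {
  sim <- simulate_goshawk(6, seed = 112)
  md <- sim$data
  md$brood_fledglings$count[1] <- 0
  expect_error(validate_monitoring_data(md), "brood_fledglings.*count >= 1")
  md2 <- sim$data
  md2$recoveries$recovery_year[1] <- md2$recoveries$ring_year[1]
  expect_error(validate_monitoring_data(md2), "recoveries.*exceed")
})
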