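sexes <- c("f", "m")

test_that("territory-count likelihood matches Poisson closed forms", {
  tr <- array(0, c(6, 2, 3))
  tr[2, 1, ] <- c(50, 50, 50)
  expect_equal(loglik_counts(c(50, 50, 50), tr),
               3 * dpois(50, 50, log = TRUE))
  tr1 <- array(0, c(6, 2, 1)); tr1[2, 1, 1] <- 2
  expect_equal(loglik_counts(3, tr1), 3 * log(2) - 2 - log(6),
               tolerance = 1e-12)
  # 3-year toy against term-by-term computation
  tr3 <- array(0, c(6, 2, 3))
  tr3[2, 1, ] <- c(3, 5, 4); tr3[4, 1, ] <- 1; tr3[5, 1, ] <- 2
  pairs <- c(6, 8, 7); obs <- c(5, 9, 7)
  expect_equal(loglik_counts(obs, tr3),
               sum(dpois(obs, pairs, log = TRUE)), tolerance = 1e-12)
  expect_error(loglik_counts(c(-1, 2, 3), tr3), "non-negative")
  # switchable normal observation model
  expect_equal(loglik_counts(obs, tr3, model = "normal", sd = 2),
               sum(dnorm(obs, pairs, 2, log = TRUE)))
})

test_that("breeder-count likelihood is binomial thinning of class sizes", {
  N <- array(0, c(6, 2, 1))
  N[2, 1, 1] <- 4; N[4, 1, 1] <- 3; N[5, 1, 1] <- 10
  N[2, 2, 1] <- 2; N[4, 2, 1] <- 2; N[5, 2, 1] <- 8; N[6, 2, 1] <- 2
  B0 <- array(0L, c(1, 2, 3))
  # p = 1: zero log-likelihood iff observed equals the true class sizes
  Bt <- B0; Bt[1, 1, ] <- c(4, 3, 10); Bt[1, 2, ] <- c(2, 2, 10)
  expect_equal(loglik_breeder_counts(Bt, N, matrix(1, 2, 1)), 0)
  Bw <- Bt; Bw[1, 1, 1] <- 3
  expect_equal(loglik_breeder_counts(Bw, N, matrix(1, 2, 1)), -Inf)
  # observed 0 of true 10 at p = 0.3
  N2 <- array(0, c(6, 2, 1)); N2[5, 1, 1] <- 10
  expect_equal(loglik_breeder_counts(B0, N2, matrix(0.3, 2, 1)),
               10 * log(0.7), tolerance = 1e-12)
  # impossible data give -Inf, not an error
  Bbig <- B0; Bbig[1, 1, 3] <- 11
  expect_equal(loglik_breeder_counts(Bbig, N2, matrix(0.3, 2, 1)), -Inf)
})

test_that("breeder-count likelihood sums to one over all outcomes", {
  # two classes with sizes 3 and 2: enumerate every observable table
  N <- array(0, c(6, 2, 1)); N[2, 1, 1] <- 3; N[4, 1, 1] <- 2
  p <- matrix(0.37, 2, 1)
  tot <- 0
  for (b1 in 0:3) for (b2 in 0:2) {
    B <- array(0L, c(1, 2, 3)); B[1, 1, 1] <- b1; B[1, 1, 2] <- b2
    tot <- tot + exp(loglik_breeder_counts(B, N, p))
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("brood-success likelihood is Bernoulli with age-specific eta", {
  bs1 <- data.frame(year = 1, age_class = 3, success = 1)
  expect_equal(loglik_success(bs1, c(0.5, 0.5, 0.8)), log(0.8))
  # n successes of N broods with constant eta equal the binomial kernel
  bs <- data.frame(year = 1, age_class = 2, success = rep(c(1, 0), c(7, 3)))
  expect_equal(loglik_success(bs, c(0.4, 0.4, 0.4)),
               7 * log(0.4) + 3 * log(0.6), tolerance = 1e-12)
  # mixed ages and years, hand-checked
  eta <- matrix(c(0.3, 0.6, 0.9, 0.2, 0.5, 0.8), 3, 2)
  bsm <- data.frame(year = c(1, 1, 2), age_class = c(1, 3, 2),
                    success = c(1, 0, 1))
  expect_equal(loglik_success(bsm, eta), log(0.3) + log(0.1) + log(0.5),
               tolerance = 1e-12)
})

test_that("productivity likelihood is a normalized zero-truncated Poisson", {
  bf <- data.frame(year = 1, age_class = 1, count = 1)
  expect_equal(loglik_productivity(bf, rep(1, 3), parameterization = "rate"),
               log(exp(-1) / (1 - exp(-1))), tolerance = 1e-12)
  # normalization over the support
  expect_equal(sum(dztpois(1:300, 4.2, log = FALSE)), 1, tolerance = 1e-12)
  # truncated mean exceeds the rate for every positive rate
  for (lam in c(0.1, 1, 2.5, 6))
    expect_gt(sum((1:300) * dztpois(1:300, lam, log = FALSE)), lam)
  # mean parameterization: the distribution's mean is rho itself
  rho <- 2.3
  lam <- ztp_rate(rho)
  expect_equal(sum((1:300) * dztpois(1:300, lam, log = FALSE)), rho,
               tolerance = 1e-9)
  expect_error(loglik_productivity(
    data.frame(year = 1, age_class = 1, count = 0), rep(2, 3)), ">= 1")
})

test_that("sex-ratio likelihood matches binomial closed forms", {
  bx <- data.frame(year = 1, age_class = 2, n_female = 2, n_male = 2)
  expect_equal(loglik_sexratio(bx, rep(0.5, 3)), log(6 / 16),
               tolerance = 1e-12)
  expect_equal(loglik_sexratio(bx, rep(0, 3)), -Inf)
  # toy table hand-checked
  xi <- matrix(c(0.4, 0.5, 0.6), 3, 1)
  bx2 <- data.frame(year = c(1, 1), age_class = c(1, 3),
                    n_female = c(1, 0), n_male = c(0, 2))
  expect_equal(loglik_sexratio(bx2, xi), log(0.4) + 2 * log(0.4),
               tolerance = 1e-12)
})

test_that("CJS likelihood matches closed forms and encodes age advance", {
  T <- 2
  s <- array(0.5, c(3, 2, T)); p <- matrix(1, 2, T)
  h10 <- list(history = matrix(c(1L, 0L), 1), sex = "f", age_first = 1L)
  h11 <- list(history = matrix(c(1L, 1L), 1), sex = "f", age_first = 1L)
  expect_equal(loglik_adult_cr(h10, s, p), log(0.5), tolerance = 1e-12)
  expect_equal(loglik_adult_cr(h11, s, p), log(0.5), tolerance = 1e-12)
  expect_error(loglik_adult_cr(list(history = matrix(0L, 1, 2), sex = "f",
                                    age_first = 1L), s, p),
               "initial identification")
  # a 1-y release survives its first interval with s2, then s3
  T2 <- 3
  s2 <- array(0, c(3, 2, T2))
  s2[2, 1, ] <- 0.6; s2[3, 1, ] <- 0.9
  p2 <- matrix(0.7, 2, T2)
  h <- list(history = matrix(c(1L, 1L, 1L), 1), sex = "f", age_first = 1L)
  expect_equal(loglik_adult_cr(h, s2, p2),
               log(0.6) + log(0.7) + log(0.9) + log(0.7), tolerance = 1e-12)
})

test_that("CJS probabilities sum to one over all continuations (T <= 5)", {
  set.seed(31)
  T <- 5
  s <- array(runif(3 * 2 * T, 0.2, 0.95), c(3, 2, T))
  p <- matrix(runif(2 * T, 0.1, 0.9), 2, T)
  for (a in 1:3) for (ix in 1:2) {
    tot <- 0
    for (mask in 0:(2^(T - 1) - 1)) {
      h <- c(1L, as.integer(intToBits(mask))[1:(T - 1)])
      cr <- list(history = matrix(h, 1), sex = sexes[ix], age_first = a)
      tot <- tot + exp(loglik_adult_cr(cr, s, p))
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("per-individual CJS equals the m-array multinomial kernel", {
  set.seed(32)
  sim <- simulate_goshawk(9)
  cr <- sim$data$adult_cr
  T <- sim$data$years
  s <- array(runif(3 * 2 * T, 0.3, 0.9), c(3, 2, T))
  p <- matrix(runif(2 * T, 0.2, 0.8), 2, T)
  ll_ind <- loglik_adult_cr(cr, s, p)
  ma <- cjs_marray(cr, T)
  ll_ma <- 0
  for (ix in 1:2) for (a in 1:3) for (t in 1:(T - 1)) {
    if (ma$R[ix, a, t] == 0) next
    pr <- cjs_cell_probs(s, p, ix, a, t, T)
    cells <- c(ma$m[ix, a, t, t:(T - 1)], ma$m[ix, a, t, T])
    ll_ma <- ll_ma + sum(cells * log(pr))
  }
  expect_equal(ll_ind, ll_ma, tolerance = 1e-8)
})

test_that("recovery likelihood matches closed forms and sums to one", {
  T <- 6
  s <- array(0, c(3, 2, T)); s[1, , ] <- 0.6; s[2, , ] <- 0.7; s[3, , ] <- 0.8
  r <- matrix(0.5, 2, T)
  rec1 <- data.frame(id = 1, sex = "f", ring_year = 1, recovery_year = 2)
  expect_equal(loglik_recovery(rec1, s, r), log(0.4 * 0.5), tolerance = 1e-12)
  # with r = 1, never-recovered means survival to the horizon
  r1 <- matrix(1, 2, T)
  pr <- rec_cell_probs(s, r1, 1, 1, T)
  expect_equal(pr[T], 0.6 * 0.7 * 0.8^3, tolerance = 1e-12)
  # full event space sums to one for every cohort and sex
  set.seed(33)
  s2 <- array(runif(3 * 2 * T, 0.2, 0.9), c(3, 2, T))
  r2 <- matrix(runif(2 * T, 0.05, 0.6), 2, T)
  for (t0 in 1:(T - 1)) for (ix in 1:2) {
    pr <- rec_cell_probs(s2, r2, ix, t0, T)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # each event probability matches the per-bird likelihood
    for (k in seq_len(T - t0)) {
      rec <- data.frame(id = 1, sex = sexes[ix], ring_year = t0,
                        recovery_year = t0 + k)
      expect_equal(exp(loglik_recovery(rec, s2, r2)), pr[k],
                   tolerance = 1e-12)
    }
  }
})

test_that("state transition density matches hand computation", {
  h <- flat_hyper(s = matrix(0.5, 3, 2), eta = c(0, 0, 0.8),
                  rho = c(1.5, 1.5, 2), xi = rep(0.5, 3),
                  alpha = matrix(0.4, 2, 2), omega = 1)
  r <- mean_rates(h, 2)
  N <- array(0, c(6, 2, 2))
  N[, 1, 1] <- c(2, 1, 0, 0, 5, 0); N[, 2, 1] <- c(1, 0, 0, 1, 4, 1)
  N[, 1, 2] <- c(1, 1, 1, 1, 3, 0); N[, 2, 2] <- c(2, 0, 0, 1, 4, 2)
  ll <- loglik_transitions(N, r)
  # hand: female fledglings = 5*0.8*2*0.5 = 4; male the same
  lam1 <- 4 * 0.5 * (1 - 0.4); lam2 <- 4 * 0.5 * 0.4
  hand <- dpois(1, lam1, log = TRUE) + dpois(1, lam2, log = TRUE) +   # f 1,2
    dbinom(1, 2, 0.5 * 0.6, log = TRUE) +                             # f 3
    log(dbinom(0, 2, 0.2) * dbinom(1, 1, 0.5) +
        dbinom(1, 2, 0.2) * dbinom(0, 1, 0.5)) +                      # f 4
    dbinom(3, 5, 0.5, log = TRUE) +                                   # f 5
    dpois(2, lam1, log = TRUE) + dpois(0, lam2, log = TRUE) +         # m 1,2
    dbinom(0, 1, 0.3, log = TRUE) +
    log(dbinom(1, 1, 0.2) * dbinom(0, 0, 0.5)) +                      # m 4
    dbinom(4, 6, 0.5, log = TRUE) +                                   # m 5
    dpois(2, 1, log = TRUE)                                           # m 6
  expect_equal(ll, hand, tolerance = 1e-10)
})

test_that("joint likelihood is additive and order-invariant", {
  sim <- simulate_goshawk(8, seed = 34)
  tr <- sim$truth$trajectory
  ctx <- list(trajectory = tr, rates = tr$rates,
              p = sim$truth$obs$p, r = sim$truth$obs$r)
  full <- joint_loglik(sim$data, ctx)
  parts <- loglik_counts(sim$data$territory_counts, tr) +
    loglik_breeder_counts(sim$data$breeder_counts, tr, ctx$p) +
    loglik_success(sim$data$brood_success, tr$rates$eta) +
    loglik_productivity(sim$data$brood_fledglings, tr$rates$rho) +
    loglik_sexratio(sim$data$brood_sex, tr$rates$xi) +
    loglik_adult_cr(sim$data$adult_cr, tr$rates$s, ctx$p) +
    loglik_recovery(sim$data$recoveries, tr$rates$s, ctx$r) +
    loglik_transitions(tr, tr$rates)
  expect_equal(full, parts, tolerance = 1e-9)
  expect_true(is.finite(full))

  # empty data components leave only the transition density
  md0 <- tiny_monitoring_data(years = tr$years,
                              counts = as.integer(breeding_pairs(tr)))
  e0 <- joint_loglik(md0, ctx, components = character(0))
  expect_equal(e0, loglik_transitions(tr, tr$rates), tolerance = 1e-9)

  # record order does not matter
  perm <- sim$data
  perm$brood_success <- perm$brood_success[sample(nrow(perm$brood_success)), ]
  perm$recoveries <- perm$recoveries[sample(nrow(perm$recoveries)), ]
  expect_equal(joint_loglik(perm, ctx), full, tolerance = 1e-9)
})

test_that("impossible latent states give -Inf rather than an error", {
  h <- flat_hyper()
  r <- mean_rates(h, 2)
  N <- array(0, c(6, 2, 2))
  N[5, 1, 1] <- 2
  N[5, 1, 2] <- 5  # more survivors than the pool
  expect_equal(loglik_transitions(N, r), -Inf)
})
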