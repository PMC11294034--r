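test_that("expected projection reproduces closed-form stage means", {
  # annihilation: all rates zero kills every stage
  h0 <- flat_hyper(s = matrix(0, 3, 2), eta = rep(0, 3), rho = rep(0, 3),
                   xi = rep(0, 3), alpha = matrix(0, 2, 2), omega = 0)
  r0 <- mean_rates(h0, 2)
  st <- ipm_state(f = c(3, 4, 5, 6, 7), m = c(1, 2, 3, 4, 5, 6))
  e <- expected_next_state(st, rates_at(r0, 1), rates_at(r0, 2))
  expect_equal(unname(as.numeric(e)), rep(0, 12))

  # single productive stage: E[N1f] = 10*0.8*2.5*0.5*0.4*0.8 = 3.2
  h1 <- flat_hyper(s = matrix(c(0.4, 0, 0, 0, 0, 0), 3, 2),
                   eta = c(0, 0, 0.8), rho = c(0, 0, 2.5),
                   xi = c(0, 0, 0.5),
                   alpha = matrix(c(0.2, 0, 0, 0), 2, 2), omega = 0)
  r1 <- mean_rates(h1, 2)
  st1 <- ipm_state(f = c(0, 0, 0, 0, 10), m = rep(0, 6))
  e1 <- expected_next_state(st1, rates_at(r1, 1), rates_at(r1, 2))
  expect_equal(e1[1, "f"], 3.2, tolerance = 1e-12)
  expect_equal(e1[2, "f"], 0.8, tolerance = 1e-12)
  # immigrant stage mean is next year's immigration rate
  expect_equal(e1[6, "m"], 0)
})

test_that("invalid states and rates are rejected", {
  h <- goshawk_hyper(); r <- mean_rates(h, 2)
  st <- ipm_state(f = c(1, 1, 1, 1, 1), m = rep(1, 6))
  bad <- unclass(st); bad[1, 1] <- -1
  expect_error(expected_next_state(bad, rates_at(r, 1), rates_at(r, 2)),
               "non-negative")
  rr <- rates_at(r, 1); rr$s[1, 1] <- 1.4
  expect_error(expected_next_state(st, rr, rates_at(r, 2)), "\\[0, 1\\]")
  expect_error(ipm_state(f = c(1, 1, 1, 1, 1), m = rep(1, 5)), "6 male")
})

test_that("Monte-Carlo means of the stochastic step match the expected step", {
  h <- goshawk_hyper()
  r <- mean_rates(h, 2)
  st <- goshawk_initial_state()
  ex <- expected_next_state(st, rates_at(r, 1), rates_at(r, 2))
  n <- 1e5
  set.seed(71)
  sim <- hawkipm:::.step_multi(array(as.numeric(st), c(6, 2, n)),
                               rates_at(r, 1), rates_at(r, 2), n)
  emp <- apply(sim$N, c(1, 2), mean)
  se <- apply(sim$N, c(1, 2), stats::sd) / sqrt(n)
  dev <- abs(emp - ex) / pmax(se, 1e-12)
  expect_lt(max(dev[se > 0]), 3)
  expect_equal(emp[se == 0], ex[se == 0], ignore_attr = TRUE)
})

test_that("stochastic transitions follow the stated distributions", {
  # N4f | N1f = 20, s2f = 0.5, alpha2f(t+1) = 0.6, N2f = 0  ~  Bin(20, 0.3)
  h <- flat_hyper(s = matrix(c(0, 0.5, 0, 0, 0.5, 0), 3, 2),
                  eta = rep(0, 3), rho = rep(0, 3), xi = rep(0.5, 3),
                  alpha = matrix(c(0, 0.6, 0, 0.6), 2, 2), omega = 0)
  r <- mean_rates(h, 2)
  st <- ipm_state(f = c(20, 0, 0, 0, 0), m = rep(0, 6))
  n <- 1e5
  set.seed(72)
  sim <- hawkipm:::.step_multi(array(as.numeric(st), c(6, 2, n)),
                               rates_at(r, 1), rates_at(r, 2), n)
  n4 <- sim$N[4, 1, ]
  obs <- tabulate(n4 + 1, nbins = 21)
  expct <- n * stats::dbinom(0:20, 20, 0.3)
  keep <- expct >= 5
  chi <- sum((obs[keep] - expct[keep])^2 / expct[keep]) +
    (n - sum(obs[keep]) - (n - sum(expct[keep])))^2 / (n - sum(expct[keep]))
  df <- sum(keep)  # pooled tail adds one cell, minus one constraint
  expect_lt(chi, stats::qchisq(0.99, df))
})

test_that("deterministic limits of the stochastic step hold", {
  # perfect survival, no reproduction: adult breeders persist unchanged
  h <- flat_hyper(s = matrix(1, 3, 2), eta = rep(0, 3), rho = rep(0, 3),
                  xi = rep(0, 3), alpha = matrix(1, 2, 2), omega = 0)
  r <- mean_rates(h, 2)
  st <- ipm_state(f = c(0, 0, 0, 0, 5), m = c(0, 0, 0, 0, 5, 0))
  cur <- st
  for (k in 1:5) {
    cur <- stochastic_next_state(cur, rates_at(r, 1), rates_at(r, 2),
                                 seed = k)
    expect_equal(cur[5, "f"], 5)
    expect_equal(cur[5, "m"], 5)
  }
  # zero first-year survival: no 1-y birds next year however productive
  h2 <- flat_hyper(s = matrix(c(0, .9, .9, 0, .9, .9), 3, 2),
                   eta = rep(1, 3), rho = rep(3, 3), xi = rep(.5, 3),
                   alpha = matrix(.5, 2, 2), omega = 0)
  r2 <- mean_rates(h2, 2)
  st2 <- ipm_state(f = c(5, 5, 5, 5, 20), m = c(5, 5, 5, 5, 20, 0))
  nx <- stochastic_next_state(st2, rates_at(r2, 1), rates_at(r2, 2), seed = 1)
  expect_equal(nx[1, "f"] + nx[2, "f"] + nx[1, "m"] + nx[2, "m"], 0)
})

test_that("binomial transitions conserve their source pools", {
  h <- goshawk_hyper()
  r <- mean_rates(h, 2)
  st <- goshawk_initial_state()
  set.seed(73)
  sim <- hawkipm:::.step_multi(array(as.numeric(st), c(6, 2, 5000)),
                               rates_at(r, 1), rates_at(r, 2), 5000)
  for (ix in 1:2) {
    expect_true(all(sim$N[3, ix, ] + sim$N[4, ix, ] <=
                      st[1, ix] + st[2, ix]))
    pool <- st[3, ix] + st[4, ix] + st[5, ix] + st[6, ix]
    expect_true(all(sim$N[5, ix, ] <= pool))
  }
})

test_that("expected abundances are monotone in survival and productivity", {
  h <- goshawk_hyper()
  st <- goshawk_initial_state()
  base <- mean_rates(h, 2)
  e0 <- expected_next_state(st, rates_at(base, 1), rates_at(base, 2))
  for (tweak in c("s3f", "s1m", "rho3", "eta1")) {
    m <- hyper_means(h)
    if (tweak == "s3f") m$s[3, "f"] <- m$s[3, "f"] + 0.05
    if (tweak == "s1m") m$s[1, "m"] <- m$s[1, "m"] + 0.05
    if (tweak == "rho3") m$rho[3] <- m$rho[3] + 0.5
    if (tweak == "eta1") m$eta[1] <- m$eta[1] + 0.1
    r2 <- mean_rates(ipm_hyper(m), 2)
    e1 <- expected_next_state(st, rates_at(r2, 1), rates_at(r2, 2))
    expect_true(all(e1 - e0 >= -1e-12))
  }
})

test_that("sex symmetry holds with equal rates, xi = 0.5 and no immigration", {
  m <- hyper_means(goshawk_hyper())
  m$s[, "m"] <- m$s[, "f"]; m$alpha[, "m"] <- m$alpha[, "f"]
  m$xi[] <- 0.5; m$omega <- 0
  r <- mean_rates(ipm_hyper(m), 2)
  st <- ipm_state(f = c(4, 5, 6, 7, 8), m = c(4, 5, 6, 7, 8, 0))
  e <- expected_next_state(st, rates_at(r, 1), rates_at(r, 2))
  expect_equal(e[1:5, "f"], e[1:5, "m"], tolerance = 1e-12)
})

test_that("trajectories are reproducible and match the expected recursion", {
  h <- goshawk_hyper()
  init <- goshawk_initial_state()
  t1 <- project_trajectory(init, h, 20, seed = 9)
  t2 <- project_trajectory(init, h, 20, seed = 9)
  expect_identical(t1$N, t2$N)
  expect_identical(t1$rates, t2$rates)
  expect_error(project_trajectory(init, h, 1), ">= 2")

  # sigma = 0, expected mode: equals repeated expected_next_state exactly
  h0 <- ipm_hyper(hyper_means(h))
  tr <- project_trajectory(init, h0, 6, mode = "expected", seed = 1)
  cur <- unclass(init)
  for (t in 1:5) {
    cur <- expected_next_state(cur, rates_at(tr$rates, t),
                               rates_at(tr$rates, t + 1))
    expect_equal(unname(tr$N[, , t + 1]), unname(cur), tolerance = 1e-10)
  }
})

test_that("annual growth rates obey closed-form identities", {
  N <- array(0, c(6, 2, 4)); N[5, 1, ] <- 10
  g <- annual_growth_rates(N)
  expect_equal(g$lambda, rep(1, 3))
  expect_equal(g$geometric_mean, 1)
  N2 <- array(0, c(6, 2, 4)); N2[5, 1, ] <- 10 * 2^(0:3)
  expect_equal(annual_growth_rates(N2)$geometric_mean, 2)
  set.seed(4)
  N3 <- array(rpois(6 * 2 * 7, 8) + 1, c(6, 2, 7))
  N3[6, 1, ] <- 0
  g3 <- annual_growth_rates(N3)
  tot <- apply(N3, 3, sum)
  expect_equal(g3$geometric_mean, (tot[7] / tot[1])^(1 / 6),
               tolerance = 1e-12)
  N4 <- N3; N4[, , 4] <- 0
  expect_error(annual_growth_rates(N4), "extinct")
})

test_that("47-year stochastic trajectories fluctuate like a real pair series", {
  # under the near-stationary preset, the CV of pair counts is of the order
  # of tens of percent
  set.seed(21)
  cvs <- replicate(15, {
    tr <- project_trajectory(goshawk_initial_state(), goshawk_hyper(), 47)
    pp <- breeding_pairs(tr)
    if (any(pp == 0)) NA else stats::sd(pp) / mean(pp)
  })
  expect_gt(median(cvs, na.rm = TRUE), 0.08)
  expect_lt(median(cvs, na.rm = TRUE), 0.60)
})
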