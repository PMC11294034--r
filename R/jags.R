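# Joint Bayesian fit of the integrated model via JAGS.
#
# The model mirrors the component likelihoods of likelihoods.R: Poisson
# territory counts, binomially thinned breeder counts, Bernoulli brood
# success, zero-truncated Poisson brood sizes (aggregated via the zeros
# trick), binomial brood sex ratios, an age-structured CJS m-array and a
# Seber-style dead-recovery m-array, on top of the discrete Poisson/binomial
# state-space transitions.  Temporal random effects sit on all demographic
# and observation rates on their link scales.

.ALL_COMPONENTS <- c("counts", "breeders", "success", "productivity",
                     "sexratio", "cjs", "recovery")

#' MCMC configuration for [fit_ipm()]
#'
#' The default is a desk-scale configuration (2 chains x 4000 iterations,
#' 1500 burn-in, thinning 5) suitable for simulation experiments; use
#' [ipm_config_paper()] for a long production run (3 chains x 110,000
#' iterations, 10,000 burn-in, thinning 50, posterior sample 6000).
#'
#' @param n_chains number of MCMC chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thin thinning interval.
#' @param n_adapt adaptation iterations.
#' @param seed integer seed; chain seeds are derived from it.
#' @param components subset of the seven data components to include.
#' @param random_effects include temporal random effects (default TRUE).
#' @param monitor_latent monitor the latent stage abundances (default TRUE
#'   when the latent block is present).
#' @param quiet suppress JAGS progress output.
#' @return list of class `ipm_config`.
#' @export
ipm_config <- function(n_chains = 2, n_iter = 4000, n_burnin = 1500, thin = 5,
                       n_adapt = 500, seed = 1,
                       components = .ALL_COMPONENTS,
                       random_effects = TRUE, monitor_latent = TRUE,
                       quiet = TRUE) {
  stopifnot(n_iter > n_burnin, thin >= 1)
  components <- match.arg(components, .ALL_COMPONENTS, several.ok = TRUE)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, n_adapt = n_adapt, seed = seed,
                 components = components, random_effects = random_effects,
                 monitor_latent = monitor_latent, quiet = quiet),
            class = "ipm_config")
}

#' @rdname ipm_config
#' @param ... overrides passed to [ipm_config()].
#' @export
ipm_config_paper <- function(seed = 1, ...) {
  ipm_config(n_chains = 3, n_iter = 110000, n_burnin = 10000, thin = 50,
             n_adapt = 1000, seed = seed, ...)
}

# ---- model code ------------------------------------------------------------

# Build the JAGS model string for a given component set.
.build_model <- function(components, random_effects, dd_blocks = character(0)) {
  re <- random_effects
  has <- function(x) x %in% components
  latent <- has("counts") || has("breeders")
  if (length(dd_blocks) && !latent)
    stop("density-dependent rates need the latent population block", call. = FALSE)
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  dd_on <- function(block) block %in% dd_blocks

  add("model {")
  # ---- demographic rates with temporal random effects ----
  # survival (logit)
  add("for (a in 1:3) { for (x in 1:2) {")
  add("  mu.s[a,x] ~ dlogis(0, 1)")
  if (re) add("  sigma.s[a,x] ~ dunif(0, 10)
  tau.s[a,x] <- pow(sigma.s[a,x], -2)")
  if (dd_on("s")) add("  beta.s[a,x] ~ dnorm(0, 1)")
  add("  for (t in 1:T) {")
  if (re) add("    eps.s[a,x,t] ~ dnorm(0, tau.s[a,x])") else
    add("    eps.s[a,x,t] <- 0")
  add("    logit(s[a,x,t]) <- mu.s[a,x] + eps.s[a,x,t]%s",
      if (dd_on("s")) " + beta.s[a,x] * Z[t]" else "")
  add("  } } }")
  # breeding success (logit)
  add("for (a in 1:3) {")
  add("  mu.eta[a] ~ dlogis(0, 1)")
  if (re) add("  sigma.eta[a] ~ dunif(0, 10)
  tau.eta[a] <- pow(sigma.eta[a], -2)")
  if (dd_on("eta")) add("  beta.eta[a] ~ dnorm(0, 1)")
  add("  for (t in 1:T) {")
  if (re) add("    eps.eta[a,t] ~ dnorm(0, tau.eta[a])") else
    add("    eps.eta[a,t] <- 0")
  add("    logit(eta[a,t]) <- mu.eta[a] + eps.eta[a,t]%s",
      if (dd_on("eta")) " + beta.eta[a] * Z[t]" else "")
  add("  } }")
  # productivity: identity link on the zero-truncated Poisson rate lam;
  # rho = mean brood size = lam / (1 - exp(-lam)) feeds the projection
  add("for (a in 1:3) {")
  add("  mu.lam[a] ~ dnorm(0, 0.01)")
  if (re) add("  sigma.lam[a] ~ dunif(0, 10)
  tau.lam[a] <- pow(sigma.lam[a], -2)")
  if (dd_on("rho")) add("  beta.lam[a] ~ dnorm(0, 1)")
  add("  for (t in 1:T) {")
  if (re) add("    eps.lam[a,t] ~ dnorm(0, tau.lam[a])") else
    add("    eps.lam[a,t] <- 0")
  add("    lam[a,t] <- max(mu.lam[a] + eps.lam[a,t]%s, 0.01)",
      if (dd_on("rho")) " + beta.lam[a] * Z[t]" else "")
  add("    rho[a,t] <- lam[a,t] / (1 - exp(-lam[a,t]))")
  add("  } }")
  # fledgling sex ratio (logit)
  add("for (a in 1:3) {")
  add("  mu.xi[a] ~ dlogis(0, 1)")
  if (re) add("  sigma.xi[a] ~ dunif(0, 10)
  tau.xi[a] <- pow(sigma.xi[a], -2)")
  if (dd_on("xi")) add("  beta.xi[a] ~ dnorm(0, 1)")
  add("  for (t in 1:T) {")
  if (re) add("    eps.xi[a,t] ~ dnorm(0, tau.xi[a])") else
    add("    eps.xi[a,t] <- 0")
  add("    logit(xi[a,t]) <- mu.xi[a] + eps.xi[a,t]%s",
      if (dd_on("xi")) " + beta.xi[a] * Z[t]" else "")
  add("  } }")
  # recruitment (logit); responds to the previous year's female total
  add("for (a in 1:2) { for (x in 1:2) {")
  add("  mu.alpha[a,x] ~ dlogis(0, 1)")
  if (re) add("  sigma.alpha[a,x] ~ dunif(0, 10)
  tau.alpha[a,x] <- pow(sigma.alpha[a,x], -2)")
  if (dd_on("alpha")) add("  beta.alpha[a,x] ~ dnorm(0, 1)")
  add("  for (t in 1:T) {")
  if (re) add("    eps.alpha[a,x,t] ~ dnorm(0, tau.alpha[a,x])") else
    add("    eps.alpha[a,x,t] <- 0")
  add("    logit(alpha[a,x,t]) <- mu.alpha[a,x] + eps.alpha[a,x,t]%s",
      if (dd_on("alpha")) " + beta.alpha[a,x] * Zlag[t]" else "")
  add("  } } }")
  # male immigration (log link, capped to keep the Poisson mean finite)
  add("mu.om ~ dnorm(0, 0.1)")
  if (re) add("sigma.om ~ dunif(0, 10)
tau.om <- pow(sigma.om, -2)")
  add("for (t in 1:T) {")
  if (re) add("  eps.om[t] ~ dnorm(0, tau.om)") else add("  eps.om[t] <- 0")
  add("  omega[t] <- exp(min(mu.om + eps.om[t], 8))")
  add("}")
  # observation probabilities (logit)
  add("for (x in 1:2) {")
  add("  mu.p[x] ~ dlogis(0, 1)
  mu.r[x] ~ dlogis(0, 1)")
  if (re) add("  sigma.p[x] ~ dunif(0, 10)
  tau.p[x] <- pow(sigma.p[x], -2)
  sigma.r[x] ~ dunif(0, 10)
  tau.r[x] <- pow(sigma.r[x], -2)")
  add("  for (t in 1:T) {")
  if (re) add("    eps.p[x,t] ~ dnorm(0, tau.p[x])
    eps.r[x,t] ~ dnorm(0, tau.r[x])") else
    add("    eps.p[x,t] <- 0
    eps.r[x,t] <- 0")
  add("    logit(p[x,t]) <- mu.p[x] + eps.p[x,t]")
  add("    logit(r[x,t]) <- mu.r[x] + eps.r[x,t]")
  add("  } }")

  if (latent) {
    # ---- latent stage abundances ----
    add("for (x in 1:2) { for (st in 1:6) {")
    add("  NI[st,x] ~ dcat(pinit[1:KI])")
    add("} }")
    add("for (x in 1:2) { for (st in 1:5) { N[st,x,1] <- NI[st,x] - 1 } }")
    add("N[6,1,1] <- 0")
    add("N[6,2,1] <- NI[6,2] - 1")
    add("for (x in 1:2) { N4a[x,1] <- 0
  N4b[x,1] <- N[4,x,1] }")
    add("for (t in 1:(T-1)) {")
    add("  FF[1,t] <- (N[2,1,t]*eta[1,t]*rho[1,t]*xi[1,t] + N[4,1,t]*eta[2,t]*rho[2,t]*xi[2,t] + N[5,1,t]*eta[3,t]*rho[3,t]*xi[3,t])")
    add("  FF[2,t] <- (N[2,1,t]*eta[1,t]*rho[1,t]*(1-xi[1,t]) + N[4,1,t]*eta[2,t]*rho[2,t]*(1-xi[2,t]) + N[5,1,t]*eta[3,t]*rho[3,t]*(1-xi[3,t]))")
    add("  for (x in 1:2) {")
    add("    N[1,x,t+1] ~ dpois(FF[x,t] * s[1,x,t] * (1 - alpha[1,x,t+1]))")
    add("    N[2,x,t+1] ~ dpois(FF[x,t] * s[1,x,t] * alpha[1,x,t+1])")
    add("    N[3,x,t+1] ~ dbin(s[2,x,t] * (1 - alpha[2,x,t+1]), N[1,x,t])")
    add("    N4a[x,t+1] ~ dbin(s[2,x,t] * alpha[2,x,t+1], N[1,x,t])")
    add("    N4b[x,t+1] ~ dbin(s[2,x,t], N[2,x,t])")
    add("    N[4,x,t+1] <- N4a[x,t+1] + N4b[x,t+1]")
    add("    N[5,x,t+1] ~ dbin(s[3,x,t], N[3,x,t] + N[4,x,t] + N[5,x,t] + N[6,x,t])")
    add("  }")
    add("  N[6,1,t+1] <- 0")
    add("  N[6,2,t+1] ~ dpois(omega[t+1])")
    add("}")
    add("for (t in 1:T) { Pairs[t] <- N[2,1,t] + N[4,1,t] + N[5,1,t] }")
    if (length(dd_blocks)) {
      add("for (t in 1:T) { Nfem[t] <- N[1,1,t]+N[2,1,t]+N[3,1,t]+N[4,1,t]+N[5,1,t]")
      add("  Z[t] <- (Nfem[t] - ddc) / dds }")
      add("Zlag[1] <- Z[1]")
      add("for (t in 2:T) { Zlag[t] <- Z[t-1] }")
    }
  }

  if (has("counts"))
    add("for (t in 1:T) { C[t] ~ dpois(Pairs[t]) }")
  if (has("breeders")) {
    add("for (t in 1:T) { for (x in 1:2) {")
    add("  B[t,x,1] ~ dbin(p[x,t], N[2,x,t])")
    add("  B[t,x,2] ~ dbin(p[x,t], N[4,x,t])")
    add("  B[t,x,3] ~ dbin(p[x,t], N[5,x,t] + N[6,x,t])")
    add("} }")
  }
  if (has("success"))
    add("for (i in 1:nS) { sY[i] ~ dbin(eta[sA[i], sT[i]], sN[i]) }")
  if (has("productivity")) {
    # aggregated zero-truncated Poisson via the zeros trick
    add("for (i in 1:nP) {")
    add("  llP[i] <- pS[i] * log(lam[pA[i], pT[i]]) - pNb[i] * lam[pA[i], pT[i]] - pNb[i] * log(1 - exp(-lam[pA[i], pT[i]]))")
    add("  zeroP[i] ~ dpois(BIGC - llP[i])")
    add("}")
  }
  if (has("sexratio"))
    add("for (i in 1:nX) { xY[i] ~ dbin(xi[xA[i], xT[i]], xN[i]) }")
  if (has("cjs")) {
    # release classes pooled to 2: age-1 releases (first interval with s2),
    # and age-2/3+ releases (adult survival throughout) whose cell
    # probabilities are identical and are therefore merged exactly
    add("for (x in 1:2) { for (a in 1:2) { for (t in 1:(T-1)) {")
    add("  cq[x,a,t,1] <- s[six[a,1],x,t]")
    add("  cpr[x,a,t,t] <- cq[x,a,t,1] * p[x,t+1]")
    add("  for (j in (t+1):(T-1)) {")
    add("    cq[x,a,t,j-t+1] <- cq[x,a,t,j-t] * (1 - p[x,j]) * s[six[a,j-t+1],x,j]")
    add("    cpr[x,a,t,j] <- cq[x,a,t,j-t+1] * p[x,j+1]")
    add("  }")
    add("  for (j in 1:(t-1)) { cpr[x,a,t,j] <- 0 }")
    add("  cpr[x,a,t,T] <- 1 - sum(cpr[x,a,t,1:(T-1)])")
    add("  cM[x,a,t,1:T] ~ dmulti(cpr[x,a,t,1:T], cR[x,a,t])")
    add("} } }")
  }
  if (has("recovery")) {
    add("for (x in 1:2) { for (t in 1:(T-1)) {")
    add("  rpr[x,t,t] <- (1 - s[1,x,t]) * r[x,t]")
    add("  rcs[x,t,t] <- s[1,x,t]")
    add("  for (j in (t+1):(T-1)) {")
    add("    rpr[x,t,j] <- rcs[x,t,j-1] * (1 - s[rix[t,j],x,j]) * r[x,j]")
    add("    rcs[x,t,j] <- rcs[x,t,j-1] * s[rix[t,j],x,j]")
    add("  }")
    add("  for (j in 1:(t-1)) { rpr[x,t,j] <- 0 }")
    add("  rpr[x,t,T] <- 1 - sum(rpr[x,t,1:(T-1)])")
    add("  rM[x,t,1:T] ~ dmulti(rpr[x,t,1:T], rR[x,t])")
    add("} }")
  }
  add("}")
  paste(L, collapse = "\n")
}

# ---- data preparation ------------------------------------------------------

# aggregate per-brood tables to (year, age) cells with n > 0
.agg_cells <- function(df, value_fun) {
  if (!nrow(df)) return(NULL)
  key <- interaction(df$year, df$age_class, drop = TRUE)
  sp <- split(df, key)
  data.frame(
    year = vapply(sp, function(d) d$year[1], 0),
    age = vapply(sp, function(d) d$age_class[1], 0),
    n = vapply(sp, nrow, 0L),
    y = vapply(sp, value_fun, 0))
}

.build_jags_data <- function(data, components, dd = NULL) {
  T <- data$years
  has <- function(x) x %in% components
  latent <- has("counts") || has("breeders")
  jd <- list(T = T)
  if (latent) {
    # discrete uniform prior on initial stage abundances: 0 .. 3x first count
    KI <- 3 * max(data$territory_counts[1], 30) + 1
    jd$KI <- as.integer(KI)
    jd$pinit <- rep(1 / KI, KI)
  }
  if (has("counts")) jd$C <- data$territory_counts
  if (has("breeders")) jd$B <- data$breeder_counts
  if (has("success")) {
    ag <- .agg_cells(data$brood_success, function(d) sum(d$success))
    if (is.null(ag)) stop("success component requested but no brood data",
                          call. = FALSE)
    jd$nS <- nrow(ag); jd$sY <- ag$y; jd$sN <- ag$n
    jd$sA <- ag$age; jd$sT <- ag$year
  }
  if (has("productivity")) {
    ag <- .agg_cells(data$brood_fledglings, function(d) sum(d$count))
    if (is.null(ag)) stop("productivity component requested but no brood data",
                          call. = FALSE)
    jd$nP <- nrow(ag); jd$pS <- ag$y; jd$pNb <- ag$n
    jd$pA <- ag$age; jd$pT <- ag$year
    jd$zeroP <- rep(0, nrow(ag)); jd$BIGC <- 10000
  }
  if (has("sexratio")) {
    bx <- data$brood_sex
    bx <- bx[bx$n_female + bx$n_male > 0, , drop = FALSE]
    ag <- .agg_cells(data.frame(year = bx$year, age_class = bx$age_class,
                                nf = bx$n_female, nn = bx$n_female + bx$n_male),
                     function(d) sum(d$nf))
    if (is.null(ag)) stop("sexratio component requested but no sexed broods",
                          call. = FALSE)
    nn <- tapply(bx$n_female + bx$n_male,
                 interaction(bx$year, bx$age_class, drop = TRUE), sum)
    jd$nX <- nrow(ag); jd$xY <- ag$y; jd$xN <- as.integer(nn)
    jd$xA <- ag$age; jd$xT <- ag$year
  }
  if (has("cjs")) {
    ma <- cjs_marray(data$adult_cr, T)
    # pool the age-2 and age-3+ release classes (identical cell probabilities)
    cM <- array(0L, c(2, 2, T - 1, T)); cR <- array(0L, c(2, 2, T - 1))
    cM[, 1, , ] <- ma$m[, 1, , ]
    cM[, 2, , ] <- ma$m[, 2, , ] + ma$m[, 3, , ]
    cR[, 1, ] <- ma$R[, 1, ]
    cR[, 2, ] <- ma$R[, 2, ] + ma$R[, 3, ]
    jd$cM <- cM; jd$cR <- cR
    six <- rbind(pmin(1 + seq_len(T - 1), 3), rep(3L, T - 1))
    jd$six <- six
  }
  if (has("recovery")) {
    ma <- rec_marray(data$recoveries, T)
    jd$rM <- ma$m; jd$rR <- ma$R
    rix <- matrix(1L, T - 1, T - 1)
    for (t in seq_len(T - 1)) for (j in seq_len(T - 1))
      if (j >= t) rix[t, j] <- min(j - t + 1L, 3L)
    jd$rix <- rix
  }
  if (!is.null(dd)) { jd$ddc <- dd$center; jd$dds <- dd$scale }
  jd
}

# initial values; `inflate` grows the latent abundances on retry
.build_inits <- function(data, components, config, chain, inflate = 1,
                         random_effects = TRUE, dd_blocks = character(0)) {
  T <- data$years
  has <- function(x) x %in% components
  latent <- has("counts") || has("breeders")
  ini <- list(
    mu.s = matrix(stats::qlogis(c(0.35, 0.65, 0.80)), 3, 2),
    mu.eta = stats::qlogis(c(0.6, 0.7, 0.8)),
    mu.lam = c(1.5, 1.8, 2.0),
    mu.xi = stats::qlogis(c(0.45, 0.45, 0.45)),
    mu.alpha = matrix(stats::qlogis(0.3), 2, 2),
    mu.om = log(2),
    mu.p = stats::qlogis(c(0.5, 0.5)),
    mu.r = stats::qlogis(c(0.1, 0.1)),
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = config$seed * 1000L + chain)
  if (random_effects) {
    ini$sigma.s <- matrix(0.2, 3, 2); ini$eps.s <- array(0, c(3, 2, T))
    ini$sigma.eta <- rep(0.2, 3); ini$eps.eta <- matrix(0, 3, T)
    ini$sigma.lam <- rep(0.2, 3); ini$eps.lam <- matrix(0, 3, T)
    ini$sigma.xi <- rep(0.2, 3); ini$eps.xi <- matrix(0, 3, T)
    ini$sigma.alpha <- matrix(0.2, 2, 2); ini$eps.alpha <- array(0, c(2, 2, T))
    ini$sigma.om <- 0.2; ini$eps.om <- rep(0, T)
    ini$sigma.p <- rep(0.2, 2); ini$eps.p <- matrix(0, 2, T)
    ini$sigma.r <- rep(0.2, 2); ini$eps.r <- matrix(0, 2, T)
  }
  for (bl in dd_blocks) {
    nm <- switch(bl, s = "beta.s", eta = "beta.eta", rho = "beta.lam",
                 xi = "beta.xi", alpha = "beta.alpha")
    ini[[nm]] <- switch(bl, s = matrix(0, 3, 2), alpha = matrix(0, 2, 2),
                        rep(0, 3))
  }
  if (latent) {
    C <- if (has("counts")) data$territory_counts else
      pmax(apply(data$breeder_counts[, 1, , drop = FALSE], 1, sum), 5)
    B <- if (has("breeders")) data$breeder_counts else array(0L, c(T, 2, 3))
    mC <- max(C, 10)
    # generous smooth latent inits consistent with every binomial constraint
    N1 <- pmax(ceiling(0.7 * mC), max(B[, , 2]) + 8, 12) * inflate
    N3 <- pmax(8, ceiling(0.2 * mC)) * inflate
    N2 <- pmax(t(B[, , 1]) + 4, 6) * inflate   # 2 x T
    N4a <- pmax(t(B[, , 2]) + 3, 4) * inflate
    N4b <- matrix(2 * inflate, 2, T)
    N5 <- pmax(max(B[, , 3]) + ceiling(0.5 * mC), mC) * inflate
    N <- array(NA_real_, c(6, 2, T))
    N[1, , ] <- N1; N[3, , ] <- N3
    N[2, , ] <- N2
    N[5, , ] <- N5
    N6 <- matrix(NA_real_, 2, T); N6[2, ] <- 2
    NI <- matrix(NA_real_, 6, 2)
    NI[1:5, 1] <- c(N1, N2[1, 1], N3, N4a[1, 1] + N4b[1, 1], N5) + 1
    NI[1:5, 2] <- c(N1, N2[2, 1], N3, N4a[2, 1] + N4b[2, 1], N5) + 1
    NI[6, 2] <- 3
    # stochastic nodes only: N stages 1,2,3,5 (t >= 2), N6 male, N4a/N4b
    Nini <- array(NA_real_, c(6, 2, T))
    Nini[1, , 2:T] <- N1; Nini[2, , 2:T] <- N2[, 2:T]
    Nini[3, , 2:T] <- N3; Nini[5, , 2:T] <- N5
    Nini[6, 2, 2:T] <- 2
    N4ai <- matrix(NA_real_, 2, T); N4ai[, 2:T] <- N4a[, 2:T]
    N4bi <- matrix(NA_real_, 2, T); N4bi[, 2:T] <- N4b[, 2:T]
    KI <- 3 * max(data$territory_counts[1], 30) + 1
    ini$NI <- pmin(round(NI), KI)
    ini$N <- round(Nini)
    ini$N4a <- round(N4ai); ini$N4b <- round(N4bi)
  }
  ini
}

# split-half R-hat over a list of per-chain draw matrices
.split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE]),
                list(ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, stats::var))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  out <- sqrt(((n - 1) / n * W + B / n) / W)
  out[W < 1e-12] <- NA_real_
  stats::setNames(out, colnames(chains[[1]]))
}

# parse a coda matrix into named arrays keyed by parameter
.extract_draws <- function(mat, name, dims) {
  if (length(dims) == 0) {
    col <- which(colnames(mat) == name)
    if (!length(col)) return(NULL)
    return(mat[, col])
  }
  pat <- paste0("^", gsub("\\.", "\\\\.", name), "\\[")
  cols <- grep(pat, colnames(mat))
  if (!length(cols)) return(NULL)
  out <- array(NA_real_, c(nrow(mat), dims))
  idx <- colnames(mat)[cols]
  pos <- do.call(rbind, lapply(strsplit(gsub("^[^\\[]+\\[|\\]$", "", idx), ","),
                               as.integer))
  for (k in seq_along(cols)) {
    ii <- cbind(seq_len(nrow(mat)),
                matrix(pos[k, ], nrow(mat), length(dims), byrow = TRUE))
    out[ii] <- mat[, cols[k]]
  }
  out
}

#' Fit the two-sex integrated population model
#'
#' Joint Bayesian analysis of (any subset of) the seven monitoring data sets:
#' MCMC over the posterior of all demographic and observation rates, their
#' temporal random effects, and the latent stage abundances.  Priors are
#' vague: logistic(0,1) on logit-scale means (uniform on the probability
#' scale), Normal(0, 10^2) on the identity/log-scale means, Uniform(0, 10) on
#' temporal SDs, and a discrete uniform on the initial stage abundances.
#'
#' @param data a [monitoring_data()] object.
#' @param config an [ipm_config()].
#' @param dd optional density dependence: list with `rates` (character subset
#'   of `c("s", "eta", "rho", "xi", "alpha")`), `center` and `scale` for the
#'   standardized female-total covariate (defaults: mean and SD of the
#'   territory counts).  Adds link-scale slopes `beta` for each selected rate.
#' @return an object of class `hawk_ipm`: posterior draws (arrays with the
#'   draw index first), convergence diagnostics, the model string and the
#'   data/config used.
#' @export
fit_ipm <- function(data, config = ipm_config(), dd = NULL) {
  stopifnot(inherits(data, "monitoring_data"))
  validate_monitoring_data(data)
  t0 <- Sys.time()
  comps <- config$components
  dd_blocks <- character(0)
  if (!is.null(dd)) {
    dd_blocks <- match.arg(dd$rates, c("s", "eta", "rho", "xi", "alpha"),
                           several.ok = TRUE)
    if (is.null(dd$center)) dd$center <- mean(data$territory_counts)
    if (is.null(dd$scale)) dd$scale <- max(stats::sd(data$territory_counts), 1)
  }
  model_str <- .build_model(comps, config$random_effects, dd_blocks)
  jd <- .build_jags_data(data, comps, dd)
  latent <- any(c("counts", "breeders") %in% comps)

  mod <- NULL
  for (try in 1:4) {
    inits <- lapply(seq_len(config$n_chains), function(ch)
      .build_inits(data, comps, config, ch, inflate = 1.4^(try - 1),
                   random_effects = config$random_effects, dd_blocks = dd_blocks))
    mod <- tryCatch(
      rjags::jags.model(textConnection(model_str), data = jd, inits = inits,
                        n.chains = config$n_chains, n.adapt = config$n_adapt,
                        quiet = config$quiet),
      error = function(e) e)
    if (!inherits(mod, "error")) break
  }
  if (inherits(mod, "error"))
    stop("JAGS initialization failed after retries: ",
         conditionMessage(mod), call. = FALSE)
  stats::update(mod, config$n_burnin)

  monitors <- c("mu.s", "mu.eta", "mu.lam", "mu.xi", "mu.alpha", "mu.om",
                "mu.p", "mu.r", "s", "eta", "rho", "xi", "alpha", "omega",
                "p", "r")
  if (config$random_effects)
    monitors <- c(monitors, "sigma.s", "sigma.eta", "sigma.lam", "sigma.xi",
                  "sigma.alpha", "sigma.om", "sigma.p", "sigma.r")
  if (latent && config$monitor_latent)
    monitors <- c(monitors, "N", "N4a", "N4b")
  if (length(dd_blocks))
    monitors <- c(monitors, paste0("beta.", vapply(dd_blocks, function(b)
      switch(b, rho = "lam", b), "")))
  sm <- rjags::coda.samples(mod, monitors,
                            n.iter = config$n_iter - config$n_burnin,
                            thin = config$thin)
  chains <- lapply(sm, as.matrix)
  mat <- do.call(rbind, chains)
  T <- data$years
  draws <- list(
    mu = list(s = .extract_draws(mat, "mu.s", c(3, 2)),
              eta = .extract_draws(mat, "mu.eta", 3),
              lam = .extract_draws(mat, "mu.lam", 3),
              xi = .extract_draws(mat, "mu.xi", 3),
              alpha = .extract_draws(mat, "mu.alpha", c(2, 2)),
              om = .extract_draws(mat, "mu.om", integer(0)),
              p = .extract_draws(mat, "mu.p", 2),
              r = .extract_draws(mat, "mu.r", 2)),
    s = .extract_draws(mat, "s", c(3, 2, T)),
    eta = .extract_draws(mat, "eta", c(3, T)),
    rho = .extract_draws(mat, "rho", c(3, T)),
    xi = .extract_draws(mat, "xi", c(3, T)),
    alpha = .extract_draws(mat, "alpha", c(2, 2, T)),
    omega = .extract_draws(mat, "omega", T),
    p = .extract_draws(mat, "p", c(2, T)),
    r = .extract_draws(mat, "r", c(2, T)))
  if (config$random_effects)
    draws$sigma <- list(s = .extract_draws(mat, "sigma.s", c(3, 2)),
                        eta = .extract_draws(mat, "sigma.eta", 3),
                        lam = .extract_draws(mat, "sigma.lam", 3),
                        xi = .extract_draws(mat, "sigma.xi", 3),
                        alpha = .extract_draws(mat, "sigma.alpha", c(2, 2)),
                        om = .extract_draws(mat, "sigma.om", integer(0)),
                        p = .extract_draws(mat, "sigma.p", 2),
                        r = .extract_draws(mat, "sigma.r", 2))
  if (latent && config$monitor_latent) {
    draws$N <- .extract_draws(mat, "N", c(6, 2, T))
    draws$N4a <- .extract_draws(mat, "N4a", c(2, T))
    draws$N4b <- .extract_draws(mat, "N4b", c(2, T))
  }
  if (length(dd_blocks)) {
    draws$beta <- list()
    for (b in dd_blocks) {
      nm <- switch(b, rho = "lam", b)
      dims <- switch(b, s = c(3, 2), alpha = c(2, 2), 3)
      draws$beta[[b]] <- .extract_draws(mat, paste0("beta.", nm), dims)
    }
    draws$dd <- list(rates = dd_blocks, center = dd$center, scale = dd$scale)
  }
  rhat <- .split_rhat(chains)
  ess <- tryCatch(coda::effectiveSize(sm), error = function(e) NULL)
  structure(list(draws = draws, rhat = rhat, ess = ess,
                 n_draws = nrow(mat), data = data, config = config,
                 dd = if (length(dd_blocks)) dd else NULL,
                 model = model_str,
                 runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "hawk_ipm")
}

#' Fit the density-dependent IPM variant
#'
#' Same as [fit_ipm()] but with link-scale means `mu_theta + beta_theta *
#' Z_t` for the selected rates, where `Z_t` is the standardized total number
#' of females in year `t` (recruitment and immigration respond to the
#' previous year's total).  With an empty `rates_with_dd` this reduces
#' exactly to [fit_ipm()].
#'
#' @inheritParams fit_ipm
#' @param rates_with_dd character subset of
#'   `c("s", "eta", "rho", "xi", "alpha")`.
#' @param center,scale standardization of the female-total covariate
#'   (defaults: mean and SD of the territory counts).
#' @return a `hawk_ipm` object with additional `beta` draws; use
#'   [dd_beta_summary()] to check which credible intervals exclude zero.
#' @export
fit_ipm_dd <- function(data, config = ipm_config(),
                       rates_with_dd = c("s", "eta", "rho", "xi", "alpha"),
                       center = NULL, scale = NULL) {
  if (!length(rates_with_dd)) return(fit_ipm(data, config))
  fit_ipm(data, config,
          dd = list(rates = rates_with_dd, center = center, scale = scale))
}

#' Summarize density-dependence strengths from a [fit_ipm_dd()] fit
#'
#' @param fit a `hawk_ipm` with `beta` draws.
#' @param prob credible level (default 0.95).
#' @return data frame: rate, posterior mean, CRI bounds, and whether the CRI
#'   includes zero.
#' @export
dd_beta_summary <- function(fit, prob = 0.95) {
  stopifnot(!is.null(fit$draws$beta))
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  rows <- list()
  lab <- list(s = outer(1:3, .SEXES, function(a, x) paste0("s[", a, ",", x, "]")),
              eta = paste0("eta[", 1:3, "]"),
              rho = paste0("rho[", 1:3, "]"),
              xi = paste0("xi[", 1:3, "]"),
              alpha = outer(1:2, .SEXES, function(a, x)
                paste0("alpha[", a, ",", x, "]")))
  for (b in names(fit$draws$beta)) {
    dr <- fit$draws$beta[[b]]
    dm <- dim(dr)[-1]
    flat <- matrix(dr, nrow = dim(dr)[1])
    nms <- as.character(lab[[b]])
    for (k in seq_len(ncol(flat))) {
      ci <- stats::quantile(flat[, k], qs, names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        rate = nms[k], mean = mean(flat[, k]), lower = ci[1], upper = ci[2],
        includes_zero = ci[1] <= 0 && ci[2] >= 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
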