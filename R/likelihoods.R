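# The seven component log-likelihoods of the integrated model, and their sum.
#
# Each component is a pure function of data + latent quantities so it can be
# checked against enumeration oracles independently of the MCMC machinery.
# Data that are impossible under the latent state return -Inf (never an
# error), so samplers can reject.

#' Zero-truncated Poisson log-density
#'
#' @param x counts (>= 1).
#' @param lambda rate of the underlying Poisson.
#' @param log return log-density (default TRUE).
#' @return (log-)densities; `-Inf` for x < 1.
#' @export
dztpois <- function(x, lambda, log = TRUE) {
  ll <- ifelse(x >= 1,
               stats::dpois(x, lambda, log = TRUE) - log(-expm1(-lambda)),
               -Inf)
  if (log) ll else exp(ll)
}

#' Territory-count log-likelihood
#'
#' Observation model for the annual counts of occupied territories given the
#' latent number of breeding pairs (breeding females, stages 2 + 4 + 5):
#' Poisson by default, or Normal with a given observation SD.
#'
#' @param counts integer vector of annual counts.
#' @param trajectory an `ipm_trajectory` or 6 x 2 x years array.
#' @param model `"poisson"` (default) or `"normal"`.
#' @param sd observation SD for the normal model.
#' @return total log-likelihood.
#' @export
loglik_counts <- function(counts, trajectory, model = c("poisson", "normal"),
                          sd = NULL) {
  model <- match.arg(model)
  if (any(counts < 0)) stop("territory counts must be non-negative", call. = FALSE)
  pairs <- breeding_pairs(trajectory)
  if (length(counts) != length(pairs))
    stop("counts and trajectory length differ", call. = FALSE)
  if (model == "poisson") {
    sum(stats::dpois(counts, pairs, log = TRUE))
  } else {
    if (is.null(sd)) stop("normal counts model needs sd", call. = FALSE)
    sum(stats::dnorm(counts, pairs, sd, log = TRUE))
  }
}

# latent class sizes behind the breeder-count observations:
# class 1 = stage 2, class 2 = stage 4, class 3+ = stage 5 (+ 6 for males)
.breeder_class_sizes <- function(N) {
  T <- dim(N)[3]
  out <- array(0, c(T, 2, 3))
  out[, , 1] <- t(N[2, , ])
  out[, , 2] <- t(N[4, , ])
  out[, 1, 3] <- N[5, 1, ]
  out[, 2, 3] <- N[5, 2, ] + N[6, 2, ]
  out
}

#' Sex- and age-specific breeder-count log-likelihood
#'
#' Binomial thinning of the true breeder class sizes with the sex- and
#' year-specific resighting probability shared with the capture-recapture
#' component.
#'
#' @param breeder_counts `years x 2 x 3` array of identified breeders.
#' @param trajectory latent trajectory (array or `ipm_trajectory`).
#' @param p resighting probabilities, `2 x years` matrix (rows `f`, `m`) or
#'   length-2 vector recycled over years.
#' @return total log-likelihood (`-Inf` if any observed count exceeds its
#'   latent class size).
#' @export
loglik_breeder_counts <- function(breeder_counts, trajectory, p) {
  N <- if (inherits(trajectory, "ipm_trajectory")) trajectory$N else trajectory
  T <- dim(N)[3]
  if (!is.matrix(p)) p <- matrix(p, 2, T)
  cls <- .breeder_class_sizes(N)
  ll <- 0
  for (ix in 1:2) for (a in 1:3) {
    lt <- stats::dbinom(breeder_counts[, ix, a], round(cls[, ix, a]), p[ix, ],
                        log = TRUE)
    ll <- ll + sum(lt)
  }
  ll
}

#' Brood-success log-likelihood
#'
#' Bernoulli per brood with the maternal-age-specific breeding success.
#'
#' @param brood_success data frame `year`, `age_class`, `success`.
#' @param eta `3 x years` matrix (or length-3 vector) of success
#'   probabilities.
#' @return total log-likelihood.
#' @export
loglik_success <- function(brood_success, eta) {
  if (!nrow(brood_success)) return(0)
  if (!is.matrix(eta)) eta <- matrix(eta, 3, max(brood_success$year))
  pr <- eta[cbind(brood_success$age_class, brood_success$year)]
  sum(stats::dbinom(brood_success$success, 1, pr, log = TRUE))
}

#' Brood-size (productivity) log-likelihood
#'
#' Zero-truncated Poisson for the fledgling counts of successful broods.
#' Under the default `"mean"` parameterization `rho` is the mean brood size
#' (> 1) and the rate is solved internally, which is the form consistent with
#' the projection model; `"rate"` treats `rho` directly as the truncated
#' Poisson rate.
#'
#' @param brood_fledglings data frame `year`, `age_class`, `count` (>= 1).
#' @param rho `3 x years` matrix (or length-3 vector) of productivity
#'   parameters.
#' @param parameterization `"mean"` or `"rate"`.
#' @return total log-likelihood.
#' @export
loglik_productivity <- function(brood_fledglings, rho,
                                parameterization = c("mean", "rate")) {
  parameterization <- match.arg(parameterization)
  if (!nrow(brood_fledglings)) return(0)
  if (any(brood_fledglings$count < 1))
    stop("brood_fledglings: successful broods must have count >= 1",
         call. = FALSE)
  if (!is.matrix(rho)) rho <- matrix(rho, 3, max(brood_fledglings$year))
  lam <- if (parameterization == "mean") {
    lr <- rho
    lr[] <- ztp_rate(pmax(rho, 1 + 1e-9))
    lr
  } else rho
  lm <- lam[cbind(brood_fledglings$age_class, brood_fledglings$year)]
  sum(dztpois(brood_fledglings$count, lm))
}

#' Fledgling sex-ratio log-likelihood
#'
#' Binomial for the number of female fledglings among the sexed fledglings
#' of each brood, with maternal-age-specific proportion of females.
#'
#' @param brood_sex data frame `year`, `age_class`, `n_female`, `n_male`.
#' @param xi `3 x years` matrix (or length-3 vector).
#' @return total log-likelihood.
#' @export
loglik_sexratio <- function(brood_sex, xi) {
  if (!nrow(brood_sex)) return(0)
  if (!is.matrix(xi)) xi <- matrix(xi, 3, max(brood_sex$year))
  pr <- xi[cbind(brood_sex$age_class, brood_sex$year)]
  n <- brood_sex$n_female + brood_sex$n_male
  sum(stats::dbinom(brood_sex$n_female, n, pr, log = TRUE))
}

# survival index for a bird of age class a (1/2/3+) over the coming interval:
# 1-y birds survive with s2, older birds with s3
.cjs_surv_index <- function(a) pmin(a + 1L, 3L)

#' Adult capture-recapture (CJS) log-likelihood
#'
#' Cormack-Jolly-Seber likelihood conditioned on first identification, with
#' sex- and age-specific survival (the age class advances 1 -> 2 -> 3+ along
#' the history) and sex- and year-specific resighting probability.  First-year
#' survival never enters: birds are identified as breeders aged >= 1.
#'
#' @param adult_cr list with `history` (0/1 matrix), `sex`, `age_first` as in
#'   [monitoring_data()].
#' @param s survival array `3 x 2 x years` (age, sex, year).
#' @param p `2 x years` matrix of resighting probabilities.
#' @return total log-likelihood.
#' @export
loglik_adult_cr <- function(adult_cr, s, p) {
  H <- adult_cr$history
  if (!nrow(H)) return(0)
  T <- ncol(H)
  if (!is.matrix(p)) p <- matrix(p, 2, T)
  ll <- 0
  for (i in seq_len(nrow(H))) {
    h <- H[i, ]
    f <- which(h == 1L)[1]
    if (is.na(f)) stop("adult_cr: history without initial identification",
                       call. = FALSE)
    ix <- match(adult_cr$sex[i], .SEXES)
    a <- adult_cr$age_first[i]
    last <- max(which(h == 1L))
    lp <- 0
    if (last > f) {
      for (t in f:(last - 1)) {
        cls <- min(a + (t - f), 3L)
        lp <- lp + log(s[.cjs_surv_index(cls), ix, t])
        lp <- lp + if (h[t + 1] == 1L) log(p[ix, t + 1]) else log(1 - p[ix, t + 1])
      }
    }
    # probability of never being seen after `last`
    chi <- 1
    if (last < T) {
      for (t in (T - 1):last) {
        cls <- min(a + (t - f), 3L)
        sv <- s[.cjs_surv_index(cls), ix, t]
        chi <- (1 - sv) + sv * (1 - p[ix, t + 1]) * chi
      }
    }
    ll <- ll + lp + log(chi)
  }
  ll
}

#' Dead-recovery log-likelihood for ringed nestlings
#'
#' Seber-style ring-recovery model: a bird ringed as a nestling in year `t0`
#' dies in interval `k` (year `k` to `k + 1`) with probability
#' `prod_{j<k} s_age(j) * (1 - s_age(k))` where the age-specific survival
#' follows the intervals (first interval: first-year survival s1, second: s2,
#' later: s3), and a death is reported with the sex-specific recovery
#' probability of that interval.  Birds never recovered contribute the
#' complementary probability (died unrecovered or survived to the horizon).
#'
#' @param recoveries data frame `id`, `sex`, `ring_year`, `recovery_year`
#'   (`NA` if never recovered).
#' @param s survival array `3 x 2 x years`.
#' @param r `2 x years` matrix of recovery probabilities (indexed by the
#'   starting year of the death interval).
#' @return total log-likelihood.
#' @export
loglik_recovery <- function(recoveries, s, r) {
  if (!nrow(recoveries)) return(0)
  T <- dim(s)[3]
  if (!is.matrix(r)) r <- matrix(r, 2, T)
  ll <- 0
  for (i in seq_len(nrow(recoveries))) {
    t0 <- recoveries$ring_year[i]
    ix <- match(recoveries$sex[i], .SEXES)
    ry <- recoveries$recovery_year[i]
    if (t0 >= T) {
      # ringed in the final year: no observable interval, contributes 1
      if (!is.na(ry)) return(-Inf)
      next
    }
    pr <- rec_cell_probs(s, r, ix, t0, T)
    if (is.na(ry)) {
      ll <- ll + log(pr[length(pr)])
    } else {
      k <- ry - t0  # 1-based interval index
      if (k < 1 || k > T - t0) return(-Inf)
      ll <- ll + log(pr[k])
    }
  }
  ll
}

#' Log-density of the latent state-space transitions
#'
#' The probability of each year's stage abundances given the previous year
#' under the Poisson/binomial projection: Poisson for the two 1-y stages and
#' the immigrant stage, binomials for the older stages.  The 2-y breeder
#' stage, fed by two binomial sources (recruiting 1-y non-breeders and
#' surviving 1-y breeders), is evaluated by exact convolution.
#'
#' @param trajectory `ipm_trajectory` or 6 x 2 x years integer array.
#' @param rates realized annual rates (`ipm_rates`).
#' @return total log-density (`-Inf` for impossible transitions).
#' @export
loglik_transitions <- function(trajectory, rates) {
  N <- if (inherits(trajectory, "ipm_trajectory")) trajectory$N else trajectory
  T <- dim(N)[3]
  ll <- 0
  for (t in seq_len(T - 1)) {
    rt <- rates_at(rates, t); rt1 <- rates_at(rates, t + 1)
    fl <- .fledglings_expected(N[, , t], rt)
    for (ix in 1:2) {
      x <- .SEXES[ix]
      s1 <- rt$s[1, x]; s2 <- rt$s[2, x]; s3 <- rt$s[3, x]
      a1 <- rt1$alpha[1, x]; a2 <- rt1$alpha[2, x]
      ll <- ll + stats::dpois(N[1, ix, t + 1], fl[[x]] * s1 * (1 - a1), log = TRUE)
      ll <- ll + stats::dpois(N[2, ix, t + 1], fl[[x]] * s1 * a1, log = TRUE)
      ll <- ll + stats::dbinom(N[3, ix, t + 1], N[1, ix, t], s2 * (1 - a2),
                               log = TRUE)
      # N4' = Bin(N1, s2 a2) + Bin(N2, s2): exact convolution
      n4 <- N[4, ix, t + 1]
      ks <- 0:min(n4, N[1, ix, t])
      pk <- stats::dbinom(ks, N[1, ix, t], s2 * a2) *
        stats::dbinom(n4 - ks, N[2, ix, t], s2)
      ll <- ll + log(sum(pk))
      pool <- N[3, ix, t] + N[4, ix, t] + N[5, ix, t] + N[6, ix, t]
      ll <- ll + stats::dbinom(N[5, ix, t + 1], pool, s3, log = TRUE)
    }
    ll <- ll + stats::dpois(N[6, 2, t + 1], rt1$omega, log = TRUE)
    if (N[6, 1, t + 1] != 0) ll <- -Inf
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Joint log-likelihood of the integrated model
#'
#' Sum of the seven component log-likelihoods plus the latent state-space
#' transition density.
#'
#' @param data a [monitoring_data()] object.
#' @param context list with `trajectory` (latent abundances), `rates`
#'   (realized annual demographic rates), `p` and `r` (`2 x years` observation
#'   probabilities).
#' @param components character subset of
#'   `c("counts", "breeders", "success", "productivity", "sexratio", "cjs",
#'   "recovery")` to include (default all).
#' @param transitions include the latent transition density (default TRUE).
#' @param counts_model,counts_sd passed to [loglik_counts()].
#' @return total joint log-likelihood.
#' @export
joint_loglik <- function(data, context, components = c("counts", "breeders",
                         "success", "productivity", "sexratio", "cjs",
                         "recovery"), transitions = TRUE,
                         counts_model = "poisson", counts_sd = NULL) {
  tr <- context$trajectory
  rates <- context$rates
  ll <- 0
  if ("counts" %in% components)
    ll <- ll + loglik_counts(data$territory_counts, tr, counts_model, counts_sd)
  if ("breeders" %in% components)
    ll <- ll + loglik_breeder_counts(data$breeder_counts, tr, context$p)
  if ("success" %in% components)
    ll <- ll + loglik_success(data$brood_success, rates$eta)
  if ("productivity" %in% components)
    ll <- ll + loglik_productivity(data$brood_fledglings, rates$rho)
  if ("sexratio" %in% components)
    ll <- ll + loglik_sexratio(data$brood_sex, rates$xi)
  if ("cjs" %in% components)
    ll <- ll + loglik_adult_cr(data$adult_cr, rates$s, context$p)
  if ("recovery" %in% components)
    ll <- ll + loglik_recovery(data$recoveries, rates$s, context$r)
  if (transitions)
    ll <- ll + loglik_transitions(tr, rates)
  ll
}
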