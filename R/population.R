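# Two-sex stage-structured projection.
#
# Stages (pre-breeding census):
#   1 = 1-y non-breeder, 2 = 1-y breeder, 3 = 2-y non-breeder, 4 = 2-y breeder,
#   5 = 3y+ breeder, 6 = immigrant breeder (males only, current year's arrivals;
#   they join stage 5 from the following year on).

#' Construct a population state
#'
#' @param f female stage abundances, length 5 (stages 1-5).
#' @param m male stage abundances, length 6 (stages 1-6; stage 6 holds the
#'   current year's immigrant breeders).
#' @return a 6 x 2 integer matrix of class `ipm_state` (female stage 6 is
#'   structurally zero).
#' @export
ipm_state <- function(f, m) {
  if (length(f) != 5L || length(m) != 6L)
    stop("need 5 female and 6 male stage abundances", call. = FALSE)
  N <- cbind(f = c(f, 0), m = m)
  rownames(N) <- .STAGES
  validate_state(N)
  structure(N, class = c("ipm_state", "matrix"))
}

validate_state <- function(N) {
  if (any(!is.finite(N)) || any(N < 0))
    stop("stage abundances must be non-negative", call. = FALSE)
  if (N[6, "f"] != 0)
    stop("stage 6 (immigrants) exists only for males", call. = FALSE)
  invisible(TRUE)
}

# expected female and male fledgling production of a state under rates r
.fledglings_expected <- function(N, r) {
  brood <- N[c(2, 4, 5), 1]                 # breeding females by age class
  tot <- brood * r$eta * r$rho                # expected fledglings per class
  c(f = sum(tot * r$xi), m = sum(tot * (1 - r$xi)))
}

#' Expected next-year state of the two-sex projection
#'
#' Returns the exact means of the Poisson/binomial stage distributions: the
#' female (and analogously male) fledglings produced by the three breeding
#' female age classes survive their first year and recruit (or not) with the
#' following year's recruitment probability; 1-y birds survive and possibly
#' recruit; all 2y+ breeders (plus the current male immigrants) survive into
#' the adult breeder stage; the expected number of new male immigrants is the
#' following year's immigration rate.
#'
#' @param state an [ipm_state()] (or 6 x 2 matrix) at year `t`.
#' @param rates year-`t` demographic rates (a single-year list as returned by
#'   internal extraction from an `ipm_rates` object, or any list with elements
#'   `s`, `eta`, `rho`, `xi`).
#' @param rates_next year-`t+1` rates; only its `alpha` and `omega` are used
#'   (recruitment and immigration are indexed by the year of arrival).
#' @return 6 x 2 real-valued matrix of expected abundances at `t + 1`.
#' @export
expected_next_state <- function(state, rates, rates_next) {
  validate_state(state)
  validate_rates_year(utils::modifyList(rates, rates_next[c("alpha", "omega")]))
  validate_rates_year(rates)
  .expected_step(state, rates, rates_next)
}

# validation-free core of the expected projection (hot path for draw-wise
# posterior analyses)
.expected_step <- function(state, rates, rates_next) {
  fl <- .fledglings_expected(state, rates)
  out <- matrix(0, 6, 2, dimnames = list(.STAGES, .SEXES))
  for (ix in 1:2) {
    s1 <- rates$s[1, ix]; s2 <- rates$s[2, ix]; s3 <- rates$s[3, ix]
    a1 <- rates_next$alpha[1, ix]; a2 <- rates_next$alpha[2, ix]
    out[1, ix] <- fl[[ix]] * s1 * (1 - a1)
    out[2, ix] <- fl[[ix]] * s1 * a1
    out[3, ix] <- state[1, ix] * s2 * (1 - a2)
    out[4, ix] <- state[1, ix] * s2 * a2 + state[2, ix] * s2
    pool <- state[3, ix] + state[4, ix] + state[5, ix] + state[6, ix]
    out[5, ix] <- pool * s3
  }
  out[6, 2] <- rates_next$omega
  out
}

# One stochastic step for n parallel populations.
# N: 6 x 2 x n array; rate elements may be scalars or length-n vectors.
# Returns list(N = 6 x 2 x n, recruits2y = 2 x n matrix of the stage-4 birds
# that newly recruited from stage 1, used for first-time/experienced breeder
# bookkeeping).
.step_multi <- function(N, rates, rates_next, n) {
  out <- array(0, c(6, 2, n))
  rec <- matrix(0, 2, n, dimnames = list(.SEXES, NULL))
  # expected fledglings per population (vectorized over n)
  eta <- matrix(rates$eta, 3, n); rho <- matrix(rates$rho, 3, n)
  xi <- matrix(rates$xi, 3, n)
  brood <- N[c(2, 4, 5), 1, , drop = FALSE]  # breeding females
  dim(brood) <- c(3, n)
  tot <- brood * eta * rho
  flf <- colSums(tot * xi); flm <- colSums(tot * (1 - xi))
  for (ix in 1:2) {
    x <- .SEXES[ix]
    s1 <- rep(rates$s[1, x], length.out = n)
    s2 <- rep(rates$s[2, x], length.out = n)
    s3 <- rep(rates$s[3, x], length.out = n)
    a1 <- rep(rates_next$alpha[1, x], length.out = n)
    a2 <- rep(rates_next$alpha[2, x], length.out = n)
    fl <- if (x == "f") flf else flm
    out[1, ix, ] <- stats::rpois(n, fl * s1 * (1 - a1))
    out[2, ix, ] <- stats::rpois(n, fl * s1 * a1)
    # conserving multinomial split of the stage-1 pool: survive, then recruit
    surv1 <- stats::rbinom(n, N[1, ix, ], s2)
    rec2 <- stats::rbinom(n, surv1, a2)
    out[3, ix, ] <- surv1 - rec2
    out[4, ix, ] <- rec2 + stats::rbinom(n, N[2, ix, ], s2)
    rec[ix, ] <- rec2
    pool <- N[3, ix, ] + N[4, ix, ] + N[5, ix, ] + N[6, ix, ]
    out[5, ix, ] <- stats::rbinom(n, pool, s3)
  }
  om <- rep(rates_next$omega, length.out = n)
  out[6, 2, ] <- stats::rpois(n, om)
  list(N = out, recruits2y = rec)
}

#' Stochastic next-year state
#'
#' Draws the year-`t+1` state from the Poisson/binomial transition
#' distributions.  Binomial transitions respect their source pools: survivors
#' of the 1-y stage are split between recruiting and non-recruiting by a
#' conserving multinomial scheme whose margins equal the stated binomials, and
#' adult-breeder survivors are drawn from the pooled 2y+/adult/immigrant
#' breeders.
#'
#' @inheritParams expected_next_state
#' @param seed optional integer seed.
#' @return an [ipm_state()] at year `t + 1`.
#' @export
stochastic_next_state <- function(state, rates, rates_next, seed = NULL) {
  validate_state(state)
  validate_rates_year(utils::modifyList(rates, rates_next[c("alpha", "omega")]))
  validate_rates_year(rates)
  if (!is.null(seed)) set.seed(seed)
  N <- array(as.numeric(state), c(6, 2, 1))
  st <- .step_multi(N, rates, rates_next, 1L)
  ipm_state(st$N[1:5, 1, 1], st$N[, 2, 1])
}

#' Project a population trajectory
#'
#' Draws annual demographic rates from the temporal random-effect
#' distributions on the link scales and iterates the two-sex projection.
#' In `"expected"` mode the means are propagated with no demographic
#' sampling (real-valued abundances); rates are still drawn unless all
#' temporal SDs are zero.
#'
#' @param initial an [ipm_state()].
#' @param hyper an [ipm_hyper()] object.
#' @param years number of annual occasions (>= 2).
#' @param mode `"stochastic"` (demographic noise) or `"expected"`.
#' @param seed optional integer seed.
#' @param dd optional density-dependence specification: a list with `beta`
#'   (link-scale slopes, any subset of the rate blocks in the shapes of
#'   [ipm_hyper()]; missing blocks mean no feedback), `center` and `scale`
#'   for standardizing the female total used as covariate.  The covariate for
#'   all rates acting on the transition from year `t` is the total number of
#'   females (aged 1+) in year `t`.
#' @return an `ipm_trajectory`: list with `N` (6 x 2 x years array),
#'   `recruits2y` (2 x years; stage-4 birds that are first-time breeders),
#'   `rates` (realized `ipm_rates`) and `years`.
#' @export
project_trajectory <- function(initial, hyper, years,
                               mode = c("stochastic", "expected"),
                               seed = NULL, dd = NULL) {
  mode <- match.arg(mode)
  if (years < 2) stop("years must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  validate_state(initial)
  eps <- draw_rate_effects(hyper, years)
  traj <- .project_with_effects(initial, hyper, eps, years, mode, dd)
  traj
}

# core projection given pre-drawn link-scale deviations.
# Density-dependence convention: the link-scale mean of s, eta, rho, xi in
# year t is offset by beta * std(Nfem_t); recruitment alpha and immigration
# omega carry the year label of the arrival year t+1 but respond to the
# female total of year t (the population recruits and immigrants enter from);
# year 1 uses its own total.
.project_with_effects <- function(initial, hyper, eps, years, mode, dd = NULL) {
  N <- array(0, c(6, 2, years), dimnames = list(.STAGES, .SEXES, NULL))
  rec <- matrix(0, 2, years, dimnames = list(.SEXES, NULL))
  N[, , 1] <- initial
  if (is.null(dd)) {
    rates <- rates_from_effects(hyper, eps)
    for (t in seq_len(years - 1)) {
      adv <- .advance(N[, , t], rates_at(rates, t), rates_at(rates, t + 1), mode)
      N[, , t + 1] <- adv$N
      rec[, t + 1] <- adv$recr
    }
    return(structure(list(N = N, recruits2y = rec, rates = rates, years = years),
                     class = "ipm_trajectory"))
  }
  offs <- lapply(hyper$sigma, function(sg) matrix(0, length(sg), years))
  offs$years <- years
  beta0 <- lapply(hyper$sigma, function(sg) rep(0, length(sg)))
  for (nm in names(dd$beta)) beta0[[nm]] <- as.numeric(dd$beta[[nm]])
  rates <- NULL
  for (t in seq_len(years)) {
    z <- (sum(N[1:5, 1, t]) - dd$center) / dd$scale
    for (nm in c("s", "eta", "rho", "xi"))
      offs[[nm]][, t] <- beta0[[nm]] * z
    if (t == 1)
      for (nm in c("alpha", "omega")) offs[[nm]][, 1] <- beta0[[nm]] * z
    if (t < years) {
      for (nm in c("alpha", "omega")) offs[[nm]][, t + 1] <- beta0[[nm]] * z
      rates <- rates_from_effects(hyper, eps, offs)
      adv <- .advance(N[, , t], rates_at(rates, t), rates_at(rates, t + 1), mode)
      N[, , t + 1] <- adv$N
      rec[, t + 1] <- adv$recr
    }
  }
  rates <- rates_from_effects(hyper, eps, offs)
  structure(list(N = N, recruits2y = rec, rates = rates, years = years),
            class = "ipm_trajectory")
}

# one projection step; returns the new state and the first-time 2-y recruits
.advance <- function(Nt, r_now, r_next, mode) {
  if (mode == "expected") {
    out <- expected_next_state(Nt, r_now, r_next)
    recr <- Nt[1, ] * r_now$s[2, ] * r_next$alpha[2, ]
  } else {
    st <- .step_multi(array(as.numeric(Nt), c(6, 2, 1)), r_now, r_next, 1L)
    out <- st$N[, , 1]
    recr <- st$recruits2y[, 1]
  }
  list(N = out, recr = recr)
}

#' Deterministic expected propagation under given realized rates
#'
#' Used by the stochasticity decomposition: starting from a realized state,
#' propagates the expected (demographic-noise-free) trajectory under an
#' already-realized annual rate sequence.
#'
#' @param initial starting state (matrix 6 x 2, may be real-valued).
#' @param rates an `ipm_rates` object (realized annual rates).
#' @return 6 x 2 x years real array.
#' @export
project_expected <- function(initial, rates) {
  years <- rates$years
  N <- array(0, c(6, 2, years), dimnames = list(.STAGES, .SEXES, NULL))
  N[, , 1] <- as.numeric(initial)
  for (t in seq_len(years - 1))
    N[, , t + 1] <- .expected_step(N[, , t], rates_at(rates, t),
                                   rates_at(rates, t + 1))
  N
}

#' Annual realized growth rates and their geometric mean
#'
#' @param x an `ipm_trajectory`, or a 6 x 2 x years abundance array.
#' @param population which total defines the growth rate: `"adults"` (all
#'   individuals aged 1+, both sexes; default), `"pairs"` (breeding females,
#'   stages 2 + 4 + 5) or `"females"` (all females aged 1+).
#' @return list with `lambda` (length `years - 1`), `geometric_mean`
#'   (`(prod lambda)^(1/(T-1))`) and `totals`.
#' @export
annual_growth_rates <- function(x, population = c("adults", "pairs", "females")) {
  population <- match.arg(population)
  N <- if (inherits(x, "ipm_trajectory")) x$N else x
  tot <- population_totals(N, population)
  if (any(tot <= 0)) stop("population went extinct: zero total abundance", call. = FALSE)
  lam <- tot[-1] / tot[-length(tot)]
  list(lambda = lam,
       geometric_mean = exp(mean(log(lam))),
       totals = tot)
}

#' Per-year population totals under a given definition
#' @inheritParams annual_growth_rates
#' @param N 6 x 2 x years array.
#' @return numeric vector of length `years`.
#' @export
population_totals <- function(N, population = c("adults", "pairs", "females")) {
  population <- match.arg(population)
  switch(population,
         adults  = apply(N, 3, sum),
         pairs   = apply(N[c(2, 4, 5), 1, , drop = FALSE], 3, sum),
         females = apply(N[, 1, , drop = FALSE], 3, sum))
}

#' Breeding-pair counts of a trajectory
#' @param x trajectory or array as in [annual_growth_rates()].
#' @return integer-valued vector of breeding females (stages 2 + 4 + 5) per year.
#' @export
breeding_pairs <- function(x) {
  N <- if (inherits(x, "ipm_trajectory")) x$N else x
  population_totals(N, "pairs")
}

# Vectorized multi-replicate stochastic projection.  Rates may differ per
# replicate: eps_list is a list of effect sets (one per replicate) OR a single
# set shared by all; here we instead accept per-replicate rate arrays prepared
# by the caller as a function(t) -> list of length-n rate vectors.
.project_multi <- function(initial, years, n, rate_fn) {
  N <- array(0, c(6, 2, years, n))
  # initial: one 6 x 2 state shared by all replicates, or a 6 x 2 x n array
  N[, , 1, ] <- if (length(initial) == 12L * n) as.numeric(initial) else
    array(rep(as.numeric(initial), n), c(6, 2, n))
  for (t in seq_len(years - 1)) {
    r <- rate_fn(t)
    st <- .step_multi(array(N[, , t, ], c(6, 2, n)), r$now, r$nxt, n)
    N[, , t + 1, ] <- st$N
  }
  N
}

#' Project many stochastic replicate trajectories at once
#'
#' All replicates share the hyperparameters but draw independent annual rates
#' and independent demographic noise.  Substantially faster than repeated
#' [project_trajectory()] calls.
#'
#' @inheritParams project_trajectory
#' @param nsim number of replicates.
#' @return array `6 x 2 x years x nsim`.
#' @export
project_multi <- function(initial, hyper, years, nsim, seed = NULL) {
  if (years < 2) stop("years must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # draw link-scale deviations for all replicates and years at once
  eff <- lapply(hyper$sigma, function(sg) {
    k <- length(sg)
    array(stats::rnorm(k * years * nsim, 0, rep(as.numeric(sg), years * nsim)),
          c(k, years, nsim))
  })
  mu <- lapply(hyper$mu, as.numeric)
  nat <- function(nm, t) {
    lv <- .clamp(mu[[nm]] + eff[[nm]][, t, , drop = FALSE])
    v <- .linkinv_fun(.par_links[[nm]])(lv)
    if (nm == "rho") v <- pmax(v, 0.01)
    matrix(v, dim(eff[[nm]])[1], nsim)
  }
  rate_fn <- function(t) {
    snow <- nat("s", t)
    now <- list(
      s = structure(snow, dim = c(3, 2, nsim)),
      eta = nat("eta", t), rho = nat("rho", t), xi = nat("xi", t))
    # .step_multi indexes s via rates$s[age, sex]; give it an indexable shim
    now$s <- .sex_age_shim(snow)
    nxt <- list(alpha = .sex_age_shim2(nat("alpha", t + 1)),
                omega = nat("omega", t + 1)[1, ])
    list(now = now, nxt = nxt)
  }
  .project_multi(initial, years, nsim, rate_fn)
}

# shims so vectorized per-replicate rates can be indexed like s[age, sex]
.sex_age_shim <- function(m) {  # m: 6 x n (ages 1..3 female, 1..3 male)
  structure(list(m = m), class = "sex_age_shim")
}
#' @export
`[.sex_age_shim` <- function(x, a, sex, ...) {
  off <- if (sex == "f") 0L else 3L
  x$m[a + off, ]
}
.sex_age_shim2 <- function(m) {  # m: 4 x n (ages 1..2 female, 1..2 male)
  structure(list(m = m), class = "sex_age_shim2")
}
#' @export
`[.sex_age_shim2` <- function(x, a, sex, ...) {
  off <- if (sex == "f") 0L else 2L
  x$m[a + off, ]
}
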