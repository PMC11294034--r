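# Population-level density-dependence test against a simulated
# exponential-growth null (Dennis-Taper style), and helpers for the
# density-dependent IPM variant (see fit_ipm_dd in jags.R).

#' Strength of density dependence of a trajectory
#'
#' Ordinary least-squares regression of log population size on the previous
#' year's log population size.  Two conventions are offered: `"growth"`
#' regresses the log growth rate `log(N_{t+1}/N_t)` on `log N_t` (no feedback
#' gives a slope near 0) and `"levels"` regresses `log N_{t+1}` on `log N_t`
#' (no feedback gives a slope near 1); the two slopes differ by exactly 1.
#' The default is the growth convention.  Either way the estimate is biased
#' downward in short noisy series because the same noise enters both sides,
#' which is why the test compares against a simulated density-independent
#' null rather than against the nominal no-feedback value.
#'
#' @param x an `ipm_trajectory`, a 6 x 2 x years array, or a numeric vector
#'   of population totals.
#' @param convention `"growth"` or `"levels"`.
#' @param population total used when `x` is a trajectory/array (default
#'   `"females"`, the covariate of the density-dependence analyses).
#' @return the OLS slope.
#' @export
dd_slope <- function(x, convention = c("growth", "levels"),
                     population = "females") {
  convention <- match.arg(convention)
  tot <- if (is.numeric(x) && is.null(dim(x))) x else
    population_totals(if (inherits(x, "ipm_trajectory")) x$N else x, population)
  if (length(tot) < 3) stop("need at least 3 years", call. = FALSE)
  if (any(tot <= 0)) stop("population totals must be positive", call. = FALSE)
  lx <- log(tot[-length(tot)])
  ly <- log(tot[-1])
  if (stats::var(lx) < 1e-12)
    stop("zero variance in log population size", call. = FALSE)
  b <- stats::cov(lx, ly) / stats::var(lx)
  if (convention == "growth") b - 1 else b
}

#' Null distribution of the density-dependence slope under exponential growth
#'
#' Simulates density-independent trajectories from the given hyperparameters
#' (process noise from the temporal random effects plus demographic
#' stochasticity, matched in length and starting state) and returns their
#' slopes.  Its mean is below the nominal no-feedback value — the regression
#' artifact the test calibrates away.
#'
#' @param hyper an [ipm_hyper()].
#' @param initial starting [ipm_state()].
#' @param years trajectory length.
#' @param nsim number of replicate null trajectories.
#' @param convention,population as in [dd_slope()].
#' @param seed optional integer seed.
#' @return numeric vector of slopes (`NA` for replicates that went extinct).
#' @export
dd_null_slopes <- function(hyper, initial, years, nsim = 200,
                           convention = "growth", population = "females",
                           seed = NULL) {
  N <- project_multi(initial, hyper, years, nsim, seed = seed)
  apply(N, 4, function(a) {
    tot <- population_totals(a, population)
    if (any(tot <= 0)) return(NA_real_)
    tryCatch(dd_slope(tot, convention), error = function(e) NA_real_)
  })
}

#' Posterior test for density dependence at the population level
#'
#' For each posterior draw, the observed slope `b_obs` is computed from the
#' latent female trajectory, and one matched density-independent replicate is
#' simulated from that draw's hyperparameters (same length, same starting
#' state, process and demographic noise from the fitted temporal SDs) to give
#' `b_null`.  The reported probability is the paired fraction
#' `P(b_obs < b_null)`: values near 1 indicate density dependence beyond the
#' regression artifact shared by both distributions.
#'
#' @param fit a `hawk_ipm` fit with monitored latent abundances and temporal
#'   random effects.
#' @param convention,population as in [dd_slope()].
#' @param seed optional integer seed.
#' @return list of class `dd_test` with `b_obs` and `b_null` (per-draw
#'   slopes), `prob`, and the two posterior means.
#' @export
dd_test <- function(fit, convention = "growth", population = "females",
                    seed = NULL) {
  stopifnot(inherits(fit, "hawk_ipm"))
  if (is.null(fit$draws$N))
    stop("fit has no monitored latent abundances", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nd <- dim(fit$draws$N)[1]
  T <- dim(fit$draws$N)[4]
  b_obs <- vapply(seq_len(nd), function(d) {
    tot <- population_totals(fit$draws$N[d, , , ], population)
    if (any(tot <= 0)) return(NA_real_)
    dd_slope(tot, convention)
  }, 0)
  # one matched null replicate per draw, from that draw's hyperparameters
  init <- fit$draws$N[, , , 1]           # nd x 6 x 2
  N0 <- aperm(init, c(2, 3, 1))          # 6 x 2 x nd
  rate_fn <- .posterior_rate_fn(fit, nd, T)
  Nnull <- .project_multi(N0, T, nd, rate_fn)
  b_null <- apply(Nnull, 4, function(a) {
    tot <- population_totals(a, population)
    if (any(tot <= 0)) return(NA_real_)
    tryCatch(dd_slope(tot, convention), error = function(e) NA_real_)
  })
  ok <- !is.na(b_obs) & !is.na(b_null)
  structure(list(b_obs = b_obs, b_null = b_null,
                 prob = mean(b_obs[ok] < b_null[ok]),
                 mean_obs = mean(b_obs, na.rm = TRUE),
                 mean_null = mean(b_null, na.rm = TRUE),
                 convention = convention), class = "dd_test")
}

#' @export
print.dd_test <- function(x, ...) {
  cat("Density-dependence test (", x$convention, " convention)\n", sep = "")
  cat("  observed slope: ", round(x$mean_obs, 3),
      " (95% CRI ", paste(round(stats::quantile(x$b_obs, c(.025, .975),
                                                na.rm = TRUE), 3),
                          collapse = ", "), ")\n", sep = "")
  cat("  null slope:     ", round(x$mean_null, 3), "\n", sep = "")
  cat("  P(b_obs < b_null) = ", round(x$prob, 3), "\n", sep = "")
  invisible(x)
}

# vectorized per-draw annual rates drawn from each posterior draw's
# hyperparameters (used for matched null simulations)
.posterior_rate_fn <- function(fit, nd, years) {
  mu <- fit$draws$mu
  sg <- fit$draws$sigma
  zl <- function(dims) array(stats::rnorm(prod(dims)), dims)
  get_sig <- function(nm, dims) {
    if (is.null(sg) || is.null(sg[[nm]])) array(0, dims) else sg[[nm]]
  }
  # link-scale values [nd, k, years]
  lk <- list(
    s = array(mu$s, c(nd, 6)), eta = mu$eta, lam = mu$lam, xi = mu$xi,
    alpha = array(mu$alpha, c(nd, 4)), om = mu$om, p = mu$p, r = mu$r)
  sig <- list(
    s = array(get_sig("s", c(nd, 3, 2)), c(nd, 6)),
    eta = get_sig("eta", c(nd, 3)), lam = get_sig("lam", c(nd, 3)),
    xi = get_sig("xi", c(nd, 3)),
    alpha = array(get_sig("alpha", c(nd, 2, 2)), c(nd, 4)),
    om = get_sig("om", nd))
  draw_year <- function(nm, k) {
    v <- .clamp(t(lk[[nm]]) + t(sig[[nm]]) * matrix(stats::rnorm(nd * k), k, nd))
    v  # k x nd
  }
  function(t) {
    s_nat <- stats::plogis(draw_year("s", 6))
    eta <- stats::plogis(draw_year("eta", 3))
    lam <- pmax(draw_year("lam", 3), 0.01)
    rho <- lam / (1 - exp(-lam))
    xi <- stats::plogis(draw_year("xi", 3))
    al <- stats::plogis(draw_year("alpha", 4))
    om <- exp(pmin(draw_year("om", 1)[1, ], 8))
    list(now = list(s = .sex_age_shim(s_nat), eta = eta, rho = rho, xi = xi),
         nxt = list(alpha = .sex_age_shim2(al), omega = om))
  }
}
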