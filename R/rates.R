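# Demographic rate containers: hyperparameters (means and temporal SDs on link
# scales) and annual realizations.

# shapes of each rate block; sex always the second margin where present
.par_template <- function(fill = 0) {
  list(
    s     = matrix(fill, 3, 2, dimnames = list(NULL, .SEXES)),  # survival age 1..3
    eta   = rep(fill, 3),                                       # breeding success
    rho   = rep(fill, 3),                                       # fledglings / successful brood
    xi    = rep(fill, 3),                                       # prop. female fledglings
    alpha = matrix(fill, 2, 2, dimnames = list(NULL, .SEXES)),  # recruitment age 1..2
    omega = fill,                                               # expected male immigrants
    p     = stats::setNames(rep(fill, 2), .SEXES),              # resighting prob
    r     = stats::setNames(rep(fill, 2), .SEXES)               # dead-recovery prob
  )
}

.par_links <- c(s = "logit", eta = "logit", rho = "identity", xi = "logit",
                alpha = "logit", omega = "log", p = "logit", r = "logit")

.link_fun <- function(link) {
  switch(link,
         logit    = stats::qlogis,
         log      = log,
         identity = identity)
}

.linkinv_fun <- function(link) {
  switch(link,
         logit    = stats::plogis,
         log      = exp,
         identity = identity)
}

# link-scale values are clamped before back-transformation for numerical safety
.LINK_CLAMP <- 20

.clamp <- function(x, lim = .LINK_CLAMP) pmin(pmax(x, -lim), lim)

#' Demographic hyperparameters of the two-sex projection model
#'
#' Bundles the long-term means and the temporal standard deviations of all
#' demographic and observation rates.  Means are supplied on the natural scale
#' and stored on the link scale (logit for probabilities, identity for the
#' number of fledglings per successful brood, log for the expected number of
#' male immigrants); the temporal SDs are interpreted on the link scale.
#'
#' @param mean named list with elements `s` (3 x 2 matrix, ages 1-3 by sex
#'   `f`/`m`), `eta`, `rho`, `xi` (length-3 vectors by maternal age class),
#'   `alpha` (2 x 2 matrix, ages 1-2 by sex), `omega` (scalar), `p`, `r`
#'   (length-2 vectors by sex), all on the natural scale.
#' @param sigma list of the same shape with non-negative temporal SDs on the
#'   link scale.  Defaults to all zero (constant rates).
#' @return an object of class `ipm_hyper` with elements `mu` (link scale) and
#'   `sigma`.
#' @seealso [goshawk_hyper()] for the default preset, [draw_rates()].
#' @export
ipm_hyper <- function(mean, sigma = .par_template(0)) {
  tmpl <- .par_template()
  mean  <- utils::modifyList(tmpl, mean[names(mean) %in% names(tmpl)])
  sigma <- utils::modifyList(.par_template(0), sigma[names(sigma) %in% names(tmpl)])
  for (nm in names(tmpl)) {
    if (!identical(dim(mean[[nm]]), dim(tmpl[[nm]])) ||
        length(mean[[nm]]) != length(tmpl[[nm]]))
      stop("mean$", nm, " has the wrong shape", call. = FALSE)
    if (any(sigma[[nm]] < 0)) stop("sigma$", nm, " must be non-negative", call. = FALSE)
  }
  # normalize dimnames so sex margins are always indexable by "f"/"m"
  for (nm in c("s", "alpha")) dimnames(mean[[nm]]) <- list(NULL, .SEXES)
  for (nm in c("p", "r")) names(mean[[nm]]) <- .SEXES
  probs <- c("s", "eta", "xi", "alpha", "p", "r")
  for (nm in probs)
    if (any(mean[[nm]] < 0 | mean[[nm]] > 1))
      stop("mean$", nm, " must lie in [0, 1]", call. = FALSE)
  if (any(mean$rho < 0)) stop("mean$rho must be non-negative", call. = FALSE)
  if (mean$omega < 0) stop("mean$omega must be non-negative", call. = FALSE)
  mu <- mean
  for (nm in names(tmpl)) {
    lk <- .link_fun(.par_links[[nm]])
    v <- lk(mean[[nm]])
    # probabilities exactly 0/1 are valid in simulation but have no finite
    # link-scale representation; pin them at the clamp boundary
    v[!is.finite(v)] <- sign(mean[[nm]][!is.finite(v)] - 0.5) * .LINK_CLAMP
    mu[[nm]] <- v
  }
  structure(list(mu = mu, sigma = sigma), class = "ipm_hyper")
}

#' @export
print.ipm_hyper <- function(x, ...) {
  cat("Two-sex IPM hyperparameters (natural-scale means; link-scale SDs)\n")
  m <- hyper_means(x)
  cat("  survival s[age, sex]:\n")
  print(round(m$s, 3))
  cat("  breeding success eta:", round(m$eta, 3), "\n")
  cat("  productivity rho:    ", round(m$rho, 3), "\n")
  cat("  sex ratio xi:        ", round(m$xi, 3), "\n")
  cat("  recruitment alpha[age, sex]:\n")
  print(round(m$alpha, 3))
  cat("  immigration omega:   ", round(m$omega, 3), "\n")
  cat("  resighting p:        ", round(m$p, 3), "\n")
  cat("  recovery r:          ", round(m$r, 3), "\n")
  invisible(x)
}

#' Natural-scale means implied by a hyperparameter set
#'
#' @param hyper an [ipm_hyper()] object.
#' @return list of rate blocks on the natural scale (the rates realized when
#'   all temporal random effects are zero).
#' @export
hyper_means <- function(hyper) {
  out <- hyper$mu
  for (nm in names(out)) {
    inv <- .linkinv_fun(.par_links[[nm]])
    out[[nm]] <- inv(.clamp(hyper$mu[[nm]]))
    if (nm == "rho") out[[nm]] <- pmax(out[[nm]], 0)
  }
  out
}

#' Draw annual demographic rates from the temporal random-effect model
#'
#' Each rate theta gets link-scale annual values `mu_theta + eps_t`,
#' `eps_t ~ Normal(0, sigma_theta^2)`, independently across years and rates.
#' Link-scale values are clamped to (-20, 20) before back-transformation;
#' the identity-linked productivity is floored at 0.01 and the log-linked
#' immigration mean capped to avoid overflow.
#'
#' @param hyper an [ipm_hyper()] object.
#' @param years number of annual occasions.
#' @param seed optional integer seed.
#' @return an `ipm_rates` object: list of arrays with a trailing year
#'   dimension (`s` is `3 x 2 x years`, `eta` `3 x years`, ..., `omega`
#'   length `years`).
#' @export
draw_rates <- function(hyper, years, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- draw_rate_effects(hyper, years)
  rates_from_effects(hyper, eps)
}

# raw link-scale deviations eps_t, one array per rate block (year last margin)
draw_rate_effects <- function(hyper, years) {
  out <- list()
  for (nm in names(hyper$sigma)) {
    sg <- hyper$sigma[[nm]]
    k <- length(sg)
    e <- matrix(stats::rnorm(k * years, 0, rep(as.numeric(sg), years)), k, years)
    out[[nm]] <- e
  }
  out$years <- years
  out
}

# turn hyper + deviations (+ optional density-dependence offset on the link
# scale, same layout as eps) into natural-scale annual rates
rates_from_effects <- function(hyper, eps, dd_offset = NULL) {
  years <- eps$years
  out <- list()
  for (nm in names(hyper$mu)) {
    mu <- as.numeric(hyper$mu[[nm]])
    lv <- mu + eps[[nm]]
    if (!is.null(dd_offset) && !is.null(dd_offset[[nm]])) lv <- lv + dd_offset[[nm]]
    lv <- .clamp(lv)
    inv <- .linkinv_fun(.par_links[[nm]])
    v <- inv(lv)
    # drawn productivity means are floored just above 1 (a successful brood
    # fledges at least one young, so its mean size must exceed 1)
    if (nm == "rho") v <- pmax(v, 1.01)
    dm <- dim(hyper$mu[[nm]])
    out[[nm]] <- if (is.null(dm)) {
      if (length(mu) == 1L) as.numeric(v) else
        array(v, c(length(mu), years))
    } else array(v, c(dm, years), dimnames = c(dimnames(hyper$mu[[nm]]), list(NULL)))
  }
  # restore sex dimnames lost for vector blocks
  if (is.matrix(out$p)) rownames(out$p) <- .SEXES
  if (is.matrix(out$r)) rownames(out$r) <- .SEXES
  out$years <- years
  class(out) <- "ipm_rates"
  out
}

#' Constant annual rates at the hyperparameter means
#'
#' @inheritParams draw_rates
#' @return an `ipm_rates` object with every year at the long-term mean
#'   (equivalent to [draw_rates()] with all temporal SDs zero).
#' @export
mean_rates <- function(hyper, years) {
  rates_from_effects(hyper, zero_rate_effects(hyper, years))
}

# all-zero deviations (no RNG use)
zero_rate_effects <- function(hyper, years) {
  out <- lapply(hyper$sigma, function(sg) matrix(0, length(sg), years))
  out$years <- years
  out
}

# extract the rates of one year as a flat list of named scalars/vectors
rates_at <- function(rates, t) {
  s <- rates$s[, , t, drop = TRUE]
  al <- rates$alpha[, , t, drop = TRUE]
  dimnames(s) <- list(NULL, .SEXES)
  dimnames(al) <- list(NULL, .SEXES)
  list(
    s     = s,
    eta   = rates$eta[, t],
    rho   = rates$rho[, t],
    xi    = rates$xi[, t],
    alpha = al,
    omega = rates$omega[t],
    p     = rates$p[, t],
    r     = rates$r[, t]
  )
}

# validate a single year's demographic rates (list as from rates_at)
validate_rates_year <- function(r) {
  pr <- c(r$s, r$eta, r$xi, r$alpha)
  if (any(!is.finite(pr)) || any(pr < 0 | pr > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(r$rho)) || any(r$rho < 0)) stop("rho must be >= 0", call. = FALSE)
  if (!is.finite(r$omega) || r$omega < 0) stop("omega must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Goshawk-like default hyperparameters
#'
#' The default preset emulates a mid-latitude European goshawk population
#' monitored for ~half a century: 30-70 breeding pairs, male-biased fledgling
#' sex ratio that weakens with maternal age, female first-year survival above
#' male, age-increasing productivity, recruitment mostly complete by age 3,
#' and moderate male-only immigration.  Temporal SDs put most year-to-year
#' variation into first-year survival and breeding success.
#'
#' @param years not used by the hyperparameters themselves; kept for symmetry
#'   with [simulate_goshawk()].
#' @return an [ipm_hyper()] object.
#' @export
goshawk_hyper <- function(years = 47) {
  mean <- list(
    s     = matrix(c(0.30, 0.67, 0.81,
                     0.23, 0.65, 0.80), 3, 2, dimnames = list(NULL, .SEXES)),
    eta   = c(0.62, 0.78, 0.86),
    rho   = c(1.87, 2.31, 2.44),
    xi    = c(0.43, 0.46, 0.47),
    alpha = matrix(c(0.35, 0.50,
                     0.08, 0.42), 2, 2, dimnames = list(NULL, .SEXES)),
    omega = 3.0,
    p     = c(f = 0.65, m = 0.45),
    r     = c(f = 0.11, m = 0.11)
  )
  sigma <- list(
    s     = matrix(c(0.35, 0.18, 0.12,
                     0.40, 0.18, 0.12), 3, 2, dimnames = list(NULL, .SEXES)),
    eta   = c(0.35, 0.35, 0.35),
    rho   = c(0.18, 0.18, 0.18),
    xi    = c(0.15, 0.15, 0.15),
    alpha = matrix(0.25, 2, 2, dimnames = list(NULL, .SEXES)),
    omega = 0.35,
    p     = c(f = 0.30, m = 0.30),
    r     = c(f = 0.30, m = 0.30)
  )
  ipm_hyper(mean, sigma)
}
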