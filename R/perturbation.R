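# Prospective (transient elasticity) and retrospective (transient LTRE)
# analyses of the realized growth rate, the environmental/demographic
# stochasticity decomposition, and derived population summaries.
#
# The realized growth rate is written as a function of the demographic rates
# and the stage structure:
#   lambda(theta, n, Ntot) = sum_i n_i c_i(theta) + omega / Ntot
# where n_i are the relative stage abundances (5 female + 6 male components,
# all individuals aged 1+) and c_i the per-capita contributions: a breeding
# female of age class a contributes eta_a * rho_a * (xi_a s1f + (1-xi_a) s1m)
# fledglings surviving to the next census plus her own survival; all other
# classes contribute survival only.  Recruitment moves individuals between
# breeder and non-breeder stages without changing the total, so it carries no
# direct sensitivity.

.RATE_NAMES <- c("s1_f", "s1_m", "s2_f", "s2_m", "s3_f", "s3_m",
                 paste0("eta_", 1:3), paste0("rho_", 1:3), paste0("xi_", 1:3),
                 "omega")
.STRUCT_NAMES <- c(paste0("n_f_", .STAGES[1:5]), paste0("n_m_", .STAGES))

# flat rate vector (length 16) from a rates-at-year list
.flat_rates <- function(r) {
  stats::setNames(c(r$s[1, 1], r$s[1, 2], r$s[2, 1], r$s[2, 2],
                    r$s[3, 1], r$s[3, 2], r$eta, r$rho, r$xi, r$omega),
                  .RATE_NAMES)
}

# per-capita next-year contributions of the 11 stage components
.percap <- function(v) {
  mix <- v[paste0("xi_", 1:3)] * v["s1_f"] +
    (1 - v[paste0("xi_", 1:3)]) * v["s1_m"]
  prod_a <- v[paste0("eta_", 1:3)] * v[paste0("rho_", 1:3)] * mix
  c(v["s2_f"], prod_a[1] + v["s2_f"], v["s3_f"], prod_a[2] + v["s3_f"],
    prod_a[3] + v["s3_f"],
    v["s2_m"], v["s2_m"], v["s3_m"], v["s3_m"], v["s3_m"], v["s3_m"])
}

# realized-lambda function and its analytic gradient.
# v: flat rates; n: 11 relative abundances (female stages 1-5, male 1-6);
# Ntot: total population aged 1+.
.lambda_fn <- function(v, n, Ntot) sum(n * .percap(v)) + v["omega"] / Ntot

.lambda_grad <- function(v, n, Ntot) {
  xi <- v[paste0("xi_", 1:3)]; eta <- v[paste0("eta_", 1:3)]
  rho <- v[paste0("rho_", 1:3)]
  mix <- xi * v["s1_f"] + (1 - xi) * v["s1_m"]
  nb <- n[c(2, 4, 5)]                     # breeding female components
  g <- stats::setNames(numeric(length(.RATE_NAMES)), .RATE_NAMES)
  g["s1_f"] <- sum(nb * eta * rho * xi)
  g["s1_m"] <- sum(nb * eta * rho * (1 - xi))
  g["s2_f"] <- n[1] + n[2]
  g["s2_m"] <- n[6] + n[7]
  g["s3_f"] <- n[3] + n[4] + n[5]
  g["s3_m"] <- n[8] + n[9] + n[10] + n[11]
  g[paste0("eta_", 1:3)] <- nb * rho * mix
  g[paste0("rho_", 1:3)] <- nb * eta * mix
  g[paste0("xi_", 1:3)] <- nb * eta * rho * (v["s1_f"] - v["s1_m"])
  g["omega"] <- 1 / Ntot
  lam <- .lambda_fn(v, n, Ntot)
  cc <- .percap(v)
  list(lambda = as.numeric(lam), rates = g,
       structure = stats::setNames((cc - lam) / Ntot * Ntot, .STRUCT_NAMES),
       # dlambda/dn_i at free-coordinate n (used by the LTRE)
       structure_free = stats::setNames(cc, .STRUCT_NAMES),
       total_size = as.numeric(-v["omega"] / Ntot^2))
}

# draw-wise contexts shared by the analysis functions: a list per draw with
# elements rates (ipm_rates-like arrays), N (6 x 2 x T), N4a/N4b (2 x T)
.analysis_contexts <- function(x) {
  if (inherits(x, "ipm_trajectory")) {
    N4b <- x$N[4, , ] - x$recruits2y
    return(list(list(s = x$rates$s, eta = x$rates$eta, rho = x$rates$rho,
                     xi = x$rates$xi, alpha = x$rates$alpha,
                     omega = x$rates$omega, N = x$N,
                     N4a = x$recruits2y, N4b = N4b)))
  }
  if (inherits(x, "hawk_ipm")) {
    if (is.null(x$draws$N))
      stop("fit has no monitored latent abundances; refit with monitor_latent = TRUE",
           call. = FALSE)
    nd <- dim(x$draws$s)[1]
    return(lapply(seq_len(nd), function(d) list(
      s = x$draws$s[d, , , ], eta = x$draws$eta[d, , ],
      rho = x$draws$rho[d, , ], xi = x$draws$xi[d, , ],
      alpha = x$draws$alpha[d, , , ], omega = x$draws$omega[d, ],
      N = x$draws$N[d, , , ], N4a = x$draws$N4a[d, , ],
      N4b = x$draws$N4b[d, , ])))
  }
  stop("x must be a hawk_ipm fit or an ipm_trajectory", call. = FALSE)
}

# temporal means of the flat rate vector and structure for one context;
# omega is aligned with the transition it feeds (year t+1 arrival)
.context_means <- function(ctx) {
  T <- dim(ctx$N)[3]
  tt <- seq_len(T - 1)
  v <- stats::setNames(c(
    mean(ctx$s[1, 1, tt]), mean(ctx$s[1, 2, tt]),
    mean(ctx$s[2, 1, tt]), mean(ctx$s[2, 2, tt]),
    mean(ctx$s[3, 1, tt]), mean(ctx$s[3, 2, tt]),
    rowMeans(ctx$eta[, tt, drop = FALSE]),
    rowMeans(ctx$rho[, tt, drop = FALSE]),
    rowMeans(ctx$xi[, tt, drop = FALSE]),
    mean(ctx$omega[tt + 1])), .RATE_NAMES)
  tot <- apply(ctx$N, 3, sum)
  nmat <- .structure_matrix(ctx$N)
  list(v = v, n = colMeans(nmat[tt, , drop = FALSE]),
       Ntot = mean(tot[tt]), T = T)
}

# (T x 11) matrix of relative stage abundances
.structure_matrix <- function(N) {
  T <- dim(N)[3]
  tot <- apply(N, 3, sum)
  m <- cbind(t(N[1:5, 1, , drop = FALSE][, 1, ]), t(N[, 2, ]))
  colnames(m) <- .STRUCT_NAMES
  sweep(m, 1, tot, "/")
}

.summarize_rows <- function(M) {
  # M: draws x components
  data.frame(component = colnames(M),
             mean = colMeans(M),
             lower = apply(M, 2, stats::quantile, 0.025, na.rm = TRUE),
             upper = apply(M, 2, stats::quantile, 0.975, na.rm = TRUE),
             row.names = NULL)
}

#' Transient elasticities of the realized population growth rate
#'
#' Proportional sensitivities of the realized growth rate to the demographic
#' rates and to the relative stage structure, evaluated at the temporal means
#' of rates and structure (computed per posterior draw for a fitted model).
#' Structure elasticities use the realized-structure convention: increasing
#' the relative abundance of a stage whose per-capita contribution exceeds
#' the current growth rate raises it, and conversely, so components with
#' below-average contributions (e.g. male stages) get negative elasticities.
#'
#' @param x a `hawk_ipm` fit (with monitored latent abundances) or an
#'   `ipm_trajectory` (known-truth analysis).
#' @return data frame with columns `component`, `type` (`"rate"` or
#'   `"structure"`), `mean`, `lower`, `upper` (95% CRI; degenerate for a
#'   single trajectory).
#' @export
transient_elasticities <- function(x) {
  ctxs <- .analysis_contexts(x)
  M <- matrix(NA_real_, length(ctxs), 16 + 11,
              dimnames = list(NULL, c(.RATE_NAMES, .STRUCT_NAMES)))
  for (d in seq_along(ctxs)) {
    cm <- .context_means(ctxs[[d]])
    if (cm$Ntot <= 0) stop("degenerate structure: zero total abundance",
                           call. = FALSE)
    gr <- .lambda_grad(cm$v, cm$n, cm$Ntot)
    M[d, .RATE_NAMES] <- cm$v * gr$rates / gr$lambda
    M[d, .STRUCT_NAMES] <- cm$n * (.percap(cm$v) - gr$lambda) / gr$lambda
  }
  out <- .summarize_rows(M)
  out$type <- ifelse(out$component %in% .RATE_NAMES, "rate", "structure")
  out[, c("component", "type", "mean", "lower", "upper")]
}

#' Transient LTRE: contributions to the variance of the realized growth rate
#'
#' First-order decomposition of `var(lambda_t)` into contributions of the
#' temporal variation in demographic rates and in the relative stage
#' structure: `sum_ij S_i S_j cov(x_i, x_j)`, with sensitivities evaluated at
#' temporal means and covariances taken over years (per posterior draw).
#' Contributions are reported relative to the summed total; the two
#' aggregates (direct via rates, delayed via structure) add to 1.
#'
#' @inheritParams transient_elasticities
#' @return list with `contributions` (data frame as in
#'   [transient_elasticities()], plus the `total_size` component), and
#'   `aggregates` (data frame: direct rates share, delayed structure share,
#'   first-order total, realized `var(lambda_t)`).
#' @export
ltre_contributions <- function(x) {
  ctxs <- .analysis_contexts(x)
  T <- dim(ctxs[[1]]$N)[3]
  if (T < 3) stop("need at least 3 years for a temporal decomposition",
                  call. = FALSE)
  comp_names <- c(.RATE_NAMES, .STRUCT_NAMES, "total_size")
  M <- matrix(NA_real_, length(ctxs), length(comp_names),
              dimnames = list(NULL, comp_names))
  agg <- matrix(NA_real_, length(ctxs), 4,
                dimnames = list(NULL, c("rates_share", "structure_share",
                                        "var_firstorder", "var_realized")))
  for (d in seq_along(ctxs)) {
    ctx <- ctxs[[d]]
    cm <- .context_means(ctx)
    gr <- .lambda_grad(cm$v, cm$n, cm$Ntot)
    S <- stats::setNames(c(gr$rates, gr$structure_free, gr$total_size),
                         comp_names)
    tt <- seq_len(T - 1)
    tot <- apply(ctx$N, 3, sum)
    X <- cbind(
      t(rbind(ctx$s[1, 1, tt], ctx$s[1, 2, tt], ctx$s[2, 1, tt],
              ctx$s[2, 2, tt], ctx$s[3, 1, tt], ctx$s[3, 2, tt],
              ctx$eta[, tt, drop = FALSE], ctx$rho[, tt, drop = FALSE],
              ctx$xi[, tt, drop = FALSE], ctx$omega[tt + 1])),
      .structure_matrix(ctx$N)[tt, , drop = FALSE],
      tot[tt])
    colnames(X) <- comp_names
    C <- stats::cov(X)
    contr <- S * as.numeric(C %*% S)
    total <- sum(contr)
    M[d, ] <- contr / total
    lam_t <- tot[tt + 1] / tot[tt]
    agg[d, ] <- c(sum(contr[.RATE_NAMES]) / total,
                  sum(contr[c(.STRUCT_NAMES, "total_size")]) / total,
                  total, stats::var(lam_t))
  }
  contributions <- .summarize_rows(M)
  contributions$type <- ifelse(contributions$component %in% .RATE_NAMES,
                               "rate", "structure")
  list(contributions = contributions[, c("component", "type", "mean",
                                         "lower", "upper")],
       aggregates = .summarize_rows(agg))
}

#' Environmental vs demographic stochasticity decomposition
#'
#' For each posterior draw (or a single known-truth trajectory), the expected
#' trajectory without demographic stochasticity is propagated from the
#' realized starting state under the realized annual rates.  Its growth
#' rates isolate the environmental component; the residual
#' `log(lambda_t) - log(lambda_env_t)` is the demographic component.  The
#' environmental share is the variance fraction of the environmental
#' component on the log scale.
#'
#' @inheritParams transient_elasticities
#' @return data frame with posterior mean and CRI of `env_share`,
#'   `dem_share`, `var_log_lambda_env` and `var_log_lambda_dem`.
#' @export
stochasticity_decomposition <- function(x) {
  ctxs <- .analysis_contexts(x)
  out <- matrix(NA_real_, length(ctxs), 4,
                dimnames = list(NULL, c("env_share", "dem_share",
                                        "var_log_lambda_env",
                                        "var_log_lambda_dem")))
  for (d in seq_along(ctxs)) {
    ctx <- ctxs[[d]]
    T <- dim(ctx$N)[3]
    rates <- list(s = ctx$s, eta = ctx$eta, rho = ctx$rho, xi = ctx$xi,
                  alpha = ctx$alpha, omega = ctx$omega,
                  p = matrix(0.5, 2, T), r = matrix(0.5, 2, T), years = T)
    class(rates) <- "ipm_rates"
    Nexp <- project_expected(ctx$N[, , 1], rates)
    tot_act <- apply(ctx$N, 3, sum)
    tot_env <- apply(Nexp, 3, sum)
    lam_act <- tot_act[-1] / tot_act[-T]
    lam_env <- tot_env[-1] / tot_env[-T]
    ve <- stats::var(log(lam_env))
    vd <- stats::var(log(lam_act) - log(lam_env))
    share <- if (ve + vd > 0) ve / (ve + vd) else NA_real_
    out[d, ] <- c(share, 1 - share, ve, vd)
  }
  .summarize_rows(out)
}

#' Derived population summaries
#'
#' Computes, per posterior draw (or once for a known-truth trajectory): the
#' geometric mean growth rate and total percentage change; the coefficient of
#' variation of breeding-pair counts; the number of fledglings per initiated
#' brood (`eta_a * rho_a`) by maternal age class; the composition of the
#' post-breeding population (fledglings, floaters, breeders); the breeder
#' decomposition into first-time breeders, experienced breeders and (males)
#' immigrants; and the adult sex ratio (proportion of males among birds aged
#' 1+).
#'
#' @inheritParams transient_elasticities
#' @return data frame with posterior mean and 95% CRI per summary.
#' @export
derived_summaries <- function(x) {
  ctxs <- .analysis_contexts(x)
  nms <- c("lambda_geomean", "pct_change", "cv_pairs",
           paste0("fledglings_per_brood_age", 1:3),
           "prop_fledglings", "prop_floaters", "prop_breeders",
           "prop_first_time_f", "prop_experienced_f",
           "prop_first_time_m", "prop_experienced_m", "prop_immigrant_m",
           "adult_sex_ratio_m", "prop_female_fledglings")
  out <- matrix(NA_real_, length(ctxs), length(nms),
                dimnames = list(NULL, nms))
  for (d in seq_along(ctxs)) {
    ctx <- ctxs[[d]]
    T <- dim(ctx$N)[3]
    tot <- apply(ctx$N, 3, sum)
    lam <- tot[-1] / tot[-T]
    pairs <- ctx$N[2, 1, ] + ctx$N[4, 1, ] + ctx$N[5, 1, ]
    fpb <- rowMeans(ctx$eta * ctx$rho)
    # expected fledglings produced each year, by sex
    brood <- ctx$N[c(2, 4, 5), 1, , drop = FALSE][, 1, ]
    if (is.null(dim(brood))) brood <- matrix(brood, 3, T)
    fl_tot <- colSums(brood * ctx$eta * ctx$rho)
    fl_f <- colSums(brood * ctx$eta * ctx$rho * ctx$xi)
    floaters <- ctx$N[1, 1, ] + ctx$N[3, 1, ] + ctx$N[1, 2, ] + ctx$N[3, 2, ]
    breeders <- tot - floaters
    post_tot <- tot + fl_tot
    # breeder decomposition
    ft_f <- ctx$N[2, 1, ] + ctx$N4a[1, ]
    ex_f <- ctx$N4b[1, ] + ctx$N[5, 1, ]
    ft_m <- ctx$N[2, 2, ] + ctx$N4a[2, ]
    ex_m <- ctx$N4b[2, ] + ctx$N[5, 2, ]
    im_m <- ctx$N[6, 2, ]
    br_f <- ft_f + ex_f
    br_m <- ft_m + ex_m + im_m
    out[d, ] <- c(
      exp(mean(log(lam))), 100 * (tot[T] / tot[1] - 1),
      100 * stats::sd(pairs) / mean(pairs), fpb,
      mean(fl_tot / post_tot), mean(floaters / post_tot),
      mean(breeders / post_tot),
      mean(ft_f / pmax(br_f, 1)), mean(ex_f / pmax(br_f, 1)),
      mean(ft_m / pmax(br_m, 1)), mean(ex_m / pmax(br_m, 1)),
      mean(im_m / pmax(br_m, 1)),
      mean(apply(ctx$N[, 2, , drop = FALSE], 3, sum) / tot),
      sum(fl_f) / sum(fl_tot))
  }
  .summarize_rows(out)
}
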