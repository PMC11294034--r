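# Posterior summaries, probability statements and posterior-predictive
# checks.

#' Posterior draws of a long-term mean rate on the natural scale
#'
#' Returns the posterior draws of the temporal mean of an annual rate —
#' the estimand recovered by simulation experiments (for a finite study
#' window the realized temporal mean, not the asymptotic hyperparameter, is
#' what the data identify).
#'
#' @param fit a `hawk_ipm` fit.
#' @param par one of `"s"`, `"eta"`, `"rho"`, `"xi"`, `"alpha"`, `"omega"`,
#'   `"p"`, `"r"`.
#' @param age age class index (for `s`, `eta`, `rho`, `xi`, `alpha`).
#' @param sex `"f"` or `"m"` (for sex-structured rates).
#' @return numeric vector of posterior draws.
#' @export
rate_mean_draws <- function(fit, par, age = NULL, sex = NULL) {
  ix <- if (!is.null(sex)) match(sex, .SEXES) else NULL
  d <- fit$draws
  switch(par,
         s = rowMeans(d$s[, age, ix, , drop = FALSE], dims = 1),
         eta = rowMeans(d$eta[, age, , drop = FALSE], dims = 1),
         rho = rowMeans(d$rho[, age, , drop = FALSE], dims = 1),
         xi = rowMeans(d$xi[, age, , drop = FALSE], dims = 1),
         alpha = rowMeans(d$alpha[, age, ix, , drop = FALSE], dims = 1),
         omega = rowMeans(d$omega),
         p = rowMeans(d$p[, ix, , drop = FALSE], dims = 1),
         r = rowMeans(d$r[, ix, , drop = FALSE], dims = 1),
         stop("unknown parameter ", par, call. = FALSE))
}

#' Posterior probability that one quantity exceeds another
#'
#' Draw-wise fraction with strict inequality, so `prob_greater(x, x)` is 0.
#'
#' @param x,y numeric vectors of posterior draws (recycled if scalar).
#' @return `P(x > y)`.
#' @export
prob_greater <- function(x, y) mean(x > y)

#' Posterior summary table of the long-term demographic rates
#'
#' @param fit a `hawk_ipm` fit.
#' @param prob credible level (default 0.95).
#' @return data frame: parameter, posterior mean, SD, CRI bounds.
#' @export
summarize_draws <- function(fit, prob = 0.95) {
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  specs <- list(
    list("s", 1, "f"), list("s", 2, "f"), list("s", 3, "f"),
    list("s", 1, "m"), list("s", 2, "m"), list("s", 3, "m"),
    list("eta", 1, NULL), list("eta", 2, NULL), list("eta", 3, NULL),
    list("rho", 1, NULL), list("rho", 2, NULL), list("rho", 3, NULL),
    list("xi", 1, NULL), list("xi", 2, NULL), list("xi", 3, NULL),
    list("alpha", 1, "f"), list("alpha", 2, "f"),
    list("alpha", 1, "m"), list("alpha", 2, "m"),
    list("omega", NULL, NULL),
    list("p", NULL, "f"), list("p", NULL, "m"),
    list("r", NULL, "f"), list("r", NULL, "m"))
  rows <- lapply(specs, function(sp) {
    dr <- rate_mean_draws(fit, sp[[1]], sp[[2]], sp[[3]])
    nm <- paste0(sp[[1]],
                 if (!is.null(sp[[2]])) paste0("_", sp[[2]]) else "",
                 if (!is.null(sp[[3]])) paste0("_", sp[[3]]) else "")
    data.frame(parameter = nm, mean = mean(dr), sd = stats::sd(dr),
               lower = stats::quantile(dr, qs[1], names = FALSE),
               upper = stats::quantile(dr, qs[2], names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- posterior-predictive machinery ---------------------------------------

# expected values and replicated data of every fitted component for one draw
.replicate_components <- function(fit, d) {
  data <- fit$data
  comps <- fit$config$components
  T <- data$years
  dr <- fit$draws
  out <- list()
  if ("counts" %in% comps && !is.null(dr$N)) {
    e <- dr$N[d, 2, 1, ] + dr$N[d, 4, 1, ] + dr$N[d, 5, 1, ]
    out$counts <- list(obs = data$territory_counts, exp = e,
                       rep = stats::rpois(T, e))
  }
  if ("breeders" %in% comps && !is.null(dr$N)) {
    cls <- .breeder_class_sizes(dr$N[d, , , ])
    p <- dr$p[d, , ]
    e <- rep <- array(0, c(T, 2, 3))
    for (ix in 1:2) for (a in 1:3) {
      e[, ix, a] <- cls[, ix, a] * p[ix, ]
      rep[, ix, a] <- stats::rbinom(T, round(cls[, ix, a]), p[ix, ])
    }
    out$breeders <- list(obs = as.numeric(data$breeder_counts),
                         exp = as.numeric(e), rep = as.numeric(rep))
  }
  if ("success" %in% comps && nrow(data$brood_success)) {
    ag <- .agg_cells(data$brood_success, function(x) sum(x$success))
    eta <- dr$eta[d, , ]
    pr <- eta[cbind(ag$age, ag$year)]
    out$success <- list(obs = ag$y, exp = ag$n * pr,
                        rep = stats::rbinom(nrow(ag), ag$n, pr))
  }
  if ("productivity" %in% comps && nrow(data$brood_fledglings)) {
    ag <- .agg_cells(data$brood_fledglings, function(x) sum(x$count))
    rho <- dr$rho[d, , ]
    m <- rho[cbind(ag$age, ag$year)]
    lam <- ztp_rate(pmax(m, 1 + 1e-9))
    rep <- vapply(seq_len(nrow(ag)), function(i)
      sum(rztpois(ag$n[i], lam[i])), 0)
    out$productivity <- list(obs = ag$y, exp = ag$n * m, rep = rep)
  }
  if ("sexratio" %in% comps && nrow(data$brood_sex)) {
    bx <- data$brood_sex
    bx <- bx[bx$n_female + bx$n_male > 0, , drop = FALSE]
    ag <- .agg_cells(data.frame(year = bx$year, age_class = bx$age_class,
                                nf = bx$n_female), function(x) sum(x$nf))
    nn <- as.integer(tapply(bx$n_female + bx$n_male,
                            interaction(bx$year, bx$age_class, drop = TRUE),
                            sum))
    xi <- dr$xi[d, , ]
    pr <- xi[cbind(ag$age, ag$year)]
    out$sexratio <- list(obs = ag$y, exp = nn * pr,
                         rep = stats::rbinom(nrow(ag), nn, pr))
  }
  if ("cjs" %in% comps && nrow(data$adult_cr$history)) {
    ma <- cjs_marray(data$adult_cr, T)
    s <- dr$s[d, , , ]; p <- dr$p[d, , ]
    obs <- e <- rep <- NULL
    for (ix in 1:2) for (a in 1:3) for (t in seq_len(T - 1)) {
      R <- ma$R[ix, a, t]
      if (R == 0) next
      pr <- cjs_cell_probs(s, p, ix, a, t, T)
      cells <- c(ma$m[ix, a, t, t:(T - 1)], ma$m[ix, a, t, T])
      obs <- c(obs, cells); e <- c(e, R * pr)
      rep <- c(rep, as.integer(stats::rmultinom(1, R, pr)))
    }
    out$cjs <- list(obs = obs, exp = e, rep = rep)
  }
  if ("recovery" %in% comps && nrow(data$recoveries)) {
    ma <- rec_marray(data$recoveries, T)
    s <- dr$s[d, , , ]; r <- dr$r[d, , ]
    obs <- e <- rep <- NULL
    for (ix in 1:2) for (t in seq_len(T - 1)) {
      R <- ma$R[ix, t]
      if (R == 0) next
      pr <- rec_cell_probs(s, r, ix, t, T)
      cells <- c(ma$m[ix, t, t:(T - 1)], ma$m[ix, t, T])
      obs <- c(obs, cells); e <- c(e, R * pr)
      rep <- c(rep, as.integer(stats::rmultinom(1, R, pr)))
    }
    out$recovery <- list(obs = obs, exp = e, rep = rep)
  }
  out
}

.freeman_tukey <- function(obs, e) sum((sqrt(obs) - sqrt(pmax(e, 0)))^2)

#' Posterior-predictive checks (Freeman-Tukey discrepancy)
#'
#' For each fitted data component, compares the Freeman-Tukey discrepancy of
#' the observed data against replicated data drawn from the posterior:
#' the Bayesian p-value is `P(D_rep > D_obs)`, with ties counted as 1/2.
#' Values near 0 or 1 flag misfit.
#'
#' @param fit a `hawk_ipm` fit.
#' @param ndraws number of posterior draws to use (subsampled).
#' @param seed optional integer seed.
#' @return list with `p_values` (named vector) and `discrepancies` (per
#'   component, a matrix of `D_obs` and `D_rep` across draws, for plotting).
#' @export
posterior_predictive_check <- function(fit, ndraws = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- if (fit$n_draws <= ndraws) seq_len(fit$n_draws) else
    sort(sample.int(fit$n_draws, ndraws))
  acc <- list()
  for (d in idx) {
    comps <- .replicate_components(fit, d)
    for (nm in names(comps)) {
      Dobs <- .freeman_tukey(comps[[nm]]$obs, comps[[nm]]$exp)
      Drep <- .freeman_tukey(comps[[nm]]$rep, comps[[nm]]$exp)
      acc[[nm]] <- rbind(acc[[nm]], c(D_obs = Dobs, D_rep = Drep))
    }
  }
  p <- vapply(acc, function(m)
    mean(m[, "D_rep"] > m[, "D_obs"]) + 0.5 * mean(m[, "D_rep"] == m[, "D_obs"]),
    0)
  list(p_values = p, discrepancies = acc)
}
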