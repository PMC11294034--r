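# S3 methods for the fitted model object.

#' @export
print.hawk_ipm <- function(x, ...) {
  cat("Two-sex integrated population model fit (JAGS)\n")
  cat("  years:", x$data$years, "  components:",
      paste(x$config$components, collapse = ", "), "\n")
  cat("  chains:", x$config$n_chains, " posterior draws:", x$n_draws,
      " runtime:", round(x$runtime), "s\n")
  rh <- suppressWarnings(max(x$rhat, na.rm = TRUE))
  cat("  max split R-hat:", round(rh, 3), "\n")
  if (is.finite(rh) && rh > 1.05)
    cat("  warning: R-hat > 1.05 for",
        sum(x$rhat > 1.05, na.rm = TRUE), "parameters\n")
  invisible(x)
}

#' Posterior means of the long-term demographic rates
#'
#' @param object a `hawk_ipm` fit.
#' @param ... unused.
#' @return named numeric vector on the natural scale (back-transformed
#'   posterior means of the link-scale hyperparameter means).
#' @export
coef.hawk_ipm <- function(object, ...) {
  mu <- object$draws$mu
  lam <- colMeans(pmax(mu$lam, 0.01))
  out <- c(
    stats::setNames(colMeans(stats::plogis(array(mu$s, c(nrow(mu$s), 6)))),
                    c("s1_f", "s2_f", "s3_f", "s1_m", "s2_m", "s3_m")),
    stats::setNames(colMeans(stats::plogis(mu$eta)), paste0("eta_", 1:3)),
    stats::setNames(lam / (1 - exp(-lam)), paste0("rho_", 1:3)),
    stats::setNames(colMeans(stats::plogis(mu$xi)), paste0("xi_", 1:3)),
    stats::setNames(colMeans(stats::plogis(array(mu$alpha,
                                                 c(nrow(mu$alpha), 4)))),
                    c("alpha1_f", "alpha2_f", "alpha1_m", "alpha2_m")),
    omega = mean(exp(mu$om)),
    stats::setNames(colMeans(stats::plogis(mu$p)), c("p_f", "p_m")),
    stats::setNames(colMeans(stats::plogis(mu$r)), c("r_f", "r_m")))
  out
}

#' @export
summary.hawk_ipm <- function(object, ...) {
  tab <- summarize_draws(object)
  structure(list(table = tab, rhat_max = suppressWarnings(
    max(object$rhat, na.rm = TRUE)),
    n_draws = object$n_draws), class = "summary.hawk_ipm")
}

#' @export
print.summary.hawk_ipm <- function(x, ...) {
  cat("Posterior summaries (natural scale, long-term means)\n")
  print(x$table, digits = 3, row.names = FALSE)
  cat("draws:", x$n_draws, " max split R-hat:", round(x$rhat_max, 3), "\n")
  invisible(x)
}

#' Plot the estimated breeding-pair trajectory
#'
#' Posterior mean and 95% CRI of the latent number of breeding pairs,
#' overlaid with the observed territory counts.
#'
#' @param x a `hawk_ipm` fit with monitored latent abundances.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hawk_ipm <- function(x, ...) {
  if (is.null(x$draws$N)) stop("no monitored latent abundances", call. = FALSE)
  pairs <- x$draws$N[, 2, 1, ] + x$draws$N[, 4, 1, ] + x$draws$N[, 5, 1, ]
  m <- colMeans(pairs)
  lo <- apply(pairs, 2, stats::quantile, 0.025)
  hi <- apply(pairs, 2, stats::quantile, 0.975)
  T <- length(m)
  graphics::plot(1:T, m, type = "n", ylim = range(lo, hi, x$data$territory_counts),
                 xlab = "Year", ylab = "Breeding pairs", ...)
  graphics::polygon(c(1:T, T:1), c(lo, rev(hi)), col = "grey85", border = NA)
  graphics::lines(1:T, m, lwd = 2)
  graphics::points(1:T, x$data$territory_counts, pch = 3)
  invisible(x)
}

#' Posterior-predictive replicated data sets
#'
#' Draws replicated monitoring data sets from randomly chosen posterior
#' draws: given a draw's latent abundances and rates, new territory counts,
#' breeder counts, brood records and m-array data are generated from the
#' fitted observation and demographic models.
#'
#' @param object a `hawk_ipm` fit with monitored latent abundances.
#' @param nsim number of replicated data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a list of replicated
#'   aggregated components (`counts`, `breeders`, `success`, `productivity`,
#'   `sexratio`, `cjs`, `recovery`) as used by the posterior-predictive
#'   checks.
#' @export
simulate.hawk_ipm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nd <- object$n_draws
  idx <- sample.int(nd, nsim, replace = nsim > nd)
  lapply(idx, function(d) .replicate_components(object, d))
}

#' Pearson residuals of the territory counts
#'
#' @param object a `hawk_ipm` fit with monitored latent abundances.
#' @param ... unused.
#' @return numeric vector `(C_t - E[pairs_t]) / sqrt(E[pairs_t])` at the
#'   posterior mean.
#' @export
residuals.hawk_ipm <- function(object, ...) {
  if (is.null(object$draws$N)) stop("no monitored latent abundances",
                                    call. = FALSE)
  pairs <- object$draws$N[, 2, 1, ] + object$draws$N[, 4, 1, ] +
    object$draws$N[, 5, 1, ]
  e <- colMeans(pairs)
  (object$data$territory_counts - e) / sqrt(pmax(e, 1e-8))
}
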