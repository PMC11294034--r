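# Individual-based generator of the seven monitoring data sets.
#
# The generator is the individual-level realization of the two-sex projection
# model: every bird carries its sex, cohort, survival outcomes, recruitment
# year and per-year breeding outcomes, so that aggregating individuals
# reproduces a valid stage-structured trajectory exactly.

# zero-truncated Poisson sampler (inverse CDF conditioned on >= 1)
rztpois <- function(n, lambda) {
  lambda <- rep(lambda, length.out = n)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Rate of a zero-truncated Poisson with given mean
#'
#' Solves `mean = lambda / (1 - exp(-lambda))` for `lambda` (vectorized
#' Newton iteration).  The productivity parameter rho of the projection model
#' is the mean number of fledglings per successful brood; the brood-size
#' distribution is a zero-truncated Poisson with this rate.
#'
#' @param mean mean(s) of the truncated distribution, > 1.
#' @return rate parameter(s) `lambda > 0`.
#' @export
ztp_rate <- function(mean) {
  if (any(mean <= 1)) stop("a zero-truncated Poisson mean must exceed 1",
                           call. = FALSE)
  lam <- pmax(2 * (mean - 1), 1e-8)  # small-lambda expansion as start
  for (i in 1:50) {
    em <- exp(-lam)
    f <- lam / (1 - em) - mean
    fp <- (1 - em - lam * em) / (1 - em)^2
    step <- f / fp
    lam <- pmax(lam - step, 1e-10)
    if (max(abs(step)) < 1e-12) break
  }
  lam
}

#' Simulate individual life histories under the two-sex IPM
#'
#' Runs an individual-based simulation of the population process: annual
#' demographic rates are drawn from the temporal random-effect model, then
#' every individual survives, recruits, and (if a breeding female) produces a
#' brood whose success, size and sex composition follow the age-specific
#' rates.  Male immigrants arrive as 3y+ breeders in their arrival year.
#'
#' @inheritParams project_trajectory
#' @return an object of class `ipm_individuals`: list with
#'   \describe{
#'     \item{individuals}{data frame: `id`, `sex` ("f"/"m"), `born` (fledge
#'       year; `NA` for immigrants and the founding population), `immigrant`,
#'       `entry` (first year in the aged population), `first_breed`,
#'       `death_interval` (year `t` such that the bird died between `t` and
#'       `t + 1`; `NA` if alive at the horizon).}
#'     \item{breeder_years}{data frame: `id`, `year`, `sex`, `age_class`
#'       (1, 2, 3 = 3y+), `first_time`.}
#'     \item{broods}{data frame: one row per breeding female and year with
#'       `success`, `n_fledged`, `n_female`, `n_male` (zero when failed).}
#'     \item{fledglings}{data frame: `id`, `year`, `sex`, `mother`.}
#'     \item{trajectory}{the true `ipm_trajectory` implied by the individuals.}
#'     \item{extinct}{TRUE if the population died out before `years` (the
#'       output is then truncated, with a warning).}
#'   }
#' @export
simulate_individuals <- function(hyper, initial, years, seed = NULL, dd = NULL) {
  if (years < 2) stop("years must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  validate_state(initial)
  eps <- draw_rate_effects(hyper, years)
  offs <- NULL
  if (!is.null(dd)) {
    offs <- lapply(hyper$sigma, function(sg) matrix(0, length(sg), years))
    offs$years <- years
    beta0 <- lapply(hyper$sigma, function(sg) rep(0, length(sg)))
    for (nm in names(dd$beta)) beta0[[nm]] <- as.numeric(dd$beta[[nm]])
  }
  rates <- rates_from_effects(hyper, eps)  # provisional; rebuilt under DD

  # current population vectors
  n0 <- sum(initial)
  id <- integer(0); sex <- integer(0); age <- integer(0); br <- logical(0)
  imm_now <- logical(0)  # in stage 6 this year (immigrant arrival year)
  next_id <- 1L
  add <- function(k) { v <- next_id:(next_id + k - 1L); next_id <<- next_id + k; v }
  ind_id <- integer(0); ind_sex <- integer(0); ind_born <- integer(0)
  ind_imm <- logical(0); ind_entry <- integer(0)
  ind_first_breed <- integer(0); ind_death <- integer(0)
  register <- function(k, sexes, born, imm, entry, first_breed) {
    ids <- add(k)
    ind_id <<- c(ind_id, ids); ind_sex <<- c(ind_sex, sexes)
    ind_born <<- c(ind_born, born); ind_imm <<- c(ind_imm, imm)
    ind_entry <<- c(ind_entry, entry)
    ind_first_breed <<- c(ind_first_breed, first_breed)
    ind_death <<- c(ind_death, rep(NA_integer_, k))
    ids
  }
  # founding population from the initial state
  for (ix in 1:2) {
    cfg <- rbind(c(1, 1, 0), c(2, 1, 1), c(3, 2, 0), c(4, 2, 1), c(5, 3, 1),
                 c(6, 3, 1))  # stage, age, breeder
    for (k in seq_len(nrow(cfg))) {
      st <- cfg[k, 1]; n <- initial[st, ix]
      if (n == 0) next
      is_imm <- st == 6L
      ids <- register(n, rep(ix, n), rep(NA_integer_, n), rep(is_imm, n),
                      rep(1L, n), rep(if (cfg[k, 3] == 1) 1L else NA_integer_, n))
      id <- c(id, ids); sex <- c(sex, rep(ix, n)); age <- c(age, rep(cfg[k, 2], n))
      br <- c(br, rep(cfg[k, 3] == 1, n)); imm_now <- c(imm_now, rep(is_imm, n))
    }
  }

  N <- array(0L, c(6, 2, years), dimnames = list(.STAGES, .SEXES, NULL))
  rec2 <- matrix(0L, 2, years, dimnames = list(.SEXES, NULL))
  by_l <- vector("list", years); brood_l <- vector("list", years)
  fled_l <- vector("list", years)
  extinct <- FALSE; last_year <- years

  for (t in seq_len(years)) {
    if (!is.null(dd)) {
      nf_now <- sum(sex == 1L)
      z <- (nf_now - dd$center) / dd$scale
      for (nm in c("s", "eta", "rho", "xi")) offs[[nm]][, t] <- beta0[[nm]] * z
      if (t == 1) for (nm in c("alpha", "omega")) offs[[nm]][, 1] <- beta0[[nm]] * z
      if (t < years) for (nm in c("alpha", "omega"))
        offs[[nm]][, t + 1] <- beta0[[nm]] * z
      rates <- rates_from_effects(hyper, eps, offs)
    }
    rt <- rates_at(rates, t)
    # record stage counts
    stage <- ifelse(age == 1L, ifelse(br, 2L, 1L),
             ifelse(age == 2L, ifelse(br, 4L, 3L),
                    ifelse(imm_now, 6L, 5L)))
    for (ix in 1:2) for (st in 1:6)
      N[st, ix, t] <- sum(sex == ix & stage == st)
    first_time <- !is.na(ind_first_breed[id]) & ind_first_breed[id] == t
    rec2[, t] <- c(sum(sex == 1L & stage == 4L & first_time[seq_along(id)]),
                   sum(sex == 2L & stage == 4L & first_time[seq_along(id)]))
    if (any(br))
      by_l[[t]] <- data.frame(id = id[br], year = t,
                              sex = .SEXES[sex[br]],
                              age_class = pmin(age[br], 3L),
                              first_time = first_time[seq_along(id)][br])
    # breeding: one brood per breeding female
    mo <- which(sex == 1L & br)
    if (length(mo)) {
      a <- pmin(age[mo], 3L)
      succ <- stats::rbinom(length(mo), 1L, rt$eta[a])
      nfl <- integer(length(mo)); nfe <- integer(length(mo))
      if (any(succ == 1L)) {
        w <- which(succ == 1L)
        nfl[w] <- rztpois(length(w), ztp_rate(rt$rho[a[w]]))
        nfe[w] <- stats::rbinom(length(w), nfl[w], rt$xi[a[w]])
      }
      brood_l[[t]] <- data.frame(year = t, mother = id[mo], age_class = a,
                                 success = succ, n_fledged = nfl,
                                 n_female = nfe, n_male = nfl - nfe)
      tot_fl <- sum(nfl)
      if (tot_fl > 0) {
        fsex <- integer(0); fmom <- integer(0)
        w <- which(nfl > 0)
        fsex <- unlist(lapply(w, function(i)
          c(rep(1L, nfe[i]), rep(2L, nfl[i] - nfe[i]))))
        fmom <- rep(id[mo][w], nfl[w])
        fids <- register(tot_fl, fsex, rep(t, tot_fl), rep(FALSE, tot_fl),
                         rep(NA_integer_, tot_fl), rep(NA_integer_, tot_fl))
        fled_l[[t]] <- data.frame(id = fids, year = t, sex = .SEXES[fsex],
                                  mother = fmom)
      }
    }
    if (t == years) break
    rt1 <- rates_at(rates, t + 1)
    # adult survival over interval (t, t+1): age 1 with s2, age 2+ with s3
    sp <- ifelse(age == 1L, rt$s[2, ][sex], rt$s[3, ][sex])
    alive <- stats::runif(length(id)) < sp
    ind_death[match(id[!alive], ind_id)] <- t
    # advance survivors
    id2 <- id[alive]; sex2 <- sex[alive]; age2 <- age[alive]; br2 <- br[alive]
    newbr <- br2
    # 1-y non-breeders may recruit at age 2; 2-y non-breeders all breed at 3
    rec_cand <- which(age2 == 1L & !br2)
    if (length(rec_cand)) {
      a2 <- rt1$alpha[2, ][sex2[rec_cand]]
      got <- stats::runif(length(rec_cand)) < a2
      newbr[rec_cand[got]] <- TRUE
      ind_first_breed[match(id2[rec_cand[got]], ind_id)] <- t + 1L
    }
    aged3 <- which(age2 == 2L & !br2)
    if (length(aged3)) {
      newbr[aged3] <- TRUE
      ind_first_breed[match(id2[aged3], ind_id)] <- t + 1L
    }
    age2 <- pmin(age2 + 1L, 3L)
    # fledglings of year t: first-year survival, then possible recruitment
    fl <- fled_l[[t]]
    fid <- integer(0); fsex2 <- integer(0); fbr <- logical(0)
    if (!is.null(fl) && nrow(fl)) {
      fsx <- match(fl$sex, .SEXES)
      s1 <- rt$s[1, ][fsx]
      fal <- stats::runif(nrow(fl)) < s1
      ind_death[match(fl$id[!fal], ind_id)] <- t
      fid <- fl$id[fal]; fsex2 <- fsx[fal]
      if (length(fid)) {
        a1 <- rt1$alpha[1, ][fsex2]
        fbr <- stats::runif(length(fid)) < a1
        ind_first_breed[match(fid[fbr], ind_id)] <- t + 1L
        ind_entry[match(fid, ind_id)] <- t + 1L
      }
    }
    # male immigrants of year t+1
    nimm <- stats::rpois(1, rt1$omega)
    iids <- integer(0)
    if (nimm > 0)
      iids <- register(nimm, rep(2L, nimm), rep(NA_integer_, nimm),
                       rep(TRUE, nimm), rep(t + 1L, nimm), rep(t + 1L, nimm))
    id <- c(id2, fid, iids)
    sex <- c(sex2, fsex2, rep(2L, nimm))
    age <- c(age2, rep(1L, length(fid)), rep(3L, nimm))
    br <- c(newbr, fbr, rep(TRUE, nimm))
    imm_now <- c(rep(FALSE, length(id2) + length(fid)), rep(TRUE, nimm))
    if (length(id) == 0) {
      warning("population went extinct in year ", t + 1,
              "; output truncated", call. = FALSE)
      extinct <- TRUE; last_year <- t
      break
    }
  }

  yrs <- last_year
  traj <- structure(list(N = N[, , seq_len(yrs), drop = FALSE],
                         recruits2y = rec2[, seq_len(yrs), drop = FALSE],
                         rates = rates, years = yrs),
                    class = "ipm_trajectory")
  structure(list(
    individuals = data.frame(id = ind_id, sex = .SEXES[ind_sex], born = ind_born,
                             immigrant = ind_imm, entry = ind_entry,
                             first_breed = ind_first_breed,
                             death_interval = ind_death),
    breeder_years = do.call(rbind, by_l[seq_len(yrs)]),
    broods = do.call(rbind, brood_l[seq_len(yrs)]),
    fledglings = do.call(rbind, fled_l[seq_len(yrs)]),
    trajectory = traj, years = yrs, extinct = extinct,
    hyper = hyper), class = "ipm_individuals")
}

#' Observation-process parameters
#'
#' @param p annual resighting (feather-identification) probability of breeders
#'   by sex, natural scale.
#' @param r dead-recovery probability by sex.
#' @param sigma_p,sigma_r temporal SDs of `p` and `r` on the logit scale.
#' @param brood_obs_frac fraction of broods whose outcome is recorded.
#' @param ring_frac fraction of fledglings ringed.
#' @param sexed_frac fraction of fledglings in a recorded brood that are sexed.
#' @param counts_model `"poisson"` (territory counts are a Poisson-noise
#'   census of the true breeding pairs) or `"exact"`.
#' @return a list of class `obs_params`.
#' @export
obs_params <- function(p = c(f = 0.65, m = 0.45), r = c(f = 0.11, m = 0.11),
                       sigma_p = 0.30, sigma_r = 0.30,
                       brood_obs_frac = 1, ring_frac = 0.75, sexed_frac = 1,
                       counts_model = c("poisson", "exact")) {
  counts_model <- match.arg(counts_model)
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1),
            sigma_p >= 0, sigma_r >= 0,
            brood_obs_frac >= 0, brood_obs_frac <= 1,
            ring_frac >= 0, ring_frac <= 1, sexed_frac >= 0, sexed_frac <= 1)
  names(p) <- .SEXES; names(r) <- .SEXES
  structure(list(p = p, r = r, sigma_p = sigma_p, sigma_r = sigma_r,
                 brood_obs_frac = brood_obs_frac, ring_frac = ring_frac,
                 sexed_frac = sexed_frac, counts_model = counts_model),
            class = "obs_params")
}

# logit-normal annual detection probabilities (clamped like the rates)
.draw_obs_rates <- function(obs, years) {
  pm <- stats::qlogis(obs$p); rm <- stats::qlogis(obs$r)
  pm[!is.finite(pm)] <- sign(obs$p[!is.finite(pm)] - 0.5) * .LINK_CLAMP
  rm[!is.finite(rm)] <- sign(obs$r[!is.finite(rm)] - 0.5) * .LINK_CLAMP
  p <- stats::plogis(.clamp(pm + matrix(stats::rnorm(2 * years, 0, obs$sigma_p), 2)))
  r <- stats::plogis(.clamp(rm + matrix(stats::rnorm(2 * years, 0, obs$sigma_r), 2)))
  rownames(p) <- .SEXES; rownames(r) <- .SEXES
  list(p = p, r = r)
}

#' Thin individual life histories into the seven monitoring data sets
#'
#' Applies the observation process to a simulated population: territory
#' counts (Poisson-noise or exact census of breeding pairs), sex- and
#' age-specific breeder counts and adult capture-recapture histories from
#' independent annual Bernoulli(p) identification of each breeder, brood
#' records kept with probability `brood_obs_frac`, ringing of fledglings with
#' probability `ring_frac`, and Bernoulli(r) recovery of each ringed bird's
#' death within the study horizon.
#'
#' @param individuals an [simulate_individuals()] result.
#' @param obs an [obs_params()] object.
#' @param seed optional integer seed.
#' @return a [monitoring_data()] object; the realized annual `p` and `r` are
#'   attached as attribute `"obs_truth"`.
#' @export
observe <- function(individuals, obs = obs_params(), seed = NULL) {
  stopifnot(inherits(individuals, "ipm_individuals"))
  if (!is.null(seed)) set.seed(seed)
  yrs <- individuals$years
  pr <- .draw_obs_rates(obs, yrs)
  traj <- individuals$trajectory
  pairs <- breeding_pairs(traj)
  counts <- if (obs$counts_model == "poisson") stats::rpois(yrs, pairs) else pairs

  by <- individuals$breeder_years
  bc <- array(0L, c(yrs, 2, 3), dimnames = list(NULL, .SEXES, NULL))
  cr <- NULL
  if (!is.null(by) && nrow(by)) {
    sx <- match(by$sex, .SEXES)
    det <- stats::runif(nrow(by)) < pr$p[cbind(sx, by$year)]
    dd <- by[det, , drop = FALSE]
    if (nrow(dd)) {
      tb <- table(factor(dd$year, levels = seq_len(yrs)),
                  factor(dd$sex, levels = .SEXES),
                  factor(dd$age_class, levels = 1:3))
      bc[] <- as.integer(tb)
      ids <- sort(unique(dd$id))
      H <- matrix(0L, length(ids), yrs)
      H[cbind(match(dd$id, ids), dd$year)] <- 1L
      first <- apply(H, 1, function(h) which(h == 1L)[1])
      afirst <- dd$age_class[match(paste(ids, first),
                                   paste(dd$id, dd$year))]
      cr <- list(history = H,
                 sex = dd$sex[match(ids, dd$id)],
                 age_first = as.integer(afirst),
                 id = ids)
    }
  }
  if (is.null(cr)) cr <- list(history = matrix(0L, 0, yrs), sex = character(0),
                              age_first = integer(0), id = integer(0))

  br <- individuals$broods
  bs <- bf <- bx <- NULL
  if (!is.null(br) && nrow(br)) {
    keep <- stats::runif(nrow(br)) < obs$brood_obs_frac
    kb <- br[keep, , drop = FALSE]
    bs <- data.frame(year = kb$year, age_class = kb$age_class,
                     success = kb$success)
    sb <- kb[kb$success == 1L, , drop = FALSE]
    if (nrow(sb)) {
      bf <- data.frame(year = sb$year, age_class = sb$age_class,
                       count = sb$n_fledged)
      nsexed <- stats::rbinom(nrow(sb), sb$n_fledged, obs$sexed_frac)
      nfs <- stats::rhyper(nrow(sb), sb$n_female, sb$n_male, nsexed)
      bx <- data.frame(year = sb$year, age_class = sb$age_class,
                       n_female = nfs, n_male = nsexed - nfs)
    }
  }
  if (is.null(bs)) bs <- data.frame(year = integer(0), age_class = integer(0),
                                    success = integer(0))
  if (is.null(bf)) bf <- data.frame(year = integer(0), age_class = integer(0),
                                    count = integer(0))
  if (is.null(bx)) bx <- data.frame(year = integer(0), age_class = integer(0),
                                    n_female = integer(0), n_male = integer(0))

  fl <- individuals$fledglings
  rec <- data.frame(id = integer(0), sex = character(0),
                    ring_year = integer(0), recovery_year = integer(0))
  if (!is.null(fl) && nrow(fl)) {
    ringed <- fl[stats::runif(nrow(fl)) < obs$ring_frac, , drop = FALSE]
    if (nrow(ringed)) {
      di <- individuals$individuals$death_interval[
        match(ringed$id, individuals$individuals$id)]
      recovered <- rep(FALSE, nrow(ringed))
      ok <- !is.na(di) & di >= ringed$year & di <= yrs - 1
      if (any(ok)) {
        sx <- match(ringed$sex[ok], .SEXES)
        recovered[ok] <- stats::runif(sum(ok)) < pr$r[cbind(sx, di[ok])]
      }
      rec <- data.frame(id = ringed$id, sex = ringed$sex,
                        ring_year = ringed$year,
                        recovery_year = ifelse(recovered, di + 1L, NA_integer_))
    }
  }
  md <- monitoring_data(years = yrs, territory_counts = counts,
                        breeder_counts = bc, brood_success = bs,
                        brood_fledglings = bf, brood_sex = bx,
                        adult_cr = cr, recoveries = rec)
  attr(md, "obs_truth") <- pr
  md
}

#' Simulate a goshawk-like monitoring study end-to-end
#'
#' Convenience wrapper: individual-based population simulation under the
#' [goshawk_hyper()] preset followed by the observation process, emulating a
#' half-century territory-monitoring study of 30-70 breeding pairs.
#'
#' @param years number of annual occasions (default 47).
#' @param seed integer seed.
#' @param hyper optional hyperparameters (default [goshawk_hyper()]).
#' @param initial optional initial state (default ~40 pairs).
#' @param obs optional [obs_params()].
#' @param dd optional density-dependence specification (see
#'   [project_trajectory()]).
#' @return list with `data` (a [monitoring_data()]), `individuals` and
#'   `truth` (true trajectory, rates and hyperparameters).
#' @export
simulate_goshawk <- function(years = 47, seed = NULL, hyper = goshawk_hyper(),
                             initial = goshawk_initial_state(), obs = obs_params(),
                             dd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- simulate_individuals(hyper, initial, years, dd = dd)
  data <- observe(ind, obs)
  list(data = data, individuals = ind,
       truth = list(trajectory = ind$trajectory, hyper = hyper,
                    obs = attr(data, "obs_truth")))
}

#' Default initial state of the goshawk preset (~40 breeding pairs)
#' @return an [ipm_state()].
#' @export
goshawk_initial_state <- function() {
  ipm_state(f = c(8, 6, 4, 7, 27), m = c(6, 2, 4, 6, 29, 3))
}
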