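# m-array summaries of the capture-recapture and dead-recovery data, and the
# corresponding multinomial cell probabilities.

#' CJS cell probabilities for one release cohort
#'
#' Probability of first recapture in years `t+1 ... T` (and of never being
#' recaptured, last element) for a breeder released in year `t` at age class
#' `a`, with the age class advancing along the history.
#'
#' @param s survival array `3 x 2 x years`.
#' @param p `2 x years` resighting probability matrix.
#' @param ix sex index (1 = female, 2 = male).
#' @param a age class at release (1, 2, 3).
#' @param t release year (1 .. T-1).
#' @param T number of occasions.
#' @return numeric vector of length `T - t + 1`; sums to 1.
#' @export
cjs_cell_probs <- function(s, p, ix, a, t, T) {
  pr <- numeric(T - t)
  cum <- 1
  for (j in (t + 1):T) {
    cls <- min(a + (j - 1 - t), 3L)          # age class in year j-1
    cum <- cum * s[.cjs_surv_index(cls), ix, j - 1]
    pr[j - t] <- cum * p[ix, j]
    cum <- cum * (1 - p[ix, j])              # not seen in year j
  }
  c(pr, 1 - sum(pr))
}

#' Ring-recovery cell probabilities for one ringing cohort
#'
#' Probability that a nestling ringed in year `t0` is recovered dead in year
#' `t0+1 ... T` (death in the preceding interval, reported with the
#' sex-specific recovery probability), and the complementary probability
#' (last element).
#'
#' @inheritParams cjs_cell_probs
#' @param r `2 x years` recovery probability matrix (indexed by the starting
#'   year of the death interval).
#' @param t0 ringing year (1 .. T-1).
#' @return numeric vector of length `T - t0 + 1`; sums to 1.
#' @export
rec_cell_probs <- function(s, r, ix, t0, T) {
  pr <- numeric(T - t0)
  alive <- 1
  for (k in t0:(T - 1)) {
    age <- min(k - t0 + 1L, 3L)
    sv <- s[age, ix, k]
    pr[k - t0 + 1] <- alive * (1 - sv) * r[ix, k]
    alive <- alive * sv
  }
  c(pr, 1 - sum(pr))
}

#' Build the age-structured CJS m-array
#'
#' Every identification is a release; rows are (sex, age class at release,
#' release year), columns the year of first recapture plus a final
#' never-recaptured column.
#'
#' @param adult_cr capture-recapture component of [monitoring_data()].
#' @param years number of occasions.
#' @return list with `m` (`2 x 3 x (years-1) x years` array; last column =
#'   never recaptured) and `R` (`2 x 3 x (years-1)` releases).
#' @export
cjs_marray <- function(adult_cr, years) {
  T <- years
  m <- array(0L, c(2, 3, T - 1, T))
  R <- array(0L, c(2, 3, T - 1))
  H <- adult_cr$history
  for (i in seq_len(nrow(H))) {
    h <- which(H[i, ] == 1L)
    ix <- match(adult_cr$sex[i], .SEXES)
    a0 <- adult_cr$age_first[i]
    f <- h[1]
    for (k in seq_along(h)) {
      t <- h[k]
      if (t >= T) break
      a <- min(a0 + (t - f), 3L)
      R[ix, a, t] <- R[ix, a, t] + 1L
      if (k < length(h)) {
        j <- h[k + 1]
        m[ix, a, t, j - 1] <- m[ix, a, t, j - 1] + 1L
      } else {
        m[ix, a, t, T] <- m[ix, a, t, T] + 1L
      }
    }
  }
  list(m = m, R = R)
}

#' Build the dead-recovery m-array
#'
#' Rows are (sex, ringing year), columns the recovery year plus a final
#' never-recovered column.
#'
#' @param recoveries recovery component of [monitoring_data()].
#' @param years number of occasions.
#' @return list with `m` (`2 x (years-1) x years`; column `j` = recovered in
#'   year `j + 1`, last column = never recovered) and `R` (`2 x (years-1)`
#'   ringed per cohort).
#' @export
rec_marray <- function(recoveries, years) {
  T <- years
  m <- array(0L, c(2, T - 1, T))
  R <- array(0L, c(2, T - 1))
  if (!nrow(recoveries)) return(list(m = m, R = R))
  for (i in seq_len(nrow(recoveries))) {
    t0 <- recoveries$ring_year[i]
    if (t0 >= T) next
    ix <- match(recoveries$sex[i], .SEXES)
    R[ix, t0] <- R[ix, t0] + 1L
    ry <- recoveries$recovery_year[i]
    if (is.na(ry)) {
      m[ix, t0, T] <- m[ix, t0, T] + 1L
    } else {
      m[ix, t0, ry - 1] <- m[ix, t0, ry - 1] + 1L
    }
  }
  list(m = m, R = R)
}
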