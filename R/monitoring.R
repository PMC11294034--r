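# Container for the seven monitoring data sets, with validation and CSV io.

#' The seven monitoring data sets of a two-sex raptor IPM
#'
#' @param years number of annual occasions.
#' @param territory_counts integer vector (length `years`) of occupied
#'   territories (breeding-pair counts).
#' @param breeder_counts integer array `years x 2 x 3` (year, sex `f`/`m`,
#'   age class 1 / 2 / 3+) of identified breeders.
#' @param brood_success data frame `year`, `age_class`, `success` (0/1).
#' @param brood_fledglings data frame `year`, `age_class`, `count` (>= 1) for
#'   successful broods.
#' @param brood_sex data frame `year`, `age_class`, `n_female`, `n_male`
#'   (sexed fledglings of a brood).
#' @param adult_cr list with `history` (0/1 matrix, one row per identified
#'   breeder, `years` columns), `sex`, `age_first` (age class at first
#'   identification) and `id`.
#' @param recoveries data frame `id`, `sex`, `ring_year`, `recovery_year`
#'   (`NA` when never recovered); one row per ringed nestling.
#' @return validated object of class `monitoring_data`.
#' @export
monitoring_data <- function(years, territory_counts, breeder_counts,
                            brood_success, brood_fledglings, brood_sex,
                            adult_cr, recoveries) {
  x <- structure(list(years = as.integer(years),
                      territory_counts = as.integer(territory_counts),
                      breeder_counts = breeder_counts,
                      brood_success = brood_success,
                      brood_fledglings = brood_fledglings,
                      brood_sex = brood_sex,
                      adult_cr = adult_cr,
                      recoveries = recoveries),
                 class = "monitoring_data")
  validate_monitoring_data(x)
  x
}

#' Validate a monitoring data set
#'
#' Checks dimensions, value ranges and the structural invariants: fledgling
#' counts of successful broods are >= 1, sexed fledglings do not outnumber
#' the brood, capture histories start with a 1, recovery years exceed ring
#' years.  Errors name the offending data set and rule.
#'
#' @param x a [monitoring_data()] object.
#' @return invisibly `TRUE`.
#' @export
validate_monitoring_data <- function(x) {
  T <- x$years
  fail <- function(set, msg) stop(set, ": ", msg, call. = FALSE)
  if (length(x$territory_counts) != T)
    fail("territory_counts", "length must equal years")
  if (any(x$territory_counts < 0)) fail("territory_counts", "negative count")
  if (!all(dim(x$breeder_counts) == c(T, 2, 3)))
    fail("breeder_counts", "must be years x 2 x 3")
  if (any(x$breeder_counts < 0)) fail("breeder_counts", "negative count")
  for (nm in c("brood_success", "brood_fledglings", "brood_sex")) {
    d <- x[[nm]]
    if (nrow(d) && (any(d$year < 1 | d$year > T)))
      fail(nm, "year out of range")
    if (nrow(d) && any(!d$age_class %in% 1:3)) fail(nm, "age_class not in 1..3")
  }
  if (nrow(x$brood_success) && !all(x$brood_success$success %in% 0:1))
    fail("brood_success", "success must be 0/1")
  if (nrow(x$brood_fledglings) && any(x$brood_fledglings$count < 1))
    fail("brood_fledglings", "successful broods must have count >= 1")
  if (nrow(x$brood_sex) && any(x$brood_sex$n_female < 0 | x$brood_sex$n_male < 0))
    fail("brood_sex", "negative sexed counts")
  H <- x$adult_cr$history
  if (ncol(H) && ncol(H) != T) fail("adult_cr", "history must have years columns")
  if (nrow(H)) {
    if (!all(H %in% 0:1)) fail("adult_cr", "history entries must be 0/1")
    if (any(rowSums(H) == 0)) fail("adult_cr", "history without any identification")
    if (length(x$adult_cr$sex) != nrow(H) || length(x$adult_cr$age_first) != nrow(H))
      fail("adult_cr", "sex/age_first length mismatch")
    if (!all(x$adult_cr$age_first %in% 1:3))
      fail("adult_cr", "age_first must be 1, 2 or 3")
  }
  rc <- x$recoveries
  if (nrow(rc)) {
    if (any(rc$ring_year < 1 | rc$ring_year > T))
      fail("recoveries", "ring_year out of range")
    bad <- !is.na(rc$recovery_year) & rc$recovery_year <= rc$ring_year
    if (any(bad)) fail("recoveries", "recovery_year must exceed ring_year")
  }
  invisible(TRUE)
}

#' @export
print.monitoring_data <- function(x, ...) {
  cat("Monitoring data over", x$years, "years\n")
  cat("  territory counts:   ", length(x$territory_counts), "years, mean",
      round(mean(x$territory_counts), 1), "\n")
  cat("  identified breeders:", sum(x$breeder_counts), "breeder-years\n")
  cat("  broods (success):   ", nrow(x$brood_success), "\n")
  cat("  successful broods:  ", nrow(x$brood_fledglings), "\n")
  cat("  sexed broods:       ", nrow(x$brood_sex), "\n")
  cat("  CR histories:       ", nrow(x$adult_cr$history), "individuals\n")
  cat("  ringed nestlings:   ", nrow(x$recoveries), "(",
      sum(!is.na(x$recoveries$recovery_year)), "recovered )\n")
  invisible(x)
}

#' Write the seven data sets as CSV files
#'
#' Files: `territory_counts.csv` (year, count), `breeder_counts.csv`
#' (year, sex, age_class, count), `brood_success.csv`, `brood_fledglings.csv`,
#' `brood_sex.csv`, `adult_cr.csv` (id, sex, age_first, y1..yT) and
#' `recoveries.csv`; plus a `manifest.json` recording the year span.
#'
#' @param x a [monitoring_data()] object.
#' @param dir output directory (created if needed).
#' @param manifest optional named list merged into the manifest (e.g. seeds
#'   and true parameters).
#' @return invisibly the directory.
#' @export
write_monitoring_csv <- function(x, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  T <- x$years
  utils::write.csv(data.frame(year = seq_len(T), count = x$territory_counts),
                   file.path(dir, "territory_counts.csv"), row.names = FALSE)
  bc <- expand.grid(year = seq_len(T), sex = .SEXES, age_class = 1:3)
  bc$count <- as.integer(
    x$breeder_counts[cbind(bc$year, match(bc$sex, .SEXES), bc$age_class)])
  utils::write.csv(bc, file.path(dir, "breeder_counts.csv"), row.names = FALSE)
  utils::write.csv(x$brood_success, file.path(dir, "brood_success.csv"),
                   row.names = FALSE)
  utils::write.csv(x$brood_fledglings, file.path(dir, "brood_fledglings.csv"),
                   row.names = FALSE)
  utils::write.csv(x$brood_sex, file.path(dir, "brood_sex.csv"),
                   row.names = FALSE)
  H <- x$adult_cr$history
  cr <- data.frame(id = x$adult_cr$id, sex = x$adult_cr$sex,
                   age_first = x$adult_cr$age_first)
  if (nrow(H)) {
    Hd <- as.data.frame(H)
    names(Hd) <- paste0("y", seq_len(T))
    cr <- cbind(cr, Hd)
  } else {
    for (t in seq_len(T)) cr[[paste0("y", t)]] <- integer(0)
  }
  utils::write.csv(cr, file.path(dir, "adult_cr.csv"), row.names = FALSE)
  utils::write.csv(x$recoveries, file.path(dir, "recoveries.csv"),
                   row.names = FALSE)
  man <- c(list(years = T, format = "hawkipm-monitoring-v1"), manifest)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read monitoring data written by [write_monitoring_csv()]
#'
#' @param dir directory holding the seven CSV files.
#' @return a validated [monitoring_data()] object.
#' @export
read_monitoring_csv <- function(dir) {
  need <- c("territory_counts.csv", "breeder_counts.csv", "brood_success.csv",
            "brood_fledglings.csv", "brood_sex.csv", "adult_cr.csv",
            "recoveries.csv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing data file: ", file.path(dir, f), call. = FALSE)
  tc <- utils::read.csv(file.path(dir, "territory_counts.csv"))
  T <- nrow(tc)
  bc_df <- utils::read.csv(file.path(dir, "breeder_counts.csv"))
  bc <- array(0L, c(T, 2, 3), dimnames = list(NULL, .SEXES, NULL))
  bc[cbind(bc_df$year, match(bc_df$sex, .SEXES), bc_df$age_class)] <-
    as.integer(bc_df$count)
  cr_df <- utils::read.csv(file.path(dir, "adult_cr.csv"))
  hc <- grep("^y[0-9]+$", names(cr_df))
  H <- as.matrix(cr_df[, hc, drop = FALSE]); dimnames(H) <- NULL
  if (nrow(H) == 0) H <- matrix(0L, 0, T)
  rec <- utils::read.csv(file.path(dir, "recoveries.csv"))
  if (!nrow(rec)) rec <- data.frame(id = integer(0), sex = character(0),
                                    ring_year = integer(0),
                                    recovery_year = integer(0))
  monitoring_data(
    years = T,
    territory_counts = tc$count[order(tc$year)],
    breeder_counts = bc,
    brood_success = utils::read.csv(file.path(dir, "brood_success.csv")),
    brood_fledglings = utils::read.csv(file.path(dir, "brood_fledglings.csv")),
    brood_sex = utils::read.csv(file.path(dir, "brood_sex.csv")),
    adult_cr = list(history = H, sex = as.character(cr_df$sex),
                    age_first = as.integer(cr_df$age_first),
                    id = cr_df$id),
    recoveries = rec)
}
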