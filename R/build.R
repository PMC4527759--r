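#' Build a cohort life table from observation records
#'
#' Aggregates a per-individual cohort log onto its observation schedule.
#' For the interval ending at checkpoint `x`:
#' \itemize{
#'   \item `lx` is the proportion of the initial cohort alive at `x`
#'     (an individual scored dead at checkpoint `x` is not alive at `x`);
#'   \item `mx` is the total number of juveniles hatched from eggs laid in
#'     the interval, divided by the number of individuals alive at `x`
#'     (or at the interval start, see `denominator`).
#' }
#' The table spans the cohort's reproductive window: from the first
#' checkpoint with any juvenile production to the last, retaining interior
#' rows with zero production. Deaths before maturity are counted in `lx`
#' (they reduce survivorship) exactly like adult deaths.
#'
#' @param records A `cohort_records` data frame (see [cohort_records()]).
#'   Every record's interval must coincide with a schedule interval.
#' @param schedule An [observation_schedule()].
#' @param denominator Population used for the `mx` denominator:
#'   `"alive_end"` (default; same population as `lx`) or `"alive_start"`
#'   (individuals alive at the interval's start).
#' @return A [life_table()] with `n0` = number of individuals in `records`.
#' @examples
#' cfg <- pacificus_config(n = 12)
#' ev <- simulate_cohort(cfg, seed = 1)
#' rec <- observe(ev, default_schedule())
#' build_life_table(rec, default_schedule())
#' @export
build_life_table <- function(records, schedule,
                             denominator = c("alive_end", "alive_start")) {
  stopifnot(inherits(records, "cohort_records"),
            inherits(schedule, "observation_schedule"))
  denominator <- match.arg(denominator)
  n_0 <- length(unique(records$individual_id))
  if (n_0 < 1L) stop("cohort log has no individuals", call. = FALSE)

  cp <- schedule$checkpoint
  starts <- cp - schedule$width
  key <- paste(signif(records$interval_start, 10),
               signif(records$interval_end, 10))
  skey <- paste(signif(starts, 10), signif(cp, 10))
  slot <- match(key, skey)
  if (anyNA(slot)) {
    i <- which(is.na(slot))[1]
    stop(sprintf(
      "record interval %g-%g h (individual %s) does not align with the schedule",
      records$interval_start[i], records$interval_end[i],
      records$individual_id[i]), call. = FALSE)
  }

  juv <- as.numeric(tapply(records$juveniles_hatched, factor(slot, seq_along(cp)),
                           sum, default = 0))
  # each individual contributes one dead record at most; deaths at or before
  # checkpoint x remove the individual from the alive count at x
  dead_slot <- slot[records$status == "dead"]
  deaths <- tabulate(dead_slot, nbins = length(cp))
  alive_end <- n_0 - cumsum(deaths)
  alive_start <- c(n_0, alive_end[-length(alive_end)])
  denom <- if (denominator == "alive_end") alive_end else alive_start

  mx <- ifelse(denom > 0, juv / denom, 0)
  lx <- alive_end / n_0

  reproductive <- which(juv > 0)
  if (length(reproductive) == 0L) {
    keep <- integer(0)
  } else {
    keep <- seq(min(reproductive), max(reproductive))
  }
  life_table(cp[keep], schedule$width[keep], lx[keep], mx[keep], n0 = n_0,
             check_counts = FALSE)
}

#' Net reproductive rate R0
#'
#' The expected lifetime number of offspring per newborn individual,
#' `R0 = sum(lx * mx)` over the life table, with the products recomputed at
#' full precision. Equivalently (for the alive-at-end fecundity convention)
#' the total number of juveniles produced by the cohort divided by its
#' initial size.
#'
#' @param lt A [life_table()].
#' @return Offspring per individual; 0 for an empty table.
#' @export
net_reproductive_rate <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  if (nrow(lt) == 0L) return(0)
  sum(lt$lx * lt$mx)
}

#' Total fertility rate
#'
#' `TFR = sum(mx)`: the lifetime number of offspring of an individual that
#' survives to the oldest reproductive age. Always `>= R0` since `lx <= 1`.
#'
#' @param lt A [life_table()].
#' @return Offspring per maximally long-lived individual; 0 if empty.
#' @export
total_fertility_rate <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  if (nrow(lt) == 0L) return(0)
  sum(lt$mx)
}

#' Age-specific fecundity schedule
#'
#' For each observation interval, the fecundity percentage is computed
#' individually for every sexually mature, alive individual as the fraction
#' of its eggs laid in that interval that hatched, then averaged
#' arithmetically across those individuals and converted to a percentage.
#' Sexual maturity is marked by the first interval with any egg laid;
#' individuals that laid no eggs in an interval contribute nothing to the
#' hatch-fraction mean for that interval (the fraction is undefined), and
#' individuals dead by the interval's end are excluded. The mean number of
#' eggs laid per alive mature individual is reported alongside.
#'
#' @param records A `cohort_records` data frame.
#' @return A data frame with one row per checkpoint at which at least one
#'   mature individual was alive: `time` (h), `fecundity_pct` (in
#'   `[0, 100]`, `NA` when no alive mature individual laid eggs),
#'   `eggs_per_interval` (mean eggs per alive mature individual).
#' @export
fecundity_schedule <- function(records) {
  stopifnot(inherits(records, "cohort_records"))
  if (nrow(records) == 0L)
    return(data.frame(time = numeric(0), fecundity_pct = numeric(0),
                      eggs_per_interval = numeric(0)))
  rec <- records
  # maturity: first interval (per individual) with eggs laid
  first_egg <- tapply(ifelse(rec$eggs_laid > 0, rec$interval_end, Inf),
                      rec$individual_id, min)
  rec$mature <- rec$interval_end >= first_egg[rec$individual_id]
  rec$alive <- rec$status == "alive"
  use <- rec$mature & rec$alive
  times <- sort(unique(rec$interval_end[use]))
  out <- lapply(times, function(tt) {
    r <- rec[use & rec$interval_end == tt, , drop = FALSE]
    laid <- r$eggs_laid > 0
    data.frame(
      time = tt,
      fecundity_pct = if (any(laid))
        100 * mean(r$juveniles_hatched[laid] / r$eggs_laid[laid]) else NA_real_,
      eggs_per_interval = mean(r$eggs_laid)
    )
  })
  do.call(rbind, out)
}

#' Cohort-level life-history summary
#'
#' Means and standard deviations of the classical per-individual traits:
#' life span (days; computed over individuals that reached maturity and
#' whose death was observed — juvenile deaths appear in the mortality
#' proportion instead, and right-censored individuals are excluded), age at
#' first egg deposition (hours), age at the individual's maximum egg-laying
#' rate (hours; the midpoint of the interval with the highest eggs laid per
#' hour), and lifetime egg total (individuals that never matured excluded).
#' Juvenile mortality is the proportion of the initial cohort that died
#' without ever laying an egg.
#'
#' @param records A `cohort_records` data frame.
#' @return An object of class `cohort_summary`: a list with elements
#'   `n0`, `n_censored`, `mean_lifespan_d`, `sd_lifespan_d`, `age_min_h`,
#'   `sd_age_min_h`, `age_max_h`, `sd_age_max_h`, `total_eggs`,
#'   `sd_total_eggs`, `juvenile_mortality`.
#' @export
cohort_summary <- function(records) {
  stopifnot(inherits(records, "cohort_records"))
  ind <- individual_summaries(records)
  # age at maximum egg-laying rate: midpoint of the interval maximizing
  # eggs laid per hour (earliest such interval on ties)
  peak_age <- vapply(split(records, records$individual_id), function(r) {
    if (all(r$eggs_laid == 0)) return(NA_real_)
    rate <- r$eggs_laid / (r$interval_end - r$interval_start)
    i <- which.max(rate)
    (r$interval_start[i] + r$interval_end[i]) / 2
  }, numeric(1))
  peak_age <- peak_age[ind$individual_id]

  mature <- !is.na(ind$first_egg_age)
  died <- !is.na(ind$death_age)
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) c(NA_real_, NA_real_) else c(mean(x), stats::sd(x))
  }
  life <- msd(ind$death_age[died & mature] / 24)
  amin <- msd(ind$first_egg_age)
  amax <- msd(peak_age)
  eggs <- msd(ind$total_eggs[mature])
  structure(list(
    n0 = nrow(ind),
    n_censored = sum(!died),
    mean_lifespan_d = life[1], sd_lifespan_d = life[2],
    age_min_h = amin[1], sd_age_min_h = amin[2],
    age_max_h = amax[1], sd_age_max_h = amax[2],
    total_eggs = eggs[1], sd_total_eggs = eggs[2],
    juvenile_mortality = sum(!mature & died) / nrow(ind)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  pm <- function(m, s, d = 1) {
    if (is.na(m)) "-" else sprintf(paste0("%.", d, "f ± %.", d, "f"), m, s)
  }
  cat("<cohort_summary>\n")
  cat(sprintf("  n0 = %d (%d censored)\n", x$n0, x$n_censored))
  cat("  Life span (d)  ", pm(x$mean_lifespan_d, x$sd_lifespan_d), "\n")
  cat("  Age_min (h)    ", pm(x$age_min_h, x$sd_age_min_h), "\n")
  cat("  Age_max (h)    ", pm(x$age_max_h, x$sd_age_max_h), "\n")
  cat("  T_eggs         ", pm(x$total_eggs, x$sd_total_eggs), "\n")
  cat(sprintf("  Juvenile mortality  %.3f\n", x$juvenile_mortality))
  invisible(x)
}
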