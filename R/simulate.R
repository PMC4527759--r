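#' Simulation configuration for a synchronized hermaphrodite cohort
#'
#' Parameterizes the individual-based simulator. Defaults describe a
#' selfing-hermaphrodite nematode cohort reared individually in hanging
#' drops: stochastic maturation age (operationally, the age of the first
#' egg deposition), normally distributed adult lifespan, a small
#' probability of death before maturation, a gamma-shaped egg-laying
#' intensity over age since maturation, an age-dependent probability that
#' an egg is fertile (a rising and a falling logistic ramp), and a normal
#' egg-to-hatch delay.
#'
#' @param n Cohort size (positive integer).
#' @param maturation_mean,maturation_sd Mean/sd of the age at first egg
#'   deposition, hours (normal, truncated below at `maturation_min`).
#' @param maturation_min Lower truncation for maturation age, hours.
#' @param lifespan_mean_d,lifespan_sd_d Mean/sd of adult lifespan, days
#'   (normal, truncated below at the individual's maturation age).
#' @param juvenile_death_prob Probability an individual dies before
#'   maturation; its death time is uniform between `maturation_min` and its
#'   drawn maturation age.
#' @param eggs_mean,eggs_sd Mean/sd of the lifetime egg count (normal,
#'   truncated below at 1, rounded).
#' @param laying_shape,laying_scale Shape and scale (hours) of the gamma
#'   egg-laying intensity over age since maturation. The default mode
#'   `(shape-1)*scale = 75.7` h puts the population's peak laying rate near
#'   141 h of age, and the default tail leaves about 21% of the egg mass
#'   after fertility has collapsed (unfertile late-life eggs).
#' @param fertility_rise_mid,fertility_rise_scale Midpoint (h of age) and
#'   scale (h) of the rising logistic ramp of egg fertility.
#' @param fertility_fall_mid,fertility_fall_scale Midpoint and scale of the
#'   falling ramp. The default ramps put peak fertility at about 97.4%
#'   near 6 days of age and 0.21% at 12.8 days.
#' @param fertility_zero_age Age (h) beyond which eggs are never fertile.
#' @param hatch_delay_mean,hatch_delay_sd Mean/sd of the egg-to-hatch delay,
#'   hours (normal, truncated to `(0, 48)` so every fertile egg is scored
#'   under the 48-h leave-in-drop rule).
#' @param sync_window_h Width of the hatching synchronization window, hours;
#'   individual hatch offsets are uniform on it (bookkeeping only: ages run
#'   on the shared cohort clock).
#' @return A validated object of class `sim_config`.
#' @seealso [pacificus_config()] for the published *P. pacificus* defaults.
#' @export
sim_config <- function(n,
                       maturation_mean = 65.1, maturation_sd = 8.4,
                       maturation_min = 24,
                       lifespan_mean_d = 22.5, lifespan_sd_d = 7.3,
                       juvenile_death_prob = 2 / 33,
                       eggs_mean = 269.6, eggs_sd = 73.4,
                       laying_shape = 1.864, laying_scale = 87.63,
                       fertility_rise_mid = 40, fertility_rise_scale = 25,
                       fertility_fall_mid = 213.4,
                       fertility_fall_scale = 15.22,
                       fertility_zero_age = 312,
                       hatch_delay_mean = 25.3, hatch_delay_sd = 1.6,
                       sync_window_h = 4) {
  cfg <- list(n = as.integer(n),
              maturation_mean = maturation_mean,
              maturation_sd = maturation_sd,
              maturation_min = maturation_min,
              lifespan_mean_d = lifespan_mean_d,
              lifespan_sd_d = lifespan_sd_d,
              juvenile_death_prob = juvenile_death_prob,
              eggs_mean = eggs_mean, eggs_sd = eggs_sd,
              laying_shape = laying_shape, laying_scale = laying_scale,
              fertility_rise_mid = fertility_rise_mid,
              fertility_rise_scale = fertility_rise_scale,
              fertility_fall_mid = fertility_fall_mid,
              fertility_fall_scale = fertility_fall_scale,
              fertility_zero_age = fertility_zero_age,
              hatch_delay_mean = hatch_delay_mean,
              hatch_delay_sd = hatch_delay_sd,
              sync_window_h = sync_window_h)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n) || cfg$n < 1)
    stop("cohort size n must be a positive integer", call. = FALSE)
  if (cfg$juvenile_death_prob < 0 || cfg$juvenile_death_prob > 1)
    stop("juvenile_death_prob must lie in [0, 1]", call. = FALSE)
  positives <- c("maturation_mean", "maturation_min", "lifespan_mean_d",
                 "eggs_mean", "laying_shape", "laying_scale",
                 "fertility_rise_scale", "fertility_fall_scale",
                 "fertility_zero_age", "hatch_delay_mean", "sync_window_h")
  for (p in positives)
    if (is.na(cfg[[p]]) || cfg[[p]] <= 0)
      stop(sprintf("config field '%s' must be positive", p), call. = FALSE)
  nonneg <- c("maturation_sd", "lifespan_sd_d", "eggs_sd", "hatch_delay_sd")
  for (p in nonneg)
    if (is.na(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("config field '%s' must be nonnegative", p), call. = FALSE)
  if (cfg$maturation_mean < cfg$maturation_min && cfg$maturation_sd == 0)
    stop("deterministic maturation age lies below maturation_min",
         call. = FALSE)
  if (cfg$fertility_zero_age <= cfg$maturation_min)
    stop("infeasible config: eggs can never be fertile", call. = FALSE)
  invisible(cfg)
}

#' Published *P. pacificus* simulator defaults
#'
#' Returns a [sim_config()] parameterized to the published life-history
#' values for *Pristionchus pacificus* PS312 at 20 degrees C on
#' 5e9 *E. coli* cells/ml: maturation 65.1 +/- 8.4 h, lifespan
#' 22.5 +/- 7.3 d, 2/33 juvenile mortality, 269.6 +/- 73.4 lifetime eggs,
#' peak laying near 141 h, peak fertility 97.4% near 6.1 d falling to
#' 0.21% at 12.8 d and zero after 13 d, and hatch delay 25.3 +/- 1.6 h.
#'
#' @param n Cohort size (default 33, the published experiment's size).
#' @return A `sim_config`.
#' @export
pacificus_config <- function(n = 33) sim_config(n = n)

#' Age-dependent egg-fertility curve
#'
#' The probability that an egg laid at age `age_h` is fertile: the product
#' of a rising and a falling logistic ramp, clamped to zero beyond
#' `fertility_zero_age`.
#'
#' @param age_h Ages in hours.
#' @param cfg A `sim_config`.
#' @return Probabilities in `[0, 1]`.
#' @export
fertility_curve <- function(age_h, cfg) {
  p <- stats::plogis((age_h - cfg$fertility_rise_mid) /
                       cfg$fertility_rise_scale) *
    stats::plogis(-(age_h - cfg$fertility_fall_mid) /
                    cfg$fertility_fall_scale)
  p[age_h > cfg$fertility_zero_age] <- 0
  p
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, p_lo, p_hi)
  stats::qnorm(u, mean, sd)
}

#' Simulate a synchronized cohort
#'
#' Draws per-individual life histories under a [sim_config()]: maturation
#' age, juvenile or adult death, a lifetime egg budget laid at the first
#' egg age plus gamma-distributed offsets (eggs falling after death are not
#' laid), a fertile/unfertile flag per egg from the age-dependent fertility
#' curve, and a hatch time for every fertile egg.
#'
#' Reproducibility: each individual gets a deterministic substream seed
#' derived from `seed` and its index, so enlarging the cohort leaves the
#' life histories of earlier individuals unchanged.
#'
#' @param cfg A `sim_config`.
#' @param seed Integer seed (required).
#' @return An object of class `event_log`: a list with the `cfg`, the
#'   `seed`, and `individuals`, a list of per-worm records (`id`,
#'   `hatch_offset`, `maturation_time` (`NA` for juvenile deaths),
#'   `death_time`, and an `eggs` data frame with `lay_time`, `fertile`,
#'   `hatch_time`).
#' @export
simulate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed) || is.na(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  seed <- as.integer(seed)
  individuals <- lapply(seq_len(cfg$n), function(i) {
    # deterministic per-individual substream, independent of cfg$n
    set.seed((seed %% 599479L) * 3581L + i)
    hatch_offset <- stats::runif(1, 0, cfg$sync_window_h)
    juvenile <- stats::runif(1) < cfg$juvenile_death_prob
    maturation <- rtrunc_norm(1, cfg$maturation_mean, cfg$maturation_sd,
                              lower = cfg$maturation_min)
    if (juvenile) {
      return(list(id = sprintf("w%03d", i), hatch_offset = hatch_offset,
                  maturation_time = NA_real_,
                  death_time = stats::runif(1, cfg$maturation_min, maturation),
                  eggs = data.frame(lay_time = numeric(0),
                                    fertile = logical(0),
                                    hatch_time = numeric(0))))
    }
    death <- rtrunc_norm(1, cfg$lifespan_mean_d * 24, cfg$lifespan_sd_d * 24,
                         lower = maturation)
    n_eggs <- round(rtrunc_norm(1, cfg$eggs_mean, cfg$eggs_sd, lower = 1))
    # first egg defines maturation; the rest follow the laying intensity
    offsets <- if (n_eggs > 1)
      stats::rgamma(n_eggs - 1, shape = cfg$laying_shape,
                    scale = cfg$laying_scale) else numeric(0)
    lay <- sort(c(maturation, maturation + offsets))
    lay <- lay[lay < death]
    fertile <- stats::runif(length(lay)) < fertility_curve(lay, cfg)
    hatch <- rep(NA_real_, length(lay))
    if (any(fertile))
      hatch[fertile] <- lay[fertile] +
        rtrunc_norm(sum(fertile), cfg$hatch_delay_mean, cfg$hatch_delay_sd,
                    lower = 1e-6, upper = 48)
    list(id = sprintf("w%03d", i), hatch_offset = hatch_offset,
         maturation_time = maturation, death_time = death,
         eggs = data.frame(lay_time = lay, fertile = fertile,
                           hatch_time = hatch))
  })
  structure(list(cfg = cfg, seed = seed, individuals = individuals),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  n_egg <- sum(vapply(x$individuals, function(w) nrow(w$eggs), 1L))
  cat(sprintf("<event_log> n = %d individuals, %d eggs (seed %d)\n",
              length(x$individuals), n_egg, x$seed))
  invisible(x)
}

#' Observe an event log through a checkpoint schedule
#'
#' Converts exact simulated event times into the interval-censored records
#' an experimenter would write down: eggs are binned to the schedule
#' interval containing their lay time, hatched juveniles are credited to
#' the same interval (the drop is scored after eggs have had time to
#' hatch), and death is reported at the first checkpoint at or after the
#' death time. Individuals dying after the last checkpoint are recorded as
#' alive throughout (right-censored). Total eggs in the records always
#' equals the total number of egg events.
#'
#' @param events An `event_log` from [simulate_cohort()].
#' @param schedule A contiguous [observation_schedule()] whose horizon
#'   covers every egg event.
#' @return A `cohort_records` data frame.
#' @export
observe <- function(events, schedule) {
  stopifnot(inherits(events, "event_log"),
            inherits(schedule, "observation_schedule"))
  if (!is_contiguous(schedule))
    stop("observation requires a contiguous schedule", call. = FALSE)
  cp <- schedule$checkpoint
  horizon <- cp[length(cp)]
  rows <- lapply(events$individuals, function(w) {
    if (nrow(w$eggs) && max(w$eggs$lay_time) > horizon)
      stop(sprintf(
        "egg event at %.1f h beyond the schedule horizon (%g h)",
        max(w$eggs$lay_time), horizon), call. = FALSE)
    dead_slot <- if (w$death_time <= horizon)
      which(cp >= w$death_time)[1] else NA_integer_
    last <- if (is.na(dead_slot)) length(cp) else dead_slot
    # (start, end] binning of lay times onto checkpoint intervals
    slot <- findInterval(w$eggs$lay_time, c(cp[1] - schedule$width[1], cp),
                         left.open = TRUE)
    eggs <- tabulate(slot, nbins = length(cp))
    juv <- tabulate(slot[w$eggs$fertile], nbins = length(cp))
    data.frame(
      individual_id = w$id,
      interval_start = (cp - schedule$width)[seq_len(last)],
      interval_end = cp[seq_len(last)],
      eggs_laid = eggs[seq_len(last)],
      juveniles_hatched = juv[seq_len(last)],
      status = c(rep("alive", last - 1L),
                 if (is.na(dead_slot)) "alive" else "dead")
    )
  })
  cohort_records(do.call(rbind, rows))
}

#' Simulated hatching-time assay
#'
#' Emulates the snapshot assay behind [hatching_time()]: adults lay eggs at
#' a constant rate through an assay window; at the end the drop is fixed
#' and eggs that have not yet hatched are counted against hatched
#' juveniles. Returns the resulting [hatching_time()] estimate.
#'
#' @param cfg A `sim_config` (supplies the hatch-delay distribution).
#' @param seed Integer seed.
#' @param n_adults Number of laying adults (default 100).
#' @param duration_h Assay window in hours (default 32).
#' @param lay_rate Eggs per adult per hour (default 0.5).
#' @return A `hatching_estimate`.
#' @export
simulate_hatching_assay <- function(cfg, seed, n_adults = 100,
                                    duration_h = 32, lay_rate = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  n_eggs_total <- stats::rpois(1, n_adults * duration_h * lay_rate)
  lay <- stats::runif(n_eggs_total, 0, duration_h)
  delay <- rtrunc_norm(n_eggs_total, cfg$hatch_delay_mean,
                       cfg$hatch_delay_sd, lower = 1e-6, upper = 48)
  hatched <- lay + delay <= duration_h
  hatching_time(n_eggs = sum(!hatched), n_juv = sum(hatched),
                t_h = duration_h)
}

#' Expected net reproductive rate under a configuration
#'
#' The simulator's analytic expectation of R0 (survival-weighted lifetime
#' fertile-egg count per initial individual), computed by numerical
#' quadrature over the maturation-age and lifespan distributions rather
#' than by simulation; used as an independent check that the pipeline's
#' life-table R0 converges to the model's expectation.
#'
#' @param cfg A `sim_config`.
#' @param grid_n Number of quadrature nodes per dimension (default 121).
#' @return Expected offspring per initial individual.
#' @export
expected_r0 <- function(cfg, grid_n = 121) {
  stopifnot(inherits(cfg, "sim_config"))
  # maturation grid (truncated normal)
  m_lo <- cfg$maturation_min
  m_hi <- cfg$maturation_mean + 6 * cfg$maturation_sd
  if (cfg$maturation_sd == 0) {
    m_nodes <- max(cfg$maturation_mean, m_lo); m_w <- 1
  } else {
    m_edges <- seq(m_lo, m_hi, length.out = grid_n + 1)
    m_nodes <- (m_edges[-1] + m_edges[-length(m_edges)]) / 2
    m_w <- diff(stats::pnorm(m_edges, cfg$maturation_mean,
                             cfg$maturation_sd))
    m_w <- m_w / sum(m_w)
  }
  # expected fertile eggs for one mature individual with maturation m:
  # first egg at m (fertile w.p. p(m)), remaining eggs_mean-1 eggs at
  # m + gamma offsets, kept if laid before death L ~ N truncated > m
  mean_eggs <- truncnorm_mean(cfg$eggs_mean, cfg$eggs_sd, lower = 1)
  u_hi <- stats::qgamma(1 - 1e-9, cfg$laying_shape, scale = cfg$laying_scale)
  u_edges <- seq(0, u_hi, length.out = 2001)
  u_nodes <- (u_edges[-1] + u_edges[-length(u_edges)]) / 2
  u_w <- diff(stats::pgamma(u_edges, cfg$laying_shape,
                            scale = cfg$laying_scale))
  per_mat <- vapply(m_nodes, function(m) {
    p_first <- fertility_curve(m, cfg)
    # P(L > m + u) under L ~ N(mean, sd) truncated below at m
    ls_mean <- cfg$lifespan_mean_d * 24
    ls_sd <- cfg$lifespan_sd_d * 24
    if (ls_sd == 0) {
      p_alive <- as.numeric(m + u_nodes < ls_mean)
    } else {
      denom <- stats::pnorm(m, ls_mean, ls_sd, lower.tail = FALSE)
      p_alive <- stats::pnorm(m + u_nodes, ls_mean, ls_sd,
                              lower.tail = FALSE) / max(denom, 1e-300)
    }
    rest <- (mean_eggs - 1) *
      sum(u_w * p_alive * fertility_curve(m + u_nodes, cfg))
    p_first + rest
  }, numeric(1))
  (1 - cfg$juvenile_death_prob) * sum(m_w * per_mat)
}

truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> n = %d\n",
           "  maturation %g ± %g h (> %g h), juvenile death prob %.3f\n",
           "  lifespan %g ± %g d, lifetime eggs %g ± %g\n",
           "  laying gamma(shape %g, scale %g h) after maturation\n",
           "  fertility ramps: rise(%g, %g), fall(%g, %g), zero after %g h\n",
           "  hatch delay %g ± %g h\n"),
    x$n, x$maturation_mean, x$maturation_sd, x$maturation_min,
    x$juvenile_death_prob, x$lifespan_mean_d, x$lifespan_sd_d,
    x$eggs_mean, x$eggs_sd, x$laying_shape, x$laying_scale,
    x$fertility_rise_mid, x$fertility_rise_scale,
    x$fertility_fall_mid, x$fertility_fall_scale, x$fertility_zero_age,
    x$hatch_delay_mean, x$hatch_delay_sd))
  invisible(x)
}
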