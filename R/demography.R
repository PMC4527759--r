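#' Age conventions
#'
#' A life-table row summarizes reproduction over an interval; demographic
#' sums need a single representative age `x` per row. `interval_end` uses
#' the row's `time` column (the checkpoint closing the interval),
#' `interval_midpoint` uses `time - D/2`, and `interval_start` uses
#' `time - D`.
#'
#' @param lt A [life_table()].
#' @param convention One of `"interval_end"`, `"interval_midpoint"`,
#'   `"interval_start"`.
#' @return Ages in hours, one per row.
#' @export
row_ages <- function(lt, convention = c("interval_end", "interval_midpoint",
                                        "interval_start")) {
  stopifnot(inherits(lt, "life_table"))
  convention <- match.arg(convention)
  switch(convention,
         interval_end = lt$time,
         interval_midpoint = lt$time - lt$D / 2,
         interval_start = lt$time - lt$D)
}

HOURS_PER_DAY <- 24

#' Left-hand side of the Euler-Lotka equation
#'
#' Evaluates `sum(exp(-rm * x) * lx * mx)` over the life table, with ages
#' `x` converted from hours to days so that `rm` is a per-day rate. At
#' `rm = 0` this equals R0 exactly.
#'
#' @param rm Intrinsic rate of natural increase, per day.
#' @inheritParams row_ages
#' @return The dimensionless discounted reproduction sum.
#' @export
euler_lotka_lhs <- function(rm, lt, convention = "interval_end") {
  x_d <- row_ages(lt, convention) / HOURS_PER_DAY
  sum(exp(-rm * x_d) * lt$lx * lt$mx)
}

#' Intrinsic rate of natural increase (Euler-Lotka root)
#'
#' Solves `sum(exp(-rm * x) * lx * mx) = 1` for `rm`. The left-hand side is
#' continuous and strictly decreasing in `rm` whenever some `lx * mx > 0`,
#' so the root is unique: positive iff `R0 > 1`, zero iff `R0 = 1`,
#' negative iff `R0 < 1`. The root is bracketed (starting from
#' `[-5, 10]` per day, expanded geometrically if needed) and refined by
#' bisection until `|LHS - 1| < tol`.
#'
#' @inheritParams row_ages
#' @param tol Convergence tolerance on `|LHS - 1|` (default `1e-10`).
#' @return `rm` in per day.
#' @export
solve_rm <- function(lt, convention = "interval_end", tol = 1e-10) {
  r0 <- net_reproductive_rate(lt)
  if (r0 <= 0)
    stop("R0 = 0: the Euler-Lotka equation has no root", call. = FALSE)
  f <- function(r) euler_lotka_lhs(r, lt, convention) - 1
  lo <- -5; hi <- 10
  for (i in 1:60) {
    if (f(lo) > 0) break
    lo <- lo * 2
  }
  for (i in 1:60) {
    if (f(hi) < 0) break
    hi <- hi * 2
  }
  if (f(lo) < 0 || f(hi) > 0)
    stop("failed to bracket the Euler-Lotka root", call. = FALSE)
  mid <- (lo + hi) / 2
  for (i in 1:400) {
    fm <- f(mid)
    if (abs(fm) < tol) break
    if (fm > 0) lo <- mid else hi <- mid
    new_mid <- (lo + hi) / 2
    if (new_mid == mid) break  # machine precision reached
    mid <- new_mid
  }
  mid
}

#' Population doubling time
#'
#' `PDT = ln(2) / rm`, converted to hours: the time for an exponentially
#' growing population (at its stable age structure) to double.
#'
#' @param rm Intrinsic rate of natural increase, per day.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(rm) {
  if (length(rm) != 1L || is.na(rm) || rm <= 0)
    stop("doubling time is undefined for rm <= 0", call. = FALSE)
  log(2) / rm * HOURS_PER_DAY
}

#' Cohort generation time G0
#'
#' The survival-and-fecundity-weighted mean reproductive age,
#' `G0 = sum(x * lx * mx) / sum(lx * mx)`, in hours.
#'
#' @inheritParams row_ages
#' @return G0 in hours.
#' @export
generation_time_g0 <- function(lt, convention = "interval_end") {
  r0 <- net_reproductive_rate(lt)
  if (r0 <= 0) stop("G0 is undefined when R0 = 0", call. = FALSE)
  x <- row_ages(lt, convention)
  sum(x * lt$lx * lt$mx) / r0
}

#' Generation time G1
#'
#' The time for a population growing at rate `rm` to increase by a factor
#' of R0: `G1 = ln(R0) / rm`, converted to hours.
#'
#' @param r0 Net reproductive rate (offspring per individual), `> 0`.
#' @param rm Intrinsic rate of natural increase, per day, nonzero.
#' @return G1 in hours.
#' @export
generation_time_g1 <- function(r0, rm) {
  if (r0 <= 0) stop("G1 is undefined when R0 <= 0", call. = FALSE)
  if (rm == 0) stop("G1 is undefined when rm = 0", call. = FALSE)
  log(r0) / rm * HOURS_PER_DAY
}

#' Generation time Gh
#'
#' The mean parental age of offspring in the growth-discounted schedule,
#' `Gh = sum(x * exp(-rm * x) * lx * mx)` with `x` in hours and the
#' exponent evaluated in days. The formula presupposes that `rm` is the
#' Euler-Lotka root of the table, where the discounted reproduction sum is
#' 1 and the discounted terms form a probability distribution over parental
#' ages. If called with any other `rm`, the sum is normalized by the
#' discounted total and the result carries attribute `normalized = TRUE`.
#'
#' @inheritParams row_ages
#' @param rm Intrinsic rate of natural increase, per day.
#' @param tol Tolerance on `|discounted sum - 1|` before normalizing.
#' @return Gh in hours.
#' @export
generation_time_gh <- function(lt, rm, convention = "interval_end",
                               tol = 1e-6) {
  x_h <- row_ages(lt, convention)
  w <- exp(-rm * x_h / HOURS_PER_DAY) * lt$lx * lt$mx
  total <- sum(w)
  gh <- sum(x_h * w)
  if (abs(total - 1) > tol) {
    gh <- gh / total
    attr(gh, "normalized") <- TRUE
  }
  gh
}

#' Snapshot hatching-time estimator
#'
#' Estimates the egg-to-hatch duration from a fixed-and-stained snapshot of
#' drops in which adults laid eggs for `t_h` hours:
#' `Ht = n_eggs / (n_juv + n_eggs) * t_h`, where `n_eggs` counts eggs still
#' unhatched at fixation and `n_juv` the juveniles already hatched. Under
#' steady egg laying, the fraction of eggs still unhatched estimates the
#' fraction of the assay window occupied by embryonic development.
#'
#' @param n_eggs Number of unhatched eggs at fixation (nonnegative count).
#' @param n_juv Number of hatched juveniles at fixation (nonnegative count).
#' @param t_h Assay duration in hours, `> 0`.
#' @return An object of class `hatching_estimate`: list with `h_t` (hours),
#'   `n_eggs`, `n_juv`, `t_h`.
#' @examples
#' hatching_time(79, 21, 32)
#' @export
hatching_time <- function(n_eggs, n_juv, t_h) {
  if (t_h <= 0) stop("assay duration t_h must be positive", call. = FALSE)
  if (n_eggs < 0 || n_juv < 0 || n_eggs != round(n_eggs) ||
      n_juv != round(n_juv))
    stop("egg and juvenile counts must be nonnegative integers",
         call. = FALSE)
  if (n_eggs + n_juv == 0)
    stop("hatching time is undefined with no eggs and no juveniles",
         call. = FALSE)
  structure(list(h_t = n_eggs / (n_juv + n_eggs) * t_h,
                 n_eggs = n_eggs, n_juv = n_juv, t_h = t_h),
            class = "hatching_estimate")
}

#' @export
print.hatching_estimate <- function(x, ...) {
  cat(sprintf(
    "<hatching_estimate> Ht = %.2f h (%d eggs, %d juveniles, %g h assay)\n",
    x$h_t, x$n_eggs, x$n_juv, x$t_h))
  invisible(x)
}

#' Leslie-matrix growth-rate oracle
#'
#' An independent route to the population growth rate: the life table is
#' laid onto a uniform age grid of width `step` hours (each row's
#' reproduction stays concentrated at its representative age, which must be
#' a multiple of `step`), the corresponding Leslie projection matrix is
#' assembled with survival subdiagonal `P_i = l((i+1)s) / l(is)` and
#' fertilities placed so that the matrix's characteristic equation is
#' exactly the discrete Euler-Lotka equation of the table, and the growth
#' rate is recovered as `log(lambda) / step` from the dominant eigenvalue.
#'
#' @inheritParams row_ages
#' @param step Projection interval in hours; must divide every
#'   representative age (default 1 h).
#' @return Growth rate in per day.
#' @export
leslie_growth_oracle <- function(lt, step = 1, convention = "interval_end") {
  stopifnot(inherits(lt, "life_table"))
  if (net_reproductive_rate(lt) <= 0)
    stop("growth rate undefined for a table with no reproduction",
         call. = FALSE)
  x <- row_ages(lt, convention)
  if (any(x <= 0))
    stop("representative ages must be positive; use a later convention",
         call. = FALSE)
  k <- x / step
  if (any(abs(k - round(k)) > 1e-8))
    stop("step must divide every representative age", call. = FALSE)
  if (step > min(lt$D))
    stop("step is coarser than the narrowest life-table interval",
         call. = FALSE)
  k <- as.integer(round(k))
  n_class <- max(k)

  # survivorship as a right-continuous step function of age:
  # l(t) = lx of the last checkpoint at or before t, 1 before the first
  surv_at <- function(t) {
    i <- findInterval(t + 1e-9, lt$time)
    ifelse(i == 0, 1, lt$lx[pmax(i, 1)])
  }
  grid <- (0:n_class) * step
  l_grid <- surv_at(grid)
  P <- ifelse(l_grid[-length(l_grid)] > 0,
              l_grid[-1] / pmax(l_grid[-length(l_grid)], .Machine$double.eps),
              0)
  # fertility placed so the characteristic-equation term for row i is
  # mx[i] * lx[i] * lambda^(-x_i/step): F = mx[i] * lx[i] / l(x_i - step)
  F_row <- numeric(n_class)
  for (i in seq_len(nrow(lt))) {
    if (lt$mx[i] == 0 || lt$lx[i] <= 0) next
    denom <- l_grid[k[i]]  # survivorship to the class start, l(x_i - step)
    if (denom <= 0) next   # no survivors reach this age: contributes nothing
    F_row[k[i]] <- F_row[k[i]] + lt$mx[i] * lt$lx[i] / denom
  }
  A <- matrix(0, n_class, n_class)
  A[1, ] <- F_row
  if (n_class > 1)
    A[cbind(2:n_class, 1:(n_class - 1))] <- P[1:(n_class - 1)]
  ev <- eigen(A, only.values = TRUE)$values
  lambda <- max(Re(ev))  # Perron root of a nonnegative matrix
  if (lambda <= 0)
    stop("projection matrix has no positive dominant eigenvalue",
         call. = FALSE)
  log(lambda) / step * HOURS_PER_DAY
}

#' Full demographic analysis of a life table
#'
#' Bundles the rate metrics computed from one life table under one age
#' convention: R0, TFR, the Euler-Lotka `rm`, PDT, and the three
#' generation-time measures. All quantities are internally consistent
#' (PDT from the solved `rm`, G1 from R0 and `rm`, Gh at the solved root).
#' When `R0 <= 1`, `rm` is zero or negative and PDT is `NA`.
#'
#' @inheritParams row_ages
#' @return An object of class `demography_result`: list with `r0`, `tfr`,
#'   `rm` (per day), `pdt_h`, `g0_h`, `g1_h`, `gh_h`, `convention`.
#' @examples
#' full_demography(pacificus_life_table())
#' @export
full_demography <- function(lt, convention = "interval_end") {
  convention <- match.arg(convention, c("interval_end", "interval_midpoint",
                                        "interval_start"))
  r0 <- net_reproductive_rate(lt)
  tfr <- total_fertility_rate(lt)
  if (r0 <= 0)
    stop("demographic rates are undefined for a table with no reproduction",
         call. = FALSE)
  rm <- solve_rm(lt, convention)
  structure(list(
    r0 = r0,
    tfr = tfr,
    rm = rm,
    pdt_h = if (rm > 0) doubling_time(rm) else NA_real_,
    g0_h = generation_time_g0(lt, convention),
    g1_h = if (rm != 0) generation_time_g1(r0, rm) else NA_real_,
    gh_h = as.numeric(generation_time_gh(lt, rm, convention)),
    convention = convention
  ), class = "demography_result")
}

#' @export
print.demography_result <- function(x, ...) {
  cat(sprintf("<demography_result> (ages: %s)\n", x$convention))
  cat(sprintf("  R0   %8.2f offspring/individual\n", x$r0))
  cat(sprintf("  TFR  %8.2f offspring/individual\n", x$tfr))
  cat(sprintf("  rm   %8.3f per day\n", x$rm))
  cat(sprintf("  PDT  %8.1f h%s\n",
              if (is.na(x$pdt_h)) NA else x$pdt_h,
              if (is.na(x$pdt_h)) " (undefined: rm <= 0)" else ""))
  cat(sprintf("  G0   %8.1f h\n", x$g0_h))
  cat(sprintf("  G1   %8.1f h\n", x$g1_h))
  cat(sprintf("  Gh   %8.1f h\n", x$gh_h))
  invisible(x)
}
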