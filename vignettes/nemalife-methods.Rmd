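---
title: "Cohort life-table demography with nemalife: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort life-table demography with nemalife}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemalife)
```

## The problem

Synchronized cohorts of selfing hermaphrodite nematodes, reared one animal
per hanging drop, are the standard way to measure life-history traits at
the individual level: at each checkpoint the worm is moved to a fresh drop,
the eggs left behind are counted, and the old drop is kept long enough
(48 h) that every fertile egg hatches and can be scored. The raw data are
therefore *interval-censored*: we never see a death time or a laying time,
only the interval in which it happened. `nemalife` turns such logs into the
classical demographic quantities.

## The life-table model

For the interval ending at age $x$ (hours on the shared cohort clock):

* $l_x$ — the proportion of the initial cohort ($n_0$) alive at $x$;
* $m_x$ — juveniles hatched from eggs laid in the interval, per surviving
  individual.

From the table,

$$R_0 = \sum_x l_x m_x, \qquad \mathrm{TFR} = \sum_x m_x,$$

and the intrinsic rate of natural increase $r_m$ is the unique root of the
Euler-Lotka equation

$$\sum_x e^{-r_m x}\, l_x m_x = 1,$$

with $x$ in days and $r_m$ per day. The derived measures are the doubling
time $\mathrm{PDT} = \ln 2 / r_m$, the cohort generation time
$G_0 = \sum x\, l_x m_x / \sum l_x m_x$, $G_1 = \ln R_0 / r_m$, and
$G_h = \sum x\, e^{-r_m x} l_x m_x$ evaluated at the root (where the
discounted terms form a probability distribution over parental ages).
The snapshot hatching-time estimator is
$H_t = N_{\mathrm{eggs}} / (N_{\mathrm{juv}} + N_{\mathrm{eggs}}) \times T_h$:
under steady laying, the fraction of eggs still unhatched after a $T_h$-hour
assay estimates the fraction of the window occupied by embryonic
development, so $H_t$ recovers the mean egg-to-hatch delay when
$T_h$ exceeds it.

```{r}
lt <- pacificus_life_table()
full_demography(lt)
```

## Conventions the data force us to choose

Published tables rarely state their bookkeeping. These are the package's
choices, each selectable where reasonable:

* **$l_x$ timing.** $l_x$ counts individuals alive at the interval's *end*
  checkpoint. This is the only convention consistent with the bundled
  table: a death at 89 h lowers $l_x$ at the 93 h row, not the 87 h row.
* **$m_x$ denominator.** Individuals alive at the interval's end (the same
  population as $l_x$); `build_life_table(denominator = "alive_start")`
  gives the alternative.
* **Representative age $x$.** A row summarizes a whole interval; sums need
  one age per row. The default `interval_end` uses the checkpoint time —
  the only choice validated by a printed value ($G_0 = 137$ h on the
  bundled table); `interval_midpoint` and `interval_start` are available,
  and the Leslie oracle accepts all three.
* **Hatch-count attribution.** Juveniles are credited to the interval in
  which their egg was *laid* (the drop), matching the leave-in-drop
  protocol — not the interval in which they hatched.
* **Juvenile deaths** count in $l_x$ and in the rate of increase, but are
  excluded from the fecundity-percentage means and from the life-span and
  egg-total summaries; they surface as the juvenile-mortality proportion.
* **Interval-censored event times** (death, first egg) are imputed at the
  midpoint of the interval in which they were scored. Under a
  near-uniform within-interval distribution this is unbiased, unlike
  end-of-interval imputation which inflates life spans by half a width.

## Numerical choices

* **Root-finding.** The Euler-Lotka left-hand side is continuous and
  strictly decreasing wherever some $l_x m_x > 0$, so the root is unique.
  It is bracketed on $[-5, 10]$ d$^{-1}$ (expanded geometrically if
  needed) and bisected until $|\mathrm{LHS} - 1| < 10^{-10}$ — bisection
  is unconditionally convergent on a monotone function.
* **Leslie-matrix oracle.** An independent route to the same growth rate:
  the table is laid on a uniform age grid (the step must divide every
  representative age), survival subdiagonal entries come from the
  survivorship step function, and fertilities are placed so the matrix's
  characteristic equation is exactly the table's discrete Euler-Lotka
  equation. The dominant eigenvalue then gives
  $r_m = \ln \lambda / \mathrm{step}$, computed by `eigen()` rather than
  root-finding. Agreement to $10^{-6}$ on the bundled table and $10^{-3}$
  on random tables is part of the test suite.
* **$G_h$ off the root.** The printed formula presupposes the root; for
  any other rate the discounted sum is not 1, so the result is normalized
  by it and flagged with attribute `normalized`.
* **Printed-product tolerance.** Readers recompute $l_x m_x$ at full
  precision; a printed product column deviating by more than 0.01 warns
  rather than fails, because published tables often derive products from
  unrounded survivorship (the bundled table deviates by up to 0.012 for
  exactly that reason).
* **Degenerate inputs.** An empty table has $R_0 = \mathrm{TFR} = 0$;
  rate metrics refuse tables with no reproduction; a shrinking cohort
  ($R_0 < 1$) yields $r_m < 0$ and an undefined PDT.

## What the simulator emulates

`simulate_cohort()` draws, per individual: a maturation age (normal
65.1 ± 8.4 h, truncated above 24 h), with probability 2/33 a juvenile
death before maturation; otherwise an adult lifespan (normal
22.5 ± 7.3 d, truncated above the maturation age), a lifetime egg budget
(normal 269.6 ± 73.4, truncated at 1), lay times, per-egg fertility from
an age-dependent curve, and a hatch delay (normal 25.3 ± 1.6 h) for each
fertile egg. `observe()` then censors the exact event times through any
checkpoint schedule; `default_schedule()` reproduces the standard cadence
(daily checks, then 6-h transfers to 126 h, 12-h to 294 h, daily again to
the horizon).

Design decisions where the published summaries left the model open:

* **Maturation is the first egg.** The reported age at first reproduction
  *is* the age of first egg deposition, so the simulator lays the first
  egg exactly at the drawn maturation age and distributes the remaining
  budget as gamma offsets after it. This makes the estimand of the
  recovery tests well-defined.
* **Laying intensity.** A single unimodal gamma over age since
  maturation, with two calibration anchors: mode 75.7 h post-maturation
  (so the population peak laying rate falls near 141 h of age) and 21% of
  the egg mass after fertility has collapsed (the reported count of
  late-life unfertile eggs), giving shape 1.864 and scale 87.63 h. The
  apparent late second "peak" of daily egg counts in such experiments is
  produced by the observer's coarser late-schedule binning, not by a
  bimodal intensity.
* **Fertility curve.** Two logistic ramps (rise times fall) through the
  reported anchors — 97.4% near 6.1 d, 0.21% at 12.8 d, zero after 13 d.
  The functional form between anchors is the package's choice; nothing in
  the summaries constrains it further.
* **Independence.** Traits are drawn independently per individual; no
  lifespan-fecundity correlation is imposed, and matricidal hatching
  (*endotokia matricida*) is not modelled.
* **Reproducible substreams.** Each individual's draws come from a seed
  derived arithmetically from the master seed and its index, so enlarging
  a cohort never reshuffles earlier individuals.

### What passing the recovery tests does and does not show

The recovery suite simulates 200 replicate cohorts of $n = 33$ and checks
that the configured means (life span 22.5 d, first-egg age 65.1 h,
lifetime eggs 269.6) fall inside the central 99% of the replicate
estimates. Two systematic effects are visible and expected: the egg-total
estimate sits a few percent below the configured mean because individuals
dying early never lay their full budget (the configured count is a
*potential*, the observed count a *realized* total), and first-egg ages
carry sub-hour binning effects from the 6-h cadence. Passing shows the
pipeline is calibrated against its own generative model under realistic
censoring — it does not validate the biological realism of the
independence assumptions, the gamma intensity shape, or the logistic
fertility ramps against raw per-worm data, which are not published.

The analytic cross-check `expected_r0()` computes the model's expected
$R_0$ by quadrature over the maturation and lifespan distributions; a
large simulated cohort's life-table $R_0$ must match it within a CLT
bound, tying the pipeline (simulate, observe, bin, build, sum) to the
model's closed-form expectation through an independent route.

## Problem sizes

The default test and reporting runs use 200 replicate cohorts of 33
individuals, single cohorts of up to 2 500 individuals for the CLT
check, and 100 random tables for the solver-vs-oracle property — sizes at
which every Monte-Carlo tolerance above is comfortably resolved.

## Known limitations

* One-sex selfing model only; no males, outcrossing, or sperm limitation.
* No bootstrap confidence intervals on $r_m$ (a natural extension:
  resample individuals, rebuild the table, re-solve).
* The fecundity percentage is undefined in intervals where no alive
  mature individual laid eggs; such checkpoints are reported as `NA`
  rather than interpolated.
* Non-contiguous schedules are representable for reading published
  tables, but `observe()` requires a contiguous schedule so that egg
  conservation is exact.
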