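test_that("juvenile deaths at 62 and 89 h reproduce the published lx pattern", {
  pp <- published_pattern_records()
  lt <- build_life_table(pp$records, pp$schedule)
  expect_equal(n0(lt), 33)
  expect_equal(lt$time[1], 75)  # window starts at first reproduction
  rows_097 <- lt$time %in% c(75, 81, 87)
  expect_equal(round(lt$lx[rows_097], 2), rep(0.97, 3))
  expect_equal(round(lt$lx[lt$time >= 93], 2),
               rep(0.94, sum(lt$time >= 93)))
})

test_that("a single always-alive individual gives lx = 1 and mx = its output", {
  sched <- observation_schedule(c(24, 48, 72))
  rec <- cohort_records(data.frame(
    individual_id = "solo",
    interval_start = c(0, 24, 48), interval_end = c(24, 48, 72),
    eggs_laid = c(0, 5, 0), juveniles_hatched = c(0, 5, 0),
    status = "alive"))
  lt <- build_life_table(rec, sched)
  expect_equal(nrow(lt), 1)     # window is the single productive interval
  expect_equal(lt$lx, 1)
  expect_equal(lt$mx, 5)
  expect_equal(net_reproductive_rate(lt), 5)
})

test_that("a cohort with no eggs yields an empty table and R0 = 0", {
  sched <- observation_schedule(c(24, 48))
  rec <- cohort_records(data.frame(
    individual_id = rep(c("a", "b"), each = 2),
    interval_start = rep(c(0, 24), 2), interval_end = rep(c(24, 48), 2),
    eggs_laid = 0, juveniles_hatched = 0, status = "alive"))
  lt <- build_life_table(rec, sched)
  expect_equal(nrow(lt), 0)
  expect_equal(net_reproductive_rate(lt), 0)
  expect_equal(total_fertility_rate(lt), 0)
})

test_that("records not aligned to the schedule raise an alignment error", {
  sched <- observation_schedule(c(24, 48))
  rec <- cohort_records(data.frame(
    individual_id = "a", interval_start = 10, interval_end = 30,
    eggs_laid = 1, juveniles_hatched = 1, status = "alive"))
  expect_error(build_life_table(rec, sched), "does not align")
})

test_that("R0 and TFR match brute-force accumulation on random tables", {
  for (seed in 1:25) {
    lt <- random_life_table(seed)
    r0_loop <- 0
    tfr_loop <- 0
    for (i in seq_len(nrow(lt))) {
      r0_loop <- r0_loop + lt$lx[i] * lt$mx[i]
      tfr_loop <- tfr_loop + lt$mx[i]
    }
    expect_equal(net_reproductive_rate(lt), r0_loop)
    expect_equal(total_fertility_rate(lt), tfr_loop)
    expect_gte(tfr_loop, r0_loop)  # lx <= 1 forces TFR >= R0
    expect_true(all(lt$lxmx >= 0))
  }
})

test_that("fecundity schedule averages per-individual hatch fractions", {
  sched <- observation_schedule(c(24, 48))
  rec <- cohort_records(data.frame(
    individual_id = c("a", "a", "b", "b"),
    interval_start = c(0, 24, 0, 24), interval_end = c(24, 48, 24, 48),
    eggs_laid = c(2, 10, 1, 10), juveniles_hatched = c(2, 10, 1, 9),
    status = "alive"))
  fec <- fecundity_schedule(rec)
  expect_equal(fec$fecundity_pct[fec$time == 48], 95)  # mean of 1.0 and 0.9
  expect_equal(fec$eggs_per_interval[fec$time == 48], 10)
})

test_that("intervals with only unfertile eggs give 0% fecundity", {
  rec <- cohort_records(data.frame(
    individual_id = c("a", "b"),
    interval_start = 0, interval_end = 24,
    eggs_laid = c(4, 6), juveniles_hatched = 0, status = "alive"))
  expect_equal(fecundity_schedule(rec)$fecundity_pct, 0)
})

test_that("immature and dead individuals are excluded from fecundity", {
  rec <- cohort_records(data.frame(
    individual_id = c("mat", "mat", "imm", "imm", "dead", "dead"),
    interval_start = c(0, 24, 0, 24, 0, 24),
    interval_end = c(24, 48, 24, 48, 24, 48),
    eggs_laid = c(2, 4, 0, 0, 8, 8),
    juveniles_hatched = c(1, 4, 0, 0, 8, 0),
    status = c("alive", "alive", "alive", "alive", "alive", "dead")))
  fec <- fecundity_schedule(rec)
  # at 48 h only "mat" counts: "imm" never laid, "dead" is dead at 48 h
  expect_equal(fec$fecundity_pct[fec$time == 48], 100)
})

test_that("simulated cohorts recover the peak fertility near its configured value", {
  cfg <- pacificus_config()
  rec <- observe(simulate_cohort(cfg, seed = 101), default_schedule())
  fec <- fecundity_schedule(rec)
  peak <- max(fec$fecundity_pct, na.rm = TRUE)
  expect_lt(abs(peak - 97.4), 3)
})

test_that("cohort summary reduces to exact values on constructed cohorts", {
  # every individual lays its first egg in the interval centred on 65 h
  rec <- cohort_records(data.frame(
    individual_id = rep(c("a", "b"), each = 2),
    interval_start = rep(c(38, 62), 2), interval_end = rep(c(62, 68), 2),
    eggs_laid = rep(c(0, 3), 2), juveniles_hatched = rep(c(0, 3), 2),
    status = "alive"))
  cs <- cohort_summary(rec)
  expect_equal(cs$age_min_h, 65)
  expect_equal(cs$sd_age_min_h, 0)
  expect_equal(cs$n_censored, 2)
  expect_true(is.na(cs$mean_lifespan_d))

  # deaths centred on 20 d and 25 d average to 22.5 d
  rec2 <- cohort_records(data.frame(
    individual_id = c("a", "a", "b", "b"),
    interval_start = c(0, 476, 0, 596), interval_end = c(476, 484, 596, 604),
    eggs_laid = c(5, 0, 5, 0), juveniles_hatched = c(5, 0, 5, 0),
    status = c("alive", "dead", "alive", "dead")))
  cs2 <- cohort_summary(rec2)
  expect_equal(cs2$mean_lifespan_d, 22.5)
  expect_equal(cs2$juvenile_mortality, 0)
})

test_that("pipeline estimates recover simulator parameters at default config", {
  cfg <- pacificus_config()
  cs <- cohort_summary(observe(simulate_cohort(cfg, seed = 7),
                               default_schedule()))
  expect_lt(abs(cs$mean_lifespan_d - cfg$lifespan_mean_d),
            2 * cfg$lifespan_sd_d)
  expect_lt(abs(cs$age_min_h - cfg$maturation_mean), 2 * cfg$maturation_sd)
  expect_lt(abs(cs$total_eggs - cfg$eggs_mean), 2 * cfg$eggs_sd)
  expect_lte(cs$age_min_h, cs$age_max_h)
  expect_gte(cs$juvenile_mortality, 0)
  expect_lte(cs$juvenile_mortality, 1)
})

test_that("juvenile-production totals are conserved under re-binning", {
  cfg <- pacificus_config(n = 20)
  ev <- simulate_cohort(cfg, seed = 3)
  fine <- observation_schedule(seq(6, 1200, by = 6))
  coarse <- observation_schedule(seq(24, 1200, by = 24))
  lt_f <- build_life_table(observe(ev, fine), fine)
  lt_c <- build_life_table(observe(ev, coarse), coarse)
  # sum over rows of mx * (alive count) = total juveniles, schedule-invariant
  expect_equal(sum(lt_f$mx * lt_f$lx * n0(lt_f)),
               sum(lt_c$mx * lt_c$lx * n0(lt_c)))
  # and therefore R0 itself is conserved exactly
  expect_equal(net_reproductive_rate(lt_f), net_reproductive_rate(lt_c))
})

test_that("R0 from a large simulated cohort matches the analytic expectation", {
  cfg <- pacificus_config(n = 2500)
  sched <- default_schedule()
  rec <- observe(simulate_cohort(cfg, seed = 19), sched)
  lt <- build_life_table(rec, sched)
  r0_hat <- net_reproductive_rate(lt)
  ind <- individual_summaries(rec)
  clt_bound <- 4 * stats::sd(ind$total_juveniles) / sqrt(cfg$n)
  expect_lt(abs(r0_hat - expected_r0(cfg)), clt_bound)
})

test_that("the two mx denominator conventions differ only at death intervals", {
  pp <- published_pattern_records()
  lt_end <- build_life_table(pp$records, pp$schedule, denominator = "alive_end")
  lt_start <- build_life_table(pp$records, pp$schedule,
                               denominator = "alive_start")
  # the 89-h death makes alive_start (32) exceed alive_end (31) at 93 h
  expect_lt(lt_start$mx[lt_start$time == 93], lt_end$mx[lt_end$time == 93])
  expect_equal(lt_start$mx[lt_start$time == 123],
               lt_end$mx[lt_end$time == 123])
})
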