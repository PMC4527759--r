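test_that("the discounted reproduction sum reduces to R0 at rm = 0", {
  for (seed in 1:20) {
    lt <- random_life_table(seed)
    expect_identical(euler_lotka_lhs(0, lt), net_reproductive_rate(lt))
  }
})

test_that("the discounted sum matches a term-by-term loop at any rate", {
  set.seed(99)
  for (seed in 1:10) {
    lt <- random_life_table(seed)
    for (rm in c(-1, -0.1, 0.3, 1.2, 4)) {
      loop <- 0
      for (i in seq_len(nrow(lt)))
        loop <- loop + exp(-rm * lt$time[i] / 24) * lt$lx[i] * lt$mx[i]
      expect_equal(euler_lotka_lhs(rm, lt), loop)
    }
  }
})

test_that("a single age class one day old with lx*mx = e sums to 1 at rm = 1", {
  lt <- life_table(24, 6, 1, exp(1), n0 = 1, check_counts = FALSE)
  expect_equal(euler_lotka_lhs(1, lt), 1)
})

test_that("the Euler-Lotka root has a closed form for one age class", {
  lt <- life_table(48, 6, 1, 20, n0 = 1)  # R0 = 20 at x = 2 d
  expect_equal(solve_rm(lt), log(20) / 2, tolerance = 1e-8)
  lt1 <- life_table(48, 6, 1, 1, n0 = 1)  # R0 = 1 -> rm = 0
  expect_equal(solve_rm(lt1), 0, tolerance = 1e-8)
})

test_that("the root's sign tracks R0 - 1 and the LHS is strictly decreasing", {
  for (seed in 21:40) {
    lt <- random_life_table(seed)
    r0 <- net_reproductive_rate(lt)
    rm <- solve_rm(lt)
    expect_lt(abs(euler_lotka_lhs(rm, lt) - 1), 1e-10)
    if (abs(r0 - 1) > 1e-6) expect_equal(sign(rm), sign(r0 - 1))
    grid <- seq(-2, 4, by = 0.5)
    vals <- vapply(grid, euler_lotka_lhs, numeric(1), lt = lt)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("doubling time converts a per-day rate to hours", {
  expect_equal(round(doubling_time(1.125), 1), 14.8)
  expect_equal(doubling_time(log(2)), 24)
  expect_equal(round(doubling_time(0.1), 2), 166.36)
  expect_error(doubling_time(0), "undefined")
  expect_error(doubling_time(-0.5), "undefined")
})

test_that("exponential growth at the solved rate doubles in one PDT", {
  for (seed in c(2, 5, 8)) {
    lt <- random_life_table(seed)
    if (net_reproductive_rate(lt) <= 1) next
    rm <- solve_rm(lt)
    pdt_d <- doubling_time(rm) / 24
    expect_equal(exp(rm * pdt_d), 2, tolerance = 1e-10)
  }
})

test_that("G0 is the reproduction-weighted mean age", {
  lt <- pacificus_life_table()
  expect_equal(generation_time_g0(lt), 137, tolerance = 0.5 / 137)

  single <- life_table(50, 5, 1, 3, n0 = 1)
  expect_equal(generation_time_g0(single), 50)

  for (seed in 41:50) {
    rt <- random_life_table(seed)
    num <- 0
    for (i in seq_len(nrow(rt))) num <- num + rt$time[i] * rt$lx[i] * rt$mx[i]
    expect_equal(generation_time_g0(rt), num / net_reproductive_rate(rt))
  }
})

test_that("G1 evaluates ln(R0)/rm in hours", {
  expect_equal(generation_time_g1(exp(1), 1), 24)
  expect_equal(generation_time_g1(108.95, 1.125), 100.1, tolerance = 5e-4)
  expect_equal(generation_time_g1(1, 0.7), 0)
  expect_error(generation_time_g1(108.95, 0), "undefined")
  expect_error(generation_time_g1(0, 1), "undefined")
})

test_that("Gh equals the age of a single reproductive class at its root", {
  lt <- life_table(50, 5, 1, 7, n0 = 1)
  rm <- solve_rm(lt)
  expect_equal(as.numeric(generation_time_gh(lt, rm)), 50, tolerance = 1e-8)
})

test_that("Gh equals G0 in the discount-free limit rm = 0", {
  lt <- life_table(c(30, 60), c(6, 6), c(1, 1), c(0.25, 0.75), n0 = 1,
                   check_counts = FALSE)  # R0 = 1 so the root is rm = 0
  rm <- solve_rm(lt)
  expect_equal(as.numeric(generation_time_gh(lt, rm)),
               generation_time_g0(lt), tolerance = 1e-6)
})

test_that("Gh never exceeds G0 for growing populations and matches a loop", {
  for (seed in 51:70) {
    lt <- random_life_table(seed)
    if (net_reproductive_rate(lt) <= 1) next
    rm <- solve_rm(lt)
    gh <- generation_time_gh(lt, rm)
    loop <- 0
    for (i in seq_len(nrow(lt)))
      loop <- loop + lt$time[i] * exp(-rm * lt$time[i] / 24) *
        lt$lx[i] * lt$mx[i]
    expect_equal(as.numeric(gh), loop, tolerance = 1e-8)
    expect_lte(as.numeric(gh), generation_time_g0(lt))
    expect_null(attr(gh, "normalized"))
  }
})

test_that("Gh at a non-root rate is normalized and flagged", {
  lt <- pacificus_life_table()
  gh <- generation_time_gh(lt, 0.25)
  expect_true(isTRUE(attr(gh, "normalized")))
  w <- exp(-0.25 * lt$time / 24) * lt$lxmx
  expect_equal(as.numeric(gh), sum(lt$time * w) / sum(w))
})

test_that("the hatching-time estimator evaluates the snapshot formula", {
  ht <- hatching_time(79, 21, 32)
  expect_s3_class(ht, "hatching_estimate")
  expect_equal(ht$h_t, 25.28)
  expect_equal(hatching_time(0, 5, 32)$h_t, 0)
  expect_equal(hatching_time(10, 10, 32)$h_t, 16)
  expect_error(hatching_time(0, 0, 32), "undefined")
  expect_error(hatching_time(3, 1, 0), "positive")
  expect_error(hatching_time(-1, 1, 32), "nonnegative")
})

test_that("the Leslie oracle recovers the closed form for one age class", {
  lt <- life_table(48, 6, 1, 20, n0 = 1)        # R0 = 20 at 2 d
  expect_equal(leslie_growth_oracle(lt, step = 1), log(20) / 2,
               tolerance = 1e-9)
  lt1 <- life_table(48, 6, 1, 1, n0 = 1)        # R0 = 1 -> zero growth
  expect_equal(leslie_growth_oracle(lt1, step = 1), 0, tolerance = 1e-9)
})

test_that("root-finder and Leslie oracle agree on the published table", {
  lt <- pacificus_life_table()
  for (conv in c("interval_end", "interval_midpoint", "interval_start")) {
    expect_equal(leslie_growth_oracle(lt, step = 3, convention = conv),
                 solve_rm(lt, conv), tolerance = 1e-6)
  }
})

test_that("root-finder and Leslie oracle agree on random tables", {
  for (seed in 1:100) {
    lt <- random_life_table(seed)
    rm <- solve_rm(lt)
    expect_lt(abs(leslie_growth_oracle(lt, step = 1) - rm), 1e-3)
  }
})

test_that("the Leslie oracle validates its age grid", {
  lt <- life_table(50, 5, 1, 3, n0 = 1)
  expect_error(leslie_growth_oracle(lt, step = 4), "divide")
  expect_error(leslie_growth_oracle(lt, step = 10), "coarser")
})

test_that("full_demography bundles internally consistent metrics", {
  lt <- pacificus_life_table()
  dem <- full_demography(lt)
  expect_equal(dem$r0, 108.95, tolerance = 0.1 / 108.95)
  expect_equal(dem$tfr, 115.35, tolerance = 0.1 / 115.35)
  expect_equal(dem$g0_h, 137, tolerance = 0.5 / 137)
  expect_equal(dem$pdt_h, doubling_time(dem$rm))
  expect_equal(dem$g1_h, generation_time_g1(dem$r0, dem$rm))
  expect_lt(abs(euler_lotka_lhs(dem$rm, lt) - 1), 1e-10)

  single <- life_table(50, 5, 1, 7, n0 = 1)
  ds <- full_demography(single)
  expect_equal(ds$g0_h, 50)
  expect_equal(ds$g1_h, 50, tolerance = 1e-8)
  expect_equal(ds$gh_h, 50, tolerance = 1e-8)

  shrinking <- life_table(48, 6, 0.5, 1, n0 = 2)  # R0 = 0.5 < 1
  dsh <- full_demography(shrinking)
  expect_lt(dsh$rm, 0)
  expect_true(is.na(dsh$pdt_h))
})

test_that("simulated-cohort demography is finite and sign-consistent", {
  sched <- default_schedule()
  rec <- observe(simulate_cohort(pacificus_config(n = 25), seed = 13), sched)
  dem <- full_demography(build_life_table(rec, sched))
  expect_true(all(is.finite(c(dem$r0, dem$tfr, dem$rm, dem$g0_h, dem$gh_h))))
  expect_equal(sign(dem$rm), sign(dem$r0 - 1))
  expect_gte(dem$tfr, dem$r0)
  expect_lte(dem$gh_h, dem$g0_h)
})
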