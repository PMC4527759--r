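# Fixtures built in code: random life tables and small cohort logs.

# A random valid life table: integer checkpoint times (so a 1-h Leslie grid
# always divides them), lx a non-increasing sequence of cohort counts / n0,
# mx nonnegative with at least one positive value.
random_life_table <- function(seed, max_rows = 12) {
  set.seed(seed)
  k <- sample(3:max_rows, 1)
  n0 <- sample(5:50, 1)
  widths <- sample(c(3, 6, 12, 24), k, replace = TRUE)
  times <- cumsum(widths) + sample(12:48, 1)
  alive <- n0 - sort(sample(0:(n0 - 1), k, replace = TRUE))
  mx <- round(stats::runif(k, 0, 8), 2)
  if (all(mx * alive == 0)) mx[sample.int(k, 1)] <- 1.5
  life_table(times, widths, alive / n0, mx, n0 = n0)
}

toy_cohort_text <- function() {
  paste(
    "individual_id\tinterval_start\tinterval_end\teggs_laid\tjuveniles_hatched\tstatus",
    "w1\t0\t24\t0\t0\talive",
    "w1\t24\t48\t3\t2\talive",
    "w1\t48\t72\t5\t5\talive",
    "w2\t0\t24\t0\t0\talive",
    "w2\t24\t48\t1\t1\talive",
    "w2\t48\t72\t0\t0\tdead",
    sep = "\n"
  )
}

write_toy_cohort <- function(path, text = toy_cohort_text()) {
  writeLines(text, path)
  path
}

# Hand-built event log with exact event times (bypasses the simulator).
manual_event_log <- function(individuals, cfg = pacificus_config(n = 33)) {
  structure(list(cfg = cfg, seed = 0L, individuals = individuals),
            class = "event_log")
}

manual_worm <- function(id, maturation, death, lay_times = numeric(0),
                        fertile = logical(0)) {
  hatch <- ifelse(fertile, lay_times + 25, NA_real_)
  list(id = id, hatch_offset = 0, maturation_time = maturation,
       death_time = death,
       eggs = data.frame(lay_time = as.numeric(lay_times),
                         fertile = as.logical(fertile),
                         hatch_time = as.numeric(hatch)))
}

# 33-individual cohort log mirroring the published survival pattern: two
# juvenile deaths (62 h and 89 h), survivors laying one hatched juvenile per
# 6-h interval from the interval ending at 75 h onward.
published_pattern_records <- function(n_intervals = 9) {
  sched <- observation_schedule(c(21, 45, seq(51, 123, by = 6)))
  cp <- sched$checkpoint
  rows <- list()
  for (i in 1:33) {
    if (i == 32) {            # juvenile death at 62 h -> dead at 63 h
      last <- which(cp >= 62)[1]
      eggs <- rep(0, last)
    } else if (i == 33) {     # juvenile death at 89 h -> dead at 93 h
      last <- which(cp >= 89)[1]
      eggs <- rep(0, last)
    } else {
      last <- length(cp)
      eggs <- as.integer(cp >= 75)
    }
    rows[[i]] <- data.frame(
      individual_id = sprintf("w%02d", i),
      interval_start = (cp - sched$width)[seq_len(last)],
      interval_end = cp[seq_len(last)],
      eggs_laid = eggs[seq_len(last)],
      juveniles_hatched = eggs[seq_len(last)],
      status = c(rep("alive", last - 1),
                 if (i %in% c(32, 33)) "dead" else "alive")
    )
  }
  list(records = cohort_records(do.call(rbind, rows)), schedule = sched)
}
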