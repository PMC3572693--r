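test_that("half-diagonal cell distance", {
  expect_equal(round(max_cell_distance(12), 2), 8.49)
  expect_equal(max_cell_distance(0), 0)
  expect_equal(max_cell_distance(10), sqrt(50))
  expect_error(max_cell_distance(-1), "non-negative")
})

test_that("nearest active source: minimum distance, ties, sentinel", {
  src <- make_sources(c(5, 2.5, 7.1), c(0, 0, 0))
  dates <- "2001-01-01"
  pan <- make_panel(src, dates, matrix(0.04, 3, 1))
  # brute-force minimum over the constructed distances {5, 2.5, 7.1}
  ns <- nearest_source(c(0, 0), src, pan, dates)
  expect_equal(ns$source_id, 2L)
  expect_equal(ns$distance, 2.5)

  co_loc <- nearest_source(c(7.1, 0), src)
  expect_equal(co_loc$distance, 0)
  expect_equal(co_loc$source_id, 3L)

  tie <- make_sources(c(-3, 3), c(0, 0))
  expect_equal(nearest_source(c(0, 0), tie)$source_id, 1L)

  pan_off <- make_panel(src, dates, matrix(NA_real_, 3, 1))
  off <- nearest_source(c(0, 0), src, pan_off, dates)
  expect_true(is.na(off$source_id))
  expect_equal(off$distance, Inf)
})

test_that("eligibility: radius rule, activity gaps, complete coverage", {
  dates <- seq(as.Date("2000-02-01"), as.Date("2001-12-31"), by = "day")
  birth <- make_birth(0, 0, "2001-06-01", 40)

  # single always-active monitor 9.0 km away: outside 8.49 km -> excluded
  s1 <- make_sources(9, 0)
  p1 <- make_panel(s1, dates, matrix(0.04, 1, length(dates)))
  e1 <- eligibility_filter(birth, s1, p1)
  expect_equal(nrow(e1$eligible), 0)
  expect_equal(e1$exclusions$first_failing_day, 1L)

  # monitor 1 km away but inactive on pregnancy day 30, nothing else
  s2 <- make_sources(1, 0)
  v2 <- matrix(0.04, 1, length(dates))
  conception <- birth$birth_date - 7 * 40
  day30 <- which(dates == conception + 30)
  v2[1, day30] <- NA
  e2 <- eligibility_filter(birth, s2, make_panel(s2, dates, v2))
  expect_equal(nrow(e2$eligible), 0)
  expect_equal(e2$exclusions$first_failing_day, 30L)

  # complete 12-km grid: zero exclusions for an interior cohort
  cfg <- quick_config(n_births = 150, seed = 31)
  src <- gen_sources(cfg)
  pan <- gen_ozone_panel(src, cfg)
  co <- gen_cohort(cfg)
  ex <- compute_exposure(co, src, pan, "grid")
  expect_equal(nrow(ex$exclusions), 0)
  expect_equal(nrow(ex$cohort), 150)

  # radius monotonicity: a larger radius never shrinks the eligible set
  mon_cfg <- quick_config(n_births = 200, seed = 32,
                          monitor_miss_rate = 0.05)
  msrc <- gen_sources(mon_cfg)
  mpan <- gen_ozone_panel(msrc, mon_cfg)
  mco <- gen_cohort(mon_cfg)
  mons <- msrc[msrc$regime == "monitor", ]
  sub <- make_panel(mons, mpan$dates,
                    mpan$values[match(mons$source_id, mpan$source_id), ,
                                drop = FALSE])
  e_small <- eligibility_filter(mco, mons, sub, radius = 8.49)
  e_big <- eligibility_filter(mco, mons, sub, radius = 20)
  expect_true(all(e_small$eligible$birth_id %in% e_big$eligible$birth_id))

  # empty cohort is fine
  e0 <- eligibility_filter(mco[0, ], mons, sub)
  expect_equal(nrow(e0$eligible), 0)
})

test_that("weekly averages: arithmetic, brute-force check, order invariance", {
  dates <- seq(as.Date("2000-02-01"), as.Date("2001-12-31"), by = "day")
  src <- make_sources(0.5, 0)
  birth <- make_birth(0, 0, "2001-06-01", 40)

  # constant series
  w <- weekly_exposure(birth, src, make_panel(src, dates,
                                              matrix(0.03, 1, length(dates))))
  expect_equal(w$values[1:40], rep(0.03, 40))
  expect_equal(w$values[41:44], rep(0, 4))
  expect_equal(which(w$valid), 1:40)

  # week 1 = mean of first seven pregnancy days
  v <- matrix(0.2, 1, length(dates))
  conception <- birth$birth_date - 7 * 40
  d1 <- which(dates == conception + 1)
  v[1, d1:(d1 + 6)] <- seq(0.01, 0.07, by = 0.01)
  w1 <- weekly_exposure(birth, src, make_panel(src, dates, v))
  expect_equal(w1$values[1], 0.04)

  # random panel, ga = 44: week 21 equals the brute-force mean of days 141-147
  b44 <- make_birth(0, 0, "2001-06-01", 44)
  set.seed(4)
  vr <- matrix(runif(length(dates), 0.01, 0.1), 1)
  w44 <- weekly_exposure(b44, src, make_panel(src, dates, vr))
  c44 <- b44$birth_date - 7 * 44
  days <- c44 + 141:147
  expect_equal(w44$values[21], mean(vr[1, match(days, dates)]))

  # invariance to the order of sources/rows in the panel
  src2 <- make_sources(c(3, 0.5), c(0, 0))
  set.seed(5)
  v2 <- matrix(runif(2 * length(dates), 0.01, 0.1), 2)
  w_a <- weekly_exposure(birth, src2, make_panel(src2, dates, v2))
  perm <- src2[2:1, ]; vp <- v2[2:1, ]
  w_b <- weekly_exposure(birth, perm, make_panel(perm, dates, vp))
  expect_equal(w_a, w_b)
})

test_that("standardization: pooled moments, idempotence, masking", {
  raw <- matrix(c(1, 2, 3, 99), 1)   # entry 4 invalid
  valid <- matrix(c(1, 1, 1, 0), 1)
  ex <- standardize_exposure(raw, valid)
  expect_equal(ex$scaling$center, 2)
  expect_equal(ex$scaling$scale, 1)
  expect_equal(ex$values, matrix(c(-1, 0, 1, 0), 1))

  set.seed(6)
  r2 <- matrix(rnorm(200), 10)
  v2 <- matrix(rbinom(200, 1, 0.8), 10)
  v2[1, 1] <- 1; v2[1, 2] <- 1
  e2 <- standardize_exposure(r2, v2)
  vv <- e2$values[v2 == 1]
  expect_lt(abs(mean(vv)), 1e-10)
  expect_lt(abs(sd(vv) - 1), 1e-10)
  # idempotence up to tolerance
  e3 <- standardize_exposure(e2$values, v2)
  expect_lt(abs(e3$scaling$center), 1e-10)
  expect_lt(abs(e3$scaling$scale - 1), 1e-10)
  expect_equal(e3$values, e2$values, tolerance = 1e-8)

  expect_error(standardize_exposure(matrix(1, 2, 2), matrix(1, 2, 2)),
               "variance")
})

test_that("trimester averages", {
  expect_equal(trimester_average(rep(0.05, 40), 40), rep(0.05, 3))
  wkv <- c(rep(1, 13), rep(2, 13), rep(3, 14))
  expect_equal(trimester_average(wkv, 40), c(1, 2, 3))
  set.seed(7)
  r <- runif(39)
  expect_equal(trimester_average(r, 39)[3], mean(r[27:39]))
})
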