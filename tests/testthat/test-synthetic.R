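test_that("source layouts: lattice geometry and nearest-distance ordering", {
  cfg <- generator_config(n_births = 10, region_extent = 120,
                          grid_spacing = 12, dense_spacing = 2, seed = 1)
  src <- gen_sources(cfg)
  grid <- src[src$regime == "grid", ]
  expect_equal(nrow(grid), 100)
  expect_equal(sort(unique(grid$x)), seq(6, 114, by = 12))
  expect_equal(sort(unique(grid$y)), seq(6, 114, by = 12))

  # brute-force nearest distances for 1000 uniform query points
  set.seed(99)
  qx <- runif(1000, 0, 120); qy <- runif(1000, 0, 120)
  dd <- function(r) nn_dist_brute(qx, qy, src$x[src$regime == r],
                                  src$y[src$regime == r])
  expect_lt(median(dd("dense")), median(dd("grid")))
  expect_lt(median(dd("grid")), median(dd("monitor")))

  cfg1 <- generator_config(n_births = 10, monitor_count = 1, seed = 2)
  src1 <- gen_sources(cfg1)
  mon <- src1[src1$regime == "monitor", ]
  ns <- nearest_source(c(30, 90), src1[src1$regime == "monitor", ])
  expect_equal(ns$source_id, mon$source_id[1])

  expect_error(generator_config(monitor_count = 0), "monitor_count")
  expect_error(generator_config(dense_spacing = 15, grid_spacing = 12),
               "dense_spacing")
})

test_that("ozone panel: seasonality, AR(1) structure, spatial correlation", {
  # degenerate noise: every series constant at the mean
  cfg0 <- quick_config(ozone_seasonal_amplitude = 0, ozone_noise_sd = 0,
                       dense_noise_sd = 0, grid_bias_add = 0,
                       grid_bias_mult = 1)
  src0 <- gen_sources(cfg0)
  pan0 <- gen_ozone_panel(src0, cfg0)
  expect_true(all(abs(pan0$values - cfg0$ozone_mean) < 1e-12))

  # lag-1 autocorrelation of deseasonalized series matches the AR coefficient
  cfg <- generator_config(
    n_births = 10, region_extent = 20, monitor_count = 1,
    grid_spacing = 12, dense_spacing = 10,
    date_range = c("1990-01-01", "2017-05-18"),  # ~10,000 days
    birth_date_range = c("1991-01-01", "2017-05-01"),
    ozone_ar_coefficient = 0.8, ozone_seasonal_amplitude = 0.005,
    ozone_noise_sd = 0.003, seed = 7)
  src <- gen_sources(cfg)
  pan <- gen_ozone_panel(src, cfg)
  mrow <- which(src$regime == "monitor")[1]
  doy <- as.integer(format(pan$dates, "%j"))
  des <- resid(lm(pan$values[mrow, ] ~ cos(2 * pi * doy / 365.25) +
                    sin(2 * pi * doy / 365.25)))
  expect_lt(abs(acf(des, plot = FALSE)$acf[2] - 0.8), 0.05)

  # spatial decay: nearby sources more correlated than distant ones
  s3 <- make_sources(c(0, 1, 100), c(0, 0, 0))
  cfg3 <- generator_config(
    n_births = 10, region_extent = 101, spatial_range = 50,
    dense_spacing = 10,
    date_range = c("1990-01-01", "2017-05-18"),
    birth_date_range = c("1991-01-01", "2017-05-01"), seed = 3)
  pan3 <- gen_ozone_panel(s3, cfg3)
  c_near <- cor(pan3$values[1, ], pan3$values[2, ])
  c_far <- cor(pan3$values[1, ], pan3$values[3, ])
  expect_gt(c_near, c_far)

  expect_error(generator_config(ozone_ar_coefficient = 1), "ar_coefficient")
})

test_that("cohort: gestational range, pregnancy dates, seed determinism", {
  cfg <- quick_config(n_births = 400, seed = 5)
  co <- gen_cohort(cfg)
  expect_equal(nrow(co), 400)
  expect_true(all(co$gestational_age %in% 37:44))
  conception <- co$birth_date - 7 * co$gestational_age
  expect_true(all(conception + 1 >= cfg$date_range[1]))
  expect_true(all(co$birth_date <= cfg$date_range[2]))
  expect_true(all(format(co$birth_date, "%Y") %in% c("2001", "2002")))

  co2 <- gen_cohort(quick_config(n_births = 400, seed = 5))
  expect_identical(co, co2)

  # degenerate covariate distribution: the constant dummy columns are
  # flagged and dropped when the design is assembled
  co3 <- gen_cohort(quick_config(n_births = 100, seed = 6),
                    covariate_probs = list(education = c(1, 0, 0)))
  expect_warning(d3 <- build_design(co3), "constant design columns")
  expect_false(any(grepl("^edu_", colnames(d3$matrix))))
})

test_that("outcomes: probit generation and prevalence calibration", {
  cfg <- quick_config(n_births = 5000, seed = 8, target_prevalence = 0.5,
                      true_beta = numeric(0), true_theta = numeric(44))
  src <- gen_sources(cfg)
  pan <- gen_ozone_panel(src, cfg)
  co <- gen_cohort(cfg)
  ex <- compute_exposure(co, src, pan, "dense")
  des <- build_design(co)
  out <- gen_outcomes(co, ex$exposure, des, cfg)
  # null effects, prevalence 0.5: symmetric probit, binomial 3-sd check
  expect_lt(abs(mean(out$outcome) - 0.5), 3 * sqrt(0.25 / 5000))
  expect_lt(abs(attr(out, "intercept_shift")), 1e-6)

  # deep-tail intercept: essentially no events
  cfg0 <- quick_config(n_births = 2000, seed = 9, target_prevalence = 1e-8,
                       true_beta = numeric(0), true_theta = numeric(44))
  out0 <- gen_outcomes(co[1:2000, ], ex$exposure, des, cfg0)
  expect_equal(sum(out0$outcome[1:2000]), 0)
})

test_that("prevalence calibration tightens with sample size", {
  rate_at <- function(n, seed) {
    cfg <- quick_config(n_births = n, seed = seed)
    src <- gen_sources(cfg)
    pan <- gen_ozone_panel(src, cfg)
    co <- gen_cohort(cfg)
    ex <- compute_exposure(co, src, pan, "dense")
    des <- build_design(co)
    mean(gen_outcomes(co, ex$exposure, des, cfg)$outcome)
  }
  r5e3 <- rate_at(5000, 21)
  r5e4 <- rate_at(50000, 22)
  expect_lt(abs(r5e4 - 0.023), 0.004)   # binomial 99.9% half-width ~ 0.0022
  expect_lt(abs(r5e4 - 0.023), abs(r5e3 - 0.023) + 0.003)
})
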