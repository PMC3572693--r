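# Population centres used for cohort clustering and monitor placement.
# First centre is the designated "urban" centre the sparse network favours.
pop_centers <- function(config) {
  e <- config$region_extent
  rbind(c(0.35, 0.40), c(0.70, 0.60)) * e
}

#' Generate the three co-registered pollution-source layouts
#'
#' Builds a sparse monitor network clustered near the main population centre,
#' a regular coarse grid of cell centres at \code{grid_spacing}, and a dense
#' regular point set at \code{dense_spacing}. For a cohort drawn from the same
#' configuration, median nearest-source distances are ordered
#' dense < grid < monitor, mirroring the distance ordering of dense
#' statistical products versus gridded chemistry output versus ground
#' monitors.
#'
#' @param config a \code{\link{generator_config}}.
#' @param include_truth also emit a \code{"truth"} regime co-located with the
#'   dense points, carrying the noiseless latent ozone field (used for
#'   validation runs).
#' @return data.frame with columns \code{source_id} (integer, unique across
#'   regimes), \code{regime} (\code{"monitor"}, \code{"grid"},
#'   \code{"dense"}, \code{"truth"}), \code{x}, \code{y} (km).
#' @export
gen_sources <- function(config, include_truth = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  e <- config$region_extent

  lattice <- function(spacing) {
    ax <- seq(spacing / 2, e, by = spacing)
    expand.grid(x = ax, y = ax)
  }
  grid <- lattice(config$grid_spacing)
  dense <- lattice(config$dense_spacing)

  ctr <- pop_centers(config)[1, ]
  nm <- config$monitor_count
  mx <- pmin(pmax(rnorm(nm, ctr[1], e / 6), 0), e)
  my <- pmin(pmax(rnorm(nm, ctr[2], e / 6), 0), e)
  mon <- data.frame(x = mx, y = my)

  out <- rbind(
    data.frame(regime = "monitor", mon),
    data.frame(regime = "grid", grid),
    data.frame(regime = "dense", dense)
  )
  if (include_truth)
    out <- rbind(out, data.frame(regime = "truth", dense))
  data.frame(source_id = seq_len(nrow(out)), out,
             stringsAsFactors = FALSE)
}

# annual cycle of the regional daily mean, peaking around mid-July
seasonal_mean <- function(dates, center, amplitude) {
  doy <- as.integer(format(dates, "%j"))
  center + amplitude * cos(2 * pi * (doy - 196) / 365.25)
}

#' Generate daily ozone series for every pollution source
#'
#' Simulates a shared latent daily-maximum 8-hour ozone field: an annual
#' sinusoid (period 365.25 d) plus AR(1) daily deviations whose innovations
#' are spatially correlated across sources with an exponential correlogram
#' (range \code{spatial_range}). Regime-specific observation models are then
#' applied: monitors report the latent field (with optional missing days),
#' the dense product reports the latent field plus small calibration noise,
#' and the coarse grid reports a spatially smoothed, multiplicatively and
#' additively biased transform of the latent field, emulating deterministic
#' chemistry-model error. All values are clipped to (0, 0.5) ppm.
#'
#' @param sources data.frame from \code{\link{gen_sources}}.
#' @param config a \code{\link{generator_config}}.
#' @return an object of class \code{"ozone_panel"}: list with \code{values}
#'   (sources x days matrix, ppm, NA on inactive days), \code{dates}, and
#'   \code{source_id}.
#' @export
gen_ozone_panel <- function(sources, config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$ozone_ar_coefficient < 0 || config$ozone_ar_coefficient >= 1)
    stop("ozone_ar_coefficient must lie in [0, 1)")
  set.seed(config$seed + 2L)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  nd <- length(dates)

  # latent field lives on unique locations so co-located regimes (dense and
  # truth) share identical latent values
  loc_key <- paste(round(sources$x, 9), round(sources$y, 9))
  uniq <- !duplicated(loc_key)
  ux <- sources$x[uniq]; uy <- sources$y[uniq]
  uid <- match(loc_key, loc_key[uniq])
  nu <- length(ux)

  m <- seasonal_mean(dates, config$ozone_mean, config$ozone_seasonal_amplitude)

  if (config$ozone_noise_sd > 0) {
    D <- sqrt(outer(ux, ux, "-")^2 + outer(uy, uy, "-")^2)
    C <- exp(-D / config$spatial_range)
    diag(C) <- diag(C) + 1e-8
    L <- t(chol(C)) * config$ozone_noise_sd
    Z <- matrix(rnorm(nu * nd), nu, nd)
    W <- L %*% Z
    a <- config$ozone_ar_coefficient
    W[, 1] <- W[, 1] / sqrt(1 - a^2)  # stationary start
    E <- t(stats::filter(t(W), a, method = "recursive"))
  } else {
    E <- matrix(0, nu, nd)
  }

  latent <- sweep(E[uid, , drop = FALSE], 2, m, "+")
  vals <- latent

  gi <- which(sources$regime == "grid")
  if (length(gi)) {
    gx <- sources$x[gi]; gy <- sources$y[gi]
    Dg <- sqrt(outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2)
    Wg <- exp(-Dg / (2 * config$grid_spacing))
    Wg[Dg > 2.5 * config$grid_spacing] <- 0
    Wg <- Wg / rowSums(Wg)
    Eg <- Wg %*% E[uid[gi], , drop = FALSE]
    vals[gi, ] <- config$grid_bias_add +
      config$grid_bias_mult * sweep(Eg, 2, m, "+")
  }

  di <- which(sources$regime == "dense")
  if (length(di) && config$dense_noise_sd > 0)
    vals[di, ] <- vals[di, ] +
      rnorm(length(di) * nd, 0, config$dense_noise_sd)

  mi <- which(sources$regime == "monitor")
  if (length(mi) && config$monitor_miss_rate > 0) {
    miss <- matrix(runif(length(mi) * nd) < config$monitor_miss_rate,
                   length(mi), nd)
    vals[mi, ][miss] <- NA_real_
  }

  vals <- pmin(pmax(vals, 5e-4), 0.4995)
  structure(list(values = vals, dates = dates,
                 source_id = sources$source_id),
            class = "ozone_panel")
}

# regional daily weather (temperature / dewpoint), one value per calendar day
gen_weather <- function(config) {
  set.seed(config$seed + 7L)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  tanom <- rnorm(length(dates), 0, 1.5)
  temp <- seasonal_mean(dates, 22, 8) + tanom
  dew <- seasonal_mean(dates, 16, 6) + 0.5 * tanom + rnorm(length(dates), 0, 1)
  data.frame(date = dates, temperature = temp, dewpoint = dew)
}

#' Generate a synthetic birth cohort (outcomes unset)
#'
#' Draws term pregnancies (gestational age 37-44 completed weeks) with
#' residential locations clustered around two population centres, birth dates
#' uniform over the admissible range (every pregnancy day must fall inside
#' \code{date_range}, taking conception as birth date minus 7 x gestational
#' age days), and maternal/seasonal covariates from configurable categorical
#' distributions. Temperature and dewpoint at the birth date come from a
#' single region-wide daily series shared by all births on that day.
#'
#' @param config a \code{\link{generator_config}}.
#' @param covariate_probs optional named list overriding the categorical
#'   distributions; elements \code{ga}, \code{sex}, \code{parity},
#'   \code{age_group}, \code{race}, \code{education} (probabilities in level
#'   order).
#' @return data.frame of birth records with \code{outcome = NA}.
#' @export
gen_cohort <- function(config, covariate_probs = list()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 3L)
  n <- config$n_births
  e <- config$region_extent

  probs <- list(
    ga = c(0.08, 0.14, 0.24, 0.28, 0.15, 0.07, 0.03, 0.01),
    sex = c(female = 0.488, male = 0.512),
    parity = c(0.40, 0.32, 0.28),
    age_group = c(0.16, 0.26, 0.25, 0.18, 0.11, 0.04),
    race = c(0.12, 0.03, 0.80, 0.05),
    education = c(0.35, 0.35, 0.30)
  )
  probs[names(covariate_probs)] <- covariate_probs

  ga <- sample(37:44, n, replace = TRUE, prob = probs$ga)
  # earliest admissible birth day: conception must not precede the panel
  first_ok <- pmax(config$date_range[1] + 7 * ga, config$birth_date_range[1])
  span <- as.integer(config$birth_date_range[2] - first_ok)
  if (any(span < 0))
    stop("date_range too short to contain a full pregnancy")
  birth_date <- first_ok + vapply(span, function(s) sample.int(s + 1L, 1L) - 1L,
                                  integer(1))

  ctr <- pop_centers(config)
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.55, 0.30, 0.15))
  x <- numeric(n); y <- numeric(n)
  for (k in 1:2) {
    i <- comp == k
    x[i] <- rnorm(sum(i), ctr[k, 1], e / 12)
    y[i] <- rnorm(sum(i), ctr[k, 2], e / 12)
  }
  i <- comp == 3
  x[i] <- runif(sum(i), 0, e); y[i] <- runif(sum(i), 0, e)
  x <- pmin(pmax(x, 0), e); y <- pmin(pmax(y, 0), e)

  mon <- as.integer(format(birth_date, "%m"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "fall", "fall", "fall", "winter")[mon]

  lev <- cohort_levels()
  draw <- function(levels, p) factor(sample(levels, n, TRUE, p), levels = levels)

  wx <- gen_weather(config)
  wi <- match(birth_date, wx$date)

  data.frame(
    birth_id = seq_len(n),
    x = x, y = y,
    birth_date = birth_date,
    gestational_age = ga,
    outcome = NA_integer_,
    sex = draw(lev$sex, probs$sex),
    season_of_birth = factor(season, levels = lev$season),
    birth_year = factor(format(birth_date, "%Y")),
    parity = draw(lev$parity, probs$parity),
    maternal_age_group = draw(lev$age_group, probs$age_group),
    race_ethnicity = draw(lev$race, probs$race),
    education = draw(lev$education, probs$education),
    temperature_at_birth = wx$temperature[wi],
    dewpoint_at_birth = wx$dewpoint[wi],
    stringsAsFactors = FALSE
  )
}

# canonical factor levels; first level is the reference used in the design
cohort_levels <- function() {
  list(sex = c("male", "female"),
       season = c("winter", "spring", "summer", "fall"),
       parity = c("0", "1", "2+"),
       age_group = c("30-34", "10-19", "20-24", "25-29", "35-39", "40+"),
       race = c("NH-white", "NH-black", "Hispanic", "NH-other"),
       education = c("<HS", "HS", ">HS"))
}

#' Draw low-birth-weight outcomes from the probit model
#'
#' Computes the true linear predictor eta_i = x_i' beta + sum_{j <= ga_i}
#' z_ij theta_j, recalibrates the intercept by bisection so the expected
#' marginal outcome rate equals \code{target_prevalence}, and draws
#' Y_i ~ Bernoulli(Phi(eta_i)).
#'
#' @param cohort data.frame from \code{\link{gen_cohort}}.
#' @param exposure an \code{exposure_matrix} (standardized) covering 44 weeks.
#' @param design a \code{design_matrix} (see \code{\link{build_design}}).
#' @param config a \code{\link{generator_config}}; \code{true_beta} is a
#'   named vector matched to design columns, \code{true_theta} the 44 weekly
#'   effects.
#' @return the cohort with \code{outcome} filled in; the calibrated intercept
#'   shift is attached as attribute \code{"intercept_shift"}.
#' @export
gen_outcomes <- function(cohort, exposure, design, config) {
  stopifnot(inherits(config, "generator_config"),
            inherits(exposure, "exposure_matrix"))
  X <- design$matrix
  beta <- numeric(ncol(X)); names(beta) <- colnames(X)
  tb <- config$true_beta
  if (length(tb)) {
    bad <- setdiff(names(tb), colnames(X))
    if (length(bad))
      stop("true_beta names not in design: ", paste(bad, collapse = ", "))
    beta[names(tb)] <- tb
  }
  eta <- drop(X %*% beta) + drop(exposure$values %*% config$true_theta)
  if (any(!is.finite(eta))) stop("non-finite linear predictor in generation")

  # bisection on the intercept shift for the expected marginal rate
  f <- function(d) mean(pnorm(eta + d)) - config$target_prevalence
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) stop("cannot calibrate intercept")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  shift <- (lo + hi) / 2

  set.seed(config$seed + 4L)
  cohort$outcome <- rbinom(nrow(cohort), 1L, pnorm(eta + shift))
  attr(cohort, "intercept_shift") <- shift
  cohort
}

#' Write generator outputs as delimited text
#'
#' \code{write_cohort}, \code{write_sources} and \code{write_panel} emit
#' births.csv / sources.csv / panel.csv (panel in long format:
#' source_id, date, value, inactive days omitted);
#' \code{write_generator_config} emits the configuration as YAML.
#'
#' @param x object to write.
#' @param path output file path.
#' @name generator_io
#' @export
write_cohort <- function(x, path) data.table::fwrite(x, path)

#' @rdname generator_io
#' @export
write_sources <- function(x, path) data.table::fwrite(x, path)

#' @rdname generator_io
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "ozone_panel"))
  long <- data.table::data.table(
    source_id = rep(x$source_id, times = length(x$dates)),
    date = rep(x$dates, each = length(x$source_id)),
    value = as.vector(x$values))
  data.table::fwrite(long[!is.na(long$value), ], path)
}

#' @rdname generator_io
#' @export
write_generator_config <- function(x, path) {
  y <- unclass(x)
  y$date_range <- as.character(y$date_range)
  y$birth_date_range <- as.character(y$birth_date_range)
  y$true_beta <- as.list(y$true_beta)
  yaml::write_yaml(y, path)
}

#' Read a long-format pollution panel back into matrix form
#'
#' @param path panel.csv written by \code{\link{write_panel}}.
#' @param sources the matching sources table.
#' @return an \code{ozone_panel}.
#' @export
read_panel <- function(path, sources) {
  long <- data.table::fread(path)
  dates <- seq(min(long$date), max(long$date), by = "day")
  vals <- matrix(NA_real_, nrow(sources), length(dates))
  i <- match(long$source_id, sources$source_id)
  j <- match(long$date, dates)
  vals[cbind(i, j)] <- long$value
  structure(list(values = vals, dates = dates,
                 source_id = sources$source_id),
            class = "ozone_panel")
}
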