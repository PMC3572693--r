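#' Configuration for the synthetic cohort and pollution-field generator
#'
#' Bundles every knob of the synthetic-data module: cohort size and region
#' geometry, the three co-registered pollution-source layouts (sparse monitor
#' network, coarse grid, dense point set), the daily ozone field model
#' (seasonal sinusoid plus spatially correlated AR(1) deviations), and the
#' true outcome model used to draw low-birth-weight indicators.
#'
#' The defaults describe the desk-scale study conditions: a 120 km square
#' region observed 2000-2004, a 12 km grid (the coarse product), a 3 km dense
#' point set, six monitors clustered near the main population centre, a ~2.3%
#' target prevalence of term low birth weight, and a true elevated-effect
#' window at gestational weeks 20-23.
#'
#' @param n_births number of pregnancies to simulate.
#' @param region_extent side length of the square study region, km.
#' @param date_range character or Date vector of length 2; first and last
#'   calendar day with pollution data. Birth dates are restricted so that
#'   every pregnancy day falls inside this range.
#' @param birth_date_range character or Date vector of length 2; admissible
#'   birth dates (default whole calendar years 2001-2004, so the birth-year
#'   factor has four levels while pollution data reach back far enough to
#'   cover every pregnancy day).
#' @param monitor_count number of sparse-network monitors (>= 1).
#' @param grid_spacing coarse-grid cell side, km (default 12).
#' @param dense_spacing dense point-set spacing, km; must be smaller than
#'   \code{grid_spacing} so that nearest-source distances are ordered
#'   dense < grid < monitor.
#' @param ozone_mean long-run mean of the daily maximum 8-hour ozone, ppm.
#' @param ozone_seasonal_amplitude amplitude of the annual sinusoid, ppm.
#' @param ozone_ar_coefficient lag-1 autocorrelation of daily deviations,
#'   in [0, 1).
#' @param ozone_noise_sd innovation standard deviation of the daily
#'   deviations, ppm.
#' @param spatial_range e-folding range of inter-source correlation, km.
#' @param monitor_miss_rate per-monitor daily probability of an inactive
#'   (missing) reading; exercises the active-monitor eligibility filter.
#' @param grid_bias_add,grid_bias_mult additive (ppm) and multiplicative
#'   components of the coarse-grid error model.
#' @param dense_noise_sd calibration noise of the dense product, ppm.
#' @param true_beta named numeric vector of true covariate effects on the
#'   probit scale; names must match design-matrix columns (see
#'   \code{\link{build_design}}); unnamed columns get effect 0. The intercept
#'   is recalibrated to hit \code{target_prevalence}.
#' @param true_theta numeric vector of 44 true weekly exposure effects, or
#'   NULL to build one from \code{true_window}/\code{window_effect}.
#' @param true_window integer vector of gestational weeks with elevated
#'   effect (default 20:23).
#' @param window_effect effect size, per standard deviation of weekly
#'   exposure, placed on each week of \code{true_window}.
#' @param target_prevalence marginal outcome rate the intercept is calibrated
#'   to (default 0.023).
#' @param seed integer seed governing all generator randomness.
#' @return an object of class \code{"generator_config"} (a validated list).
#' @export
generator_config <- function(n_births = 10000,
                             region_extent = 120,
                             date_range = c("2000-02-01", "2004-12-31"),
                             birth_date_range = c("2001-01-01", "2004-12-31"),
                             monitor_count = 6,
                             grid_spacing = 12,
                             dense_spacing = 3,
                             ozone_mean = 0.045,
                             ozone_seasonal_amplitude = 0.012,
                             ozone_ar_coefficient = 0.6,
                             ozone_noise_sd = 0.008,
                             spatial_range = 100,
                             monitor_miss_rate = 0,
                             grid_bias_add = 0.005,
                             grid_bias_mult = 0.85,
                             dense_noise_sd = 0.002,
                             true_beta = c("ga_weeks" = -0.1, "sex_female" = 0.2),
                             true_theta = NULL,
                             true_window = 20:23,
                             window_effect = 0.154,
                             target_prevalence = 0.023,
                             seed = 1L) {
  if (n_births < 1) stop("n_births must be a positive integer")
  if (region_extent <= 0) stop("region_extent must be positive")
  if (monitor_count < 1) stop("monitor_count must be >= 1")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (dense_spacing >= grid_spacing)
    stop("dense_spacing must be smaller than grid_spacing ",
         "(nearest-source distances must be ordered dense < grid)")
  if (ozone_ar_coefficient < 0 || ozone_ar_coefficient >= 1)
    stop("ozone_ar_coefficient must lie in [0, 1)")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)")
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      date_range[2] <= date_range[1])
    stop("date_range must be two ordered calendar days")
  birth_date_range <- as.Date(birth_date_range)
  if (length(birth_date_range) != 2 || any(is.na(birth_date_range)) ||
      birth_date_range[2] <= birth_date_range[1])
    stop("birth_date_range must be two ordered calendar days")
  if (birth_date_range[1] - 7 * 44 < date_range[1] ||
      birth_date_range[2] > date_range[2])
    stop("date_range too short: every pregnancy day of every admissible ",
         "birth must fall inside it")
  if (is.null(true_theta)) {
    true_theta <- numeric(44)
    true_theta[true_window] <- window_effect
  }
  if (length(true_theta) != 44) stop("true_theta must have length 44")
  if (!is.numeric(true_beta) || (length(true_beta) > 0 && is.null(names(true_beta))))
    stop("true_beta must be a named numeric vector")
  cfg <- list(
    n_births = as.integer(n_births),
    region_extent = region_extent,
    date_range = date_range,
    birth_date_range = birth_date_range,
    monitor_count = as.integer(monitor_count),
    grid_spacing = grid_spacing,
    dense_spacing = dense_spacing,
    ozone_mean = ozone_mean,
    ozone_seasonal_amplitude = ozone_seasonal_amplitude,
    ozone_ar_coefficient = ozone_ar_coefficient,
    ozone_noise_sd = ozone_noise_sd,
    spatial_range = spatial_range,
    monitor_miss_rate = monitor_miss_rate,
    grid_bias_add = grid_bias_add,
    grid_bias_mult = grid_bias_mult,
    dense_noise_sd = dense_noise_sd,
    true_beta = true_beta,
    true_theta = true_theta,
    true_window = as.integer(true_window),
    target_prevalence = target_prevalence,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Prior specification for the temporal probit model
#'
#' Covariate coefficients get independent normal priors with a large fixed
#' variance. Under the structured variant the weekly effects theta get a
#' MVN(0, sigma2 * Sigma(phi)) prior with exponential temporal correlation
#' Sigma(phi)[i, j] = exp(-phi |i - j|); phi is Uniform(0.0001, 3) and
#' sigma2 is Inverse-Gamma(3, 2), which is conjugate. The diffuse variant
#' (the naive weekly model and the trimester model) replaces the structured
#' prior with independent normals of variance \code{beta_variance}.
#'
#' @param beta_variance prior variance of each covariate coefficient.
#' @param phi_lower,phi_upper support of the uniform prior on phi.
#' @param sigma2_shape,sigma2_scale Inverse-Gamma shape and scale for the
#'   overall weekly-effect variance.
#' @return an object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(beta_variance = 1000,
                       phi_lower = 1e-4, phi_upper = 3,
                       sigma2_shape = 3, sigma2_scale = 2) {
  stopifnot(beta_variance > 0, phi_lower > 0, phi_lower < phi_upper,
            sigma2_shape > 0, sigma2_scale > 0)
  structure(list(beta_variance = beta_variance,
                 phi_lower = phi_lower, phi_upper = phi_upper,
                 sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale),
            class = "prior_spec")
}

#' MCMC run configuration
#'
#' @param n_burnin burn-in iterations to discard.
#' @param n_samples post-burn-in iterations to keep (before thinning).
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed RNG seed for the run.
#' @param phi_proposal_sd random-walk proposal sd for phi on the logit scale.
#' @param adapt adapt the proposal sd during burn-in toward an acceptance
#'   rate in [0.2, 0.5]; frozen afterwards.
#' @param profile convenience: \code{"paper"} sets 50,000 + 50,000
#'   iterations, \code{"test"} sets 2,000 + 2,000; explicit
#'   \code{n_burnin}/\code{n_samples} win.
#' @return an object of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(n_burnin = NULL, n_samples = NULL, thin = 1L,
                        seed = 1L, phi_proposal_sd = 0.5, adapt = TRUE,
                        profile = c("test", "paper")) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") 50000L else 2000L
  if (is.null(n_burnin)) n_burnin <- def
  if (is.null(n_samples)) n_samples <- def
  stopifnot(n_burnin >= 0, n_samples >= 1, thin >= 1, phi_proposal_sd > 0)
  structure(list(n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed),
                 phi_proposal_sd = phi_proposal_sd, adapt = isTRUE(adapt),
                 profile = profile),
            class = "mcmc_config")
}
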