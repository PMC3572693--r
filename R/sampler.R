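#' Exponential temporal correlation matrix for weekly effects
#'
#' Corr(theta_i, theta_j) = exp(-phi |i - j|): effects of exposures a few
#' weeks apart are highly correlated and the correlation decays with lag,
#' which is what lets the model borrow strength across adjacent gestational
#' weeks and tame the multicollinearity of weekly exposures.
#'
#' @param phi decay rate (> 0).
#' @param g number of weekly effects (>= 1).
#' @return g x g correlation matrix (symmetric, unit diagonal, positive
#'   definite).
#' @export
corr_matrix <- function(phi, g) {
  if (phi <= 0) stop("phi must be positive")
  if (g < 1) stop("g must be >= 1")
  exp(-phi * abs(outer(seq_len(g), seq_len(g), "-")))
}

# The exponential-correlation matrix has unit-lag correlation rho = exp(-phi)
# and Sigma_ij = rho^|i-j|, the stationary AR(1) form, so its inverse is
# tridiagonal and its log determinant is (g-1) log(1 - rho^2). These closed
# forms keep every sweep O(g).
ar1_precision <- function(rho, g) {
  if (g == 1) return(matrix(1, 1, 1))
  f <- 1 / (1 - rho^2)
  Q <- matrix(0, g, g)
  diag(Q) <- f * c(1, rep(1 + rho^2, g - 2), 1)
  idx <- seq_len(g - 1)
  Q[cbind(idx, idx + 1)] <- Q[cbind(idx + 1, idx)] <- -rho * f
  Q
}

ar1_quad <- function(theta, rho) {
  g <- length(theta)
  if (g == 1) return(theta^2)
  inner <- if (g > 2) sum(theta[2:(g - 1)]^2) else 0
  (sum(theta^2) + rho^2 * inner -
     2 * rho * sum(theta[-g] * theta[-1])) / (1 - rho^2)
}

ar1_logdet <- function(rho, g) (g - 1) * log(1 - rho^2)

# log MVN(theta; 0, sigma2 * Sigma(phi)) up to a constant
theta_prior_logdens <- function(theta, sigma2, phi) {
  rho <- exp(-phi)
  g <- length(theta)
  -0.5 * (g * log(sigma2) + ar1_logdet(rho, g) +
            ar1_quad(theta, rho) / sigma2)
}

#' Probit linear predictor
#'
#' eta_i = x_i' beta + sum_j z_ij theta_j; the exposure block is already
#' masked by gestational age, so the sum effectively runs to ga_i. With
#' \code{probs = TRUE} also returns p_i = Phi(eta_i).
#'
#' @param X n x p design matrix.
#' @param Z n x g exposure block (or NULL).
#' @param beta,theta coefficient vectors.
#' @param probs also return outcome probabilities.
#' @return numeric eta, or list(eta, p) when \code{probs}.
#' @export
linear_predictor <- function(X, Z, beta, theta, probs = FALSE) {
  if (anyNA(X) || (!is.null(Z) && anyNA(Z)) || anyNA(beta) ||
      (!is.null(theta) && anyNA(theta)))
    stop("NaN/NA in linear predictor inputs")
  eta <- drop(X %*% beta)
  if (!is.null(Z) && length(theta)) eta <- eta + drop(Z %*% theta)
  if (probs) list(eta = eta, p = pnorm(eta)) else eta
}

#' Sample truncated-normal latent variables
#'
#' Data augmentation for the probit likelihood: w_i ~ N(eta_i, 1) truncated
#' to (0, Inf) when y_i = 1 and to (-Inf, 0] when y_i = 0. Sampling is exact
#' inverse-CDF on the log-probability scale, which stays finite and
#' well-conditioned arbitrarily far into the tails (no rejection loops).
#'
#' @param y binary outcome vector.
#' @param eta linear predictor.
#' @return numeric vector of latent draws.
#' @export
sample_latents <- function(y, eta) {
  n <- length(y)
  w <- numeric(n)
  pos <- y == 1
  # z ~ N(0,1) truncated to (a, Inf): P(Z > z) = v, v ~ U(0, P(Z > a))
  rtail <- function(a) {
    lt <- pnorm(a, lower.tail = FALSE, log.p = TRUE)
    -qnorm(lt + log(runif(length(a))), log.p = TRUE)
  }
  if (any(pos)) w[pos] <- eta[pos] + rtail(-eta[pos])
  if (any(!pos)) w[!pos] <- eta[!pos] - rtail(eta[!pos])
  w
}

# draw from MVN with precision A and mean A^{-1} b, via one Cholesky
draw_mvn_precision <- function(A, b, R = NULL) {
  if (is.null(R)) R <- chol(A)
  mean <- backsolve(R, forwardsolve(t(R), b))
  drop(mean + backsolve(R, rnorm(length(b))))
}

#' Conjugate update of the covariate coefficients
#'
#' Full conditional: MVN with precision (X'X + V0^{-1}) and mean solving
#' that precision against X'(w - Z theta), where V0 is the diagonal prior
#' covariance.
#'
#' @param latents current latent vector w.
#' @param X design matrix.
#' @param Z exposure block (or NULL).
#' @param theta current weekly effects.
#' @param prior a \code{\link{prior_spec}}.
#' @return a draw of beta.
#' @export
update_beta <- function(latents, X, Z, theta, prior) {
  p <- ncol(X)
  r <- latents
  if (!is.null(Z) && length(theta)) r <- r - drop(Z %*% theta)
  A <- crossprod(X) + diag(1 / prior$beta_variance, p)
  draw_mvn_precision(A, drop(crossprod(X, r)))
}

#' Update of the weekly exposure effects
#'
#' Structured variant: full conditional MVN with precision
#' Z'Z + (sigma2 Sigma(phi))^{-1}. Diffuse variant (naive weekly and
#' trimester models): the structured prior precision is replaced by
#' I / beta_variance.
#'
#' @param latents current latent vector w.
#' @param X design matrix.
#' @param Z exposure block.
#' @param beta current covariate coefficients.
#' @param sigma2,phi current hyperparameters (structured variant).
#' @param prior a \code{\link{prior_spec}}.
#' @param structured use the temporally correlated prior.
#' @return a draw of theta.
#' @export
update_theta <- function(latents, X, Z, beta, sigma2, phi, prior,
                         structured = TRUE) {
  g <- ncol(Z)
  Q <- if (structured) ar1_precision(exp(-phi), g) / sigma2
       else diag(1 / prior$beta_variance, g)
  A <- crossprod(Z) + Q
  r <- latents - drop(X %*% beta)
  draw_mvn_precision(A, drop(crossprod(Z, r)))
}

#' Conjugate update of the weekly-effect variance
#'
#' Full conditional: Inverse-Gamma(shape + g/2,
#' scale + theta' Sigma(phi)^{-1} theta / 2).
#'
#' @param theta current weekly effects.
#' @param phi current correlation decay.
#' @param prior a \code{\link{prior_spec}}.
#' @return a draw of sigma2_theta.
#' @export
update_sigma2 <- function(theta, phi, prior) {
  g <- length(theta)
  a <- prior$sigma2_shape + g / 2
  b <- prior$sigma2_scale + ar1_quad(theta, exp(-phi)) / 2
  1 / rgamma(1, shape = a, rate = b)
}

#' Metropolis update of the correlation decay phi
#'
#' Random-walk Metropolis on the logit-transformed scale over the uniform
#' prior support (phi_lower, phi_upper), with the Jacobian correction; the
#' target is MVN(theta; 0, sigma2 Sigma(phi)) times the flat prior.
#'
#' @param theta,sigma2 current state.
#' @param phi_current current phi.
#' @param prior a \code{\link{prior_spec}}.
#' @param proposal_sd random-walk sd on the transformed scale.
#' @return list(phi, accepted).
#' @export
update_phi <- function(theta, sigma2, phi_current, prior,
                       proposal_sd = 0.5) {
  L <- prior$phi_lower; U <- prior$phi_upper
  to_x <- function(phi) qlogis((phi - L) / (U - L))
  to_phi <- function(x) L + (U - L) * plogis(x)
  log_jac <- function(x) log(U - L) + plogis(x, log.p = TRUE) +
    plogis(-x, log.p = TRUE)
  x <- to_x(phi_current)
  xp <- x + rnorm(1, 0, proposal_sd)
  phip <- to_phi(xp)
  la <- theta_prior_logdens(theta, sigma2, phip) + log_jac(xp) -
    theta_prior_logdens(theta, sigma2, phi_current) - log_jac(x)
  if (is.finite(la) && log(runif(1)) < la)
    list(phi = phip, accepted = TRUE)
  else
    list(phi = phi_current, accepted = FALSE)
}

#' Fit the temporal probit model by Markov chain Monte Carlo
#'
#' Systematic-scan Gibbs sampler with latent-variable augmentation:
#' latents -> beta -> theta -> sigma2 -> phi. The hyperparameter updates
#' (sigma2, phi) run only for the structured weekly model; the trimester
#' and naive weekly variants give the exposure coefficients diffuse
#' independent normal priors. Initialization: beta = 0, theta = 0,
#' sigma2 = 1 (prior mean), phi = 1.5 (support midpoint), latents at
#' +/- 0.5 by outcome.
#'
#' @param y binary outcome vector.
#' @param X n x p design matrix.
#' @param Z n x g exposure block (NULL for a covariates-only fit).
#' @param model \code{"weekly_structured"} (model 1), \code{"trimester"}
#'   (model 2), or \code{"weekly_naive"} (model 3).
#' @param prior a \code{\link{prior_spec}}.
#' @param config an \code{\link{mcmc_config}}.
#' @param weeks optional gestational-week index per exposure column
#'   (carried through to summaries).
#' @param fix optional list fixing hyperparameters, e.g.
#'   \code{list(sigma2 = 1, phi = 1.5)}; fixed parameters are not updated.
#' @return an object of class \code{"posterior_draws"}: matrices
#'   \code{beta} (draws x p) and \code{theta} (draws x g), vectors
#'   \code{sigma2} and \code{phi} (structured model), the phi acceptance
#'   rate, per-parameter batch-means MC errors, and bookkeeping fields.
#' @export
run_mcmc <- function(y, X, Z = NULL,
                     model = c("weekly_structured", "trimester",
                               "weekly_naive"),
                     prior = prior_spec(), config = mcmc_config(),
                     weeks = NULL, fix = list()) {
  model <- match.arg(model)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (!is.null(Z)) stopifnot(nrow(Z) == nrow(X))
  structured <- model == "weekly_structured" && !is.null(Z)
  set.seed(config$seed)

  n <- nrow(X); p <- ncol(X)
  g <- if (is.null(Z)) 0L else ncol(Z)
  if (is.null(weeks)) weeks <- seq_len(g)

  v0inv <- 1 / prior$beta_variance
  Rbeta <- chol(crossprod(X) + diag(v0inv, p))
  ZtZ <- if (g) crossprod(Z) else NULL

  beta <- numeric(p); theta <- numeric(g)
  sigma2 <- if (!is.null(fix$sigma2)) fix$sigma2 else 1
  phi <- if (!is.null(fix$phi)) fix$phi else 1.5
  Xb <- numeric(n); Zt <- numeric(n)
  w <- ifelse(y == 1, 0.5, -0.5)

  total <- config$n_burnin + config$n_samples
  keep <- floor(config$n_samples / config$thin)
  B <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(X)))
  TH <- if (g) matrix(NA_real_, keep, g,
                      dimnames = list(NULL, colnames(Z))) else NULL
  S2 <- PH <- if (structured) numeric(keep) else NULL
  psd <- config$phi_proposal_sd
  acc_total <- 0L; n_prop <- 0L; acc_win <- 0L
  k <- 0L

  for (it in seq_len(total)) {
    w <- sample_latents(y, Xb + Zt)

    b <- drop(crossprod(X, w - Zt))
    beta <- draw_mvn_precision(NULL, b, R = Rbeta)
    Xb <- drop(X %*% beta)

    if (g) {
      Q <- if (structured) ar1_precision(exp(-phi), g) / sigma2
           else diag(v0inv, g)
      theta <- draw_mvn_precision(ZtZ + Q, drop(crossprod(Z, w - Xb)))
      Zt <- drop(Z %*% theta)
    }

    if (structured) {
      if (is.null(fix$sigma2)) sigma2 <- update_sigma2(theta, phi, prior)
      if (is.null(fix$phi)) {
        st <- update_phi(theta, sigma2, phi, prior, psd)
        phi <- st$phi
        n_prop <- n_prop + 1L
        if (st$accepted) { acc_win <- acc_win + 1L }
        if (it > config$n_burnin && st$accepted) acc_total <- acc_total + 1L
        if (config$adapt && it <= config$n_burnin && it %% 100L == 0L) {
          rate <- acc_win / 100
          if (rate < 0.2) psd <- psd * 0.8
          else if (rate > 0.5) psd <- psd * 1.25
          acc_win <- 0L
        }
      }
    }

    if (!is.finite(sigma2) || anyNA(beta) || (g && anyNA(theta)))
      stop("sampler diverged at iteration ", it)

    if (it > config$n_burnin &&
        (it - config$n_burnin) %% config$thin == 0L) {
      k <- k + 1L
      B[k, ] <- beta
      if (g) TH[k, ] <- theta
      if (structured) { S2[k] <- sigma2; PH[k] <- phi }
    }
  }

  mce <- if (keep >= 400)
    c(apply(B, 2, mc_error),
      if (g) apply(TH, 2, mc_error),
      if (structured) c(sigma2 = mc_error(S2), phi = mc_error(PH)))
  else NULL

  structure(list(beta = B, theta = TH, sigma2 = S2, phi = PH,
                 phi_acceptance_rate = if (structured && is.null(fix$phi))
                   acc_total / config$n_samples else NA_real_,
                 phi_proposal_sd = psd,
                 mc_errors = mce,
                 model = model,
                 model_tag = match(model, c("weekly_structured", "trimester",
                                            "weekly_naive")),
                 weeks = weeks, n = n, config = config, prior = prior,
                 fixed = fix),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Temporal probit posterior (model ", x$model_tag, ": ", x$model,
      ")\n", sep = "")
  cat("  n = ", x$n, ", p = ", ncol(x$beta),
      ", exposure effects = ", if (is.null(x$theta)) 0 else ncol(x$theta),
      "\n", sep = "")
  cat("  kept draws = ", nrow(x$beta), sep = "")
  if (!is.na(x$phi_acceptance_rate))
    cat(", phi acceptance = ", round(x$phi_acceptance_rate, 3), sep = "")
  cat("\n")
  invisible(x)
}
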