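test_that("exponential correlation matrix and its AR(1) closed forms", {
  S <- corr_matrix(1, 5)
  expect_equal(S[1, 2], exp(-1))
  expect_equal(diag(S), rep(1, 5))
  expect_equal(S, t(S))

  S0 <- corr_matrix(1e-4, 44)
  expect_true(all(S0 >= exp(-0.0043)))

  for (phi in c(0.001, 0.1, 1, 3))
    expect_silent(chol(corr_matrix(phi, 44)))
  expect_error(corr_matrix(0, 5), "positive")
  expect_error(corr_matrix(-1, 5), "positive")

  # tridiagonal inverse and log determinant against dense linear algebra
  for (phi in c(0.05, 0.7, 2.5)) {
    for (g in c(1, 2, 3, 44)) {
      S <- corr_matrix(phi, g)
      Q <- critwin:::ar1_precision(exp(-phi), g)
      expect_equal(Q, solve(S), tolerance = 1e-8)
      th <- rnorm(g)
      expect_equal(critwin:::ar1_quad(th, exp(-phi)),
                   drop(t(th) %*% solve(S, th)), tolerance = 1e-8)
      expect_equal(critwin:::ar1_logdet(exp(-phi), g),
                   determinant(S)$modulus[1], tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("linear predictor accumulates covariate and exposure terms", {
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(linear_predictor(X, NULL, c(0, 0), NULL, probs = TRUE)$p,
               rep(0.5, 10))
  Z1 <- matrix(1, 1, 1)
  lp <- linear_predictor(matrix(0, 1, 1), Z1, 0, 1.6449, probs = TRUE)
  expect_equal(lp$p, 0.95, tolerance = 1e-4)

  set.seed(21)
  Z <- matrix(rnorm(30), 10, 3)
  beta <- rnorm(2); theta <- rnorm(3)
  eta <- linear_predictor(X, Z, beta, theta)
  # naive row-by-row accumulation oracle
  eta_o <- vapply(1:10, function(i)
    sum(X[i, ] * beta) + sum(Z[i, ] * theta), numeric(1))
  expect_equal(eta, eta_o)
  X[1, 1] <- NA
  expect_error(linear_predictor(X, Z, beta, theta), "NaN/NA")
})

test_that("truncated-normal latents: moments, signs, far tails", {
  set.seed(22)
  n <- 1e5
  w1 <- sample_latents(rep(1, n), rep(0, n))
  expect_true(all(w1 > 0))
  expect_equal(mean(w1), sqrt(2 / pi), tolerance = 0.01)

  w0 <- sample_latents(rep(0, n), rep(0, n))
  expect_true(all(w0 <= 0))
  expect_equal(mean(w0), -sqrt(2 / pi), tolerance = 0.01)

  # far tail: y = 0 with eta = +5 and deeper; inverse-CDF on the log scale
  # must stay finite and on the correct side
  for (eta in c(5, 10, 30)) {
    wt <- sample_latents(rep(0, 1000), rep(eta, 1000))
    expect_true(all(is.finite(wt)))
    expect_true(all(wt <= 0))
  }
  # oracle for the tail mean: E[Z | Z > a] = phi(a)/Phi(-a), via y = 1, eta = -5
  a <- 5
  wt1 <- sample_latents(rep(1, 2e4), rep(-a, 2e4)) + a  # shift back to Z > a
  expect_equal(mean(wt1), dnorm(a) / pnorm(-a), tolerance = 0.01)
})

test_that("conjugate beta update matches the normal-equations oracle", {
  set.seed(23)
  n <- 40; p <- 3
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  w <- rnorm(n, X %*% c(1, -2, 0.5))

  # deterministic check of the draw decomposition: mean + R^{-1} z
  pr <- prior_spec(beta_variance = 1e6)
  A <- crossprod(X) + diag(1e-6, p)
  b <- crossprod(X, w)
  set.seed(77); d <- update_beta(w, X, NULL, NULL, pr)
  set.seed(77); z <- rnorm(p)
  expect_equal(d, drop(solve(A, b) + backsolve(chol(A), z)),
               tolerance = 1e-8)
  # diffuse-prior limit: conditional mean equals least squares
  expect_equal(drop(solve(A, b)), unname(coef(lm(w ~ X - 1))),
               tolerance = 1e-4)

  # no data: a draw from the prior
  set.seed(24)
  d0 <- replicate(4000, update_beta(numeric(0),
                                    matrix(numeric(0), 0, 2), NULL, NULL,
                                    prior_spec(beta_variance = 9)))
  expect_equal(apply(d0, 1, sd), c(3, 3), tolerance = 0.15)
  expect_equal(rowMeans(d0), c(0, 0), tolerance = 0.2)
})

test_that("theta update matches the closed-form GLS oracle", {
  set.seed(25)
  n <- 20; g <- 3
  Z <- matrix(rnorm(n * g), n, g)
  X <- matrix(1, n, 1)
  beta <- 0.3
  w <- rnorm(n)
  sigma2 <- 0.7; phi <- 0.9
  pr <- prior_spec()

  Q <- solve(corr_matrix(phi, g) * sigma2)
  A <- crossprod(Z) + Q
  b <- crossprod(Z, w - X %*% beta)
  set.seed(78); d <- update_theta(w, X, Z, beta, sigma2, phi, pr)
  set.seed(78); z <- rnorm(g)
  expect_equal(d, drop(solve(A, b) + backsolve(chol(A), z)),
               tolerance = 1e-8)

  # Z = 0: prior recovery, MVN(0, sigma2 * Sigma(phi))
  set.seed(26)
  Z0 <- matrix(0, n, g)
  d0 <- replicate(4000, update_theta(w, X, Z0, beta, sigma2, phi, pr))
  expect_equal(unname(apply(d0, 1, sd)), rep(sqrt(sigma2), g),
               tolerance = 0.06)
  expect_lt(abs(cor(d0[1, ], d0[2, ]) - exp(-phi)), 0.06)

  # sigma2 -> 0 shrinks the draw to zero
  dsh <- update_theta(w, X, Z, beta, 1e-10, phi, pr)
  expect_lt(max(abs(dsh)), 1e-3)
})

test_that("sigma2 update follows its Inverse-Gamma full conditional", {
  set.seed(27)
  pr <- prior_spec()
  # theta = 0, g = 44: IG(3 + 22, 2), mean 2/24
  d <- replicate(1e5, update_sigma2(numeric(44), 0.5, pr))
  expect_equal(mean(d), 2 / 24, tolerance = 0.005)

  # KS agreement with the analytic CDF for a random theta and phi
  g <- 10; phi <- 0.8
  theta <- rnorm(g, 0, 0.3)
  b_post <- 2 + critwin:::ar1_quad(theta, exp(-phi)) / 2
  d2 <- replicate(2e4, update_sigma2(theta, phi, pr))
  ks <- ks.test(d2, pinvgamma, shape = 3 + g / 2, scale = b_post)
  expect_gt(ks$p.value, 0.01)
})

test_that("phi Metropolis step: support, degenerate proposal, grid oracle", {
  set.seed(28)
  pr <- prior_spec()
  g <- 44; sigma2 <- 1; phi_true <- 1.5
  L <- t(chol(corr_matrix(phi_true, g) * sigma2))
  theta <- drop(L %*% rnorm(g))

  # near-zero proposal sd: chain accepts almost always, barely moves
  acc <- 0; phi <- 1.0
  for (i in 1:200) {
    st <- update_phi(theta, sigma2, phi, pr, proposal_sd = 1e-7)
    acc <- acc + st$accepted; phi <- st$phi
  }
  expect_gt(acc / 200, 0.95)
  expect_lt(abs(phi - 1.0), 1e-3)

  # posterior sampling vs 1-d grid-posterior oracle
  phi <- 1.0; draws <- numeric(4000)
  for (i in seq_along(draws)) {
    st <- update_phi(theta, sigma2, phi, pr, proposal_sd = 0.6)
    phi <- st$phi; draws[i] <- phi
  }
  expect_true(all(draws > pr$phi_lower & draws < pr$phi_upper))
  oracle <- phi_grid_posterior(theta, sigma2)
  expect_lt(abs(median(draws) - oracle$median), 0.15)
  expect_lt(abs(mean(draws) - oracle$mean), 0.15)
})

test_that("run_mcmc: determinism, draw counts, diffuse limit", {
  set.seed(29)
  n <- 200; g <- 5
  X <- cbind(intercept = 1, x = rnorm(n))
  Z <- matrix(rnorm(n * g), n, g,
              dimnames = list(NULL, paste0("week_", 1:g)))
  y <- rbinom(n, 1, pnorm(-1 + 0.3 * Z[, 3]))
  cfg <- mcmc_config(n_burnin = 400, n_samples = 600, seed = 31)

  f1 <- run_mcmc(y, X, Z, "weekly_structured", config = cfg)
  f2 <- run_mcmc(y, X, Z, "weekly_structured", config = cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$theta, f2$theta)
  expect_equal(nrow(f1$beta), 600)
  expect_true(all(f1$sigma2 > 0))
  expect_true(all(f1$phi > 1e-4 & f1$phi < 3))

  cfg_thin <- mcmc_config(n_burnin = 200, n_samples = 600, thin = 3, seed = 5)
  f3 <- run_mcmc(y, X, Z, "weekly_naive", config = cfg_thin)
  expect_equal(nrow(f3$theta), 200)
  expect_null(f3$sigma2)

  # phi -> 3 with sigma2 matched to the diffuse variance: the structured
  # posterior approaches the independent diffuse posterior
  v0 <- 25
  cfgL <- mcmc_config(n_burnin = 500, n_samples = 3000, seed = 32)
  fs <- run_mcmc(y, X, Z, "weekly_structured", prior = prior_spec(),
                 config = cfgL, fix = list(phi = 3, sigma2 = v0))
  fd <- run_mcmc(y, X, Z, "weekly_naive",
                 prior = prior_spec(beta_variance = v0), config = cfgL)
  expect_equal(colMeans(fs$theta), colMeans(fd$theta), tolerance = 0.05)
})
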