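# Independent oracles and small fixture builders used across the suite.

# de Boor recursion for B-spline basis functions N_{i,k} on a given knot
# vector; written directly from the recurrence, independent of splines::bs.
deboor_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  N <- matrix(0, length(x), nb)
  for (i in seq_len(nb)) {
    for (r in seq_along(x)) N[r, i] <- deboor_N(x[r], i, degree, knots)
  }
  N
}

deboor_N <- function(x, i, k, t) {
  if (k == 0) {
    # right-closed at the final interval so the boundary point is covered
    last <- max(which(t < t[length(t)]))
    if ((t[i] <= x && x < t[i + 1]) ||
        (x == t[length(t)] && i == last)) 1 else 0
  } else {
    d1 <- t[i + k] - t[i]
    d2 <- t[i + k + 1] - t[i + 1]
    a <- if (d1 > 0) (x - t[i]) / d1 * deboor_N(x, i, k - 1, t) else 0
    b <- if (d2 > 0) (t[i + k + 1] - x) / d2 * deboor_N(x, i + 1, k - 1, t) else 0
    a + b
  }
}

# brute-force nearest neighbour distances
nn_dist_brute <- function(px, py, sx, sy) {
  vapply(seq_along(px), function(i)
    min(sqrt((sx - px[i])^2 + (sy - py[i])^2)), numeric(1))
}

# small-region generator configuration used to keep unit tests fast
quick_config <- function(n_births = 300, seed = 42, ...) {
  generator_config(
    n_births = n_births,
    region_extent = 60,
    date_range = c("2000-02-01", "2002-12-31"),
    birth_date_range = c("2001-01-01", "2002-12-31"),
    monitor_count = 4,
    dense_spacing = 6,
    seed = seed, ...)
}

# hand-built panel over explicit sources/dates/values
make_panel <- function(sources, dates, values) {
  structure(list(values = values, dates = as.Date(dates),
                 source_id = sources$source_id),
            class = "ozone_panel")
}

make_sources <- function(x, y, regime = "monitor") {
  data.frame(source_id = seq_along(x), regime = regime, x = x, y = y)
}

make_birth <- function(x, y, birth_date, ga, id = 1L) {
  data.frame(birth_id = id, x = x, y = y,
             birth_date = as.Date(birth_date), gestational_age = ga)
}

# Inverse-Gamma distribution function via the complementary gamma CDF
pinvgamma <- function(q, shape, scale)
  pgamma(1 / q, shape = shape, rate = scale, lower.tail = FALSE)

# 1-d grid posterior for phi given theta drawn from its structured prior
phi_grid_posterior <- function(theta, sigma2, lower = 1e-4, upper = 3,
                               n_grid = 4000) {
  grid <- seq(lower + 1e-9, upper - 1e-9, length.out = n_grid)
  ll <- vapply(grid, function(phi) {
    S <- critwin::corr_matrix(phi, length(theta)) * sigma2
    R <- chol(S)
    -sum(log(diag(R))) - 0.5 * sum(backsolve(R, theta, transpose = TRUE)^2)
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  list(grid = grid, weights = w,
       median = grid[which(cumsum(w) >= 0.5)[1]],
       mean = sum(grid * w))
}
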