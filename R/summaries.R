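#' Posterior window summaries for weekly exposure effects
#'
#' Per gestational week: posterior median, equal-tailed credible interval,
#' significance flag (interval excludes 0), and interval width. The average
#' interval width across weeks — the headline cross-metric comparison
#' statistic — is attached as attribute \code{"avg_width"}.
#'
#' @param draws a \code{posterior_draws} object (>= 100 kept draws).
#' @param level credible level (default 0.95).
#' @param max_report_week optionally truncate the report to the first so
#'   many weeks (display only; fitting is unaffected). Useful for the naive
#'   weekly model whose last-week intervals are extremely wide.
#' @return data.frame with columns \code{week}, \code{median},
#'   \code{lower95}, \code{upper95}, \code{significant},
#'   \code{interval_width}.
#' @export
summarize_windows <- function(draws, level = 0.95, max_report_week = NULL) {
  th <- if (inherits(draws, "posterior_draws")) draws$theta else draws
  if (is.null(th) || nrow(th) < 100)
    stop("need at least 100 posterior draws to summarize")
  weeks <- if (inherits(draws, "posterior_draws")) draws$weeks
           else seq_len(ncol(th))
  a <- (1 - level) / 2
  qs <- apply(th, 2, quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  out <- data.frame(week = weeks,
                    median = qs[2, ],
                    lower95 = qs[1, ],
                    upper95 = qs[3, ])
  out$significant <- out$lower95 > 0 | out$upper95 < 0
  out$interval_width <- out$upper95 - out$lower95
  if (!is.null(max_report_week))
    out <- out[is.na(out$week) | out$week <= max_report_week, , drop = FALSE]
  attr(out, "avg_width") <- mean(out$interval_width)
  out
}

#' Identify contiguous significant windows
#'
#' Maximal runs of consecutive gestational weeks whose credible intervals
#' exclude zero with a common sign.
#'
#' @param summaries data.frame from \code{\link{summarize_windows}},
#'   sorted by week.
#' @return data.frame with \code{start_week}, \code{end_week}, \code{sign}
#'   (+1/-1); zero rows when nothing is significant.
#' @export
identify_windows <- function(summaries) {
  s <- summaries[order(summaries$week), , drop = FALSE]
  sig <- which(s$significant)
  empty <- data.frame(start_week = integer(), end_week = integer(),
                      sign = integer())
  if (!length(sig)) return(empty)
  sgn <- sign(s$median[sig])
  brk <- c(TRUE, diff(s$week[sig]) != 1 | diff(sgn) != 0)
  run <- cumsum(brk)
  do.call(rbind, lapply(split(seq_along(sig), run), function(ix) {
    data.frame(start_week = s$week[sig[ix[1]]],
               end_week = s$week[sig[ix[length(ix)]]],
               sign = sgn[ix[1]])
  }))
}

#' Bernoulli-probit deviance
#'
#' -2 sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)] with
#' p_i = Phi(x_i' beta + z_i' theta); probabilities are clamped to
#' [1e-12, 1 - 1e-12].
#'
#' @param beta,theta parameter vectors.
#' @param y binary outcomes.
#' @param X design matrix.
#' @param Z exposure block (or NULL).
#' @return deviance (numeric scalar).
#' @export
probit_deviance <- function(beta, theta, y, X, Z = NULL) {
  p <- pnorm(linear_predictor(X, Z, beta, theta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Deviance information criterion
#'
#' d_bar is the posterior mean deviance, d_hat the deviance at the posterior
#' means of (beta, theta) (the classical plug-in), p_D = d_bar - d_hat the
#' effective number of parameters, and DIC = d_bar + p_D; smaller values
#' indicate a better model.
#'
#' @param draws a \code{posterior_draws} object.
#' @param y,X,Z the data the model was fit to.
#' @return an object of class \code{"fit_metrics"}: list(dic, p_d, d_bar,
#'   d_hat).
#' @export
compute_dic <- function(draws, y, X, Z = NULL) {
  B <- draws$beta
  TH <- draws$theta
  ndr <- nrow(B)
  W <- cbind(X, if (!is.null(Z)) Z)
  P <- t(cbind(B, if (!is.null(TH)) TH))
  dev <- numeric(ndr)
  chunk <- split(seq_len(ndr), ceiling(seq_len(ndr) / 250))
  for (ix in chunk) {
    pr <- pnorm(W %*% P[, ix, drop = FALSE])
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    dev[ix] <- -2 * colSums(y * log(pr) + (1 - y) * log(1 - pr))
  }
  d_bar <- mean(dev)
  d_hat <- probit_deviance(colMeans(B),
                           if (!is.null(TH)) colMeans(TH), y, X, Z)
  structure(list(dic = d_bar + (d_bar - d_hat),
                 p_d = d_bar - d_hat,
                 d_bar = d_bar, d_hat = d_hat),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("DIC = %.2f (p_D = %.2f, Dbar = %.2f, Dhat = %.2f)\n",
              x$dic, x$p_d, x$d_bar, x$d_hat))
  invisible(x)
}

#' Batch-means Monte Carlo standard error of a posterior mean
#'
#' Splits the chain into about sqrt(draws) consecutive batches and reports
#' the standard error of the batch means, which accounts for the chain's
#' autocorrelation.
#'
#' @param x numeric vector of draws (>= 400).
#' @return MC standard error.
#' @export
mc_error <- function(x) {
  n <- length(x)
  if (n < 400) stop("need at least 400 draws for a batch-means MC error")
  nb <- floor(sqrt(n))
  b <- floor(n / nb)
  m <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  sd(m) / sqrt(nb)
}

#' Compare window summaries across pollution metrics
#'
#' @param runs named list of window-summary data.frames on the same week
#'   grid (first element is the reference run).
#' @return an object of class \code{"metric_comparison"}: \code{metrics}
#'   (per-metric average interval width and Jaccard overlap of
#'   significant-week sets with the reference) and \code{median_diffs}
#'   (per-week posterior-median differences vs the reference).
#' @export
compare_metrics <- function(runs) {
  stopifnot(length(runs) >= 1)
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  wk <- runs[[1]]$week
  for (r in runs)
    if (!identical(r$week, wk)) stop("mismatched week grids across runs")
  jacc <- function(a, b) {
    u <- union(a, b)
    if (!length(u)) return(1)
    length(intersect(a, b)) / length(u)
  }
  ref_sig <- runs[[1]]$week[runs[[1]]$significant]
  metrics <- data.frame(
    metric = names(runs),
    avg_interval_width = vapply(runs, function(r) mean(r$interval_width),
                                numeric(1)),
    n_significant = vapply(runs, function(r) sum(r$significant), integer(1)),
    jaccard_vs_ref = vapply(runs, function(r)
      jacc(r$week[r$significant], ref_sig), numeric(1)),
    row.names = NULL)
  md <- data.frame(week = wk)
  for (nm in names(runs)) md[[nm]] <- runs[[nm]]$median - runs[[1]]$median
  structure(list(metrics = metrics, median_diffs = md),
            class = "metric_comparison")
}

#' @export
print.metric_comparison <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

#' Plot posterior medians and credible intervals by gestational week
#'
#' @param summaries data.frame from \code{\link{summarize_windows}}.
#' @param main plot title.
#' @export
plot_windows <- function(summaries, main = "Weekly ozone effects") {
  s <- summaries[!is.na(summaries$week), ]
  plot(s$week, s$median, ylim = range(s$lower95, s$upper95), pch = 16,
       col = ifelse(s$significant, "black", "grey50"),
       xlab = "Gestational week", ylab = "Effect per SD of weekly ozone",
       main = main)
  segments(s$week, s$lower95, s$week, s$upper95,
           lty = ifelse(s$significant, 3, 1),
           col = ifelse(s$significant, "black", "grey50"))
  abline(h = 0, lty = 2, col = "grey70")
  invisible(summaries)
}

#' Write summary outputs
#'
#' \code{write_windows} writes windows.csv; \code{write_fit_metrics} writes
#' fit_metrics.json; \code{write_comparison} writes comparison.csv.
#' @param x object to write.
#' @param path output path.
#' @name summary_io
#' @export
write_windows <- function(x, path) data.table::fwrite(x, path)

#' @rdname summary_io
#' @export
write_fit_metrics <- function(x, path)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)

#' @rdname summary_io
#' @export
write_comparison <- function(x, path) {
  data.table::fwrite(x$metrics, path)
  invisible(x)
}
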