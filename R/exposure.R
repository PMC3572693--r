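#' Maximum distance from a square cell centre
#'
#' For pollution products reported at the centres of square cells of side
#' \code{cell_side}, the farthest any point of the cell lies from its centre
#' is half the cell diagonal, \code{cell_side * sqrt(2) / 2}. On a 12 km
#' grid this is 8.485... km, the origin of the conventional 8.49 km
#' (5.28 mile) eligibility radius for monitor-based exposure assignment.
#'
#' @param cell_side cell side length, km (>= 0).
#' @return half-diagonal distance, km.
#' @export
max_cell_distance <- function(cell_side) {
  if (any(cell_side < 0)) stop("cell_side must be non-negative")
  cell_side * sqrt(2) / 2
}

# squared Euclidean cross-distances between point sets, column-chunk safe
cross_dist <- function(ax, ay, bx, by) {
  sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
}

panel_active <- function(panel) !is.na(panel$values)

#' Nearest active pollution source to a location
#'
#' Returns the source minimizing Euclidean distance among those active
#' (reporting a value) on the given day; ties are broken by smallest
#' \code{source_id} so reruns are deterministic. If no panel/day is supplied
#' all sources are considered active.
#'
#' @param location numeric length-2 (x, y) in km.
#' @param sources data.frame with \code{source_id}, \code{x}, \code{y}.
#' @param panel optional \code{ozone_panel} giving per-day activity.
#' @param day optional calendar day (Date) to evaluate activity on.
#' @return list with \code{source_id} and \code{distance} (km);
#'   \code{source_id = NA} and \code{distance = Inf} when no source is
#'   active (the "no-source" sentinel).
#' @export
nearest_source <- function(location, sources, panel = NULL, day = NULL) {
  keep <- rep(TRUE, nrow(sources))
  if (!is.null(panel) && !is.null(day)) {
    j <- match(as.Date(day), panel$dates)
    if (is.na(j)) stop("day outside panel date range")
    keep <- !is.na(panel$values[match(sources$source_id, panel$source_id), j])
  }
  if (!any(keep))
    return(list(source_id = NA_integer_, distance = Inf))
  d <- sqrt((sources$x - location[1])^2 + (sources$y - location[2])^2)
  idx <- which(keep)[order(d[keep], sources$source_id[keep])[1]]
  list(source_id = sources$source_id[idx], distance = d[idx])
}

#' Eligibility filter: an active source within the radius on every pregnancy day
#'
#' A birth is eligible when on every day of the pregnancy at least one source
#' within \code{radius} km of the residence reports a value. Births failing
#' the rule are excluded; the exclusion log records the first pregnancy day
#' (1-based, counted from conception) on which no in-radius source was
#' active. With complete-coverage products (grid or dense regimes at spacing
#' <= 12 km) no births are excluded.
#'
#' @param cohort birth-record data.frame (needs \code{x}, \code{y},
#'   \code{birth_date}, \code{gestational_age}).
#' @param sources sources of one regime.
#' @param panel matching \code{ozone_panel}.
#' @param radius eligibility radius, km (default 8.49).
#' @return list with \code{eligible} (cohort subset) and \code{exclusions}
#'   (data.frame \code{birth_id}, \code{first_failing_day}, \code{reason}).
#' @export
eligibility_filter <- function(cohort, sources, panel, radius = 8.49) {
  stopifnot(radius > 0)
  if (nrow(cohort) == 0)
    return(list(eligible = cohort,
                exclusions = data.frame(birth_id = integer(),
                                        first_failing_day = integer(),
                                        reason = character())))
  rows <- match(sources$source_id, panel$source_id)
  act <- !is.na(panel$values[rows, , drop = FALSE])
  complete <- all(act)
  d0 <- as.integer(panel$dates[1])

  ok <- logical(nrow(cohort))
  fail_day <- rep(NA_integer_, nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))

  chunks <- split(seq_len(nrow(cohort)),
                  ceiling(seq_len(nrow(cohort)) / 2000))
  for (ch in chunks) {
    D <- cross_dist(cohort$x[ch], cohort$y[ch], sources$x, sources$y)
    within <- D <= radius
    for (k in seq_along(ch)) {
      i <- ch[k]
      S <- which(within[k, ])
      if (!length(S)) {
        fail_day[i] <- 1L
        reason[i] <- "no source within radius"
        next
      }
      if (complete) { ok[i] <- TRUE; next }
      ndays <- 7L * cohort$gestational_age[i]
      j0 <- as.integer(cohort$birth_date[i]) - ndays - d0 + 1L
      idx <- j0 + seq_len(ndays)
      if (idx[1] < 1L || idx[length(idx)] > ncol(act))
        stop("pregnancy days outside panel date range for birth ",
             cohort$birth_id[i])
      a <- act[S, idx, drop = FALSE]
      any_active <- if (length(S) == 1L) a[1, ] else colSums(a) > 0
      if (all(any_active)) ok[i] <- TRUE
      else {
        fail_day[i] <- which(!any_active)[1]
        reason[i] <- "no active source within radius on day"
      }
    }
  }
  list(eligible = cohort[ok, , drop = FALSE],
       exclusions = data.frame(
         birth_id = cohort$birth_id[!ok],
         first_failing_day = fail_day[!ok],
         reason = reason[!ok],
         stringsAsFactors = FALSE))
}

#' Weekly pregnancy-average exposures for one birth
#'
#' Assigns each pregnancy day the value of the nearest active source and
#' averages days 7(j-1)+1 ... 7j after conception into gestational-week j,
#' for j = 1 ... gestational age. Weeks beyond the gestational age are
#' invalid and set to 0. Conception is taken as birth date minus
#' 7 x gestational age days (completed weeks).
#'
#' @param birth one row of the cohort.
#' @param sources sources of one regime.
#' @param panel matching \code{ozone_panel}.
#' @param radius assignment sanity radius, km; a pregnancy day whose nearest
#'   active source is farther than this raises an error (such births should
#'   have been excluded by \code{\link{eligibility_filter}}).
#' @return list with \code{values} (numeric 44, raw ppm, 0 where invalid)
#'   and \code{valid} (logical 44).
#' @export
weekly_exposure <- function(birth, sources, panel, radius = 8.49) {
  ga <- birth$gestational_age
  ndays <- 7L * ga
  d0 <- as.integer(panel$dates[1])
  j0 <- as.integer(birth$birth_date) - ndays - d0 + 1L
  idx <- j0 + seq_len(ndays)
  if (idx[1] < 1L || idx[length(idx)] > length(panel$dates))
    stop("pregnancy days outside panel date range")

  rows <- match(sources$source_id, panel$source_id)
  V <- panel$values[rows, idx, drop = FALSE]
  d <- sqrt((sources$x - birth$x)^2 + (sources$y - birth$y)^2)
  ord <- order(d, sources$source_id)

  daily <- rep(NA_real_, ndays)
  dist_used <- rep(NA_real_, ndays)
  for (s in ord) {
    fill <- is.na(daily) & !is.na(V[s, ])
    if (any(fill)) {
      daily[fill] <- V[s, fill]
      dist_used[fill] <- d[s]
    }
    if (!anyNA(daily)) break
  }
  if (anyNA(daily) || any(dist_used > radius))
    stop("pregnancy day with no active source within ", radius,
         " km; birth should have been excluded")

  wk <- colMeans(matrix(daily, nrow = 7L))
  values <- numeric(44)
  values[seq_len(ga)] <- wk
  list(values = values, valid = seq_len(44) <= ga)
}

#' Standardize a raw weekly exposure matrix
#'
#' Pools all valid person-week entries to a single centre and scale (sample
#' standard deviation) so that one unit of the standardized exposure is "one
#' standard deviation" of weekly ozone across the whole cohort; invalid
#' entries (weeks beyond the gestational age) are exactly 0 so they never
#' contribute to the probit linear predictor. Per-week scaling is available
#' as an option.
#'
#' @param raw n x 44 matrix of raw weekly averages (ppm).
#' @param valid n x 44 logical/0-1 mask, 1 iff week j <= gestational age.
#' @param method \code{"pooled"} (default) or \code{"per_week"}.
#' @return an object of class \code{"exposure_matrix"}: list with
#'   \code{values}, \code{valid}, and \code{scaling} (centre/scale, ppm).
#' @export
standardize_exposure <- function(raw, valid, method = c("pooled", "per_week")) {
  method <- match.arg(method)
  valid <- valid != 0
  v <- raw[valid]
  if (length(v) < 2) stop("need at least 2 valid entries to standardize")
  if (method == "pooled") {
    center <- mean(v)
    scale <- sd(v)
    if (!is.finite(scale) || scale == 0) stop("zero variance in valid exposures")
    out <- (raw - center) / scale
  } else {
    center <- scale <- numeric(ncol(raw))
    out <- raw
    for (j in seq_len(ncol(raw))) {
      vj <- raw[valid[, j], j]
      if (length(vj) < 2) { center[j] <- 0; scale[j] <- 1; next }
      center[j] <- mean(vj)
      scale[j] <- sd(vj)
      if (!is.finite(scale[j]) || scale[j] == 0)
        stop("zero variance in week ", j)
      out[, j] <- (raw[, j] - center[j]) / scale[j]
    }
  }
  out[!valid] <- 0
  structure(list(values = out, valid = 1 * valid,
                 scaling = list(center = center, scale = scale,
                                method = method)),
            class = "exposure_matrix")
}

#' Trimester averages of a weekly exposure vector
#'
#' Conventional split: trimester 1 = weeks 1-13, trimester 2 = weeks 14-26,
#' trimester 3 = weeks 27 through the gestational age.
#'
#' @param weekly numeric vector of raw weekly values (length >= ga).
#' @param ga gestational age in completed weeks (>= 27).
#' @return numeric length 3.
#' @export
trimester_average <- function(weekly, ga) {
  stopifnot(ga >= 27, length(weekly) >= ga)
  c(mean(weekly[1:13]), mean(weekly[14:26]), mean(weekly[27:ga]))
}

#' Assign weekly exposures to a whole cohort under one metric regime
#'
#' Applies the eligibility filter, computes each eligible birth's weekly
#' nearest-active-source averages, and standardizes. For complete-coverage
#' regimes a fast path reuses the single nearest source per birth.
#'
#' @param cohort birth-record data.frame.
#' @param sources full sources table (all regimes).
#' @param panel \code{ozone_panel} covering all sources.
#' @param regime one of \code{"monitor"}, \code{"grid"}, \code{"dense"},
#'   \code{"truth"}.
#' @param radius eligibility radius, km.
#' @param standardize_method passed to \code{\link{standardize_exposure}}.
#' @return list with \code{exposure} (an \code{exposure_matrix}),
#'   \code{cohort} (eligible subset, row order preserved),
#'   \code{exclusions}, and \code{raw} (raw weekly matrix, ppm).
#' @export
compute_exposure <- function(cohort, sources, panel, regime,
                             radius = 8.49,
                             standardize_method = "pooled") {
  src <- sources[sources$regime == regime, , drop = FALSE]
  if (!nrow(src)) stop("no sources for regime ", regime)
  src <- src[order(src$source_id), , drop = FALSE]
  sub <- structure(list(
    values = panel$values[match(src$source_id, panel$source_id), , drop = FALSE],
    dates = panel$dates, source_id = src$source_id), class = "ozone_panel")

  elig <- eligibility_filter(cohort, src, sub, radius)
  co <- elig$eligible
  n <- nrow(co)
  raw <- matrix(0, n, 44)
  valid <- matrix(FALSE, n, 44)
  if (n) {
    complete <- !anyNA(sub$values)
    d0 <- as.integer(sub$dates[1])
    if (complete) {
      # nearest source is day-invariant: chunked nearest-neighbour lookup
      nn <- integer(n)
      chunks <- split(seq_len(n), ceiling(seq_len(n) / 2000))
      for (ch in chunks) {
        D <- cross_dist(co$x[ch], co$y[ch], src$x, src$y)
        nn[ch] <- apply(D, 1, which.min)
      }
      for (i in seq_len(n)) {
        ga <- co$gestational_age[i]
        ndays <- 7L * ga
        j0 <- as.integer(co$birth_date[i]) - ndays - d0
        if (j0 < 0L || j0 + ndays > ncol(sub$values))
          stop("pregnancy days outside panel date range for birth ",
               co$birth_id[i])
        daily <- sub$values[nn[i], j0 + seq_len(ndays)]
        raw[i, seq_len(ga)] <- colMeans(matrix(daily, nrow = 7L))
        valid[i, seq_len(ga)] <- TRUE
      }
    } else {
      for (i in seq_len(n)) {
        w <- weekly_exposure(co[i, ], src, sub, radius)
        raw[i, ] <- w$values
        valid[i, ] <- w$valid
      }
    }
  }
  exposure <- standardize_exposure(raw, valid, standardize_method)
  list(exposure = exposure, cohort = co,
       exclusions = elig$exclusions, raw = raw)
}

#' Write an exposure matrix as delimited text
#'
#' Long format: one row per person-week with raw and standardized values and
#' the validity flag.
#' @param exposure an \code{exposure_matrix}.
#' @param raw matching raw matrix (ppm).
#' @param birth_id vector of birth identifiers (one per row).
#' @param path output csv path.
#' @export
write_exposure <- function(exposure, raw, birth_id, path) {
  n <- nrow(exposure$values)
  long <- data.table::data.table(
    birth_id = rep(birth_id, times = 44),
    week = rep(seq_len(44), each = n),
    raw = as.vector(raw),
    standardized = as.vector(exposure$values),
    valid = as.integer(as.vector(exposure$valid)))
  data.table::fwrite(long, path)
}
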