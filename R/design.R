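#' Cubic B-spline basis with four degrees of freedom
#'
#' Order-4 (cubic) B-spline basis without an intercept column: boundary
#' knots at the observed minimum and maximum, one interior knot at the
#' median, giving exactly 4 basis columns. Used for the temperature and
#' dewpoint adjustment terms.
#'
#' @param values numeric vector (>= 5 distinct values).
#' @param df degrees of freedom (basis columns); default 4.
#' @return n x df basis matrix.
#' @export
bspline_basis <- function(values, df = 4) {
  if (length(unique(values)) < 5)
    stop("need at least 5 distinct values for a cubic spline basis")
  b <- splines::bs(values, df = df, degree = 3, intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(values))
  colnames(m) <- paste0("bs", seq_len(ncol(m)))
  m
}

# indicator columns for the non-reference levels of a factor
dummy_cols <- function(x, levels, prefix) {
  x <- as.character(x)
  if (any(!x %in% levels))
    stop("unseen level in ", prefix, ": ",
         paste(unique(setdiff(x, levels)), collapse = ", "))
  out <- vapply(levels[-1], function(l) as.numeric(x == l),
                numeric(length(x)))
  colnames(out) <- paste0(prefix, "_", gsub("[^0-9A-Za-z]+", "_", levels[-1]))
  out
}

#' Build the fixed-covariate design matrix
#'
#' Assembles the probit model's covariate matrix: intercept; gestational age
#' (linear, weeks); season of birth (vs winter); infant sex (female vs
#' male); parity (vs no previous live birth); maternal age group (vs 30-34);
#' race/ethnicity (vs non-Hispanic white); education (vs less than high
#' school); birth year (vs the first year); and 4-df cubic B-spline bases
#' for temperature and dewpoint at the birth date. With every factor present
#' and splines on, p = 29 columns. Constant and collinear columns are
#' dropped with a warning so the returned matrix has full column rank.
#'
#' @param cohort birth-record data.frame.
#' @param covariates character vector choosing blocks, a subset of
#'   \code{c("ga", "season", "sex", "parity", "age", "race", "education",
#'   "year", "weather")}; default all.
#' @param include_splines include the temperature/dewpoint spline bases
#'   (equivalent to dropping \code{"weather"} when FALSE).
#' @return an object of class \code{"design_matrix"}: list with
#'   \code{matrix}, \code{column_names}, \code{reference_levels}.
#' @export
build_design <- function(cohort,
                         covariates = c("ga", "season", "sex", "parity",
                                        "age", "race", "education", "year",
                                        "weather"),
                         include_splines = TRUE) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  if (!include_splines) covariates <- setdiff(covariates, "weather")
  lev <- cohort_levels()
  n <- nrow(cohort)
  yl <- sort(unique(as.character(cohort$birth_year)))

  parts <- list(intercept = matrix(1, n, 1,
                                   dimnames = list(NULL, "intercept")))
  if ("ga" %in% covariates)
    parts$ga <- matrix(as.numeric(cohort$gestational_age), n, 1,
                       dimnames = list(NULL, "ga_weeks"))
  if ("season" %in% covariates)
    parts$season <- dummy_cols(cohort$season_of_birth, lev$season, "season")
  if ("sex" %in% covariates) {
    s <- dummy_cols(cohort$sex, lev$sex, "sex")
    colnames(s) <- "sex_female"
    parts$sex <- s
  }
  if ("parity" %in% covariates)
    parts$parity <- dummy_cols(cohort$parity, lev$parity, "parity")
  if ("age" %in% covariates)
    parts$age <- dummy_cols(cohort$maternal_age_group, lev$age_group, "age")
  if ("race" %in% covariates)
    parts$race <- dummy_cols(cohort$race_ethnicity, lev$race, "race")
  if ("education" %in% covariates)
    parts$edu <- dummy_cols(cohort$education, lev$education, "edu")
  if ("year" %in% covariates && length(yl) > 1)
    parts$year <- dummy_cols(cohort$birth_year, yl, "year")
  if ("weather" %in% covariates) {
    parts$temp <- bspline_basis(cohort$temperature_at_birth)
    colnames(parts$temp) <- paste0("temp_", colnames(parts$temp))
    parts$dew <- bspline_basis(cohort$dewpoint_at_birth)
    colnames(parts$dew) <- paste0("dew_", colnames(parts$dew))
  }

  X <- do.call(cbind, parts)

  # drop constant columns (single observed level), then enforce full rank
  const <- apply(X, 2, function(v) all(v == v[1]))
  const["intercept"] <- FALSE
  if (any(const)) {
    warning("dropping constant design columns: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_ix <- q$pivot[seq.int(q$rank + 1L, ncol(X))]
    warning("dropping collinear design columns: ",
            paste(colnames(X)[drop_ix], collapse = ", "))
    X <- X[, -drop_ix, drop = FALSE]
  }

  refs <- c(season = lev$season[1], sex = lev$sex[1], parity = lev$parity[1],
            age = lev$age_group[1], race = lev$race[1],
            education = lev$education[1],
            year = if (length(yl)) yl[1] else NA_character_)
  structure(list(matrix = X, column_names = colnames(X),
                 reference_levels = refs),
            class = "design_matrix")
}

#' Assemble the exposure block for a model variant
#'
#' Weekly variants (the temporally structured model and the naive
#' independent-effects model) emit one column per estimable gestational week
#' up to \code{max_week}: weeks with zero valid observations are dropped
#' (e.g. week 44 when no birth reaches 44 completed weeks). The trimester
#' variant emits 3 columns of standardized trimester averages computed from
#' the raw weekly values.
#'
#' @param exposure an \code{exposure_matrix}.
#' @param model \code{"weekly_structured"}, \code{"trimester"}, or
#'   \code{"weekly_naive"}.
#' @param max_week last gestational week eligible for a weekly effect
#'   (default 43; week 44 is rarely estimable).
#' @param raw raw weekly matrix (required for \code{"trimester"}).
#' @param ga gestational ages (required for \code{"trimester"}).
#' @return list with \code{block} (n x g), \code{labels}, \code{weeks}
#'   (gestational-week index per column; NA for trimester columns), and
#'   \code{model}.
#' @export
build_exposure_block <- function(exposure,
                                 model = c("weekly_structured", "trimester",
                                           "weekly_naive"),
                                 max_week = 43, raw = NULL, ga = NULL) {
  model <- match.arg(model)
  stopifnot(max_week <= 44)
  if (model == "trimester") {
    if (is.null(raw) || is.null(ga))
      stop("trimester block needs raw weekly values and gestational ages")
    Tm <- t(vapply(seq_along(ga),
                   function(i) trimester_average(raw[i, ], ga[i]),
                   numeric(3)))
    Tm <- scale(Tm)  # one-sd units per trimester
    block <- matrix(as.numeric(Tm), nrow = nrow(Tm))
    colnames(block) <- paste0("trimester_", 1:3)
    return(list(block = block, labels = colnames(block),
                weeks = rep(NA_integer_, 3), model = model))
  }
  nvalid <- colSums(exposure$valid != 0)
  weeks <- which(seq_len(44) <= max_week & nvalid > 0)
  block <- exposure$values[, weeks, drop = FALSE]
  colnames(block) <- paste0("week_", weeks)
  list(block = block, labels = colnames(block),
       weeks = as.integer(weeks), model = model)
}

#' Write a design matrix with labeled columns for audit
#' @param design a \code{design_matrix}.
#' @param path output csv path.
#' @export
write_design <- function(design, path)
  data.table::fwrite(as.data.frame(design$matrix), path)
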