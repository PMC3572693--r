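#' Read a cohort table written by \code{\link{write_cohort}}
#'
#' Restores factor codings (reference levels first) and Date columns so a
#' cohort round-trips through births.csv unchanged.
#'
#' @param path births.csv path.
#' @return birth-record data.frame.
#' @export
read_cohort <- function(path) {
  co <- as.data.frame(data.table::fread(path))
  lev <- cohort_levels()
  co$birth_date <- as.Date(co$birth_date)
  co$sex <- factor(co$sex, levels = lev$sex)
  co$season_of_birth <- factor(co$season_of_birth, levels = lev$season)
  co$parity <- factor(as.character(co$parity), levels = lev$parity)
  co$maternal_age_group <- factor(co$maternal_age_group,
                                  levels = lev$age_group)
  co$race_ethnicity <- factor(co$race_ethnicity, levels = lev$race)
  co$education <- factor(co$education, levels = lev$education)
  co$birth_year <- factor(as.character(co$birth_year))
  co
}

#' Read a sources table written by \code{\link{write_sources}}
#' @param path sources.csv path.
#' @return sources data.frame.
#' @export
read_sources <- function(path) as.data.frame(data.table::fread(path))

model_from_tag <- function(m) {
  if (is.numeric(m))
    c("weekly_structured", "trimester", "weekly_naive")[m]
  else m
}

#' Run the critical-window analysis pipeline
#'
#' Orchestrates generate -> expose -> design -> fit -> summarize as one
#' reproducible run: simulates the cohort and pollution fields, assigns and
#' standardizes weekly exposures under each requested metric regime, fits
#' the requested model variants, and produces window summaries, DIC, and
#' (for multi-metric runs) a cross-metric comparison on the common eligible
#' subset. All tables are written as CSV under \code{out_dir} together with
#' a manifest recording the configuration hash, seeds, stage timings and
#' row counts.
#'
#' @param gen_config a \code{\link{generator_config}}.
#' @param out_dir output directory (created if missing); NULL to skip all
#'   file output.
#' @param metrics metric regimes to run, subset of
#'   \code{c("monitor", "grid", "dense", "truth")}.
#' @param models model variants, by name or tag (1 = weekly_structured,
#'   2 = trimester, 3 = weekly_naive).
#' @param prior a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_config}}; each fit offsets its seed so
#'   fits are independent but reproducible.
#' @param radius eligibility radius, km (default 8.49).
#' @param max_week last gestational week given a weekly effect (default 43).
#' @param outcome_metric regime whose exposures generate the outcomes
#'   (default \code{"truth"} if requested, else \code{"dense"}).
#' @param common_subset when several metrics are run, restrict every fit to
#'   the births eligible under all of them (default TRUE), so runs differ
#'   only in the exposure values.
#' @param write_panel_file also write the (large) daily panel.csv.
#' @param write_draws_file also write draws.csv (long format).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the cohort, sources, exposures, fits,
#'   window summaries, windows, fit metrics, comparison and manifest.
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         out_dir = NULL,
                         metrics = "dense",
                         models = "weekly_structured",
                         prior = prior_spec(),
                         mcmc = mcmc_config(),
                         radius = 8.49,
                         max_week = 43,
                         outcome_metric = NULL,
                         common_subset = TRUE,
                         write_panel_file = FALSE,
                         write_draws_file = FALSE,
                         quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           ...)
  models <- vapply(models, model_from_tag, character(1))
  stopifnot(all(metrics %in% c("monitor", "grid", "dense", "truth")))
  if (is.null(outcome_metric))
    outcome_metric <- if ("truth" %in% metrics) "truth" else "dense"
  need_truth <- "truth" %in% c(metrics, outcome_metric)
  timings <- c()
  tick <- function(label) {
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[label] <<- round(el - sum(timings), 2)
  }

  say("generating sources, pollution panel, cohort")
  sources <- gen_sources(gen_config, include_truth = need_truth)
  panel <- gen_ozone_panel(sources, gen_config)
  cohort <- gen_cohort(gen_config)
  tick("generate")

  say("assigning outcome-model exposures (", outcome_metric, ")")
  ex_out <- compute_exposure(cohort, sources, panel, outcome_metric, radius)
  if (nrow(ex_out$cohort) != nrow(cohort))
    stop("outcome metric must have complete coverage")
  design_full <- build_design(cohort)
  cohort <- gen_outcomes(cohort, ex_out$exposure, design_full, gen_config)
  tick("outcomes")

  say("assigning exposures per metric")
  exposures <- lapply(stats::setNames(metrics, metrics), function(m) {
    if (m == outcome_metric) {
      out <- ex_out
      out$cohort <- cohort[match(out$cohort$birth_id, cohort$birth_id), ]
      out
    } else compute_exposure(cohort, sources, panel, m, radius)
  })
  for (m in metrics)
    exposures[[m]]$cohort <-
      cohort[cohort$birth_id %in% exposures[[m]]$cohort$birth_id, ]

  if (common_subset && length(metrics) > 1) {
    ids <- Reduce(intersect, lapply(exposures, function(e) e$cohort$birth_id))
    say("restricting to common eligible subset: ", length(ids), " births")
    for (m in metrics) {
      keep <- exposures[[m]]$cohort$birth_id %in% ids
      exposures[[m]]$cohort <- exposures[[m]]$cohort[keep, , drop = FALSE]
      exposures[[m]]$raw <- exposures[[m]]$raw[keep, , drop = FALSE]
      # restandardize within the analysis subset
      exposures[[m]]$exposure <- standardize_exposure(
        exposures[[m]]$raw, exposures[[m]]$exposure$valid[keep, , drop = FALSE])
    }
  }
  tick("expose")

  fits <- list(); windows <- list(); summaries <- list(); metrics_out <- list()
  fit_k <- 0L
  for (m in metrics) {
    co <- exposures[[m]]$cohort
    des <- build_design(co)
    y <- co$outcome
    for (mod in models) {
      fit_k <- fit_k + 1L
      key <- paste(m, mod, sep = ".")
      say("fitting ", key, " (n = ", nrow(co), ")")
      blk <- build_exposure_block(
        exposures[[m]]$exposure, mod, max_week = max_week,
        raw = exposures[[m]]$raw, ga = co$gestational_age)
      cfg <- mcmc
      cfg$seed <- mcmc$seed + 1000L * fit_k
      fit <- run_mcmc(y, des$matrix, blk$block, model = mod,
                      prior = prior, config = cfg, weeks = blk$weeks)
      fits[[key]] <- fit
      sm <- summarize_windows(fit)
      summaries[[key]] <- sm
      # contiguous-week runs only make sense for weekly effect grids
      windows[[key]] <- if (mod == "trimester")
        data.frame(start_week = integer(), end_week = integer(),
                   sign = integer())
      else identify_windows(sm)
      metrics_out[[key]] <- compute_dic(fit, y, des$matrix, blk$block)
    }
  }
  tick("fit")

  comparison <- NULL
  if (length(metrics) > 1 && "weekly_structured" %in% models) {
    keys <- paste(metrics, "weekly_structured", sep = ".")
    comparison <- compare_metrics(stats::setNames(summaries[keys], metrics))
  }
  tick("summarize")

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "births.csv"))
    write_sources(sources, file.path(out_dir, "sources.csv"))
    if (write_panel_file) write_panel(panel, file.path(out_dir, "panel.csv"))
    cfgp <- file.path(out_dir, "generator_config.yaml")
    write_generator_config(gen_config, cfgp)
    for (m in metrics) {
      write_exposure(exposures[[m]]$exposure, exposures[[m]]$raw,
                     exposures[[m]]$cohort$birth_id,
                     file.path(out_dir, paste0("exposure_", m, ".csv")))
      if (nrow(exposures[[m]]$exclusions))
        data.table::fwrite(exposures[[m]]$exclusions,
                           file.path(out_dir, paste0("exclusions_", m, ".csv")))
    }
    for (key in names(summaries)) {
      write_windows(summaries[[key]],
                    file.path(out_dir, paste0("windows_", key, ".csv")))
      fi <- c(unclass(metrics_out[[key]]),
              list(model = fits[[key]]$model,
                   n = fits[[key]]$n,
                   kept_draws = nrow(fits[[key]]$beta),
                   phi_acceptance_rate =
                     if (!is.na(fits[[key]]$phi_acceptance_rate))
                       fits[[key]]$phi_acceptance_rate,
                   mc_error_range = if (!is.null(fits[[key]]$mc_errors))
                     range(fits[[key]]$mc_errors)))
      fi <- Filter(Negate(is.null), fi)
      jsonlite::write_json(fi, file.path(out_dir,
                                         paste0("fit_metrics_", key, ".json")),
                           auto_unbox = TRUE, digits = NA)
      if (write_draws_file) {
        f <- fits[[key]]
        dr <- cbind(as.data.frame(f$beta), as.data.frame(f$theta))
        dr <- data.table::data.table(
          iteration = rep(seq_len(nrow(f$beta)), times = ncol(dr)),
          parameter = rep(colnames(dr), each = nrow(f$beta)),
          value = unlist(dr, use.names = FALSE))
        data.table::fwrite(dr, file.path(out_dir, paste0("draws_", key, ".csv")))
      }
    }
    if (!is.null(comparison))
      write_comparison(comparison, file.path(out_dir, "comparison.csv"))
    manifest <- list(
      config_md5 = unname(tools::md5sum(cfgp)),
      seed = gen_config$seed,
      mcmc_seed = mcmc$seed,
      metrics = metrics, models = models, radius = radius,
      n_births = nrow(cohort),
      n_eligible = vapply(exposures, function(e) nrow(e$cohort), integer(1)),
      prevalence = mean(cohort$outcome),
      stage_seconds = as.list(timings),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("done")
  invisible(list(cohort = cohort, sources = sources, panel = panel,
                 exposures = exposures, fits = fits, summaries = summaries,
                 windows = windows, fit_metrics = metrics_out,
                 comparison = comparison, manifest = manifest,
                 timings = timings))
}
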