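#' Configure a per-stage analysis run
#'
#' @param input path to a CSV (header row, `.` decimal) or the name of a
#'   shipped scenario preset (see [scenario_names()]).
#' @param outcome outcome column name (CSV inputs; presets always use
#'   `"acuity"`).
#' @param covariates covariate column names; default all remaining numeric
#'   columns.
#' @param g_rule,g coefficient-prior scale, see [prior_settings()].
#' @param sampler logical; run the MC3 cross-check and add a `pmp_mcmc`
#'   column to the top-models table.
#' @param n_iter,burn_in MC3 iteration counts, see [mc3_settings()].
#' @param top_m number of top models reported.
#' @param thresholds evidence cut points, strictly increasing in `(0, 1)`.
#' @param variance posterior-SD form, see [bma_average()].
#' @param seed integer seed used for preset generation and the sampler.
#' @param stage_label optional label; defaults to the preset name or file
#'   name.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, outcome = "acuity", covariates = NULL,
                       g_rule = "uip", g = NULL, sampler = FALSE,
                       n_iter = 100000L, burn_in = 10000L, top_m = 3L,
                       thresholds = c(0.5, 0.75, 0.95),
                       variance = "total", seed = 1L, stage_label = NULL) {
  if (!is.null(covariates) && outcome %in% covariates)
    stop("outcome column must not appear among the covariates", call. = FALSE)
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be strictly increasing in (0, 1)", call. = FALSE)
  structure(list(input = input, outcome = outcome, covariates = covariates,
                 g_rule = g_rule, g = g, sampler = isTRUE(sampler),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 top_m = as.integer(top_m), thresholds = thresholds,
                 variance = variance, seed = as.integer(seed),
                 stage_label = stage_label),
            class = "run_config")
}

#' Run one school-stage analysis end to end
#'
#' Loads (or generates) the study table, centers it, enumerates and fits all
#' models under the g-prior, computes posterior model probabilities,
#' model-averaged summaries and evidence grades, and optionally cross-checks
#' the exact PMPs with the MC3 sampler.
#'
#' @param config a [run_config()] (or a preset name / CSV path, in which case
#'   a default config is built around it).
#' @param ... passed to [run_config()] when `config` is a character input.
#' @return An object of class `stage_report`: `variable_table` (name, PIP,
#'   post mean, post SD, sign consistency, evidence grade; PIP descending),
#'   `top_models_table` (inclusion indicators, exact and, with the sampler
#'   on, MCMC PMPs; PMP non-increasing), `size_distribution`,
#'   `inclusion_map` (models-by-variables signed inclusion, +1/-1/0, ordered
#'   by PMP), the underlying `fit`, the `convergence` diagnostics (sampler
#'   on) and a `run_log` (n, s, dropped rows, g, seed, wall-clock seconds).
#' @export
run_stage <- function(config, ...) {
  if (is.character(config)) config <- run_config(config, ...)
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]

  if (file.exists(config$input)) {
    tab <- read_study_csv(config$input, outcome = config$outcome,
                          covariates = config$covariates,
                          stage_label = config$stage_label %||%
                            basename(config$input))
    source_kind <- "csv"
  } else if (config$input %in% scenario_names()) {
    sc <- scenario_preset(config$input, seed = config$seed)
    tab <- generate_stage(sc)
    tab$stage_label <- config$stage_label %||% config$input
    if (!is.null(config$covariates))
      tab <- study_table(as.data.frame(tab), outcome = "acuity",
                         covariates = config$covariates,
                         stage_label = tab$stage_label)
    source_kind <- "preset"
  } else {
    stop("input '", config$input,
         "' is neither an existing file nor a known preset", call. = FALSE)
  }

  prior <- prior_settings(config$g_rule, config$g)
  if (tab$s > 25L)
    stop("s = ", tab$s, " exceeds the enumeration cap; full-space ",
         "enumeration is unavailable (use mc3_run() directly)", call. = FALSE)
  core <- bma_core(tab, prior = prior, variance = config$variance,
                   thresholds = config$thresholds)
  fit <- structure(c(core, list(call = sys.call())), class = "bma_lm")

  pmp_mcmc <- NULL
  convergence <- NULL
  if (config$sampler) {
    trace <- mc3_run(core$table, prior = prior,
                     settings = mc3_settings(config$n_iter, config$burn_in,
                                             seed = config$seed))
    convergence <- convergence_report(trace, exact = core$pmp)
    fit$trace <- trace
    pmp_mcmc <- trace$pmp_mcmc
  }

  report <- structure(
    list(variable_table = variable_table(fit),
         top_models_table = top_models_table(fit, top_m = config$top_m,
                                             pmp_mcmc = pmp_mcmc),
         size_distribution = data.frame(
           size = as.integer(names(core$model_size_distribution)),
           probability = as.numeric(core$model_size_distribution)),
         inclusion_map = signed_inclusion_map(fit),
         fit = fit, convergence = convergence, config = config,
         run_log = list(input = config$input, source = source_kind,
                        stage_label = tab$stage_label, n = core$n,
                        s = core$s, dropped = core$dropped, g = core$g,
                        g_rule = config$g_rule, sampler = config$sampler,
                        seed = config$seed,
                        elapsed_sec = proc.time()[["elapsed"]] - t0)),
    class = "stage_report")
  report
}

#' @export
print.stage_report <- function(x, ...) {
  rl <- x$run_log
  cat(sprintf("Stage report [%s]: n = %d, s = %d, g = %.6g, seed = %d\n\n",
              rl$stage_label, rl$n, rl$s, rl$g, rl$seed))
  vt <- x$variable_table
  vt[2:5] <- lapply(vt[2:5], signif, 4)
  print(vt, row.names = FALSE)
  cat("\nTop models:\n")
  tm <- x$top_models_table
  tm$pmp_exact <- signif(tm$pmp_exact, 4)
  if (!is.null(tm$pmp_mcmc)) tm$pmp_mcmc <- signif(tm$pmp_mcmc, 4)
  print(tm, row.names = FALSE)
  invisible(x)
}

#' Write a stage report to disk
#'
#' Writes `variable_table.csv`, `top_models.csv`, `size_distribution.csv`,
#' `inclusion_map.csv` (signed inclusion coded +1/-1/0 plus each model's
#' PMP) and a `run_manifest.json`.  The CSV tables are deterministic: a
#' re-run with the same config and seed reproduces them byte for byte (the
#' manifest additionally records wall-clock time).
#'
#' @param report a [run_stage()] report.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "stage_report"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- c(variable_table = file.path(dir, "variable_table.csv"),
             top_models = file.path(dir, "top_models.csv"),
             size_distribution = file.path(dir, "size_distribution.csv"),
             inclusion_map = file.path(dir, "inclusion_map.csv"),
             manifest = file.path(dir, "run_manifest.json"))
  utils::write.csv(report$variable_table, paths["variable_table"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$top_models_table, paths["top_models"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$size_distribution, paths["size_distribution"],
                   row.names = FALSE, quote = FALSE)
  im <- as.data.frame(report$inclusion_map)
  im <- cbind(model_rank = seq_len(nrow(im)), im,
              pmp = as.numeric(attr(report$inclusion_map, "pmp")))
  utils::write.csv(im, paths["inclusion_map"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(report$run_log, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[bmareg] wrote stage report [%s] to %s",
                  report$run_log$stage_label, dir))
  invisible(paths)
}

#' Run the three school-stage presets in one invocation
#'
#' Runs `primary_null`, `junior_paper` and `senior_paper` with independent
#' RNG streams (stage `i` uses `seed + 1000 * i`, so no stage shares state
#' with another).
#'
#' @param seed base integer seed.
#' @param out_dir optional directory; each stage's report is rendered into a
#'   subdirectory.
#' @param sampler logical, passed through to [run_config()].
#' @param ... further [run_config()] arguments shared by the stages.
#' @return Named list of three [run_stage()] reports.
#' @export
run_three_stages <- function(seed = 1L, out_dir = NULL, sampler = FALSE,
                             ...) {
  presets <- c("primary_null", "junior_paper", "senior_paper")
  reports <- lapply(seq_along(presets), function(i) {
    run_stage(run_config(presets[i], sampler = sampler,
                         seed = as.integer(seed + 1000L * i), ...))
  })
  names(reports) <- presets
  if (!is.null(out_dir))
    for (nm in presets)
      render_report(reports[[nm]], file.path(out_dir, nm))
  reports
}
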