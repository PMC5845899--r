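# Delimited-text I/O for trial records and the end-to-end pipeline driver:
# design -> simulate -> aggregate -> fit -> report, with a reproducibility
# manifest.

TRIAL_ENUMS <- list(attention = ATTENTION_LEVELS,
                    triplet_version = TRIPLET_VERSIONS,
                    response = RESPONSE_LEVELS,
                    outcome = OUTCOME_LEVELS,
                    timbre_level = TIMBRE_LEVELS)

#' Read trial records from a CSV file
#'
#' Reads and validates classified (or response-only) trial records. Unknown
#' columns are preserved; column order is irrelevant. Any row with an
#' unknown enum value raises a parse error naming the offending rows; a
#' missing required column raises an error naming it. When the `outcome`
#' column is absent it is recomputed from attention, triplet version and
#' response.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return data frame of validated trial records (possibly zero rows).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "attention", "triplet_version", "response")
  miss <- setdiff(required, names(tr))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tr) == 0L) return(tr)
  problems <- character()
  for (col in names(TRIAL_ENUMS)) {
    if (!col %in% names(tr)) next
    tr[[col]] <- as.character(tr[[col]])  # all-NA columns read as logical
    vals <- tr[[col]]
    bad <- !is.na(vals) & !vals %in% TRIAL_ENUMS[[col]]
    if (any(bad)) {
      problems <- c(problems,
                    paste0("column `", col, "` has invalid value(s) ",
                           paste(unique(vals[bad]), collapse = ", "),
                           " at row(s) ", paste(which(bad), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("parse error in ", path, ":\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  if (!"outcome" %in% names(tr)) {
    tr$outcome <- classify_trial(tr$attention, tr$triplet_version, tr$response)
  }
  tr
}

#' Write trial records to CSV
#'
#' @param trials data frame of trial records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param config a named list of overrides, or the path to a YAML file of
#'   the same structure. Recognized top-level keys: `experiment`
#'   (`"exp2"`/`"exp1"`), `group` (`"LAB"`/`"SCAN"`), `n_compositions`,
#'   `seed`, `truth` (overrides passed to [truth_params()]) and `model`
#'   (overrides passed to [model_config()]).
#' @return validated configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("experiment", "group", "n_compositions", "seed", "truth", "model")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(experiment = "exp2", group = "LAB", n_compositions = 16L,
                   seed = 1L, truth = list(), model = list())
  cfg <- utils::modifyList(defaults, config)
  cfg$experiment <- match.arg(cfg$experiment, c("exp2", "exp1"))
  cfg$group <- match.arg(cfg$group, c("LAB", "SCAN"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates per-subject schedules, simulates the cohort under the
#' configured truth, aggregates measurement cells, fits the hierarchical
#' model, computes the descriptive report (group summaries, split-half
#' reliability, morph effects and their rank correlation with overall
#' performance for timbre designs), and writes all artifacts plus a run
#' manifest to `output_dir`. Every output regenerates identically under the
#' same configuration (timestamps live only in the manifest).
#'
#' @param config a [pipeline_config()] list, raw list, or YAML path.
#' @param output_dir directory for the artifacts (created if needed).
#' @return invisibly, a list with the in-memory objects and artifact paths.
#' @export
run_pipeline <- function(config = list(), output_dir = tempfile("sdt_run_")) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] seed=", cfg$seed)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- stage("config", do.call(truth_params,
                                   c(list(experiment = cfg$experiment,
                                          seed = cfg$seed), cfg$truth)))
  sim <- stage("design+simulate",
               simulate_cohort(truth, group = cfg$group,
                               n_compositions = cfg$n_compositions,
                               seed = cfg$seed))
  cells <- stage("aggregate", aggregate_counts(sim$trials))

  paths <- list(schedule = file.path(output_dir, "schedule.csv"),
                trials = file.path(output_dir, "trials.csv"),
                cells = file.path(output_dir, "cells.csv"),
                posterior = file.path(output_dir, "posterior_summary.json"),
                report = file.path(output_dir, "report.json"),
                manifest = file.path(output_dir, "manifest.json"))
  sched_df <- do.call(rbind, lapply(seq_along(sim$schedules), function(s) {
    cbind(data.frame(subject_id = sprintf("S%02d", s)),
          sim$schedules[[s]]$trials)
  }))
  write.csv(sched_df, paths$schedule, row.names = FALSE, quote = FALSE)
  write_trials(sim$trials, paths$trials)
  write.csv(as.data.frame(cells), paths$cells, row.names = FALSE, quote = FALSE)

  mcfg <- stage("config", do.call(model_config,
                                  c(list(experiment = cfg$experiment,
                                         seed = cfg$seed), cfg$model)))
  fit <- stage("fit", fit_model(cells, mcfg))
  eff <- cell_effects(fit)
  summarize <- function(v) {
    h <- hdi(v)
    list(mean = mean(v), hdi_low = h$low, hdi_high = h$high)
  }
  post <- list(grand_mean = summarize(eff$grand),
               attention_effects = lapply(as.data.frame(eff$attention),
                                          summarize))
  if (cfg$experiment == "exp2") {
    post$timbre_effects <- lapply(as.data.frame(eff$timbre), summarize)
    post$contrast_maximum_minus_minimum <- summarize(
      contrast(fit, "timbre", c("maximum", "minimum"))$draws)
  }
  diag_st <- fit$diagnostics[fit$diagnostics$structural, ]
  post$diagnostics <- list(max_rhat = max(diag_st$rhat, na.rm = TRUE),
                           min_ess = min(diag_st$ess, na.rm = TRUE),
                           warnings = fit$convergence_warnings)
  # Per-parameter-group draw exports (chain, draw, value).
  group_cols <- list(intercept = "^beta0$", attention = "^beta_att\\[",
                     subject = "^beta_subj\\[",
                     sigma = "^sigma_(res|beta)\\[")
  if (cfg$experiment == "exp2") {
    group_cols$timbre <- "^beta_timb\\["
    group_cols$interaction <- "^beta_ati\\["
  }
  for (g in names(group_cols)) {
    sel <- grep(group_cols[[g]], fit$param_names)
    rows <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
      d <- fit$draws[[ch]][, sel, drop = FALSE]
      data.frame(chain = ch, draw = seq_len(nrow(d)),
                 d, check.names = FALSE)
    }))
    paths[[paste0("posterior_", g)]] <-
      file.path(output_dir, paste0("posterior_", g, ".csv"))
    write.csv(rows, paths[[paste0("posterior_", g)]], row.names = FALSE)
  }
  jsonlite::write_json(post, paths$posterior, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  report <- stage("report", {
    scores <- subject_scores(sim$trials)
    rel <- split_half_reliability(sim$trials, seed = cfg$seed)
    rep <- list(n_subjects = truth$n_subjects,
                correct_rate = group_summary(scores$correct_rate),
                split_half = list(r = rel$r, p = rel$p),
                per_subject = scores)
    if (cfg$experiment == "exp2") {
      me <- morph_effect(sim$trials)
      rep$morph_effect <- list(values = me)
      if (nrow(me) >= 4L) {
        sp <- spearman(1 - scores$correct_rate, me$morph_effect)
        rep$morph_effect$spearman_vs_error_rate <- list(rho = sp$rho,
                                                        p = sp$p)
      }
    }
    rep
  })
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(package_version = as.character(packageVersion("streamsdt")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = unclass(cfg),
                   seeds = list(global = cfg$seed, truth = truth$seed,
                                model = mcfg$seed),
                   artifacts = vapply(paths[names(paths) != "manifest"],
                                      basename, ""),
                   warnings = fit$convergence_warnings)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(config = cfg, truth = truth, trials = sim$trials,
                 cells = cells, fit = fit, posterior_summary = post,
                 report = report, paths = paths))
}
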