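# Tiny FNV-1a hash of the deparsed config, used to stamp report files so a
# report can be traced back to the exact configuration that produced it.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' @param generator A [generator_config()] used to simulate the cohort, or
#'   `NULL` when `input_csv` supplies one.
#' @param input_csv Path to an existing cohort CSV (alternative to
#'   `generator`).
#' @param stages Stages to run, in dependency order, from
#'   `c("simulate", "score", "screen", "fit", "slopes", "power")`.
#' @param out_dir Output directory for report files.
#' @param threshold PHQ-9 screening threshold.
#' @param power_scenarios List of [power_scenario()] objects to run in the
#'   `power` stage (default: none).
#' @param seed Global seed, propagated to every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_csv = NULL,
                            stages = c("simulate", "score", "screen",
                                       "fit", "slopes"),
                            out_dir = tempfile("modmod_run_"),
                            threshold = 5, power_scenarios = list(),
                            seed = 1L) {
  known <- c("simulate", "score", "screen", "fit", "slopes", "power")
  if (!all(stages %in% known))
    validation_error(paste("unknown stage(s):",
                           paste(setdiff(stages, known), collapse = ", ")))
  stages <- known[known %in% stages]   # enforce dependency order
  if (is.null(generator) && is.null(input_csv) && "simulate" %in% stages)
    validation_error("simulate stage needs a generator config")
  structure(list(generator = generator, input_csv = input_csv,
                 stages = stages, out_dir = out_dir,
                 threshold = threshold,
                 power_scenarios = power_scenarios,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline or generator configuration from YAML/JSON
#'
#' Reads a structured config file mirroring [generator_config()] (under a
#' `generator:` key) and the [pipeline_config()] fields.
#'
#' @param path YAML or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    if (!is.null(g$latent_correlations))
      g$latent_correlations <- matrix(unlist(g$latent_correlations), 3, 3)
    for (nm in c("scale_means", "scale_sds"))
      if (!is.null(g[[nm]])) g[[nm]] <- unlist(g[[nm]])
    if (!is.null(g$contamination)) g$contamination <- unlist(g$contamination)
    gen <- do.call(generator_config, g)
  }
  args <- raw[setdiff(names(raw), c("generator", "power_scenarios"))]
  args$generator <- gen
  do.call(pipeline_config, args)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Chains simulate -> score -> screen -> fit -> slopes -> power, writing
#' one artifact per stage into `out_dir`: `cohort.csv`, `scores.csv`,
#' `screening.json`, `descriptives.csv` (means/SDs and the correlation
#' matrix), `model1.csv` / `model3.csv` coefficient tables,
#' `slope_tests.csv`, `plot_data.csv` and `power_<scenario>.csv`, plus a
#' `run_info.json` stamped with the seed and a config hash. Every stage
#' output is a pure function of (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages (default `TRUE`).
#' @return Named list of produced artifact paths and in-memory results,
#'   invisibly.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list(); results <- list()

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    say("stage simulate")
    cohort <- generate_cohort(config$generator)
    paths$cohort <- file.path(config$out_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort)
  } else if (!is.null(config$input_csv)) {
    if (!file.exists(config$input_csv))
      dependency_error(paste("input cohort not found:", config$input_csv))
    cohort <- read_cohort(config$input_csv)
  }

  scores <- NULL
  if ("score" %in% config$stages || "screen" %in% config$stages) {
    if (is.null(cohort))
      dependency_error("score/screen stages need a cohort (simulate stage or input_csv)")
  }
  screened <- NULL
  if ("screen" %in% config$stages) {
    say("stage screen")
    report <- screening_report(cohort, config$threshold)
    results$screening <- report
    paths$screening <- file.path(config$out_dir, "screening.json")
    write_json_report(list(
      n_raw = report$n_raw, n_excluded = report$n_excluded,
      rule_counts = as.list(report$rule_counts),
      n_retained = report$n_retained,
      exclusion_pct = report$exclusion_pct,
      n_positive = report$n_positive,
      prevalence_pct = report$prevalence_pct,
      band_counts = as.list(report$band_counts),
      threshold = report$threshold), paths$screening)
    scores <- score_cohort(apply_exclusions(cohort)$retained)
    screened <- screen_positive(scores, config$threshold)
  } else if ("score" %in% config$stages) {
    say("stage score")
    scores <- score_cohort(cohort)
    screened <- scores
  }
  if (!is.null(scores)) {
    paths$scores <- file.path(config$out_dir, "scores.csv")
    utils::write.csv(scores, paths$scores, row.names = FALSE, na = "")
    desc <- pearson_matrix(screened)
    results$descriptives <- desc
    tab <- data.frame(variable = names(desc$mean), mean = desc$mean,
                      sd = desc$sd, round(desc$r, 6))
    paths$descriptives <- file.path(config$out_dir, "descriptives.csv")
    utils::write.csv(tab, paths$descriptives, row.names = FALSE)
  }

  if ("fit" %in% config$stages) {
    if (is.null(screened))
      dependency_error("fit stage needs scores (run score/screen first)")
    say("stage fit")
    for (mdl in c(1, 3)) {
      fit <- fit_model(screened, model = mdl)
      results[[paste0("model", mdl)]] <- fit
      p <- file.path(config$out_dir, sprintf("model%d.csv", mdl))
      tab <- fit$coefficients
      tab$r_squared <- fit$r_squared; tab$f <- fit$f; tab$n <- fit$n
      utils::write.csv(tab, p, row.names = FALSE)
      paths[[paste0("model", mdl)]] <- p
    }
  }

  if ("slopes" %in% config$stages) {
    if (is.null(results$model3))
      dependency_error("slopes stage needs the model-3 fit (run fit first)")
    say("stage slopes")
    sl <- simple_slopes(results$model3)
    sd_tests <- slope_difference_tests(results$model3)
    pd <- interaction_plot_data(results$model3)
    results$slopes <- sl; results$slope_tests <- sd_tests
    paths$slope_tests <- file.path(config$out_dir, "slope_tests.csv")
    utils::write.csv(cbind(as.data.frame(sd_tests)), paths$slope_tests,
                     row.names = FALSE)
    paths$plot_data <- file.path(config$out_dir, "plot_data.csv")
    utils::write.csv(pd, paths$plot_data, row.names = FALSE)
  }

  if ("power" %in% config$stages) {
    say("stage power")
    if (length(config$power_scenarios) == 0)
      dependency_error("power stage needs at least one power_scenario")
    for (sc in config$power_scenarios) {
      curve <- run_power(sc)
      results[[paste0("power_", sc$scenario)]] <- curve
      p <- file.path(config$out_dir,
                     sprintf("power_%s.csv", sc$scenario))
      utils::write.csv(curve, p, row.names = FALSE)
      paths[[paste0("power_", sc$scenario)]] <- p
    }
  }

  paths$run_info <- file.path(config$out_dir, "run_info.json")
  write_json_report(list(seed = config$seed,
                         config_hash = config_hash(unclass(config)),
                         stages = config$stages), paths$run_info)
  invisible(list(paths = paths, results = results))
}
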