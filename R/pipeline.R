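#' Study configuration
#'
#' Validated configuration for [run_study()]: simulation design, batch
#' keys, filters, harmonization methods and significance level. Can be
#' written to / read from YAML with [load_study_config()].
#'
#' @param design A [synth_design()] (the synthetic study to simulate).
#' @param batch_keys Key columns defining batches.
#' @param min_batch_frequency Minimum batch frequency (default 2).
#' @param methods Harmonizers to run: subset of `"combat"`, `"longcombat"`.
#' @param combat_method EB mode for the cross-sectional harmonizer.
#' @param screen_params Acquisition parameters to screen.
#' @param alpha Significance level.
#' @param subject,time Column names for the longitudinal stage.
#' @return A list of class `study_config`.
#' @export
study_config <- function(design = synth_design(),
                         batch_keys = c("kernel", "kvp"),
                         min_batch_frequency = 2L,
                         methods = c("combat", "longcombat"),
                         combat_method = "nonparametric_eb",
                         screen_params = c("scanner", "kvp", "kernel",
                                           "exposure_time_ms",
                                           "tube_current_ma",
                                           "contrast_agent"),
                         alpha = 0.05,
                         subject = "patient_id", time = "timepoint") {
  stopifnot(inherits(design, "synth_design"),
            all(methods %in% c("combat", "longcombat")),
            combat_method %in% c("nonparametric_eb", "parametric_eb", "no_eb"),
            is.numeric(alpha), alpha > 0, alpha < 1,
            min_batch_frequency >= 1)
  structure(list(design = design, batch_keys = batch_keys,
                 min_batch_frequency = as.integer(min_batch_frequency),
                 methods = methods, combat_method = combat_method,
                 screen_params = screen_params, alpha = alpha,
                 subject = subject, time = time),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML file may set any [study_config()] argument; the `design` block
#' maps onto [synth_design()] arguments, with `batches` given either as
#' `"default"` or as a list of per-batch records.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
load_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dargs <- raw$design %||% list()
  if (!is.null(dargs$batches)) {
    dargs$batches <- if (identical(dargs$batches, "default")) {
      default_batches()
    } else {
      do.call(batch_effects, purrr::transpose(dargs$batches) |>
                purrr::map(unlist))
    }
  }
  design <- do.call(synth_design, dargs)
  args <- raw[setdiff(names(raw), "design")]
  do.call(study_config, c(list(design = design), args))
}

#' Run the full synthetic study
#'
#' Orchestrates the complete pipeline on synthetic data: simulate a
#' longitudinal feature table with injected batch effects, screen
#' acquisition parameters, define and filter batches, assess batch
#' dependence, harmonize (cross-sectional ComBat and/or longitudinal
#' ComBat), re-assess, and compare. All tables, models and reports are
#' written under `out_dir` as CSV/JSON, together with a machine-readable
#' run log (seed, package version, stage timings). Fully deterministic
#' given the config.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts (`table`,
#'   `assignment`, `screening`, assessments, harmonized tables, models,
#'   `comparison`, `paths`).
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("study")) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(started = "run", seed = config$design$seed,
              package_version = as.character(utils::packageVersion("radharmon")),
              stages = character(0))
  stage <- function(name) log$stages <<- c(log$stages, name)
  path <- function(f) file.path(out_dir, f)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- list(stage = name, message = conditionMessage(e))
      jsonlite::write_json(err, path("error.json"), auto_unbox = TRUE)
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  stage("simulate")
  sim <- run_stage("simulate", gen_longitudinal_table(config$design))
  write_feature_table(sim, path("table.csv"))

  stage("screen")
  scr <- run_stage("screen", screen_parameters(sim$table,
                                               config$screen_params,
                                               alpha = config$alpha))
  write.csv(scr$report, path("screening.csv"), row.names = FALSE)

  stage("batch")
  asg <- run_stage("batch", assign_batches(sim$table, config$batch_keys))
  flt <- run_stage("batch", filter_min_frequency(sim$table, asg,
                                                 config$min_batch_frequency))
  write.csv(flt$assignment$batches, path("batch_map.csv"), row.names = FALSE)
  write.csv(flt$exclusions, path("batch_exclusions.csv"), row.names = FALSE)

  stage("assess_pre")
  tab_b <- with_batches(flt$table, flt$assignment)
  pre <- run_stage("assess_pre",
                   significance_rate(tab_b, "batch_id", alpha = config$alpha,
                                     stage = "pre"))
  write.csv(tidy(pre), path("assessment_pre.csv"), row.names = FALSE)

  out <- list(table = sim$table, truth = sim$truth, screening = scr,
              assignment = flt$assignment, pre = pre)

  if ("combat" %in% config$methods) {
    stage("combat")
    cb <- run_stage("combat",
                    combat_harmonize(flt$table, flt$assignment,
                                     method = config$combat_method))
    write.csv(cb$table, path("harmonized_combat.csv"), row.names = FALSE)
    write_model_json(cb$model, path("model_combat.json"))
    post_cb <- significance_rate(with_batches(cb$table, flt$assignment),
                                 "batch_id", alpha = config$alpha,
                                 stage = "post_combat")
    write.csv(tidy(post_cb), path("assessment_post_combat.csv"),
              row.names = FALSE)
    cmp <- compare_pre_post(pre, post_cb)
    write.csv(cmp$summary, path("comparison_combat.csv"), row.names = FALSE)
    out$combat <- cb
    out$post_combat <- post_cb
    out$comparison_combat <- cmp
  }

  if ("longcombat" %in% config$methods) {
    stage("longcombat")
    lflt <- run_stage("longcombat",
                      filter_longitudinal(flt$table, flt$assignment,
                                          config$subject, config$time))
    pre_long <- significance_rate(with_batches(lflt$table, lflt$assignment),
                                  "batch_id", alpha = config$alpha,
                                  stage = "pre_longcombat")
    lc <- run_stage("longcombat",
                    longcombat_harmonize(lflt$table, lflt$assignment,
                                         config$subject, config$time))
    write.csv(lc$table, path("harmonized_longcombat.csv"), row.names = FALSE)
    write_model_json(lc$model, path("model_longcombat.json"))
    post_lc <- significance_rate(with_batches(lc$table, lflt$assignment),
                                 "batch_id", alpha = config$alpha,
                                 stage = "post_longcombat")
    write.csv(tidy(post_lc), path("assessment_post_longcombat.csv"),
              row.names = FALSE)
    cmp_lc <- compare_pre_post(pre_long, post_lc)
    write.csv(cmp_lc$summary, path("comparison_longcombat.csv"),
              row.names = FALSE)
    out$longcombat <- lc
    out$pre_longcombat <- pre_long
    out$post_longcombat <- post_lc
    out$comparison_longcombat <- cmp_lc
    out$longitudinal_exclusions <- list(subjects = lflt$removed_subjects,
                                        batches = lflt$removed_batches)
    jsonlite::write_json(out$longitudinal_exclusions,
                         path("longitudinal_exclusions.json"),
                         auto_unbox = TRUE)
  }

  jsonlite::write_json(log, path("run_log.json"), auto_unbox = TRUE)
  out$paths <- list.files(out_dir, full.names = TRUE)
  invisible(out)
}
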