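#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()]. Two presets bundle the
#' study-replica defaults: `"replica"` (37 couples, 12 weeks, 3 chains x
#' 20,000 iterations) and `"fast"` (same design, 3 chains x 2,000
#' iterations with a relaxed convergence bound for quick runs).
#'
#' @param preset `"fast"` or `"replica"`.
#' @param out_dir run directory for all stage outputs.
#' @param seed global seed; every stochastic stage derives from it.
#' @param params optional [true_parameters()] overriding the preset design.
#' @param panel_file,hair_file optional paths to existing long-format CSVs;
#'   when given, the simulate stage is skipped and these are scored instead.
#' @param occur_denominator,pss_reverse_items scoring options (see
#'   [score_panel()]).
#' @param spec optional [state_space_spec()] overriding the preset MCMC
#'   settings.
#' @param adjust_sex adjust the observation means and lag regression for sex.
#' @param pool_method tau^2 estimator for retest pooling.
#' @param verbose print stage progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("fast", "replica"),
                            out_dir = "dyadstress_run", seed = 1L,
                            params = NULL, panel_file = NULL, hair_file = NULL,
                            occur_denominator = "all_items",
                            pss_reverse_items = c(4, 5, 7, 8),
                            spec = NULL, adjust_sex = FALSE,
                            pool_method = "REML", verbose = TRUE) {
  preset <- match.arg(preset)
  if (is.null(params)) params <- true_parameters(seed = seed)
  if (is.null(spec)) {
    spec <- if (preset == "replica") {
      state_space_spec(n_iter = 20000L, rhat_threshold = 1.01,
                       adjust_sex = adjust_sex)
    } else {
      state_space_spec(n_iter = 2000L, rhat_threshold = 1.05,
                       adjust_sex = adjust_sex)
    }
  }
  structure(list(preset = preset, out_dir = out_dir, seed = as.integer(seed),
                 params = params, panel_file = panel_file,
                 hair_file = hair_file,
                 occur_denominator = occur_denominator,
                 pss_reverse_items = pss_reverse_items, spec = spec,
                 adjust_sex = adjust_sex, pool_method = pool_method,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> score -> psychometrics -> state-space
#' fit -> lag scan, persisting every stage's outputs under `out_dir` and a
#' manifest recording the seed, configuration hash, decision switches and
#' convergence diagnostics. Each stage reads only the previous stage's
#' persisted outputs, so any stage can be re-run standalone.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (a list), invisibly; it is also written as
#'   `manifest.json` in the run directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(...)
  stage <- "setup"
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadstress")),
    seed = config$seed, preset = config$preset,
    switches = list(occur_denominator = config$occur_denominator,
                    pss_reverse_items = config$pss_reverse_items,
                    adjust_sex = config$adjust_sex,
                    pool_method = config$pool_method,
                    n_chains = config$spec$n_chains,
                    n_iter = config$spec$n_iter,
                    warmup = config$spec$warmup,
                    rhat_threshold = config$spec$rhat_threshold))
  cfg_file <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(manifest$switches, cfg_file, auto_unbox = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))

  result <- tryCatch({
    data_dir <- file.path(config$out_dir, "data")
    stage <- "simulate"
    if (is.null(config$panel_file)) {
      say("[simulate] generating synthetic study (",
          config$params$n_couples, " couples)")
      study <- simulate_study(config$params, seed = config$seed)
      paths <- write_study(study, data_dir)
      panel_file <- paths[["panel"]]; hair_file <- paths[["hair"]]
      sex <- study$truth$sex
    } else {
      say("[simulate] skipped; using supplied data files")
      panel_file <- config$panel_file; hair_file <- config$hair_file
      sex <- NULL
    }

    stage <- "score"
    say("[score] scoring item panel")
    panel <- read_panel(panel_file)
    scores <- score_panel(panel,
                          occur_denominator = config$occur_denominator,
                          pss_reverse_items = config$pss_reverse_items)
    hcc <- preprocess_hcc(read_hair(hair_file))
    score_dir <- file.path(config$out_dir, "scores")
    dir.create(score_dir, showWarnings = FALSE)
    utils::write.csv(scores, file.path(score_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(hcc, file.path(score_dir, "hcc.csv"), row.names = FALSE)
    manifest$median_replicate_cv_pct <- attr(hcc, "median_cv")

    stage <- "psychometrics"
    say("[psychometrics] reliability, retest pooling, correlation matrix")
    psy_dir <- file.path(config$out_dir, "psychometrics")
    dir.create(psy_dir, showWarnings = FALSE)
    rel <- reliability_table(panel)
    utils::write.csv(rel, file.path(psy_dir, "reliability.csv"), row.names = FALSE)
    pooled <- list()
    for (inf in c("self", "partner")) {
      pooled[[paste0("WHS_", inf)]] <-
        retest_profile(scores, "WHS_occur", inf, method = config$pool_method)
      pooled[[paste0("PSS_", inf)]] <-
        retest_profile(scores, "PSS", inf, method = config$pool_method)
    }
    pooled <- do.call(rbind, pooled)
    utils::write.csv(pooled, file.path(psy_dir, "retest_pooled.csv"),
                     row.names = FALSE)
    cm <- averaged_correlation_matrix(scores, hcc)
    utils::write.csv(cm$r, file.path(psy_dir, "correlation_matrix.csv"))

    stage <- "fit"
    say("[fit] dyadic state-space model (", config$spec$n_chains, " chains x ",
        config$spec$n_iter, " iterations)")
    std <- standardize_measures(scores, config$spec$instruments)
    fit <- fit_state_space(std, config$spec, sex = sex,
                           seed = config$seed + 1L)
    fit_dir <- file.path(config$out_dir, "fit")
    dir.create(fit_dir, showWarnings = FALSE)
    utils::write.csv(standardized_loadings(fit),
                     file.path(fit_dir, "loadings.csv"), row.names = FALSE)
    utils::write.csv(informant_coupling(fit),
                     file.path(fit_dir, "coupling.csv"), row.names = FALSE)
    utils::write.csv(drift_summary(fit),
                     file.path(fit_dir, "drift.csv"), row.names = FALSE)
    rhat_df <- data.frame(parameter = names(fit$rhat), rhat = unname(fit$rhat))
    utils::write.csv(rhat_df, file.path(fit_dir, "rhat.csv"), row.names = FALSE)
    manifest$max_rhat <- if (all(is.na(fit$rhat))) NA else
      max(fit$rhat, na.rm = TRUE)
    manifest$converged <- fit$converged
    if (is.na(manifest$converged)) {
      warning("single chain: convergence diagnostics unavailable")
    }

    stage <- "lagscan"
    say("[lagscan] lag-association profile")
    prof <- lag_profile(fit, log_hcc = stats::setNames(hcc$log_hcc,
                                                       hcc$participant_id),
                        sex = sex, adjust_sex = config$adjust_sex)
    lag_dir <- file.path(config$out_dir, "lagscan")
    dir.create(lag_dir, showWarnings = FALSE)
    utils::write.csv(as.data.frame(prof), file.path(lag_dir, "profile.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(prof, "peak"), file.path(lag_dir, "peak.csv"),
                     row.names = FALSE)
    manifest$peak <- attr(prof, "peak")
    manifest
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  jsonlite::write_json(result, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("[done] outputs in ", config$out_dir)
  invisible(result)
}
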