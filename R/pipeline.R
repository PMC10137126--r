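#' Pipeline configuration
#'
#' @param design A [design_spec()], a preset name (`"visual"`,
#'   `"auditory"`, `"null"`), or a path to a design YAML file.
#' @param modality Which modality's component/band windows to analyse
#'   (`"visual"` or `"auditory"`); defaults to the design preset when one is
#'   used, else `"visual"`.
#' @param seed Integer master seed (required when the design is generative).
#' @param preprocess A [preprocess_config()].
#' @param alpha Gate level for the statistical scheme.
#' @param gg Greenhouse-Geisser correction flag, passed through to
#'   [rm_anova_2way()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = "visual", modality = NULL, seed = 1,
                            preprocess = preprocess_config(), alpha = 0.05,
                            gg = FALSE) {
  if (is.character(design)) {
    if (is.null(modality) && design %in% c("visual", "auditory"))
      modality <- design
    design <- switch(design,
                     visual = default_design("visual"),
                     auditory = default_design("auditory"),
                     null = null_design(),
                     {
                       if (!file.exists(design))
                         stop("design preset or file not found: ", design, call. = FALSE)
                       read_design_yaml(design)
                     })
  }
  validate_design_spec(design)
  structure(list(design = design, modality = modality %||% "visual",
                 seed = seed, preprocess = preprocess, alpha = alpha, gg = gg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `design` (preset name, path, or inline design
#' mapping), `modality`, `seed`, `alpha`, and a `preprocess` mapping with
#' the [preprocess_config()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, x$preprocess %||% list())
  design <- x$design %||% "visual"
  if (is.list(design)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(design, tmp)
    design <- read_design_yaml(tmp)
    unlink(tmp)
  }
  pipeline_config(design = design, modality = x$modality,
                  seed = x$seed %||% 1, preprocess = pp,
                  alpha = x$alpha %||% 0.05, gg = isTRUE(x$gg))
}

#' Simulate the study described by a pipeline configuration
#'
#' Generates every subject's epochs and writes one epoch container per
#' subject plus the pooled behaviour CSV under `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the vector of container paths.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  epochs <- generate_epochs(config$design, config$seed)
  paths <- character(0)
  binfo <- list()
  for (s in names(epochs)) {
    p <- file.path(out_dir, paste0("epochs_", s))
    write_epochs(epochs[[s]], p)
    paths <- c(paths, p)
    binfo[[s]] <- epochs[[s]]$trial_info
  }
  write_behavior_csv(do.call(rbind, binfo), file.path(out_dir, "behavior.csv"))
  invisible(paths)
}

read_subject_epochs <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^epochs_", full.names = TRUE))
  if (!length(paths)) stop("no epoch containers under ", dir, call. = FALSE)
  eps <- lapply(paths, read_epochs)
  names(eps) <- sub("^epochs_", "", basename(paths))
  eps
}

#' Compute the measure tables for a set of subject epochs
#'
#' Preprocesses each subject (low-pass, downsample if needed, trial
#' qualification), then builds the ERP window-amplitude table and the
#' ITC/ERSP band-window tables for the configured modality.
#'
#' @param config A `pipeline_config`.
#' @param epochs Named list of [epoch_set()] per subject.
#' @return Combined long-format measure table.
#' @export
pipeline_measure <- function(config, epochs) {
  pp <- config$preprocess
  prep <- lapply(epochs, function(e) {
    e <- remove_ocular_artifacts(e)
    if (e$sampling_rate > pp$target_rate_hz) e <- downsample(e, pp$target_rate_hz)
    e <- fir_lowpass(e, pp$lowpass_hz)
    select_qualified_trials(e, pp)
  })
  windows <- Filter(function(cw) all(cw$channels %in% prep[[1]]$channels),
                    default_component_windows(config$modality))
  chans <- prep[[1]]$channels
  erp_tab <- build_erp_measure_table(prep, windows,
                                     config$design$first_stim_offset_s)
  tf_tab <- build_tf_measure_table(
    prep,
    itc_windows = default_band_windows(config$modality, "itc"),
    ersp_windows = default_band_windows(config$modality, "ersp"),
    channels = chans)
  rbind(erp_tab, tf_tab)
}

#' Run the full pipeline
#'
#' Simulate (or load) the epochs, preprocess, compute the ERP and
#' time-frequency measure tables, run the behavioural statistics and the
#' gated MA x TP analysis, and write everything under `out_dir`:
#' `measures.csv`, `behavior.csv`, `reports.json`, `reports.txt` and
#' `provenance.json` (config hash, seed, package version). Identical
#' config + seed give byte-identical CSV output.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param out_dir Output directory.
#' @param epochs_dir Optional directory of previously written epoch
#'   containers; when given, epochs are read instead of simulated.
#' @return Invisibly, a list with `measures`, `behavior_report`,
#'   `gated_report` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, epochs_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(epochs_dir)) {
    epochs <- generate_epochs(config$design, config$seed)
    behavior <- do.call(rbind, lapply(epochs, `[[`, "trial_info"))
  } else {
    epochs <- read_subject_epochs(epochs_dir)
    bpath <- file.path(epochs_dir, "behavior.csv")
    behavior <- if (file.exists(bpath)) read_behavior_csv(bpath)
      else do.call(rbind, lapply(epochs, `[[`, "trial_info"))
  }
  rownames(behavior) <- NULL
  measures <- pipeline_measure(config, epochs)
  gated <- run_gated_analysis(measures, config$alpha)
  brep <- behavior_stats(behavior, config$preprocess$anticipation_floor_s,
                         config$alpha)
  utils::write.csv(measures, file.path(out_dir, "measures.csv"), row.names = FALSE)
  write_behavior_csv(behavior, file.path(out_dir, "behavior.csv"))
  jsonlite::write_json(gated_report_to_list(gated),
                       file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(utils::capture.output(print(gated)),
           "", "-- behavioural summary (per-cell means) --",
           utils::capture.output(print(stats::aggregate(
             cbind(rt_mean_s, accuracy) ~ ma + tp, brep$summary, mean))))
  writeLines(txt, file.path(out_dir, "reports.txt"))
  prov <- list(seed = config$seed, alpha = config$alpha,
               modality = config$modality,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("gatewave")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(measures = measures, behavior_report = brep,
                 gated_report = gated, out_dir = out_dir))
}

# Cheap deterministic hash of the serialized config (djb2 over the YAML text).
config_hash <- function(config) {
  txt <- yaml::as.yaml(list(design = design_to_list(config$design),
                            seed = config$seed, alpha = config$alpha,
                            modality = config$modality,
                            preprocess = unclass(config$preprocess)))
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

gated_report_to_list <- function(gated) {
  lapply(unclass(gated), function(rep) {
    list(measure = rep$measure, branch = rep$branch, alpha = rep$alpha,
         anova = as.data.frame(rep$anova),
         simple = lapply(rep$simple, as.data.frame),
         pairwise = rep$pairwise)
  })
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write epoch containers), `measure` (read
#' containers, write `measures.csv`), `stats` (read `measures.csv`, write
#' reports), `run-all` (everything in one shot). Flags: `--config <yaml>`,
#' `--seed <int>`, `--out <dir>`, `--epochs <dir>`, `--measures <csv>`.
#' Returns 0 on success, 2 on usage/validation errors; a thin Rscript
#' wrapper is installed under `inst/cli/gatewave.R`.
#'
#' @param argv Character vector of arguments (as from `commandArgs(TRUE)`).
#' @return Integer exit code.
#' @export
gatewave_cli <- function(argv = character()) {
  usage <- function() {
    message("usage: gatewave.R <simulate|measure|stats|run-all> [--config <yaml>]")
    message("       [--seed <int>] [--out <dir>] [--epochs <dir>] [--measures <csv>]")
    2L
  }
  if (!length(argv)) return(usage())
  cmd <- argv[1]; argv <- argv[-1]
  if (!cmd %in% c("simulate", "measure", "stats", "run-all")) return(usage())
  opts <- list(out = "gatewave_out", seed = NULL, config = NULL,
               epochs = NULL, measures = NULL)
  i <- 1
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!argv[i] %in% c("--config", "--seed", "--out", "--epochs", "--measures") ||
        i == length(argv))
      return(usage())
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  res <- tryCatch({
    config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
      else pipeline_config()
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    switch(cmd,
      "simulate" = pipeline_simulate(config, opts$out),
      "measure" = {
        eps <- read_subject_epochs(opts$epochs %||% opts$out)
        measures <- pipeline_measure(config, eps)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(measures, file.path(opts$out, "measures.csv"),
                         row.names = FALSE)
      },
      "stats" = {
        mpath <- opts$measures %||% file.path(opts$out, "measures.csv")
        measures <- utils::read.csv(mpath, stringsAsFactors = FALSE)
        gated <- run_gated_analysis(measures, config$alpha)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(gated_report_to_list(gated),
                             file.path(opts$out, "reports.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        writeLines(utils::capture.output(print(gated)),
                   file.path(opts$out, "reports.txt"))
      },
      "run-all" = run_pipeline(config, opts$out))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  res
}
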