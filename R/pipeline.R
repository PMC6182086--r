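#' Load a run configuration from YAML or JSON
#'
#' A run configuration bundles everything one reproducible run needs: the
#' model family, architecture overrides, task settings, trainer settings,
#' the analysis policy, a root seed and an output directory. Defaults are
#' filled for anything omitted; unknown keys are rejected by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param x Named list with at least `family`; optional `architecture`,
#'   `task`, `trainer`, `analysis_policy`, `root_seed`, `output_dir`.
#' @return A `run_config`.
#' @export
as_run_config <- function(x) {
  known <- c("family", "architecture", "task", "trainer", "analysis_policy",
             "root_seed", "output_dir")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop_invalid("unknown config key(s): %s", paste(extra, collapse = ", "))
  }
  if (is.null(x$family)) stop_invalid("config must name a model family")
  family <- match.arg(x$family, c("hf", "pycog", "pyrl", "rhebb"))
  arch_over <- x$architecture %||% list()
  task_over <- x$task %||% list()
  trainer_over <- x$trainer %||% list()
  ctor_args <- names(formals(task_config))
  bad_task <- setdiff(names(task_over), ctor_args)
  if (length(bad_task)) {
    stop_invalid("unknown task key(s): %s", paste(bad_task, collapse = ", "))
  }
  base <- unclass(default_task_config(family))
  task_cfg <- do.call(task_config,
                      utils::modifyList(base[intersect(names(base), ctor_args)],
                                        task_over))
  trainer_ctor <- switch(family, hf = hf_spec, pycog = pycog_spec,
                         pyrl = pyrl_spec, rhebb = rhebb_config)
  bad_trainer <- setdiff(names(trainer_over), names(formals(trainer_ctor)))
  if (length(bad_trainer)) {
    stop_invalid("unknown trainer key(s): %s", paste(bad_trainer, collapse = ", "))
  }
  trainer_spec <- do.call(trainer_ctor, trainer_over)
  bad_arch <- setdiff(names(arch_over), c("N_rec", "N_rec_baseline"))
  if (length(bad_arch)) {
    stop_invalid("unknown architecture key(s): %s", paste(bad_arch, collapse = ", "))
  }
  structure(list(
    family = family,
    N_rec = arch_over$N_rec,
    N_rec_baseline = arch_over$N_rec_baseline,
    task = task_cfg,
    trainer = trainer_spec,
    analysis_policy = x$analysis_policy %||% default_policy(
      if (family == "pyrl") "pyrl_policy" else family),
    root_seed = as.integer(x$root_seed %||% 1L),
    output_dir = x$output_dir %||% "plasticrnn-run"
  ), class = "run_config")
}

#' Save a run configuration to YAML
#'
#' Round-trips through [load_config()] without loss.
#' @param config A `run_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  tc <- config$task
  out <- list(
    family = config$family,
    architecture = Filter(Negate(is.null),
                          list(N_rec = config$N_rec,
                               N_rec_baseline = config$N_rec_baseline)),
    task = list(
      coherence_levels_motion = tc$coherence_levels_motion,
      coherence_levels_color = tc$coherence_levels_color,
      noise_std_motion = tc$noise_std_motion,
      noise_std_color = tc$noise_std_color,
      dt = tc$dt, trial_duration = tc$trial_duration,
      encoding_mode = tc$encoding_mode, baseline_input = tc$baseline_input,
      decision_window = tc$decision_window,
      zero_coherence = tc$zero_coherence
    ),
    analysis_policy = config$analysis_policy,
    root_seed = config$root_seed,
    output_dir = config$output_dir
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the train / analyze / inactivate pipeline
#'
#' Executes the requested stages for one configuration, writing a training
#' record (RDS), distribution-statistics CSVs, a tidy inactivation-sweep CSV
#' with its ANOVA table, and a manifest (JSON) recording the derived
#' per-stage seeds and per-file checksums.
#'
#' @param config A `run_config` (or path to one).
#' @param stages Subset of `c("train", "analyze", "inactivate")`.
#' @param record Optional pre-existing `training_record` (or RDS path), to
#'   run analysis stages without training.
#' @param n_systems Replicate systems for the inactivation stage.
#' @return Invisibly, the output directory; artifacts on disk.
#' @export
run_pipeline <- function(config, stages = c("train", "analyze", "inactivate"),
                         record = NULL, n_systems = 1L) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(family = config$family, root_seed = config$root_seed,
                   stages = stages, files = list())
  rec_path <- file.path(config$output_dir, "record.rds")

  records <- NULL
  arch <- NULL
  if ("train" %in% stages) {
    records <- lapply(seq_len(n_systems), function(i) {
      res <- train_family(config$family, N_rec = config$N_rec,
                          task_cfg = config$task,
                          trainer_spec = config$trainer,
                          N_rec_baseline = config$N_rec_baseline,
                          seed = derive_seed(config$root_seed, i))
      arch <<- res$arch
      if (config$family == "pyrl") res$record$policy else res$record
    })
    saveRDS(if (n_systems == 1L) records[[1]] else records, rec_path)
    manifest$files$record <- unname(tools::md5sum(rec_path))
    manifest$train_seeds <- vapply(seq_len(n_systems),
                                   function(i) derive_seed(config$root_seed, i),
                                   integer(1))
  } else if (!is.null(record)) {
    if (is.character(record)) record <- readRDS(record)
    records <- if (inherits(record, "training_record")) list(record) else record
    arch <- records[[1]]$config$arch
  }

  if (any(c("analyze", "inactivate") %in% stages)) {
    if (is.null(records)) {
      stop_invalid("analysis stages need a training record; none trained or supplied")
    }
  }
  if ("analyze" %in% stages) {
    smry <- summarize_model(records[[1]], arch, config$analysis_policy)
    saveRDS(smry, file.path(config$output_dir, "summary.rds"))
    for (lv in c("post_mean_diff", "post_mean_last", "element_diff")) {
      f <- file.path(config$output_dir, paste0("stats_", lv, ".csv"))
      write_stats_csv(stats::setNames(list(smry), config$family), f, lv)
      manifest$files[[paste0("stats_", lv)]] <- unname(tools::md5sum(f))
    }
  }
  if ("inactivate" %in% stages) {
    sweep <- run_inactivation_sweep(records, arch, config$task,
                                    policy = config$analysis_policy,
                                    seed = derive_seed(config$root_seed, 7001))
    f <- file.path(config$output_dir, "inactivation.csv")
    utils::write.csv(sweep$data, f, row.names = FALSE)
    manifest$files$inactivation <- unname(tools::md5sum(f))
    if (length(records) >= 2) {
      at <- two_way_anova(sweep)
      fa <- file.path(config$output_dir, "anova.csv")
      utils::write.csv(at, fa, row.names = FALSE)
      manifest$files$anova <- unname(tools::md5sum(fa))
    }
  }
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$output_dir)
}
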