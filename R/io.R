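# Configuration, subject-table I/O and pipeline orchestration. One
# top-level seed flows through documented per-stage derivations; every
# run echoes its resolved configuration next to the outputs.

#' Default pipeline configuration
#'
#' @param seed top-level seed.
#' @param n_train,n_male,n_female synthetic cohort sizes.
#' @param fwhm_mm,target_mm,mask_threshold preprocessing parameters.
#' @param rvr_tol,rvr_max_iter,rvr_prune_alpha RVR controls.
#' @param alpha significance level for all branches.
#' @param holm_m quartile-family size for Holm correction.
#' @param effects generator coupling: `"default"` or `"null"`.
#' @return Named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1L, n_train = 561L, n_male = 118L,
                            n_female = 110L, fwhm_mm = 8, target_mm = 8,
                            mask_threshold = 0.1, rvr_tol = 1e-6,
                            rvr_max_iter = 1000L, rvr_prune_alpha = 1e12,
                            alpha = 0.05, holm_m = 4L,
                            effects = "default") {
  structure(list(seed = as.integer(seed), n_train = as.integer(n_train),
                 n_male = as.integer(n_male), n_female = as.integer(n_female),
                 fwhm_mm = fwhm_mm, target_mm = target_mm,
                 mask_threshold = mask_threshold, rvr_tol = rvr_tol,
                 rvr_max_iter = as.integer(rvr_max_iter),
                 rvr_prune_alpha = rvr_prune_alpha, alpha = alpha,
                 holm_m = as.integer(holm_m), effects = effects),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected with their location; known keys override the
#' defaults of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  defaults <- pipeline_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(unclass(defaults), vals)
  do.call(pipeline_config, cfg)
}

#' Read a subject table from CSV
#'
#' Mandatory columns: `subject_id` (or `id`), `age`, `gender`. Marker and
#' cognitive columns are optional; blank marker cells become NA; gender is
#' parsed case-insensitively.
#'
#' @param path CSV file path.
#' @return data.frame of typed subject records.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if ("id" %in% names(df) && !"subject_id" %in% names(df))
    names(df)[names(df) == "id"] <- "subject_id"
  need <- c("subject_id", "age", "gender")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("subject table ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(df)
  df$subject_id <- as.character(df$subject_id)
  df$gender <- tolower(as.character(df$gender))
  num_cols <- setdiff(names(df), c("subject_id", "gender", "site"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad) > 0)
        stop("non-numeric value in column '", cl, "' at data row ",
             bad[1], " of ", path, call. = FALSE)
      df[[cl]] <- conv
    }
  }
  if (any(!is.na(df$age) & df$age <= 0))
    stop("ages must be positive in ", path, call. = FALSE)
  df
}

#' @rdname read_subject_table
#' @param df subject data.frame.
#' @export
write_subject_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

stage_msg <- function(fmt, ...) {
  message(sprintf("[brainage %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full pipeline: simulate, train, estimate, analyze
#'
#' Generates the synthetic training and test cohorts, trains the
#' brain-age model, estimates BrainAGE for both test cohorts and runs the
#' complete health-marker analysis, writing all artifacts (subject tables,
#' scores, model archive, report tables, configuration echo) under `out`.
#' Deterministic given the same configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param out output directory.
#' @param write_volumes also write every volume as NIfTI (off by default;
#'   slow and large).
#' @return The analysis report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out,
                         write_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out, "config_echo.yaml"))

  stage_msg("simulate: training n=%d, test %d male / %d female (seed %d)",
            config$n_train, config$n_male, config$n_female, config$seed)
  scfg <- synth_config(
    seed = config$seed, n_train = config$n_train, n_male = config$n_male,
    n_female = config$n_female,
    effects = if (identical(config$effects, "null")) NULL else config$effects)
  train <- generate_training_cohort(scfg)
  test <- list(male = generate_test_cohort(scfg, "male"),
               female = generate_test_cohort(scfg, "female"))
  utils::write.csv(train$ages, file.path(out, "train_ages.csv"),
                   row.names = FALSE)
  subjects <- rbind(test$male$subjects, test$female$subjects)
  write_subject_table(subjects, file.path(out, "subjects.csv"))
  if (write_volumes) {
    vdir <- file.path(out, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (v in c(train$volumes, test$male$volumes, test$female$volumes))
      write_nifti_volume(v, file.path(vdir, paste0(v$subject_id, ".nii.gz")))
  }

  stage_msg("train: PCA + RVR on %d subjects", config$n_train)
  mcfg <- brainage_config(fwhm_mm = config$fwhm_mm,
                          target_mm = config$target_mm,
                          mask_threshold = config$mask_threshold,
                          rvr_tol = config$rvr_tol,
                          rvr_max_iter = config$rvr_max_iter,
                          rvr_prune_alpha = config$rvr_prune_alpha)
  model <- train_brainage(train$volumes, train$ages$age, mcfg)
  write_brainage_model(model, file.path(out, "model.rds"))

  stage_msg("estimate: %d test subjects", nrow(subjects))
  scores <- do.call(rbind, lapply(names(test), function(g) {
    est <- estimate_brainage(model, test[[g]]$volumes)
    brainage_scores(est, test[[g]]$subjects$age,
                    test[[g]]$subjects$subject_id)
  }))
  utils::write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE)

  stage_msg("analyze: %d scored subjects", nrow(scores))
  cohort <- merge(subjects, scores[, c("subject_id", "brainage")],
                  by = "subject_id", sort = FALSE)
  report <- run_full_analysis(cohort, top_k = config$holm_m)
  write_report(report, file.path(out, "report"))
  stage_msg("done: %s", out)
  invisible(report)
}

cli_usage <- function() {
  paste(
    "usage: brainage <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate  --config cfg.yaml --seed N --out dir/ [--volumes]",
    "  train     --train-table ages.csv --volumes dir/ --out model.rds",
    "  estimate  --model model.rds --table subjects.csv --volumes dir/ --out scores.csv",
    "  analyze   --scores scores.csv --subjects subjects.csv --out report/",
    "  run       --config cfg.yaml --seed N --out dir/",
    sep = "\n")
}

cli_args <- function(args) {
  opts <- list(flags = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1L])) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts$flags <- c(opts$flags, key); i <- i + 1L }
    } else stop("unexpected argument: ", a, call. = FALSE)
  }
  opts
}

cli_require <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss) > 0)
    stop("missing required option(s): ",
         paste0("--", miss, collapse = ", "), call. = FALSE)
}

load_volume_dir <- function(dir, ids) {
  lapply(ids, function(id) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(dir, paste0(id, ext))
      if (file.exists(p)) return(read_nifti_volume(p, subject_id = id))
    }
    stop("no volume found for subject ", id, " under ", dir, call. = FALSE)
  })
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `train`, `estimate`, `analyze`, `run`. See
#' `inst`alled script `exec/brainage`. Exit codes: 0 success, 1 usage
#' error, 2 stage failure.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return Exit status integer, invisibly.
#' @export
brainage_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(args) == 0) 1L else 0L))
  }
  cmd <- args[1]
  status <- tryCatch({
    opts <- cli_args(args[-1])
    cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
           else pipeline_config()
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    switch(cmd,
      simulate = {
        cli_require(opts, "out")
        scfg <- synth_config(
          seed = cfg$seed, n_train = cfg$n_train, n_male = cfg$n_male,
          n_female = cfg$n_female,
          effects = if (identical(cfg$effects, "null")) NULL else "default")
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        train <- generate_training_cohort(scfg)
        tm <- generate_test_cohort(scfg, "male")
        tf <- generate_test_cohort(scfg, "female")
        utils::write.csv(train$ages, file.path(opts$out, "train_ages.csv"),
                         row.names = FALSE)
        write_subject_table(rbind(tm$subjects, tf$subjects),
                            file.path(opts$out, "subjects.csv"))
        vdir <- file.path(opts$out, "volumes")
        dir.create(vdir, showWarnings = FALSE)
        for (v in c(train$volumes, tm$volumes, tf$volumes))
          write_nifti_volume(v, file.path(vdir,
                                          paste0(v$subject_id, ".nii.gz")))
        yaml::write_yaml(unclass(cfg), file.path(opts$out,
                                                 "config_echo.yaml"))
      },
      train = {
        cli_require(opts, c("train-table", "volumes", "out"))
        tab <- utils::read.csv(opts$`train-table`, stringsAsFactors = FALSE)
        if ("id" %in% names(tab)) names(tab)[names(tab) == "id"] <- "subject_id"
        vols <- load_volume_dir(opts$volumes, tab$subject_id)
        model <- train_brainage(vols, tab$age,
                                brainage_config(
                                  fwhm_mm = cfg$fwhm_mm,
                                  target_mm = cfg$target_mm,
                                  mask_threshold = cfg$mask_threshold,
                                  rvr_tol = cfg$rvr_tol,
                                  rvr_max_iter = cfg$rvr_max_iter,
                                  rvr_prune_alpha = cfg$rvr_prune_alpha))
        write_brainage_model(model, opts$out)
      },
      estimate = {
        cli_require(opts, c("model", "table", "volumes", "out"))
        model <- read_brainage_model(opts$model)
        tab <- read_subject_table(opts$table)
        vols <- load_volume_dir(opts$volumes, tab$subject_id)
        est <- estimate_brainage(model, vols)
        utils::write.csv(brainage_scores(est, tab$age, tab$subject_id),
                         opts$out, row.names = FALSE)
      },
      analyze = {
        cli_require(opts, c("scores", "subjects", "out"))
        scores <- utils::read.csv(opts$scores, stringsAsFactors = FALSE)
        subjects <- read_subject_table(opts$subjects)
        cohort <- merge(subjects,
                        scores[, c("subject_id", "brainage")],
                        by = "subject_id", sort = FALSE)
        write_report(run_full_analysis(cohort, top_k = cfg$holm_m),
                     opts$out)
      },
      run = {
        cli_require(opts, "out")
        run_pipeline(cfg, opts$out,
                     write_volumes = "volumes" %in% opts$flags)
      },
      stop("unknown subcommand: ", cmd, "\n", cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
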