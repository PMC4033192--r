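# End-to-end brain-age model: preprocessing parameters + mask + PCA basis +
# RVR state, trained from registered GM volumes and chronological ages.

#' Default model configuration
#'
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @param target_mm working grid resolution in mm (default 8).
#' @param mask_threshold mean-GM mask threshold (default 0.1).
#' @param n_components PCA retention, `"all"` or a count.
#' @param rvr_tol,rvr_max_iter,rvr_prune_alpha RVR iteration controls.
#' @return Named list of configuration values.
#' @export
brainage_config <- function(fwhm_mm = 8, target_mm = 8, mask_threshold = 0.1,
                            n_components = "all", rvr_tol = 1e-6,
                            rvr_max_iter = 1000L, rvr_prune_alpha = 1e12) {
  list(fwhm_mm = fwhm_mm, target_mm = target_mm,
       mask_threshold = mask_threshold, n_components = n_components,
       rvr_tol = rvr_tol, rvr_max_iter = as.integer(rvr_max_iter),
       rvr_prune_alpha = rvr_prune_alpha)
}

preprocess_volumes <- function(vols, config, mask = NULL) {
  proc <- lapply(vols, function(v)
    resample_to_grid(smooth_volume(v, config$fwhm_mm), config$target_mm))
  if (is.null(mask)) mask <- build_mask(proc, config$mask_threshold)
  list(features = vectorize(proc, mask), mask = mask)
}

#' Train a brain-age model from GM volumes and chronological ages
#'
#' Pipeline: smooth at native resolution, block-resample to the working
#' grid, build the mean-GM mask, vectorize, PCA (full retention by
#' default), then relevance vector regression of age on the linear kernel
#' of PCA scores.
#'
#' @param vols list of [gm_volume]s (>= 10).
#' @param ages chronological ages (years), one per volume.
#' @param config a [brainage_config()] list.
#' @return An object of class `brainage_model`.
#' @export
train_brainage <- function(vols, ages, config = brainage_config()) {
  if (length(vols) < 10L)
    stop("training needs at least 10 subjects", call. = FALSE)
  if (length(ages) != length(vols))
    stop("one age per training volume is required", call. = FALSE)
  pp <- preprocess_volumes(vols, config)
  pca <- fit_pca(pp$features, config$n_components)
  scores <- pca_transform(pca, pp$features)
  rvr <- fit_rvr(scores, ages, tol = config$rvr_tol,
                 max_iter = config$rvr_max_iter,
                 prune_alpha = config$rvr_prune_alpha)
  structure(
    list(pca = pca, rvr = rvr, mask = pp$mask, config = config,
         native_voxel_mm = vols[[1]]$voxel_size_mm,
         training = list(n = length(vols), age_range = range(ages),
                         age_mean = mean(ages), age_sd = stats::sd(ages))),
    class = "brainage_model")
}

#' Estimate brain ages for new GM volumes
#'
#' @param model a `brainage_model`.
#' @param vols list of [gm_volume]s on the training grid.
#' @return Numeric vector of estimated brain ages (years).
#' @export
estimate_brainage <- function(model, vols) {
  stopifnot(inherits(model, "brainage_model"))
  pp <- preprocess_volumes(vols, model$config, mask = model$mask)
  predict_age(model$rvr, pca_transform(model$pca, pp$features))
}

#' BrainAGE scores: estimated minus chronological age
#'
#' Positive scores indicate accelerated structural brain aging: a
#' 70-year-old with a score of +5 years expresses the typical atrophy
#' pattern of a 75-year-old.
#'
#' @param estimated estimated brain ages (years).
#' @param chronological chronological ages (years).
#' @param subject_id optional identifiers.
#' @return data.frame with columns `subject_id`, `chronological_age`,
#'   `estimated_age`, `brainage`.
#' @export
brainage_scores <- function(estimated, chronological, subject_id = NULL) {
  if (length(estimated) != length(chronological))
    stop("estimated and chronological ages must have equal length",
         call. = FALSE)
  if (is.null(subject_id)) subject_id <- as.character(seq_along(estimated))
  data.frame(subject_id = as.character(subject_id),
             chronological_age = as.numeric(chronological),
             estimated_age = as.numeric(estimated),
             brainage = as.numeric(estimated) - as.numeric(chronological),
             stringsAsFactors = FALSE)
}

#' Evaluate a brain-age model on a labelled test set
#'
#' @param model a `brainage_model`.
#' @param vols list of test [gm_volume]s (>= 3).
#' @param ages chronological test ages (years).
#' @return list with `mae` (years) and `r` (Pearson correlation between
#'   chronological and estimated age; NA with a warning when ages are
#'   constant).
#' @export
evaluate_model <- function(model, vols, ages) {
  if (length(vols) < 3L) stop("need at least 3 test subjects", call. = FALSE)
  est <- estimate_brainage(model, vols)
  mae <- mean(abs(est - ages))
  r <- if (stats::sd(ages) == 0 || stats::sd(est) == 0) {
    warning("constant ages: Pearson r undefined", call. = FALSE)
    NA_real_
  } else stats::cor(ages, est)
  list(mae = mae, r = r, n = length(ages))
}

#' Persist / restore a brain-age model
#'
#' The model is stored as a single versioned RDS archive holding the mask,
#' the numeric PCA/RVR state and a configuration echo. A reloaded model
#' predicts identically.
#'
#' @param model a `brainage_model`.
#' @param path archive path.
#' @return `path` (write) or the restored `brainage_model` (read).
#' @export
write_brainage_model <- function(model, path) {
  stopifnot(inherits(model, "brainage_model"))
  saveRDS(list(format = "brainage_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_brainage_model
#' @export
read_brainage_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "brainage_model"))
    stop("not a brainage model archive: ", path, call. = FALSE)
  obj$model
}
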