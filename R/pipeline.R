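# End-to-end orchestration of the analysis chain on synthetic scenes:
# simulate -> correct -> crop -> segment -> denoise -> average -> PCA ->
# EW selection -> image-level split -> SVM grid search -> evaluation ->
# classification maps.

#' Full pipeline configuration
#'
#' One flat configuration covering every stage; every field has a default.
#' Unknown fields are rejected.
#'
#' @param scene a [scene_config()] shared by all simulated scenes (each
#'   scene gets a seed derived from its own `rng_seed`).
#' @param n_images number of scenes to simulate (split at image level).
#' @param crop_low_nm,crop_high_nm working spectral range.
#' @param denoise a [denoise_config()].
#' @param n_components retained principal components.
#' @param prominence_fraction,dedup_window_nm EW selection parameters.
#' @param pixel_cap maximum pixels pooled for PCA fitting (seeded uniform
#'   subsample above this).
#' @param cost_exponents,gamma_exponents,cv_folds SVM grid-search settings.
#' @param min_roi_size,connectivity segmentation settings.
#' @param rng_seed master seed; scene, subsample and fold seeds derive
#'   from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), n_images = 7,
                            crop_low_nm = 975, crop_high_nm = 1646,
                            denoise = denoise_config(), n_components = 6,
                            prominence_fraction = 0.1, dedup_window_nm = 10,
                            pixel_cap = 50000, cost_exponents = -8:8,
                            gamma_exponents = -8:8, cv_folds = 5,
                            min_roi_size = 10, connectivity = 8,
                            rng_seed = 1) {
  structure(list(scene = scene, n_images = as.integer(n_images),
                 crop_low_nm = crop_low_nm, crop_high_nm = crop_high_nm,
                 denoise = denoise, n_components = n_components,
                 prominence_fraction = prominence_fraction,
                 dedup_window_nm = dedup_window_nm, pixel_cap = pixel_cap,
                 cost_exponents = cost_exponents,
                 gamma_exponents = gamma_exponents, cv_folds = cv_folds,
                 min_roi_size = min_roi_size, connectivity = connectivity,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

# analyse one scene: correct, crop, segment, denoise, average
process_scene <- function(scene, config) {
  refs <- reference_pair(scene$dark, scene$white)
  corrected <- correct_reflectance(scene$raw, refs)
  corrected <- crop_bands(corrected, config$crop_low_nm, config$crop_high_nm)
  band <- select_contrast_band(corrected)
  mask <- build_mask(corrected, band$band)
  rois <- label_rois(mask, min_roi_size = config$min_roi_size,
                     connectivity = config$connectivity)
  denoised <- denoise_cube(corrected, mask, config$denoise)
  spectra <- roi_mean_spectra(denoised, rois)
  truth_classes <- roi_truth_classes(rois, scene$truth)
  spectra$class <- truth_classes
  list(corrected = denoised, mask = mask, rois = rois,
       contrast_band = band, spectra = spectra,
       truth_classes = truth_classes)
}

pool_pixels <- function(processed, cap, rng_seed) {
  mats <- lapply(processed, function(p) {
    idx <- which(p$mask == 1L)
    cube_pixel_matrix(p$corrected)[idx, , drop = FALSE]
  })
  X <- do.call(rbind, mats)
  if (nrow(X) > cap) {
    keep <- with_local_seed(rng_seed, sample.int(nrow(X), cap))
    X <- X[keep, , drop = FALSE]
  }
  X
}

#' Run the full discrimination pipeline on synthetic scenes
#'
#' Simulates `n_images` scenes, analyses each (reflectance correction, band
#' crop, segmentation, pixel-wise wavelet denoising, per-seed averaging),
#' fits pixel-level PCA on the pooled calibration-image foreground, selects
#' effective wavelengths from the loading extrema, trains the RBF-SVM by
#' grid search on the calibration objects and evaluates on the prediction
#' objects; the reserved external image yields per-seed classification maps
#' and object-level map accuracy.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts (tables, maps, log).
#' @return list of class `pipeline_result` with the split, PCA model,
#'   `ews`, `model`, `report_calibration`, `report_prediction`,
#'   `external` (per-image maps + accuracy) and the config hash.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_images < 4L)
    stop("n_images must be >= 4 (external image + 2:1 calibration:prediction split)")
  scenes <- lapply(seq_len(config$n_images), function(i) {
    sc <- config$scene
    sc$rng_seed <- (config$scene$rng_seed + 7919L * i) %% .Machine$integer.max
    generate_scene(sc)
  })
  processed <- lapply(scenes, process_scene, config = config)
  split <- split_by_image(seq_len(config$n_images), ratio = c(2, 1),
                          rng_seed = config$rng_seed, n_external = 1)
  Xpix <- pool_pixels(processed[split$calibration_ids], config$pixel_cap,
                      config$rng_seed)
  wl <- processed[[1L]]$corrected$wavelengths_nm
  pca <- fit_pixel_pca(Xpix, config$n_components, wavelengths_nm = wl,
                       clamp_rank = TRUE)
  ews <- select_ews(pca, prominence_fraction = config$prominence_fraction,
                    dedup_window_nm = config$dedup_window_nm)
  obj_tables <- lapply(seq_along(processed), function(i) {
    tab <- restrict_to_ews(processed[[i]]$spectra, ews)
    tab$image <- i
    tab
  })
  gather <- function(ids) do.call(rbind, obj_tables[ids])
  cal <- gather(split$calibration_ids)
  pred <- gather(split$prediction_ids)
  model <- grid_search_svm(table_spectra(cal), cal$class,
                           cost_exponents = config$cost_exponents,
                           gamma_exponents = config$gamma_exponents,
                           cv_folds = config$cv_folds,
                           rng_seed = config$rng_seed)
  report_cal <- evaluate(model, cal, cal$class)
  report_pred <- evaluate(model, pred, pred$class)
  external <- lapply(split$external_ids, function(i) {
    tab <- obj_tables[[i]]
    p <- predict_objects(model, tab)
    map <- paint_map(processed[[i]]$rois, p)
    acc <- map_accuracy(p$predicted, tab$class)
    list(image = i, predictions = p, truth = tab$class, map = map,
         accuracy = acc)
  })
  result <- structure(
    list(split = split, pca = pca, ews = ews, model = model,
         report_calibration = report_cal, report_prediction = report_pred,
         external = external, contrast_bands = vapply(processed, function(p)
           p$contrast_band$wavelength_nm, numeric(1)),
         n_objects = vapply(processed, function(p) length(p$rois$sizes),
                            integer(1)),
         config_hash = config_hash(config), config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, processed, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d images (%d cal / %d pred / %d ext), ",
                     "%d EWs, best (c, g) = (%g, %g)\n"),
              x$config$n_images, length(x$split$calibration_ids),
              length(x$split$prediction_ids), length(x$split$external_ids),
              nrow(x$ews), x$model$cost, x$model$gamma))
  cat(sprintf("calibration accuracy: %.1f%%, prediction accuracy: %.1f%%\n",
              x$report_calibration$overall_pct, x$report_prediction$overall_pct))
  for (e in x$external)
    cat(sprintf("external image %d: %.1f%% (%d/%d)\n", e$image,
                e$accuracy$percent, e$accuracy$correct, e$accuracy$total))
  invisible(x)
}

write_pipeline_artifacts <- function(result, processed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$ews, file.path(out_dir, "effective_wavelengths.csv"))
  write_table(data.frame(component = seq_along(result$pca$explained_variance_fraction),
                         explained_fraction = result$pca$explained_variance_fraction),
              file.path(out_dir, "pca_variance.csv"))
  loadings <- as.data.frame(result$pca$loadings)
  loadings$wavelength_nm <- result$pca$wavelengths_nm
  write_table(loadings, file.path(out_dir, "pca_loadings.csv"))
  write_table(as.data.frame(result$report_calibration$confusion),
              file.path(out_dir, "confusion_calibration.csv"))
  write_table(as.data.frame(result$report_prediction$confusion),
              file.path(out_dir, "confusion_prediction.csv"))
  for (e in result$external) {
    write_map(unclass(e$map),
              file.path(out_dir, sprintf("classification_map_%02d.png", e$image)))
    write_table(data.frame(label = e$predictions$id,
                           predicted = e$predictions$predicted,
                           truth = e$truth,
                           correct = e$predictions$predicted == e$truth),
                file.path(out_dir, sprintf("external_predictions_%02d.csv", e$image)))
  }
  log_line <- sprintf("[%s] run config_hash=%s seed=%d", format(Sys.time()),
                      result$config_hash, result$config$rng_seed)
  cat(log_line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
  invisible(out_dir)
}
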