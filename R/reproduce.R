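# Dataset-level drivers: learn kernels from images + vessel ground truth,
# compare them, and fit the direction-process model.

#' Learn a co-occurrence kernel from images and vessel masks
#'
#' Full Algorithm-1 pipeline per image: thin the vessel mask to
#' centerlines, lift the image with cake wavelets, take dominant
#' orientations at the centerline pixels, accumulate shift-twist pair
#' histograms, and sum the per-image histograms over the dataset.
#'
#' @param images list of grayscale matrices.
#' @param masks list of binary vessel masks (same shapes).
#' @param av_labels optional list of label matrices (0 = background,
#'   1 = artery, 2 = vein); when given, pair statistics are accumulated
#'   per label and the artery and vein histograms added (arteries and
#'   veins are never directly connected).
#' @param config a [pipeline_config()].
#' @return a normalized `cooc_kernel`.
#' @export
learn_dataset_kernel <- function(images, masks, av_labels = NULL,
                                 config = pipeline_config()) {
  stopifnot(length(images) == length(masks))
  wl <- make_cake_wavelets(config$n_theta, config$wavelet_size,
                           config$angular_order, config$nyquist_taper)
  sets <- list()
  for (i in seq_along(images)) {
    cl <- thin_to_centerlines(masks[[i]])
    sc <- orientation_score(images[[i]], wl)
    om <- dominant_orientations(sc, cl > 0)
    if (is.null(av_labels)) {
      sets[[length(sets) + 1]] <- build_interest_points(cl, om)
    } else {
      av <- av_labels[[i]]
      for (lab in c(1, 2)) {
        clv <- cl * (abs(av - lab) < 0.25)
        if (any(clv > 0))
          sets[[length(sets) + 1]] <- build_interest_points(clv, om)
      }
    }
  }
  learn_cooc_kernel(sets, config$d, config$n_theta, normalize = TRUE)
}

#' Reproduce the kernel-learning and model-fitting workflow on a dataset
#'
#' Expects `dataset_dir` to contain `images/` and `masks/` with matching
#' file names (PNG/TIFF), optionally `av/` with artery/vein label images
#' (pixel values near 0.5 = artery, near 1 = vein).  Learns the
#' whole-vasculature kernel (and the AV-separated variant when labels are
#' present), tabulates their pairwise relative l2 errors, fits the
#' direction-process parameters to each, and writes kernels and CSV
#' tables to `out_dir`.
#'
#' @param dataset_dir dataset directory.
#' @param config a [pipeline_config()]; the fit uses log grids
#'   `alpha_range x d33_range` with `n_alpha x n_d33` values.
#' @param out_dir output directory (created).
#' @return report list: kernels, pairwise error table, fits.
#' @export
run_reproduction <- function(dataset_dir, config = pipeline_config(),
                             out_dir = file.path(dataset_dir, "report")) {
  img_dir <- file.path(dataset_dir, "images")
  msk_dir <- file.path(dataset_dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("dataset_dir must contain images/ and masks/")
  img_files <- sort(list.files(img_dir, "\\.(png|tif|tiff)$", full.names = TRUE))
  if (!length(img_files)) stop("no images found in ", img_dir)
  msk_files <- file.path(msk_dir, basename(img_files))
  missing <- msk_files[!file.exists(msk_files)]
  if (length(missing))
    stop("missing ground-truth masks: ", paste(basename(missing),
                                               collapse = ", "))
  av_dir <- file.path(dataset_dir, "av")
  av_files <- file.path(av_dir, basename(img_files))
  have_av <- dir.exists(av_dir) && all(file.exists(av_files))

  images <- lapply(img_files, read_image)
  masks <- lapply(msk_files, function(f) (read_image(f) > 0.5) * 1L)
  kernels <- list(whole = learn_dataset_kernel(images, masks,
                                               config = config))
  if (have_av) {
    av <- lapply(av_files, function(f) round(read_image(f) * 2))
    kernels$av <- learn_dataset_kernel(images, masks, av_labels = av,
                                       config = config)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairwise <- data.frame(k1 = character(0), k2 = character(0),
                         error_percent = numeric(0))
  nm <- names(kernels)
  if (length(kernels) >= 2) {
    for (i in seq_along(kernels)) for (j in seq_along(kernels)) {
      if (i < j)
        pairwise[nrow(pairwise) + 1, ] <-
          list(nm[i], nm[j],
               as.numeric(kernel_distance(kernels[[i]], kernels[[j]],
                                          symmetric = TRUE)))
    }
  }
  grids <- fit_grids(config$alpha_range, config$n_alpha,
                     config$d33_range, config$n_d33)
  fits <- lapply(kernels, fit_kernel, alpha_grid = grids$alpha,
                 d33_grid = grids$d33, blur_s = config$blur_s)
  for (n in nm) {
    save_kernel(kernels[[n]], file.path(out_dir, paste0("kernel_", n, ".bin")),
                provenance = paste("learned from", dataset_dir))
    utils::write.csv(fits[[n]]$error_surface,
                     file.path(out_dir, paste0("fit_surface_", n, ".csv")))
  }
  utils::write.csv(pairwise, file.path(out_dir, "pairwise_errors.csv"),
                   row.names = FALSE)
  fit_tab <- data.frame(
    kernel = nm,
    error_percent = vapply(fits, function(f) f$error_percent, 0),
    alpha = vapply(fits, function(f) f$best_alpha, 0),
    D33 = vapply(fits, function(f) f$best_d33, 0))
  utils::write.csv(fit_tab, file.path(out_dir, "best_fits.csv"),
                   row.names = FALSE)
  list(kernels = kernels, pairwise = pairwise, fits = fits,
       out_dir = out_dir)
}
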