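#' Pipeline configuration
#'
#' Central bundle of the tunable parameters, serializable to JSON.
#' Defaults follow the study conditions: 16 orientations, pairing
#' distance 65 px, intensity bandwidth 0.2.
#'
#' @param n_theta orientation bins.
#' @param d pairing / kernel half-width (px).
#' @param sigma_int intensity affinity bandwidth.
#' @param wavelet_size,angular_order,nyquist_taper cake-wavelet recipe.
#' @param alpha_range,n_alpha,d33_range,n_d33 fitting grids (log-spaced).
#' @param blur_s probabilistic-kernel spatial blur (px).
#' @param max_groups,min_size clustering controls.
#' @param seed master RNG seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_theta = 16, d = 65, sigma_int = 0.2,
                            wavelet_size = 31, angular_order = 3,
                            nyquist_taper = 0.9,
                            alpha_range = c(1e-5, 1e-2), n_alpha = 50,
                            d33_range = c(1e-6, 5e-3), n_d33 = 100,
                            blur_s = 0.5, max_groups = 10,
                            min_size = NULL, seed = 1) {
  structure(list(n_theta = as.integer(n_theta), d = as.integer(d),
                 sigma_int = sigma_int, wavelet_size = as.integer(wavelet_size),
                 angular_order = angular_order,
                 nyquist_taper = nyquist_taper,
                 alpha_range = alpha_range, n_alpha = as.integer(n_alpha),
                 d33_range = d33_range, n_d33 = as.integer(n_d33),
                 blur_s = blur_s, max_groups = as.integer(max_groups),
                 min_size = min_size, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for [save_config()]).
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, TRUE)])
}
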