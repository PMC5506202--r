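# Kernel container: raw little-endian binary (doubles, column-major) plus
# a JSON sidecar `<path>.json` carrying {dims, d, n_theta, normalized,
# kind, class, provenance}.  Round trips are bit-exact.

#' Save a kernel to a binary container
#'
#' Writes the array as little-endian doubles at `path` and a JSON sidecar
#' at `path.json` with the metadata needed to reconstruct and validate it.
#'
#' @param kernel a `cooc_kernel`, `resolvent_kernel` or
#'   `projective_kernel`.
#' @param path output file; the sidecar is written next to it.
#' @param provenance free-text provenance note stored in the sidecar.
#' @return `path`, invisibly.
#' @export
save_kernel <- function(kernel, path, provenance = "") {
  stopifnot(inherits(kernel, c("cooc_kernel", "resolvent_kernel",
                               "projective_kernel")))
  meta <- list(
    format = "linecooc-kernel-v1",
    class = class(kernel)[1],
    dims = dim(kernel),
    d = attr(kernel, "d"),
    n_theta = attr(kernel, "n_theta"),
    normalized = isTRUE(attr(kernel, "normalized")),
    kind = attr(kernel, "kind") %||% NA,
    provenance = provenance)
  p <- attr(kernel, "params")
  if (!is.null(p)) meta$params <- list(alpha = p$alpha, D33 = p$D33,
                                       blur_s = p$blur_s)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(kernel), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a kernel from a binary container
#'
#' Validates the sidecar metadata (shape consistency with `d` and
#' `n_theta`, file size) and reconstructs the kernel object bit-exactly.
#'
#' @param path file written by [save_kernel()].
#' @return the reconstructed kernel.
#' @export
load_kernel <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("kernel container or sidecar missing: ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "linecooc-kernel-v1"))
    stop("unrecognized kernel container format")
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  if (file.info(path)$size != 8 * n)
    stop("kernel container size does not match metadata dims")
  d <- as.integer(meta$d); n_theta <- as.integer(meta$n_theta)
  if (dims[1] != 2L * d + 1L || dims[2] != 2L * d + 1L)
    stop("metadata/shape mismatch: spatial side must be 2d+1")
  expected_depth <- switch(meta$class,
                           cooc_kernel = n_theta,
                           resolvent_kernel = 2L * n_theta,
                           projective_kernel = 2L * n_theta,
                           stop("unknown kernel class in metadata"))
  if (dims[3] != expected_depth)
    stop("metadata/shape mismatch: theta depth inconsistent with n_theta")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  arr <- array(vals, dims)
  if (meta$class == "cooc_kernel") {
    new_cooc_kernel(arr, d, n_theta, normalized = isTRUE(meta$normalized),
                    kind = meta$kind)
  } else {
    p <- if (!is.null(meta$params))
      direction_process_params(meta$params$alpha, meta$params$D33,
                               meta$params$blur_s)
    else NULL
    out <- new_resolvent_kernel(arr, p, n_theta, d)
    if (meta$class == "projective_kernel") class(out) <- "projective_kernel"
    out
  }
}

#' Read a grayscale image
#'
#' Reads PNG (or TIFF when the tiff package is available), rescales to
#' [0, 1], and reduces RGB inputs to the green channel (the
#' highest-contrast channel for retinal fundus images).
#'
#' @param path image file.
#' @return numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- img[, , min(2, dim(img)[3])]
  img
}

#' Write a grayscale image or label map as PNG
#'
#' Numeric matrices in [0, 1] are written as 8-bit grayscale.  Integer
#' matrices (label maps, 0 = background) are encoded as gray value
#' `label / 255`, which round trips exactly through 8-bit PNG for up to
#' 255 groups; recover labels with `round(read_image(path) * 255)`.
#'
#' @param x numeric matrix in [0, 1] or integer label matrix >= 0.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.integer(x) || max(x) > 1) {
    if (max(x) > 255) stop("more than 255 labels cannot be PNG-encoded")
    png::writePNG(x / 255, path)
  } else {
    png::writePNG(clamp01(x), path)
  }
  invisible(path)
}
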