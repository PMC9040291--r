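#' Multi-channel 2-D image with physical pixel size
#'
#' `image2d()` is the universal raster container of the package: a named list
#' of intensity matrices (one per channel, identical dimensions) together
#' with the physical pixel size in micrometers. Channel names follow the
#' labelling roles of the assays (`aqp4`, `lectin`, `gfp`, `tracer`, `ptau`,
#' `nuclei`), but any names are accepted.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions and non-negative intensities (arbitrary fluorescence units).
#' @param pixel_size_um physical size of one pixel in micrometers (> 0).
#' @param meta optional list of provenance metadata (source path, notes).
#' @return an object of class `Image2D`.
#' @export
image2d <- function(channels, pixel_size_um, meta = list()) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    stop("every channel must be a numeric matrix")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all channels must share dimensions")
  }
  if (any(vapply(channels, function(m) any(m < 0), TRUE))) {
    stop("intensities must be >= 0")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_size_um = as.numeric(pixel_size_um),
         meta = meta),
    class = "Image2D"
  )
}

#' @export
dim.Image2D <- function(x) dim(x$channels[[1L]])

#' @export
print.Image2D <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<Image2D> %d x %d px @ %.4g um/px; channels: %s\n",
              d[1L], d[2L], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract one channel as a matrix
#' @param image an `Image2D`.
#' @param channel channel name.
#' @return numeric matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "Image2D"))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[channel]]
}

#' Read a multi-page TIFF (plus sidecar metadata) as an Image2D
#'
#' Images are stored as multi-page 32-bit float TIFF, one page per channel,
#' with a YAML sidecar (`<path>.meta.yaml`) recording channel names and
#' `pixel_size_um`. The pixel size must be present in the sidecar or given
#' via `pixel_size_um`; there is no silent default.
#'
#' @param path TIFF file path.
#' @param pixel_size_um override/supply the pixel size in micrometers.
#' @param channels optional character vector of channel names overriding the
#'   sidecar (length must equal the number of TIFF pages).
#' @return an `Image2D`.
#' @export
read_image <- function(path, pixel_size_um = NULL, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages) || !is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p
  })
  side <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(channels)) channels <- meta$channels
  if (is.null(channels)) channels <- paste0("ch", seq_along(pages))
  if (length(channels) != length(pages)) {
    stop(sprintf("channel map has %d names but TIFF has %d pages",
                 length(channels), length(pages)))
  }
  psz <- if (!is.null(pixel_size_um)) pixel_size_um else meta$pixel_size_um
  if (is.null(psz)) {
    stop("pixel size missing: not in sidecar metadata and no `pixel_size_um` supplied")
  }
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  ch <- lapply(pages, function(p) p * scale)
  names(ch) <- channels
  image2d(ch, psz, meta = list(source = path))
}

#' Write an Image2D as multi-page TIFF with a YAML metadata sidecar
#'
#' Intensities are rescaled to [0, 1] for TIFF storage; the scale factor is
#' recorded in the sidecar so `read_image()` restores the original AU values.
#'
#' @param image an `Image2D`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "Image2D"))
  mx <- max(1, vapply(image$channels, max, 0))
  pages <- lapply(image$channels, function(m) m / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(
    list(channels = names(image$channels),
         pixel_size_um = image$pixel_size_um,
         intensity_scale = mx),
    paste0(path, ".meta.yaml")
  )
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this helper so that
# no function leaves hidden global random state behind.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
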