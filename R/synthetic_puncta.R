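#' Generate a GFP puncta field with known per-punctum areas
#'
#' Renders each requested punctum as an isotropic Gaussian blob whose area
#' above half-maximum equals the requested area: a blob of amplitude `A`
#' and width `sigma` exceeds `A/2` inside radius `sigma * sqrt(2 log 2)`,
#' so `sigma = sqrt(area / (2 * pi * log(2)))`. Puncta are placed uniformly
#' at random without overlap (bounded retries), away from the image border.
#'
#' @param areas_um2 numeric vector of requested above-half-maximum areas in
#'   square micrometers (> 0). An empty vector yields a blank image.
#' @param pixel_size_um micrometers per pixel (default 0.1, super-resolution
#'   sampling; puncta of ~1 um^2 need sub-0.2 um pixels to be resolved).
#' @param width_px,height_px image size; if `NULL`, a size large enough to
#'   place all puncta is chosen.
#' @param amplitude blob peak amplitude in AU.
#' @param noise_sigma Gaussian noise SD in AU.
#' @param seed RNG seed.
#' @param max_retries placement retries per punctum before giving up.
#' @return list with `image` ([image2d()], channel `gfp`) and `truth`
#'   (data.frame: `punctum`, `x_px`, `y_px`, `sigma_um`, `area_um2`).
#' @export
generate_puncta_field <- function(areas_um2, pixel_size_um = 0.1,
                                  width_px = NULL, height_px = NULL,
                                  amplitude = 100, noise_sigma = 0,
                                  seed = 1L, max_retries = 200L) {
  if (length(areas_um2) && any(areas_um2 <= 0)) stop("areas must be > 0")
  n <- length(areas_um2)
  sigma_um <- sqrt(areas_um2 / (2 * pi * log(2)))
  if (is.null(width_px) || is.null(height_px)) {
    spacing_um <- if (n) 8 * max(sigma_um) + 2 else 5
    side_um <- max(5, ceiling((ceiling(sqrt(max(n, 1))) + 1) * spacing_um))
    side_px <- ceiling(side_um / pixel_size_um)
    if (is.null(width_px)) width_px <- side_px
    if (is.null(height_px)) height_px <- side_px
  }
  img <- matrix(0, nrow = height_px, ncol = width_px)
  truth <- data.frame(punctum = integer(), x_px = numeric(), y_px = numeric(),
                      sigma_um = numeric(), area_um2 = numeric())
  if (n > 0) {
    res <- with_seed(seed, {
      centers <- matrix(NA_real_, nrow = n, ncol = 2)
      radius_px <- sigma_um * sqrt(2 * log(2)) / pixel_size_um
      margin_px <- 4 * sigma_um / pixel_size_um + 2
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          cx <- stats::runif(1, margin_px[i], width_px - margin_px[i])
          cy <- stats::runif(1, margin_px[i], height_px - margin_px[i])
          prev <- seq_len(i - 1L)
          if (i == 1L ||
              all(sqrt((centers[prev, 1] - cx)^2 + (centers[prev, 2] - cy)^2) >
                  4 * (sigma_um[prev] + sigma_um[i]) / pixel_size_um + 2)) {
            centers[i, ] <- c(cx, cy)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(sprintf(
            "could not place punctum %d without overlap after %d retries",
            i, max_retries))
        }
      }
      for (i in seq_len(n)) {
        s_px <- sigma_um[i] / pixel_size_um
        ext <- ceiling(5 * s_px)
        cols <- max(1, floor(centers[i, 1] - ext)):min(width_px, ceiling(centers[i, 1] + ext))
        rows <- max(1, floor(centers[i, 2] - ext)):min(height_px, ceiling(centers[i, 2] + ext))
        X <- matrix(cols - 0.5, nrow = length(rows), ncol = length(cols),
                    byrow = TRUE)
        Y <- matrix(rows - 0.5, nrow = length(rows), ncol = length(cols))
        r2 <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2
        img[rows, cols] <- img[rows, cols] +
          amplitude * exp(-r2 / (2 * s_px^2))
      }
      if (noise_sigma > 0) {
        img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                                 nrow = height_px), 0)
      }
      list(img = img, centers = centers)
    })
    img <- res$img
    truth <- data.frame(punctum = seq_len(n), x_px = res$centers[, 1],
                        y_px = res$centers[, 2], sigma_um = sigma_um,
                        area_um2 = areas_um2)
  }
  list(image = image2d(list(gfp = img), pixel_size_um), truth = truth)
}
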