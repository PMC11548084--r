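#' Generate an ultrasound-like grayscale phantom
#'
#' Builds a piecewise-smooth synthetic image loosely resembling a B-mode
#' ultrasound frame: a dark background, a bright fan-shaped (sector) imaging
#' region with mild depth attenuation, and optionally a number of elliptical
#' inclusions ("lesions") whose intensity differs from the surrounding
#' tissue. The content provides both flat regions and curved edges, the two
#' features the denoising chain must respectively smooth and preserve.
#'
#' The phantom is deterministic: the same `(height, width, n_lesions, seed)`
#' always yields a bit-identical image.
#'
#' @param height,width image dimensions in pixels; both must be at least 32.
#' @param n_lesions number of elliptical inclusions (>= 0).
#' @param seed integer seed controlling lesion placement and shape.
#' @return A [gray_image()] on the unit range.
#' @examples
#' ph <- make_phantom(64, 64, n_lesions = 2, seed = 1)
#' range(ph$pixels)
#' @export
make_phantom <- function(height, width, n_lesions = 2, seed = 1) {
  check_number(height, "height"); check_number(width, "width")
  if (height < 32 || width < 32) {
    stop("`height` and `width` must be at least 32", call. = FALSE)
  }
  check_number(n_lesions, "n_lesions", min = 0)
  h <- as.integer(height); w <- as.integer(width)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  # Dark background with a faint vertical gradient.
  px <- 0.10 + 0.05 * (rows - 1) / (h - 1)

  # Sector ("fan") region: apex above the top edge, centred horizontally.
  cx <- (w + 1) / 2
  apex <- -0.15 * h
  dy <- rows - apex
  dx <- cols - cx
  ang <- atan2(dx, dy)                       # 0 = straight down
  rad <- sqrt(dx^2 + dy^2)
  rmax <- 1.08 * h
  fan <- abs(ang) < (38 * pi / 180) & rad < rmax & rad > 0.18 * h
  # Tissue intensity with depth attenuation and a gentle lateral falloff.
  tissue <- 0.62 - 0.22 * (rad / rmax) - 0.08 * (abs(ang) / (38 * pi / 180))
  px[fan] <- tissue[fan]

  if (n_lesions > 0) {
    les <- with_seed(seed, {
      data.frame(
        r0 = stats::runif(n_lesions, 0.30, 0.80) * h,
        c0 = cx + stats::runif(n_lesions, -0.22, 0.22) * w,
        a  = stats::runif(n_lesions, 0.05, 0.12) * min(h, w),
        b  = stats::runif(n_lesions, 0.05, 0.12) * min(h, w),
        th = stats::runif(n_lesions, 0, pi),
        # hypoechoic (dark) or hyperechoic (bright) inclusion
        off = stats::runif(n_lesions, 0.15, 0.35) *
          ifelse(stats::runif(n_lesions) < 0.7, -1, 1)
      )
    })
    for (i in seq_len(nrow(les))) {
      u <- (rows - les$r0[i]) * cos(les$th[i]) + (cols - les$c0[i]) * sin(les$th[i])
      v <- -(rows - les$r0[i]) * sin(les$th[i]) + (cols - les$c0[i]) * cos(les$th[i])
      inside <- (u / les$a[i])^2 + (v / les$b[i])^2 < 1 & fan
      px[inside] <- px[inside] + les$off[i]
    }
  }

  clip_image(gray_image(px, "unit"))
}

#' Corrupt an image with additive Gaussian noise
#'
#' Noise is drawn i.i.d. per pixel as \eqn{N(\mu, \sigma^2)} on the 8-bit
#' intensity scale, the convention in which noise levels for medical images
#' are usually quoted (e.g. \eqn{\sigma = 25} grey levels). Images on the
#' unit range are rescaled internally, so `sd = 25` corrupts a unit-range
#' image with noise of standard deviation 25/255. The result is clipped to
#' the image's declared range. Deterministic per seed.
#'
#' @param img a [gray_image()] (or matrix, assumed unit range).
#' @param mean noise mean on the 8-bit scale (default 0).
#' @param sd noise standard deviation on the 8-bit scale (default 25).
#' @param seed integer seed.
#' @return A noisy [gray_image()] on the same range as `img`.
#' @export
add_gaussian_noise <- function(img, mean = 0, sd = 25, seed = 1) {
  img <- as_gray_image(img)
  check_number(mean, "mean")
  check_number(sd, "sd", min = 0)
  scale <- range_max(img$range) / 255
  noise <- with_seed(seed, stats::rnorm(length(img$pixels), mean, sd))
  out <- img
  out$pixels <- img$pixels + matrix(noise * scale, nrow(img$pixels))
  clip_image(out)
}

#' Corrupt an image with Poisson (shot) noise
#'
#' Each output pixel is drawn from a Poisson distribution whose mean equals
#' the pixel's clean intensity expressed in counts. For unit-range images
#' the intensity is scaled by `peak` counts (default 255, i.e. the 8-bit
#' grey level is treated as the photon count), the draw is divided back by
#' `peak`, and the result is clipped to the declared range. For 8-bit images
#' the grey level itself is the Poisson mean. Deterministic per seed.
#'
#' @param img a [gray_image()] with non-negative pixels.
#' @param seed integer seed.
#' @param peak counts corresponding to full scale on unit-range input.
#' @return A noisy [gray_image()] on the same range as `img`.
#' @export
add_poisson_noise <- function(img, seed = 1, peak = 255) {
  img <- as_gray_image(img)
  check_number(peak, "peak", min = 0, strict = TRUE)
  if (any(img$pixels < 0)) {
    stop("Poisson noise requires non-negative pixel intensities", call. = FALSE)
  }
  lam <- if (identical(img$range, "unit")) img$pixels * peak else img$pixels
  draws <- with_seed(seed, stats::rpois(length(lam), as.vector(lam)))
  out <- img
  vals <- if (identical(img$range, "unit")) draws / peak else draws
  out$pixels <- matrix(vals, nrow(img$pixels))
  clip_image(out)
}
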