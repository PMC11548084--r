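#' Estimate the noise standard deviation from a wavelet pyramid
#'
#' Robust median-absolute-deviation estimator applied to the finest-scale
#' diagonal detail band, which is dominated by noise for natural images:
#' \deqn{\hat\sigma_n = \mathrm{median}(|d_1|) / 0.6745.}
#'
#' @param pyr a `wavelet_pyramid` from [dwt2()].
#' @return Non-negative noise standard deviation in coefficient units.
#' @export
estimate_noise_sigma <- function(pyr) {
  if (!inherits(pyr, "wavelet_pyramid")) {
    stop("`pyr` must be a wavelet_pyramid", call. = FALSE)
  }
  d1 <- pyr$details[[1]]$d
  if (length(d1) == 0L) stop("empty diagonal detail band", call. = FALSE)
  stats::median(abs(d1)) / 0.6745
}

#' BayesShrink threshold for one detail band
#'
#' Data-adaptive threshold \eqn{T = \hat\sigma_n^2 / \hat\sigma_x} where
#' \eqn{\hat\sigma_x = \sqrt{\max(\bar{w^2} - \hat\sigma_n^2,\, 0)}} is the
#' estimated signal standard deviation of the (zero-mean) band. When the
#' band carries no estimated signal (\eqn{\hat\sigma_x = 0}) the threshold
#' is the band's maximum absolute coefficient, annihilating it. A zero
#' noise estimate yields a zero threshold (no shrinkage).
#'
#' @param band numeric matrix (or vector) of detail coefficients.
#' @param sigma_noise noise standard deviation, >= 0.
#' @return A non-negative threshold.
#' @export
bayes_shrink_threshold <- function(band, sigma_noise) {
  check_number(sigma_noise, "sigma_noise", min = 0)
  if (length(band) == 0L) stop("empty coefficient band", call. = FALSE)
  if (sigma_noise == 0) return(0)
  m2 <- mean(band^2)                       # population second moment
  sx2 <- max(m2 - sigma_noise^2, 0)
  if (sx2 == 0) return(max(abs(band)))
  sigma_noise^2 / sqrt(sx2)
}

#' Soft thresholding of wavelet coefficients
#'
#' \eqn{w \mapsto \mathrm{sign}(w)\,\max(|w| - T, 0)}: coefficients at or
#' below the threshold are zeroed, larger ones shrink toward zero by `T`.
#'
#' @param coeffs numeric vector or matrix of coefficients.
#' @param threshold non-negative threshold `T`.
#' @return Shrunken coefficients with the same shape.
#' @export
soft_threshold <- function(coeffs, threshold) {
  check_number(threshold, "threshold", min = 0)
  sign(coeffs) * pmax(abs(coeffs) - threshold, 0)
}

#' Wavelet shrinkage denoising
#'
#' Decomposes the image with a multilevel orthogonal DWT, soft-thresholds
#' every detail band with its BayesShrink threshold (the approximation band
#' is never touched), and reconstructs. The noise level is estimated once
#' from the finest diagonal band and reused for every band.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param wavelet basis name (default `"db2"`).
#' @param levels decomposition depth (default 5).
#' @return A list of class `wavelet_denoise` with elements
#'   \describe{
#'     \item{image}{the denoised [gray_image()], clipped to its range;}
#'     \item{sigma_noise}{the MAD noise estimate \eqn{\hat\sigma_n};}
#'     \item{thresholds}{named numeric vector of per-band thresholds
#'       (`"1h"`, `"1v"`, `"1d"`, `"2h"`, ..., finest level first).}
#'   }
#' @examples
#' clean <- make_phantom(64, 64, 2, seed = 1)
#' noisy <- add_gaussian_noise(clean, sd = 25, seed = 2)
#' den <- wavelet_denoise(noisy, levels = 3)
#' den$sigma_noise
#' @export
wavelet_denoise <- function(img, wavelet = "db2", levels = 5) {
  img <- as_gray_image(img)
  pyr <- dwt2(img, wavelet, levels)
  sigma <- estimate_noise_sigma(pyr)
  thr <- numeric(0)
  for (j in seq_len(pyr$levels)) {
    for (b in c("h", "v", "d")) {
      t_jb <- bayes_shrink_threshold(pyr$details[[j]][[b]], sigma)
      pyr$details[[j]][[b]] <- soft_threshold(pyr$details[[j]][[b]], t_jb)
      thr[paste0(j, b)] <- t_jb
    }
  }
  out <- clip_image(idwt2(pyr))
  structure(list(image = out, sigma_noise = sigma, thresholds = thr,
                 wavelet = wavelet, levels = pyr$levels),
            class = "wavelet_denoise")
}

#' @export
print.wavelet_denoise <- function(x, ...) {
  cat(sprintf("<wavelet_denoise> %s, %d level(s), sigma_noise = %.5g\n",
              x$wavelet, x$levels, x$sigma_noise))
  cat("  thresholds:\n")
  print(round(x$thresholds, 5))
  invisible(x)
}
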