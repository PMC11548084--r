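#' Bilateral filter parameter triple
#'
#' Validates and packages the three tunable parameters of the bilateral
#' filter: the neighbourhood diameter `d` (pixels), the range (intensity)
#' spread `sigma_color` in 8-bit grey levels, and the spatial spread
#' `sigma_space` in pixels.
#'
#' @param d positive integer window diameter.
#' @param sigma_color range kernel standard deviation (> 0, 8-bit units).
#' @param sigma_space spatial kernel standard deviation (> 0, pixels).
#' @return A list of class `bilateral_params`.
#' @export
bilateral_params <- function(d, sigma_color, sigma_space) {
  check_number(d, "d", min = 1)
  if (d != round(d)) stop("`d` must be a whole number", call. = FALSE)
  check_number(sigma_color, "sigma_color", min = 0, strict = TRUE)
  check_number(sigma_space, "sigma_space", min = 0, strict = TRUE)
  structure(list(d = as.integer(d), sigma_color = sigma_color,
                 sigma_space = sigma_space),
            class = "bilateral_params")
}

# Coerce a bilateral_params, a list, or a named numeric vector (as returned
# by coef() on a fit) to a validated bilateral_params triple.
as_bilateral_params <- function(x) {
  if (inherits(x, "bilateral_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) x <- as.list(x)
  if (is.list(x) && all(c("d", "sigma_color", "sigma_space") %in% names(x))) {
    return(bilateral_params(x$d, x$sigma_color, x$sigma_space))
  }
  stop("cannot interpret `params`: supply bilateral_params(), a list or a ",
       "named vector with d, sigma_color, sigma_space", call. = FALSE)
}

#' @export
print.bilateral_params <- function(x, ...) {
  cat(sprintf("<bilateral_params> d = %d, sigma_color = %.4g, sigma_space = %.4g\n",
              x$d, x$sigma_color, x$sigma_space))
  invisible(x)
}

#' Offsets of the square filtering window
#'
#' For odd `d` the window is centred: offsets \eqn{-(d-1)/2, \dots,
#' (d-1)/2} in each axis. For even `d` the asymmetric truncation convention
#' of common implementations is used: offsets \eqn{-d/2, \dots, d/2 - 1}.
#' Either way the window holds exactly \eqn{d^2} pixels.
#'
#' @param d window diameter, >= 1.
#' @return A data frame with integer columns `dx`, `dy` (one row per
#'   window position).
#' @export
window_offsets <- function(d) {
  check_number(d, "d", min = 1)
  if (d != round(d)) stop("`d` must be a whole number", call. = FALSE)
  d <- as.integer(d)
  r <- if (d %% 2L == 1L) seq.int(-(d - 1L) %/% 2L, (d - 1L) %/% 2L)
       else seq.int(-d %/% 2L, d %/% 2L - 1L)
  expand.grid(dx = r, dy = r, KEEP.OUT.ATTRS = FALSE)
}

# Half-sample reflective padding of a matrix (edge pixel duplicated).
reflect_pad <- function(x, top, bottom, left, right) {
  n <- nrow(x); m <- ncol(x)
  if (top >= n || bottom >= n || left >= m || right >= m) {
    stop("padding exceeds image size", call. = FALSE)
  }
  ri <- c(rev(seq_len(top)), seq_len(n), n + 1L - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(m), m + 1L - seq_len(right))
  x[ri, ci, drop = FALSE]
}

#' Bilateral edge-preserving filter
#'
#' Each output pixel is the normalized weighted average of the pixels in
#' its `d`-diameter square window, the weight of a neighbour being the
#' product of a spatial Gaussian in its distance and a range Gaussian in
#' its intensity difference from the centre pixel:
#' \deqn{I_B(x, y) = \frac{1}{W_P}\sum_{x',y'} I(x', y')\,
#'   e^{-\frac{(x - x')^2 + (y - y')^2}{2\sigma_s^2}}\,
#'   e^{-\frac{(I(x,y) - I(x',y'))^2}{2\sigma_r^2}},}
#' with \eqn{W_P} the sum of the weights. The output is therefore a convex
#' combination of window intensities and never leaves the input's range.
#'
#' Intensities are processed on the 8-bit scale internally, so
#' `sigma_color` is always in grey levels regardless of the input's
#' declared range. Borders are handled by reflective padding.
#'
#' @param img a [gray_image()] or matrix (assumed unit range).
#' @param d window diameter in pixels (see [window_offsets()] for the even
#'   `d` convention).
#' @param sigma_color range spread in 8-bit grey levels (> 0).
#' @param sigma_space spatial spread in pixels (> 0).
#' @return The filtered [gray_image()] on the input's range.
#' @examples
#' img <- make_phantom(64, 64, 1, seed = 1)
#' noisy <- add_gaussian_noise(img, sd = 25, seed = 2)
#' sm <- bilateral_filter(noisy, d = 5, sigma_color = 120, sigma_space = 3)
#' @export
bilateral_filter <- function(img, d, sigma_color, sigma_space) {
  img <- as_gray_image(img)
  p <- bilateral_params(d, sigma_color, sigma_space)
  off <- window_offsets(p$d)

  x <- img$pixels * (255 / range_max(img$range))
  h <- nrow(x); w <- ncol(x)
  lo <- -min(off$dx); hi <- max(off$dx)       # same for dy (square window)
  padded <- reflect_pad(x, lo, hi, lo, hi)

  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  inv2ss <- 1 / (2 * p$sigma_space^2)
  inv2sr <- 1 / (2 * p$sigma_color^2)
  for (i in seq_len(nrow(off))) {
    dx <- off$dx[i]; dy <- off$dy[i]
    ws <- exp(-(dx * dx + dy * dy) * inv2ss)
    shifted <- padded[(lo + 1L + dy):(lo + h + dy),
                      (lo + 1L + dx):(lo + w + dx), drop = FALSE]
    wgt <- ws * exp(-(x - shifted)^2 * inv2sr)
    num <- num + wgt * shifted
    den <- den + wgt
  }
  out <- img
  out$pixels <- (num / den) * (range_max(img$range) / 255)
  out
}
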