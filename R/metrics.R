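# Metrics operate on the unit working range (MAX = 1): printed MSE values of
# order 1e-4 next to PSNR ~33 dB only satisfy PSNR = 10 log10(MAX^2 / MSE)
# on that scale.
metric_pair <- function(ref, test) {
  ref <- convert_range(as_gray_image(ref), "unit")
  test <- convert_range(as_gray_image(test), "unit")
  if (!identical(dim(ref$pixels), dim(test$pixels))) {
    stop("`ref` and `test` must have identical dimensions", call. = FALSE)
  }
  list(ref = ref$pixels, test = test$pixels)
}

#' Mean squared error between two images
#'
#' \eqn{\mathrm{MSE} = \frac{1}{N}\sum_i (I_i - \hat I_i)^2} on the unit
#' intensity range.
#'
#' @param ref,test [gray_image()]s (or matrices) of identical shape.
#' @return Non-negative mean squared error.
#' @export
mse <- function(ref, test) {
  p <- metric_pair(ref, test)
  mean((p$ref - p$test)^2)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{\mathrm{PSNR} = 10 \log_{10}(\mathrm{MAX}^2 / \mathrm{MSE})} in
#' decibels, with \eqn{\mathrm{MAX} = 1} on the unit working range.
#' Identical images yield `Inf`.
#'
#' @inheritParams mse
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(ref, test) {
  e <- mse(ref, test)
  if (e == 0) return(Inf)
  10 * log10(1 / e)
}

#' Structural similarity index
#'
#' \deqn{\mathrm{SSIM}(x, y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with population moments, \eqn{C_1 = (k_1 \mathrm{MAX})^2} and
#' \eqn{C_2 = (k_2 \mathrm{MAX})^2}. In `"global"` mode (the default) the
#' formula is evaluated once over the whole image; in `"local"` mode it is
#' evaluated over every sliding square window and the window scores are
#' averaged.
#'
#' @inheritParams mse
#' @param k1,k2 stabilization constants (defaults 0.01, 0.03).
#' @param window `"global"` or `"local"`.
#' @param window_size odd side length of the local window (default 7).
#' @return SSIM in \eqn{[-1, 1]}; 1 iff the images are identical.
#' @export
ssim <- function(ref, test, k1 = 0.01, k2 = 0.03,
                 window = c("global", "local"), window_size = 7) {
  p <- metric_pair(ref, test)
  window <- match.arg(window)
  c1 <- (k1 * 1)^2
  c2 <- (k2 * 1)^2
  if (window == "global") {
    return(ssim_formula(mean(p$ref), mean(p$test),
                        mean(p$ref^2) - mean(p$ref)^2,
                        mean(p$test^2) - mean(p$test)^2,
                        mean(p$ref * p$test) - mean(p$ref) * mean(p$test),
                        c1, c2))
  }
  k <- as.integer(window_size)
  if (k < 1L || k %% 2L == 0L) {
    stop("`window_size` must be a positive odd integer", call. = FALSE)
  }
  if (k > nrow(p$ref) || k > ncol(p$ref)) {
    stop("`window_size` exceeds the image dimensions", call. = FALSE)
  }
  n <- k * k
  mx <- box_sum(p$ref, k) / n
  my <- box_sum(p$test, k) / n
  vx <- box_sum(p$ref^2, k) / n - mx^2
  vy <- box_sum(p$test^2, k) / n - my^2
  cxy <- box_sum(p$ref * p$test, k) / n - mx * my
  mean(ssim_formula(mx, my, vx, vy, cxy, c1, c2))
}

ssim_formula <- function(mx, my, vx, vy, cxy, c1, c2) {
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# Sums over all k x k sliding windows via an integral image.
box_sum <- function(x, k) {
  S <- apply(x, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S))
  h <- nrow(x); w <- ncol(x)
  i <- seq_len(h - k + 1L); j <- seq_len(w - k + 1L)
  S[i + k, j + k, drop = FALSE] - S[i, j + k, drop = FALSE] -
    S[i + k, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Full reference-based quality report
#'
#' Computes PSNR, MSE and SSIM for a (reference, test) pair on the unit
#' working range.
#'
#' @inheritParams ssim
#' @param ... further arguments passed to [ssim()].
#' @return A list of class `quality_report` with `psnr_db`, `mse`, `ssim`.
#' @examples
#' a <- make_phantom(64, 64, 1, seed = 1)
#' b <- add_gaussian_noise(a, sd = 25, seed = 2)
#' quality_report(a, b)
#' @export
quality_report <- function(ref, test, ...) {
  structure(list(psnr_db = psnr(ref, test), mse = mse(ref, test),
                 ssim = ssim(ref, test, ...)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB | MSE %.6f | SSIM %.4f\n",
              x$psnr_db, x$mse, x$ssim))
  invisible(x)
}
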