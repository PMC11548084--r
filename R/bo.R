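#' Search space for the bilateral filter parameters
#'
#' Box bounds for the tunable triple. `d` is an integer dimension; the two
#' sigmas are continuous. The defaults bracket the parameter values a tuned
#' bilateral post-filter typically lands on for 8-bit medical images.
#'
#' @param d integer interval for the window diameter (default 3..9).
#' @param sigma_color interval for the range spread, 8-bit units
#'   (default 10..150).
#' @param sigma_space interval for the spatial spread, pixels
#'   (default 1..15).
#' @return A list of class `search_space`.
#' @export
search_space <- function(d = c(3, 9), sigma_color = c(10, 150),
                         sigma_space = c(1, 15)) {
  chk <- function(r, name) {
    if (length(r) != 2L || !is.numeric(r) || r[1] >= r[2]) {
      stop(sprintf("`%s` must be a (lower, upper) interval", name),
           call. = FALSE)
    }
  }
  chk(d, "d"); chk(sigma_color, "sigma_color"); chk(sigma_space, "sigma_space")
  structure(list(d = as.numeric(d), sigma_color = as.numeric(sigma_color),
                 sigma_space = as.numeric(sigma_space)),
            class = "search_space")
}

space_lower <- function(s) c(s$d[1], s$sigma_color[1], s$sigma_space[1])
space_upper <- function(s) c(s$d[2], s$sigma_color[2], s$sigma_space[2])

# unit cube <-> parameter space; d rounded to integer at decode time
space_decode <- function(u, space) {
  lo <- space_lower(space); up <- space_upper(space)
  x <- lo + u * (up - lo)
  x[1] <- round(x[1])
  x
}
space_encode <- function(x, space) {
  lo <- space_lower(space); up <- space_upper(space)
  (x - lo) / (up - lo)
}

param_key <- function(x) {
  sprintf("%d|%.6f|%.6f", as.integer(x[1]), x[2], x[3])
}

#' Propose the next parameters to evaluate
#'
#' Maximizes expected improvement over a seeded candidate set (uniform
#' draws over the space plus perturbations of the incumbent), with the
#' diameter rounded to an integer. When EI is numerically zero everywhere
#' (no predicted improvement and no uncertainty) the candidate with the
#' largest predictive standard deviation is returned instead, keeping the
#' search exploratory. Deterministic per seed.
#'
#' @param model a `gp_surrogate` from [fit_surrogate()] (trained on
#'   unit-cube inputs).
#' @param space a [search_space()].
#' @param seed integer seed for the candidate draws.
#' @param n_candidates size of the candidate set.
#' @return A [bilateral_params()] triple.
#' @export
propose_next <- function(model, space, seed = 1, n_candidates = 1500) {
  if (!inherits(model, "gp_surrogate")) {
    stop("`model` must be a gp_surrogate", call. = FALSE)
  }
  p <- ncol(model$X)
  cand <- with_seed(seed, {
    U <- matrix(stats::runif(n_candidates * p), n_candidates, p)
    inc <- model$X[which.min(model$y), , drop = FALSE]
    nloc <- max(50L, n_candidates %/% 5L)
    loc <- matrix(stats::rnorm(nloc * p, mean = rep(inc, each = nloc),
                               sd = 0.05), nloc, p)
    rbind(U, pmin(pmax(loc, 0), 1))
  })
  pr <- gp_predict(model, cand)
  ei <- expected_improvement(pr$mean, pr$sd, min(model$y))
  pick <- if (max(ei) > 1e-12) which.max(ei) else which.max(pr$sd)
  x <- space_decode(cand[pick, ], space)
  bilateral_params(x[1], x[2], x[3])
}

#' Bayesian minimization of a black-box objective over a parameter box
#'
#' Sequential model-based optimization: a Latin-hypercube initial design of
#' `n_initial` points is evaluated, then for each of `iterations` steps a
#' Gaussian-process surrogate is refitted and the expected-improvement
#' maximizer is evaluated next. The diameter dimension is optimized on a
#' continuous relaxation and rounded at evaluation time; already-evaluated
#' integer triples are served from a cache so the number of expensive
#' objective calls never exceeds `n_initial + iterations`, while the trace
#' always has exactly that many rows.
#'
#' @param fn objective to minimize; called as `fn(d, sigma_color,
#'   sigma_space)` and returning a single finite number.
#' @param space a [search_space()].
#' @param iterations number of model-guided evaluations (>= 1).
#' @param n_initial size of the space-filling initial design (>= 2).
#' @param seed integer seed governing the whole run.
#' @param early_stop if `TRUE`, stop once the incumbent has not improved by
#'   more than `tol` over `patience` consecutive iterations.
#' @param tol,patience early-stopping tolerance (objective units) and
#'   window.
#' @return A list of class `bo_trace`: `trace` (data frame with one row per
#'   evaluation: parameters, `objective`, running `incumbent`, `phase`,
#'   `cached`), `best` (list with `params` and `objective`), `fn_calls`,
#'   plus the run settings.
#' @export
bo_minimize <- function(fn, space = search_space(), iterations = 25,
                        n_initial = 10, seed = 1, early_stop = FALSE,
                        tol = 1e-3, patience = 15) {
  check_number(iterations, "iterations", min = 1)
  check_number(n_initial, "n_initial", min = 2)
  iterations <- as.integer(iterations); n_initial <- as.integer(n_initial)

  cache <- new.env(parent = emptyenv())
  fn_calls <- 0L
  eval_point <- function(x) {
    key <- param_key(x)
    if (!is.null(cache[[key]])) {
      return(list(value = cache[[key]], cached = TRUE))
    }
    val <- fn(x[1], x[2], x[3])
    if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
      stop("objective must return a single finite number", call. = FALSE)
    }
    fn_calls <<- fn_calls + 1L
    cache[[key]] <- val
    list(value = val, cached = FALSE)
  }

  U0 <- with_seed(seed, lhs::randomLHS(n_initial, 3))
  n_total <- n_initial + iterations
  X <- matrix(NA_real_, n_total, 3)
  y <- numeric(n_total)
  cached <- logical(n_total)
  pars <- matrix(NA_real_, n_total, 3)

  for (i in seq_len(n_initial)) {
    x <- space_decode(U0[i, ], space)
    r <- eval_point(x)
    pars[i, ] <- x
    X[i, ] <- space_encode(x, space)
    y[i] <- r$value
    cached[i] <- r$cached
  }

  n_done <- n_initial
  theta_prev <- NULL
  for (t in seq_len(iterations)) {
    model <- fit_surrogate(X[seq_len(n_done), , drop = FALSE],
                           y[seq_len(n_done)],
                           n_restarts = 1, seed = derive_seed(seed, 2L * t),
                           init = theta_prev)
    theta_prev <- model$theta
    prop <- propose_next(model, space, seed = derive_seed(seed, 2L * t + 1L))
    x <- c(prop$d, prop$sigma_color, prop$sigma_space)
    r <- eval_point(x)
    n_done <- n_done + 1L
    pars[n_done, ] <- x
    X[n_done, ] <- space_encode(x, space)
    y[n_done] <- r$value
    cached[n_done] <- r$cached
    if (early_stop && n_done - n_initial >= patience) {
      inc <- cummin(y[seq_len(n_done)])
      if (inc[n_done - patience] - inc[n_done] <= tol) break
    }
  }

  keep <- seq_len(n_done)
  trace <- data.frame(
    eval = keep,
    d = as.integer(pars[keep, 1]),
    sigma_color = pars[keep, 2],
    sigma_space = pars[keep, 3],
    objective = y[keep],
    incumbent = cummin(y[keep]),
    phase = rep(c("init", "bo"), c(n_initial, n_done - n_initial)),
    cached = cached[keep]
  )
  ib <- which.min(trace$objective)
  structure(list(
    trace = trace,
    best = list(params = bilateral_params(trace$d[ib], trace$sigma_color[ib],
                                          trace$sigma_space[ib]),
                objective = trace$objective[ib]),
    fn_calls = fn_calls, space = space, seed = seed,
    n_initial = n_initial, iterations = iterations
  ), class = "bo_trace")
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf("<bo_trace> %d evaluations (%d init + %d guided), %d objective calls\n",
              nrow(x$trace), x$n_initial, nrow(x$trace) - x$n_initial,
              x$fn_calls))
  cat(sprintf("  best objective %.6g at d = %d, sigma_color = %.4g, sigma_space = %.4g\n",
              x$best$objective, x$best$params$d, x$best$params$sigma_color,
              x$best$params$sigma_space))
  invisible(x)
}

# PSNR cap applied inside the optimizer so a perfect match (infinite PSNR)
# maps to a finite objective floor of -300 dB.
PSNR_CAP <- 300

#' Negative-PSNR objective for bilateral parameter tuning
#'
#' Applies the bilateral filter with the given parameters to the
#' wavelet-denoised image and returns \eqn{-\mathrm{PSNR}} against the
#' clean reference (PSNR capped at 300 dB so identical images give a
#' finite value). Minimizing this maximizes PSNR.
#'
#' @param clean clean reference [gray_image()].
#' @param wavelet_out wavelet-denoised [gray_image()] (same shape).
#' @param params a [bilateral_params()] or list with `d`, `sigma_color`,
#'   `sigma_space`.
#' @return Negative PSNR in dB.
#' @export
bilateral_objective <- function(clean, wavelet_out, params) {
  filtered <- bilateral_filter(wavelet_out, params$d, params$sigma_color,
                               params$sigma_space)
  -min(psnr(clean, filtered), PSNR_CAP)
}

#' Tune the bilateral post-filter by Bayesian optimization
#'
#' The model-fitting entry point of the package. The noisy image is first
#' wavelet-denoised (db2, BayesShrink soft thresholding); the bilateral
#' filter applied to that output is then tuned by Gaussian-process Bayesian
#' optimization with expected-improvement acquisition, minimizing the
#' negative PSNR against the clean reference. The wavelet stage is computed
#' once; each optimization step costs one bilateral filtering pass.
#'
#' @param clean clean reference [gray_image()].
#' @param noisy noisy input [gray_image()] of the same shape.
#' @param space a [search_space()] for `(d, sigma_color, sigma_space)`.
#' @param iterations guided evaluations after initialization (default 100).
#' @param n_initial space-filling initial evaluations (default 10).
#' @param seed integer seed; the whole run is deterministic given it.
#' @param wavelet,levels wavelet stage settings (default db2, 5 levels).
#' @param early_stop,tol,patience see [bo_minimize()].
#' @return An object of class `bilateral_opt` with the optimization trace,
#'   the incumbent parameters and PSNR, and the cached wavelet stage.
#'   Supports `print()`, `summary()`, `coef()` (named parameter vector),
#'   `plot()` (convergence curve) and `predict()` (apply the tuned pipeline
#'   to a new image).
#' @examples
#' clean <- make_phantom(64, 64, 2, seed = 1)
#' noisy <- add_gaussian_noise(clean, sd = 25, seed = 2)
#' fit <- optimize_bilateral(clean, noisy, iterations = 5, n_initial = 4,
#'                           seed = 3, levels = 3)
#' coef(fit)
#' @export
optimize_bilateral <- function(clean, noisy, space = search_space(),
                               iterations = 100, n_initial = 10, seed = 1,
                               wavelet = "db2", levels = 5,
                               early_stop = FALSE, tol = 1e-3, patience = 15) {
  clean <- as_gray_image(clean); noisy <- as_gray_image(noisy)
  if (!identical(dim(clean$pixels), dim(noisy$pixels))) {
    stop("`clean` and `noisy` must have identical dimensions", call. = FALSE)
  }
  wd <- wavelet_denoise(noisy, wavelet, levels)
  fn <- function(d, sigma_color, sigma_space) {
    bilateral_objective(clean, wd$image,
                        list(d = d, sigma_color = sigma_color,
                             sigma_space = sigma_space))
  }
  res <- bo_minimize(fn, space, iterations, n_initial, seed,
                     early_stop, tol, patience)
  structure(list(trace = res$trace, best = res$best,
                 best_psnr = -res$best$objective, fn_calls = res$fn_calls,
                 space = space, seed = seed, n_initial = res$n_initial,
                 iterations = res$iterations,
                 wavelet_result = wd, wavelet = wavelet, levels = levels),
            class = "bilateral_opt")
}

#' @export
print.bilateral_opt <- function(x, ...) {
  cat(sprintf("Bilateral post-filter tuned by Bayesian optimization (%d evaluations)\n",
              nrow(x$trace)))
  cat(sprintf("  incumbent: d = %d, sigma_color = %.4g, sigma_space = %.4g\n",
              x$best$params$d, x$best$params$sigma_color,
              x$best$params$sigma_space))
  cat(sprintf("  incumbent PSNR: %.2f dB\n", x$best_psnr))
  invisible(x)
}

#' @export
summary.bilateral_opt <- function(object, ...) {
  tr <- object$trace
  cat(sprintf("Bayesian optimization of the bilateral post-filter\n"))
  cat(sprintf("  wavelet stage: %s, %d level(s), sigma_noise = %.5g\n",
              object$wavelet, object$levels,
              object$wavelet_result$sigma_noise))
  cat(sprintf("  evaluations: %d (%d initial + %d guided), objective calls: %d\n",
              nrow(tr), object$n_initial, nrow(tr) - object$n_initial,
              object$fn_calls))
  cat(sprintf("  PSNR: first incumbent %.2f dB -> final %.2f dB\n",
              -tr$incumbent[object$n_initial], object$best_psnr))
  print(object$best$params)
  invisible(object)
}

#' @export
coef.bilateral_opt <- function(object, ...) {
  p <- object$best$params
  c(d = p$d, sigma_color = p$sigma_color, sigma_space = p$sigma_space)
}

#' @export
plot.bilateral_opt <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$eval, -tr$incumbent, type = "s",
                 xlab = "evaluation", ylab = "incumbent PSNR (dB)",
                 main = "Bayesian optimization convergence", ...)
  graphics::points(tr$eval, -tr$objective, pch = 20, col = "grey60")
  graphics::abline(v = x$n_initial + 0.5, lty = 3)
  invisible(x)
}

#' Apply a tuned pipeline to a new image
#'
#' Runs the wavelet stage (same settings as the fit) followed by the
#' bilateral filter with the incumbent parameters on `newdata`. This is the
#' parameter-transfer deployment mode: parameters tuned on one reference
#' image are reused on images for which no clean reference exists.
#'
#' @param object a `bilateral_opt` fit.
#' @param newdata a noisy [gray_image()]; defaults to the image the fit was
#'   run on.
#' @param ... unused.
#' @return The denoised [gray_image()].
#' @export
predict.bilateral_opt <- function(object, newdata = NULL, ...) {
  wd <- if (is.null(newdata)) object$wavelet_result
        else wavelet_denoise(newdata, object$wavelet, object$levels)
  p <- object$best$params
  bilateral_filter(wd$image, p$d, p$sigma_color, p$sigma_space)
}
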