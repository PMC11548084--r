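#' Expected improvement acquisition value
#'
#' Closed form of \eqn{E[\max(f_{best} - f(x), 0)]} for a Gaussian
#' predictive distribution \eqn{f(x) \sim N(\mu, s^2)} under minimization:
#' \deqn{\mathrm{EI} = (f_{best} - \mu)\,\Phi(z) + s\,\phi(z), \qquad
#'   z = (f_{best} - \mu)/s,}
#' degenerating to \eqn{\max(f_{best} - \mu, 0)} at \eqn{s = 0}. Always
#' non-negative. Vectorized over `mu` and `sd`.
#'
#' @param mu predictive mean(s).
#' @param sd predictive standard deviation(s), >= 0.
#' @param f_best incumbent (best observed) objective value.
#' @return Expected improvement value(s), >= 0.
#' @export
expected_improvement <- function(mu, sd, f_best) {
  if (any(sd < 0)) stop("`sd` must be non-negative", call. = FALSE)
  check_number(f_best, "f_best")
  imp <- f_best - mu
  out <- pmax(imp, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- imp[pos] / sd[pos]
    out[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

# ---- Gaussian-process surrogate -------------------------------------------
# Squared-exponential kernel with per-dimension length-scales (automatic
# relevance determination), a signal amplitude and a small noise term.
# Inputs are expected in the unit cube; outputs are standardized internally.

sqdist_ard <- function(A, B, ls) {
  As <- sweep(A, 2, ls, "/")
  Bs <- sweep(B, 2, ls, "/")
  D <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  pmax(D, 0)
}

gp_nll <- function(theta, X, y) {
  p <- ncol(X)
  ls <- exp(theta[seq_len(p)])
  sf2 <- exp(2 * theta[p + 1L])
  sn2 <- exp(2 * theta[p + 2L])
  n <- nrow(X)
  K <- sf2 * exp(-0.5 * sqdist_ard(X, X, ls)) + diag(sn2 + 1e-8, n)
  U <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(U)) return(1e10)
  a <- backsolve(U, forwardsolve(t(U), y))
  sum(log(diag(U))) + 0.5 * sum(y * a) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian-process surrogate to evaluated points
#'
#' Fits a zero-mean GP with a squared-exponential ARD kernel plus a small
#' noise/jitter term to (input, objective) pairs, by maximizing the log
#' marginal likelihood over log hyperparameters with multistart L-BFGS-B.
#' Inputs must be scaled to the unit cube by the caller; the objective is
#' standardized internally.
#'
#' @param X numeric matrix of inputs (rows = evaluations), in `[0, 1]^p`.
#' @param y numeric vector of objective values.
#' @param n_restarts optimizer restarts beyond the default start.
#' @param seed integer seed for the restart draws.
#' @param init optional starting log-hyperparameters (warm start).
#' @return A list of class `gp_surrogate` holding the training data,
#'   hyperparameters and Cholesky factor used for prediction.
#' @seealso [gp_predict()], [propose_next()]
#' @export
fit_surrogate <- function(X, y, n_restarts = 2, seed = 1, init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 evaluations", call. = FALSE)
  if (nrow(unique(X)) < 2L) {
    stop("all inputs are identical; the surrogate is unidentifiable ",
         "(evaluate at least two distinct parameter settings)", call. = FALSE)
  }
  p <- ncol(X)
  ymu <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ymu) / ysd

  lower <- c(rep(log(0.02), p), log(0.05), log(1e-4))
  upper <- c(rep(log(5), p), log(5), log(0.5))
  starts <- list(c(rep(log(0.3), p), log(1), log(1e-3)))
  if (!is.null(init)) starts <- c(starts, list(pmin(pmax(init, lower), upper)))
  extra <- with_seed(seed, lapply(seq_len(n_restarts), function(i) {
    stats::runif(p + 2L, lower, upper)
  }))
  starts <- c(starts, extra)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_nll, X = X, y = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 40, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  theta <- if (is.null(best)) starts[[1]] else best$par

  ls <- exp(theta[seq_len(p)])
  sf2 <- exp(2 * theta[p + 1L])
  sn2 <- exp(2 * theta[p + 2L])
  K <- sf2 * exp(-0.5 * sqdist_ard(X, X, ls)) + diag(sn2 + 1e-8, nrow(X))
  U <- chol(K + diag(1e-10, nrow(X)))
  alpha <- backsolve(U, forwardsolve(t(U), ys))
  structure(list(X = X, y = y, ymu = ymu, ysd = ysd, ls = ls, sf2 = sf2,
                 sn2 = sn2, U = U, alpha = alpha, theta = theta),
            class = "gp_surrogate")
}

#' Posterior predictive mean and standard deviation of the surrogate
#'
#' @param model a `gp_surrogate` from [fit_surrogate()].
#' @param Xnew matrix of query inputs in the unit cube.
#' @return A list with numeric vectors `mean` and `sd` (on the original
#'   objective scale).
#' @export
gp_predict <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- model$sf2 * exp(-0.5 * sqdist_ard(model$X, Xnew, model$ls))
  v <- forwardsolve(t(model$U), Ks)
  mu <- model$ymu + model$ysd * drop(crossprod(Ks, model$alpha))
  var <- pmax(model$sf2 + model$sn2 - colSums(v^2), 0)
  list(mean = mu, sd = model$ysd * sqrt(var))
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf("<gp_surrogate> n = %d, length-scales = %s, sf2 = %.3g, sn2 = %.3g\n",
              nrow(x$X), paste(signif(x$ls, 3), collapse = ", "),
              x$sf2, x$sn2))
  invisible(x)
}
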