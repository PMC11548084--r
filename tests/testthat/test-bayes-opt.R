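test_that("expected improvement matches its closed form and degenerate cases", {
  expect_equal(expected_improvement(0, 0, 0), 0)
  expect_equal(expected_improvement(5, 0, 3), 0)       # worse mean, no sd
  expect_equal(expected_improvement(1, 0, 3), 2)       # better mean, no sd
  expect_equal(expected_improvement(0, 1, 0), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_true(all(expected_improvement(rnorm(20), abs(rnorm(20)), 0.5) >= 0))
  expect_error(expected_improvement(0, -1, 0), "non-negative")
})

test_that("expected improvement agrees with a Monte-Carlo estimate", {
  set.seed(50)
  for (case in list(c(0, 1, 0.5), c(-2, 0.3, -1.8), c(1, 2, 0))) {
    mu <- case[1]; s <- case[2]; fb <- case[3]
    draws <- pmax(fb - rnorm(2e5, mu, s), 0)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(expected_improvement(mu, s, fb) - mean(draws)), 3 * se)
  }
})

test_that("the surrogate recovers a smooth function and ranks uncertainty", {
  x <- matrix(seq(0, 1, length.out = 7), ncol = 1)
  y <- as.vector(4 * (x - 0.4)^2)
  gp <- fit_surrogate(x, y, seed = 1)
  held <- matrix(0.35, 1, 1)
  pred <- gp_predict(gp, held)
  expect_lt(abs(pred$mean - 4 * (0.35 - 0.4)^2), 0.1 * max(y))

  at_train <- gp_predict(gp, x[3, , drop = FALSE])
  far <- gp_predict(gp, matrix(0.93, 1, 1))
  expect_lte(at_train$sd, far$sd)

  expect_error(fit_surrogate(matrix(0.5, 4, 1), rnorm(4)), "identical")
  expect_error(fit_surrogate(matrix(0.5, 1, 1), 1), "at least 2")
})

test_that("proposals are deterministic and land in the learned basin", {
  sp <- search_space()
  # objective with a deep minimum at the centre of the space
  set.seed(51)
  U <- lhs::randomLHS(25, 3)
  y <- rowSums((U - 0.5)^2)
  gp <- fit_surrogate(U, y, seed = 2)
  p1 <- propose_next(gp, sp, seed = 7)
  p2 <- propose_next(gp, sp, seed = 7)
  expect_identical(unclass(p1), unclass(p2))
  u <- c((p1$d - sp$d[1]) / diff(sp$d),
         (p1$sigma_color - sp$sigma_color[1]) / diff(sp$sigma_color),
         (p1$sigma_space - sp$sigma_space[1]) / diff(sp$sigma_space))
  expect_lt(sqrt(sum((u - 0.5)^2)), 0.35)
})

test_that("a flat surrogate still yields a valid in-space proposal", {
  U <- matrix(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8), 2, 3, byrow = TRUE)
  gp <- fit_surrogate(U, c(1, 1), seed = 3)
  p <- propose_next(gp, search_space(), seed = 4)
  expect_s3_class(p, "bilateral_params")
  expect_true(p$d >= 3 && p$d <= 9)
})

test_that("optimization keeps an exact budget and a monotone incumbent", {
  quad <- function(d, sc, ss) {
    (d - 6)^2 + ((sc - 120) / 20)^2 + ((ss - 10) / 3)^2
  }
  res <- bo_minimize(quad, search_space(), iterations = 15, n_initial = 8,
                     seed = 11)
  expect_equal(nrow(res$trace), 23)
  expect_lte(res$fn_calls, 23)
  expect_true(all(diff(res$trace$incumbent) <= 0))
  expect_equal(res$trace$incumbent, cummin(res$trace$objective))
  # recovery of the known optimum within one step of each scaled coordinate
  p <- res$best$params
  expect_lte(abs(p$d - 6), 1)
  expect_lte(abs(p$sigma_color - 120), 20)
  expect_lte(abs(p$sigma_space - 10), 3)

  res2 <- bo_minimize(quad, search_space(), iterations = 15, n_initial = 8,
                      seed = 11)
  expect_identical(res$trace, res2$trace)
})

test_that("duplicate proposals are served from the evaluation cache", {
  calls <- 0
  coarse <- function(d, sc, ss) { calls <<- calls + 1; (d - 6)^2 }
  # flat in the sigmas: proposals often collapse onto the same integer d
  res <- bo_minimize(coarse, search_space(), iterations = 10, n_initial = 6,
                     seed = 12)
  expect_equal(nrow(res$trace), 16)
  expect_equal(res$fn_calls, calls)
  expect_lte(calls, 16)
})

test_that("the negative-PSNR objective mirrors PSNR ordering and caps at a match", {
  clean <- make_phantom(64, 64, 2, seed = 1)
  noisy <- add_gaussian_noise(clean, sd = 25, seed = 2)
  wout <- wavelet_denoise(noisy, levels = 3)$image
  p1 <- list(d = 5, sigma_color = 60, sigma_space = 3)
  p2 <- list(d = 3, sigma_color = 15, sigma_space = 1)
  o1 <- bilateral_objective(clean, wout, p1)
  o2 <- bilateral_objective(clean, wout, p2)
  ps1 <- psnr(clean, bilateral_filter(wout, 5, 60, 3))
  ps2 <- psnr(clean, bilateral_filter(wout, 3, 15, 1))
  expect_equal(order(c(o1, o2)), order(-c(ps1, ps2)))

  const <- gray_image(matrix(0.5, 64, 64))
  expect_equal(bilateral_objective(const, const,
                                   list(d = 3, sigma_color = 10,
                                        sigma_space = 1)), -300)
})

test_that("tuned smoothing beats no smoothing on a noisy input", {
  clean <- make_phantom(96, 96, 2, seed = 5)
  noisy <- add_gaussian_noise(clean, sd = 25, seed = 6)
  tuned <- bilateral_objective(clean, noisy,
                               list(d = 7, sigma_color = 140, sigma_space = 10))
  ident <- bilateral_objective(clean, noisy,
                               list(d = 1, sigma_color = 1e-3,
                                    sigma_space = 1e-3))
  expect_lte(tuned, ident)
})

test_that("optimizing the bilateral stage never falls below the wavelet stage", {
  clean <- make_phantom(96, 96, 2, seed = 7)
  noisy <- add_gaussian_noise(clean, sd = 25, seed = 8)
  fit <- optimize_bilateral(clean, noisy, iterations = 12, n_initial = 8,
                            seed = 9, levels = 4)
  expect_equal(nrow(fit$trace), 20)
  expect_true(all(diff(fit$trace$incumbent) <= 0))
  wav_psnr <- psnr(clean, fit$wavelet_result$image)
  expect_gte(fit$best_psnr, wav_psnr - 0.5)
  expect_gt(fit$best_psnr, psnr(clean, noisy))
  # classed-model surface
  expect_s3_class(fit, "bilateral_opt")
  co <- coef(fit)
  expect_named(co, c("d", "sigma_color", "sigma_space"))
  out <- predict(fit)
  expect_identical(dim(out), dim(clean))
  out2 <- predict(fit, newdata = add_gaussian_noise(clean, sd = 25, seed = 10))
  expect_identical(dim(out2), dim(clean))
})
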