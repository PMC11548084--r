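test_that("multilevel transform reconstructs exactly for all bases and depths", {
  for (w in c("db1", "db2", "db4")) {
    for (size in list(c(64, 64), c(65, 63), c(96, 80))) {
      img <- rand_image(size[1], size[2], seed = size[1] + nchar(w))
      maxlev <- min(3L, max_dwt_levels(size[1], size[2], w))
      for (lev in seq_len(maxlev)) {
        rec <- idwt2(dwt2(img, w, lev))
        expect_lt(sqrt(mean((rec$pixels - img$pixels)^2)), 1e-8,
                  label = sprintf("%s %dx%d lev%d", w, size[1], size[2], lev))
      }
    }
  }
})

test_that("vanishing moments kill details of constant and linear images", {
  const <- gray_image(matrix(0.37, 32, 32), "unit")
  p <- dwt2(const, "db2", 2)
  for (j in 1:2) {
    for (b in c("h", "v", "d")) {
      expect_lt(max(abs(p$details[[j]][[b]])), 1e-10)
    }
  }
  # db2 has two vanishing moments: a plane is also annihilated
  plane <- gray_image(outer(1:32, 1:32, function(i, j) (i + 2 * j) / 96), "unit")
  p2 <- dwt2(plane, "db2", 1)
  expect_lt(max(abs(p2$details[[1]]$d)), 1e-10)
})

test_that("single-level analysis matches the direct convolution oracle", {
  for (s in 1:20) {
    img <- rand_image(16, 16, seed = 100 + s)
    p <- dwt2(img, "db2", 1)
    o <- oracle_dwt2(img$pixels)
    expect_lt(max(abs(p$approx - o$a)), 1e-8)
    expect_lt(max(abs(p$details[[1]]$h - o$h)), 1e-8)
    expect_lt(max(abs(p$details[[1]]$v - o$v)), 1e-8)
    expect_lt(max(abs(p$details[[1]]$d - o$d)), 1e-8)
  }
})

test_that("infeasible depth is rejected naming the maximum level count", {
  expect_error(dwt2(rand_image(32, 32, 1), "db2", 5), "at most 3 level")
  expect_error(idwt2(list()), "wavelet_pyramid")
  expect_error(dwt2(rand_image(32, 32, 1), "db9", 1), "unsupported wavelet")
})

test_that("zeroing the finest detail level smooths a noisy image", {
  noisy <- add_gaussian_noise(make_phantom(64, 64, 2, seed = 1), seed = 2)
  p <- dwt2(noisy, "db2", 2)
  tv_before <- total_variation(idwt2(p)$pixels)
  p$details[[1]]$h[] <- 0
  p$details[[1]]$v[] <- 0
  p$details[[1]]$d[] <- 0
  tv_after <- total_variation(idwt2(p)$pixels)
  expect_lt(tv_after, tv_before)
})

test_that("noise sigma estimator is consistent and monotone in noise level", {
  const <- gray_image(matrix(0.5, 32, 32), "unit")
  expect_equal(estimate_noise_sigma(dwt2(const, "db2", 1)), 0)

  # MAD consistency on a pure Gaussian field
  set.seed(42)
  field <- gray_image(matrix(rnorm(256 * 256, 0, 25 / 255), 256, 256), "unit")
  sig <- estimate_noise_sigma(dwt2(field, "db2", 1))
  expect_lt(abs(sig - 25 / 255) / (25 / 255), 0.1)

  # constant-magnitude diagonal band
  p <- dwt2(const, "db2", 1)
  p$details[[1]]$d[] <- 0.2 * (-1)^(seq_along(p$details[[1]]$d))
  expect_equal(estimate_noise_sigma(p), 0.2 / 0.6745, tolerance = 1e-12)

  # strictly increasing in the injected noise level
  ph <- make_phantom(96, 96, 2, seed = 3)
  sigs <- vapply(c(5, 15, 25), function(s) {
    estimate_noise_sigma(dwt2(add_gaussian_noise(ph, sd = s, seed = 4), "db2", 1))
  }, 0)
  expect_true(all(diff(sigs) > 0))
})

test_that("BayesShrink threshold follows its closed form and branch cases", {
  set.seed(7)
  band <- matrix(rnorm(100, 0, 0.05), 10, 10)

  expect_equal(bayes_shrink_threshold(band, 0), 0)

  # signal-absent branch: band variance below the noise floor
  expect_equal(bayes_shrink_threshold(band, 10), max(abs(band)))

  # band of iid N(0, 2 sigma_n^2): sigma_x ~ sigma_n so T ~ sigma_n
  sn <- 0.1
  big <- matrix(rnorm(1e4, 0, sqrt(2) * sn), 100, 100)
  expect_lt(abs(bayes_shrink_threshold(big, sn) - sn) / sn, 0.1)

  # closed-form check against plugged-in sample moments
  m2 <- mean(big^2)
  expect_equal(bayes_shrink_threshold(big, sn), sn^2 / sqrt(m2 - sn^2),
               tolerance = 1e-12)

  expect_error(bayes_shrink_threshold(band, -1), ">=")
})

test_that("thresholds do not increase with band signal variance", {
  sn <- 0.1
  set.seed(8)
  weak <- matrix(rnorm(4096, 0, sqrt(sn^2 + 0.05^2)), 64, 64)
  strong <- matrix(rnorm(4096, 0, sqrt(sn^2 + 0.3^2)), 64, 64)
  expect_gt(bayes_shrink_threshold(weak, sn),
            bayes_shrink_threshold(strong, sn))
})

test_that("soft thresholding shrinks toward zero and never expands", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  expect_equal(soft_threshold(c(1.5, -2, 0.3), 2), c(0, 0, 0))
  x <- matrix(rnorm(100), 10, 10)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(x, -0.1), ">=")
  # contraction property over random thresholds
  set.seed(9)
  for (t in runif(5, 0, 2)) {
    y <- soft_threshold(x, t)
    expect_true(all(abs(y) <= abs(x) + 1e-15))
  }
})

test_that("wavelet denoising is exact on clean constants and helps on noise", {
  const <- gray_image(matrix(0.6, 64, 64), "unit")
  out <- wavelet_denoise(const, levels = 3)
  expect_lt(max(abs(out$image$pixels - const$pixels)), 1e-8)
  expect_equal(out$sigma_noise, 0)
  expect_true(all(out$thresholds == 0))

  clean <- make_phantom(96, 96, 2, seed = 1)
  noisy <- add_gaussian_noise(clean, sd = 25, seed = 2)
  den <- wavelet_denoise(noisy, levels = 4)
  expect_gt(psnr(clean, den$image), psnr(clean, noisy))
  expect_length(den$thresholds, 12)
  expect_true(all(den$thresholds >= 0))
})

test_that("shrinkage never increases pyramid energy", {
  noisy <- add_gaussian_noise(make_phantom(64, 64, 2, seed = 5), seed = 6)
  p <- dwt2(noisy, "db2", 3)
  sig <- estimate_noise_sigma(p)
  for (j in 1:3) {
    for (b in c("h", "v", "d")) {
      band <- p$details[[j]][[b]]
      shrunk <- soft_threshold(band, bayes_shrink_threshold(band, sig))
      expect_lte(sum(shrunk^2), sum(band^2))
    }
  }
})
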