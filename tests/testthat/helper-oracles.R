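# Independent brute-force reference implementations used to cross-check the
# vectorized package code. These are deliberately written as naive loops,
# sharing no code with the package internals.

# Bilateral filter: per-pixel double loop over the window of the two-kernel
# weighted average, with the same half-sample reflective border convention
# (documented in ?bilateral_filter). `x` is a plain matrix on the scale in
# which sigma_color is expressed.
oracle_bilateral <- function(x, d, sigma_color, sigma_space) {
  offs <- if (d %% 2 == 1) seq(-(d - 1) / 2, (d - 1) / 2)
          else seq(-d / 2, d / 2 - 1)
  h <- nrow(x); w <- ncol(x)
  reflect <- function(i, n) {
    # half-sample reflection with edge duplication: 0 -> 1, -1 -> 2, n+1 -> n
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      num <- 0; den <- 0
      for (dy in offs) {
        for (dx in offs) {
          rr <- reflect(r + dy, h)
          cx <- reflect(cc + dx, w)
          wgt <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2)) *
            exp(-(x[r, cc] - x[rr, cx])^2 / (2 * sigma_color^2))
          num <- num + wgt * x[rr, cx]
          den <- den + wgt
        }
      }
      out[r, cc] <- num / den
    }
  }
  out
}

# One-level 1-D db2 analysis: textbook symmetric extension, explicit full
# convolution, downsample by two. Filter taps recomputed here from the
# closed form rather than taken from the package tables.
oracle_db2_dec_filters <- function() {
  s3 <- sqrt(3)
  rec_lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  dec_lo <- rev(rec_lo)
  dec_hi <- rec_lo * c(-1, 1, -1, 1)
  list(lo = dec_lo, hi = dec_hi)
}

oracle_dwt1 <- function(x) {
  f <- oracle_db2_dec_filters()
  n <- length(x); p <- 3
  ext <- c(x[p:1], x, x[n:(n - p + 1)])
  conv_valid <- function(g) {
    m <- length(ext) - 3
    y <- numeric(m)
    for (i in seq_len(m)) y[i] <- sum(rev(g) * ext[i:(i + 3)])
    y
  }
  lo <- conv_valid(f$lo); hi <- conv_valid(f$hi)
  idx <- seq(2, length(lo), by = 2)
  list(a = lo[idx], d = hi[idx])
}

# One-level 2-D analysis from the 1-D oracle (rows pass then columns pass).
oracle_dwt2 <- function(x) {
  lo <- NULL; hi <- NULL
  for (j in seq_len(ncol(x))) {
    r <- oracle_dwt1(x[, j])
    lo <- cbind(lo, r$a); hi <- cbind(hi, r$d)
  }
  second <- function(m) {
    a <- NULL; d <- NULL
    for (i in seq_len(nrow(m))) {
      r <- oracle_dwt1(m[i, ])
      a <- rbind(a, r$a); d <- rbind(d, r$d)
    }
    list(a = a, d = d)
  }
  s1 <- second(lo); s2 <- second(hi)
  list(a = s1$a, h = s1$d, v = s2$a, d = s2$d)
}

# Direct five-moment evaluation of the structural-similarity formula.
oracle_ssim_global <- function(x, y, k1 = 0.01, k2 = 0.03) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  c1 <- k1^2; c2 <- k2^2
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# Windowed Gaussian spatial blur with the package's window and border
# conventions; the sigma_r -> Inf limit of the bilateral filter. Written
# directly (spatial weights only), not via oracle_bilateral.
oracle_gaussian_blur <- function(x, d, sigma_space) {
  offs <- if (d %% 2 == 1) seq(-(d - 1) / 2, (d - 1) / 2)
          else seq(-d / 2, d / 2 - 1)
  h <- nrow(x); w <- ncol(x)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      num <- 0; den <- 0
      for (dy in offs) {
        for (dx in offs) {
          wgt <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2))
          num <- num + wgt * x[reflect(r + dy, h), reflect(cc + dx, w)]
          den <- den + wgt
        }
      }
      out[r, cc] <- num / den
    }
  }
  out
}

rand_image <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(runif(h * w), h, w), "unit")
}

total_variation <- function(x) {
  sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
}
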