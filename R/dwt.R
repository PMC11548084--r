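# Orthogonal Daubechies analysis filters (lowpass, pywt ordering).
# Synthesis filters are the time-reversals; the highpass analysis filter is
# the alternating-sign quadrature mirror of the reversed lowpass filter.
.daub_dec_lo <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852,
          0.030841381835560764, -0.18703481171909309,
          -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

wavelet_filters <- function(wavelet = "db2") {
  dec_lo <- .daub_dec_lo[[wavelet]]
  if (is.null(dec_lo)) {
    stop("unsupported wavelet basis: ", wavelet,
         " (available: ", paste(names(.daub_dec_lo), collapse = ", "), ")",
         call. = FALSE)
  }
  rec_lo <- rev(dec_lo)
  dec_hi <- rec_lo * rep_len(c(-1, 1), length(rec_lo))
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rev(dec_hi), length = length(dec_lo))
}

#' Maximum feasible decomposition depth
#'
#' Number of levels for which every scale still holds at least one full
#' filter support: \eqn{\lfloor \log_2(n / (L - 1)) \rfloor} with `n` the
#' shorter image side and `L` the filter length.
#'
#' @param height,width image dimensions.
#' @param wavelet basis name (`"db1"`, `"db2"`, `"db4"`).
#' @return Integer maximum level count (possibly 0).
#' @export
max_dwt_levels <- function(height, width, wavelet = "db2") {
  L <- wavelet_filters(wavelet)$length
  n <- min(height, width)
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

# Half-sample symmetric extension of the rows of a matrix by p samples.
sym_ext_rows <- function(x, p) {
  n <- nrow(x)
  rbind(x[p:1, , drop = FALSE], x, x[n:(n - p + 1), , drop = FALSE])
}

# One analysis step along the rows of `x`: symmetric extension, valid
# convolution with each analysis filter, downsample by two. Output has
# floor((n + L - 1) / 2) rows.
dwt_step_rows <- function(x, flt) {
  L <- flt$length
  ext <- sym_ext_rows(x, L - 1L)
  m <- nrow(ext) - L + 1L
  lo <- matrix(0, m, ncol(x))
  hi <- matrix(0, m, ncol(x))
  rl <- rev(flt$dec_lo); rh <- rev(flt$dec_hi)
  for (k in seq_len(L)) {
    seg <- ext[k:(k + m - 1L), , drop = FALSE]
    lo <- lo + rl[k] * seg
    hi <- hi + rh[k] * seg
  }
  idx <- seq(2L, m, by = 2L)
  list(lo = lo[idx, , drop = FALSE], hi = hi[idx, , drop = FALSE])
}

# One synthesis step along the rows: upsample both branches, full
# convolution with the synthesis filters, sum, and crop offset L-2 to
# recover the original n rows (verified exact for even and odd n).
idwt_step_rows <- function(lo, hi, n, flt) {
  L <- flt$length
  m <- nrow(lo)
  up <- function(c) {
    u <- matrix(0, 2L * m, ncol(c))
    u[seq(1L, 2L * m, by = 2L), ] <- c
    u
  }
  fullconv <- function(u, f) {
    nf <- nrow(u) + L - 1L
    y <- matrix(0, nf, ncol(u))
    for (k in seq_len(L)) {
      y[k:(k + nrow(u) - 1L), ] <- y[k:(k + nrow(u) - 1L), ] + f[k] * u
    }
    y
  }
  r <- fullconv(up(lo), flt$rec_lo) + fullconv(up(hi), flt$rec_hi)
  off <- L - 2L
  if (off + n > nrow(r)) stop("inconsistent band shapes", call. = FALSE)
  r[(off + 1L):(off + n), , drop = FALSE]
}

# Single-level separable 2-D analysis. Returns approximation plus
# horizontal/vertical/diagonal detail bands. H carries detail along rows
# (horizontal structure), V along columns, D along both.
dwt2_step <- function(x, flt) {
  colpass <- dwt_step_rows(x, flt)                   # filter along rows
  ll_lh <- dwt_step_rows(t(colpass$lo), flt)         # then along columns
  hl_hh <- dwt_step_rows(t(colpass$hi), flt)
  list(a = t(ll_lh$lo), h = t(ll_lh$hi),
       v = t(hl_hh$lo), d = t(hl_hh$hi))
}

idwt2_step <- function(a, h, v, d, shape, flt) {
  # invert the width pass (signals of length shape[2]), then the height pass
  lo <- t(idwt_step_rows(t(a), t(h), shape[2], flt))
  hi <- t(idwt_step_rows(t(v), t(d), shape[2], flt))
  idwt_step_rows(lo, hi, shape[1], flt)
}

#' Multilevel 2-D discrete wavelet transform
#'
#' Separable orthogonal DWT with half-sample symmetric boundary extension.
#' Each level produces one approximation band and three detail bands
#' (horizontal, vertical, diagonal); the approximation is recursively
#' decomposed. Band sizes follow \eqn{\lfloor (n + L - 1)/2 \rfloor} per
#' side, slightly redundant so that reconstruction is exact for both even
#' and odd dimensions.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param wavelet basis name (default `"db2"`).
#' @param levels decomposition depth (default 5).
#' @return An object of class `wavelet_pyramid`: list with `approx` (matrix
#'   at the coarsest scale), `details` (list, finest level first, each with
#'   matrices `h`, `v`, `d`), `shapes` (per-level input dimensions),
#'   `wavelet`, `levels`, `original_shape`, `range`.
#' @seealso [idwt2()], [wavelet_denoise()]
#' @export
dwt2 <- function(img, wavelet = "db2", levels = 5) {
  img <- as_gray_image(img)
  flt <- wavelet_filters(wavelet)
  check_number(levels, "levels", min = 1)
  levels <- as.integer(levels)
  maxlev <- max_dwt_levels(nrow(img$pixels), ncol(img$pixels), wavelet)
  if (levels > maxlev) {
    stop(sprintf("image %d x %d supports at most %d level(s) with %s (%d requested)",
                 nrow(img$pixels), ncol(img$pixels), maxlev, wavelet, levels),
         call. = FALSE)
  }
  x <- img$pixels
  details <- vector("list", levels)
  shapes <- vector("list", levels)
  for (j in seq_len(levels)) {
    shapes[[j]] <- dim(x)
    s <- dwt2_step(x, flt)
    details[[j]] <- list(h = s$h, v = s$v, d = s$d)
    x <- s$a
  }
  structure(list(approx = x, details = details, shapes = shapes,
                 wavelet = wavelet, levels = levels,
                 original_shape = dim(img$pixels), range = img$range),
            class = "wavelet_pyramid")
}

#' Inverse multilevel 2-D discrete wavelet transform
#'
#' Exact inverse of [dwt2()] on an unmodified pyramid; on a shrunken
#' pyramid it reconstructs the denoised image.
#'
#' @param pyr a `wavelet_pyramid` from [dwt2()].
#' @return A [gray_image()] of the original shape and range.
#' @export
idwt2 <- function(pyr) {
  if (!inherits(pyr, "wavelet_pyramid")) {
    stop("`pyr` must be a wavelet_pyramid", call. = FALSE)
  }
  flt <- wavelet_filters(pyr$wavelet)
  x <- pyr$approx
  for (j in rev(seq_len(pyr$levels))) {
    b <- pyr$details[[j]]
    if (!identical(dim(b$h), dim(x)) || !identical(dim(b$v), dim(x)) ||
        !identical(dim(b$d), dim(x))) {
      stop("inconsistent band shapes at level ", j, call. = FALSE)
    }
    x <- idwt2_step(x, b$h, b$v, b$d, pyr$shapes[[j]], flt)
  }
  gray_image(x, pyr$range)
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("<wavelet_pyramid> %s, %d level(s), image %d x %d\n",
              x$wavelet, x$levels, x$original_shape[1], x$original_shape[2]))
  cat(sprintf("  approx: %d x %d\n", nrow(x$approx), ncol(x$approx)))
  for (j in seq_len(x$levels)) {
    d <- x$details[[j]]$d
    cat(sprintf("  level %d details: %d x %d\n", j, nrow(d), ncol(d)))
  }
  invisible(x)
}
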