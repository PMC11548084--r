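#' Grayscale image container
#'
#' A minimal container for a single-channel image: a numeric matrix of pixel
#' intensities plus a declared value range. All processing stages in the
#' package consume and produce `gray_image` objects. Two ranges are
#' supported: `"unit"` (\eqn{[0, 1]}, the internal working scale) and
#' `"eight_bit"` (\eqn{[0, 255]}, the storage scale of 8-bit PNG/PGM files).
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param range declared intensity scale, `"unit"` or `"eight_bit"`.
#' @return An object of class `gray_image` with elements `pixels` and
#'   `range`.
#' @examples
#' img <- gray_image(matrix(0.5, 16, 16))
#' dim(img)
#' @export
gray_image <- function(pixels, range = c("unit", "eight_bit")) {
  range <- match.arg(range)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("`pixels` must be finite", call. = FALSE)
  }
  structure(list(pixels = pixels, range = range), class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, range %s, values [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Peak intensity of a declared range.
range_max <- function(range) if (identical(range, "eight_bit")) 255 else 1

# Accept a bare matrix (assumed unit range) or a gray_image.
as_gray_image <- function(x, range = "unit") {
  if (inherits(x, "gray_image")) return(x)
  gray_image(as.matrix(x), range)
}

#' Convert an image between the unit and 8-bit working ranges
#'
#' Pure rescaling by 255; no quantization is performed.
#'
#' @param img a [gray_image()].
#' @param range target range.
#' @return A `gray_image` on the requested scale.
#' @export
convert_range <- function(img, range = c("unit", "eight_bit")) {
  img <- as_gray_image(img)
  range <- match.arg(range)
  if (identical(img$range, range)) return(img)
  f <- range_max(range) / range_max(img$range)
  gray_image(img$pixels * f, range)
}

#' Clip an image to its declared value range
#'
#' @param img a [gray_image()].
#' @return The image with pixels clamped into `[0, range_max]`.
#' @export
clip_image <- function(img) {
  img <- as_gray_image(img)
  mx <- range_max(img$range)
  img$pixels[img$pixels < 0] <- 0
  img$pixels[img$pixels > mx] <- mx
  img
}

#' Read a grayscale image from PNG or PGM
#'
#' PNG files are read with the \pkg{png} package; RGB(A) inputs are reduced
#' to luminance (Rec. 601 weights) since the pipeline is grayscale-only.
#' PGM files (both ASCII `P2` and binary `P5`, maxval up to 65535) are
#' parsed directly.
#'
#' @param path file path; format is chosen by extension (`.png`, `.pgm`).
#' @param range range to return the image on (default `"unit"`).
#' @return A [gray_image()].
#' @export
read_gray <- function(path, range = c("unit", "eight_bit")) {
  range <- match.arg(range)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      ch <- dim(a)[3]
      a <- if (ch >= 3L) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
           else a[, , 1]
    }
    img <- gray_image(a, "unit")
  } else if (ext == "pgm") {
    img <- read_pgm(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  convert_range(img, range)
}

#' Write a grayscale image to PNG or PGM
#'
#' Output is quantized to 8 bits. Writing then reading an image whose pixels
#' already sit on the 8-bit lattice is lossless.
#'
#' @param img a [gray_image()].
#' @param path destination path (`.png` or `.pgm`).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  img <- clip_image(convert_range(as_gray_image(img), "unit"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img$pixels, path)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokens(con, 4L)
  magic <- tok[[1]]
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  w <- as.integer(tok[[2]]); h <- as.integer(tok[[3]])
  maxval <- as.integer(tok[[4]])
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE,
                 comment.char = "#")
  } else if (maxval < 256L) {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                    endian = "big")
  }
  px <- matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  gray_image(px, "unit")
}

# Read whitespace-separated header tokens, honouring '#' comments; leaves the
# connection positioned at the first raster byte (one whitespace consumed).
pgm_tokens <- function(con, n) {
  toks <- character(0)
  cur <- ""
  in_comment <- FALSE
  while (length(toks) < n || nzchar(cur)) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (in_comment) {
      if (ch %in% c("\n", "\r")) in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("^[[:space:]]$", ch)) {
      if (nzchar(cur)) { toks <- c(toks, cur); cur <- "" }
      if (length(toks) == n) break
    } else {
      cur <- paste0(cur, ch)
    }
  }
  as.list(toks)
}

write_pgm <- function(img, path) {
  img <- clip_image(convert_range(img, "eight_bit"))
  vals <- as.integer(round(t(img$pixels)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img$pixels), nrow(img$pixels)),
            con, eos = NULL)
  writeBin(as.raw(vals), con)
  invisible(path)
}
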