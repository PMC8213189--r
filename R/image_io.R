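# Image reading and channel extraction for 8-bit RGB rasters.

#' Read an 8-bit RGB image (PNG or JPEG)
#'
#' Decodes a PNG or JPEG file into an integer pixel array. Grayscale files
#' are promoted to RGB by triplicating the single component; an alpha
#' channel, if present, is dropped. PNG files with bit depth other than 8
#' are rejected rather than rescaled.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An object of class `image_array`: integer array of dimension
#'   `height x width x 3` with values in 0..255 and a `source_id` attribute
#'   (the file name).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = {
             check_png_bit_depth(path)
             png::readPNG(path)
           },
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported image format '.", ext, "'")),
    error = function(e)
      stop("failed to decode image '", path, "': ", conditionMessage(e),
           call. = FALSE))
  px <- round(raw * 255)
  if (length(dim(px)) == 2L) {               # grayscale on disk
    px <- array(px, dim = c(dim(px), 3L))
  } else if (dim(px)[3] == 2L) {             # gray + alpha
    px <- array(px[, , 1L], dim = c(dim(px)[1:2], 3L))
  } else if (dim(px)[3] == 4L) {             # RGBA
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] != 3L) {
    stop("unexpected channel count ", dim(px)[3], " in ", path)
  }
  image_array(px, source_id = basename(path))
}

# png::readPNG rescales silently, so the declared bit depth is read from the
# IHDR chunk (byte 25 of the file: 8-byte signature, 4-byte length, "IHDR",
# 4+4 bytes of dimensions, then bit depth).
check_png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("truncated PNG header")
  depth <- as.integer(hdr[25L])
  if (depth != 8L)
    stop("only 8-bit PNG images are supported; '", path,
         "' has bit depth ", depth)
  invisible(TRUE)
}

#' Construct an image array
#'
#' @param pixels Numeric or integer array `height x width x 3` with values
#'   in 0..255.
#' @param source_id Opaque identifier for the image.
#' @return An `image_array` object.
#' @export
image_array <- function(pixels, source_id = NA_character_) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("'pixels' must be a height x width x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop("image must have positive dimensions")
  if (any(pixels != floor(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("pixel components must be integers in 0..255")
  storage.mode(pixels) <- "integer"
  structure(pixels, source_id = source_id, class = "image_array")
}

#' @export
print.image_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_array> %d x %d RGB (%s)\n", d[1], d[2],
              attr(x, "source_id")))
  invisible(x)
}

#' Default luma weights for gray conversion
#'
#' The default (0.2125, 0.7154, 0.0721) follows the rgb2gray convention of
#' the scikit-image toolbox (ITU-R BT.709 primaries); `gray_weights("bt601")`
#' selects the ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param scheme `"bt709"` (default) or `"bt601"`, or a numeric vector of
#'   three non-negative weights summing to 1.
#' @return Numeric vector of three weights.
#' @export
gray_weights <- function(scheme = "bt709") {
  if (is.numeric(scheme)) {
    if (length(scheme) != 3L || any(scheme < 0) || abs(sum(scheme) - 1) > 1e-6)
      stop("numeric gray weights must be 3 non-negative values summing to 1")
    return(as.numeric(scheme))
  }
  switch(match.arg(scheme, c("bt709", "bt601")),
         bt709 = c(0.2125, 0.7154, 0.0721),
         bt601 = c(0.299, 0.587, 0.114))
}

#' Extract one color view from an RGB image
#'
#' For `red`, `green`, `blue` the corresponding component is returned
#' verbatim. For `gray` a luma-weighted combination of (R, G, B) is rounded
#' half-to-even (R's `round`) and clipped to 0..255.
#'
#' @param img An [image_array].
#' @param channel One of `"gray"`, `"red"`, `"green"`, `"blue"`.
#' @param weights Gray-conversion weights, see [gray_weights].
#' @return Integer matrix `height x width` with values in 0..255.
#' @export
extract_channel <- function(img, channel, weights = gray_weights()) {
  if (!inherits(img, "image_array")) stop("'img' must be an image_array")
  channel <- match_channel(channel)
  px <- unclass(img)
  comp <- function(k) matrix(px[, , k], nrow = dim(px)[1])  # keep 1x1 shape
  out <- switch(channel,
                red = comp(1L),
                green = comp(2L),
                blue = comp(3L),
                gray = {
                  w <- gray_weights(weights)
                  y <- round(w[1] * comp(1L) + w[2] * comp(2L) +
                               w[3] * comp(3L))
                  pmin(pmax(y, 0), 255)
                })
  storage.mode(out) <- "integer"
  out
}

#' Tally the intensities of a single-channel pixel grid
#'
#' @param grid Integer matrix with values in 0..255.
#' @param channel Channel label to record, one of `"gray"`, `"red"`,
#'   `"green"`, `"blue"`.
#' @param source_id Opaque identifier of the originating image.
#' @return A [channel_counts] object with `counts[g + 1]` the number of
#'   pixels at intensity `g` and `n_pixels = height * width`.
#' @export
count_intensities <- function(grid, channel = "gray",
                              source_id = NA_character_) {
  v <- as.integer(grid)
  if (length(v) == 0L) stop("empty grid: no pixels to count")
  if (any(is.na(v)) || any(v < 0L) || any(v > 255L))
    stop("grid entries must be integers in 0..255")
  channel_counts(tabulate(v + 1L, nbins = N_LEVELS),
                 channel = channel, source_id = source_id)
}
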