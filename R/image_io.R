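#' Channel-role assignment for an RGB section image
#'
#' Maps the analysis roles to RGB channel indices, 1 = red, 2 = green,
#' 3 = blue (the convention of the default parameter table). The outline
#' channel carries the fiber-boundary stain (e.g. laminin), the nuclei
#' channel the DAPI signal, the type channel the fiber-type stain (e.g.
#' slow myosin heavy chain) and the object channel the extra-fiber stain
#' (e.g. PECAM for capillaries).
#'
#' @param outline,nuclei,type,object channel index in `1:3`.
#' @return An object of class `channel_roles`.
#' @export
channel_roles <- function(outline = 1L, nuclei = 3L, type = 2L, object = 2L) {
  r <- list(outline = as.integer(outline), nuclei = as.integer(nuclei),
            type = as.integer(type), object = as.integer(object))
  for (nm in names(r))
    if (length(r[[nm]]) != 1L || is.na(r[[nm]]) || !r[[nm]] %in% 1:3)
      stop("channel role '", nm, "' must be 1 (red), 2 (green) or 3 (blue)")
  if (r$outline == r$nuclei)
    stop("outline and nuclei channels must differ")
  structure(r, class = "channel_roles")
}

#' Load an RGB section image
#'
#' Reads a BMP, JPEG, PNG or TIFF image into a `section_image`: an 8-bit
#' RGB raster with a physical pixel size. Higher bit depths are linearly
#' rescaled to 0-255; alpha channels are dropped. Grayscale images are
#' rejected because the channel roles would be undefined.
#'
#' @param path path to a `.bmp`, `.jpg`/`.jpeg`, `.png`, `.tif`/`.tiff` file.
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @param roles a [channel_roles()] object.
#' @return A `section_image`: list with `pixels` (h x w x 3 integer array,
#'   0-255), `height`, `width`, `pixel_size`, `roles`.
#' @export
load_image <- function(path, pixel_size = 0.645, roles = channel_roles()) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0 (micrometers per pixel)")
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = {
      x <- png::readPNG(path)
      clamp8(x * 255)
    },
    jpg = , jpeg = {
      x <- jpeg::readJPEG(path)
      clamp8(x * 255)
    },
    bmp = read_bmp(path),
    tif = , tiff = {
      x <- read_tiff(path)
      bits <- attr(x, "bits") %||% 8L
      if (bits > 8L) x <- clamp8(x / (2^bits - 1) * 255)  # linear rescale
      x
    },
    stop("unsupported image extension '", ext, "' for: ", path)
  )
  if (is.matrix(a) || (length(dim(a)) == 3L && dim(a)[3] < 3L))
    stop("grayscale image: channel roles are undefined for: ", path)
  if (length(dim(a)) == 3L && dim(a)[3] > 3L)
    a <- a[, , 1:3, drop = FALSE]  # drop alpha
  storage.mode(a) <- "integer"
  attr(a, "bits") <- NULL
  section_image(a, pixel_size = pixel_size, roles = roles)
}

section_image <- function(pixels, pixel_size, roles = channel_roles()) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(list(pixels = pixels, height = dim(pixels)[1],
                 width = dim(pixels)[2], pixel_size = pixel_size,
                 roles = roles),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %.4g um/px (%.0f x %.0f um)\n",
              x$height, x$width, x$pixel_size,
              x$height * x$pixel_size, x$width * x$pixel_size))
  cat(sprintf("  roles: outline=ch%d nuclei=ch%d type=ch%d object=ch%d\n",
              x$roles$outline, x$roles$nuclei, x$roles$type, x$roles$object))
  invisible(x)
}

#' Extract one channel of a section image as a numeric matrix
#'
#' @param image a `section_image`.
#' @param which a channel index in `1:3` or a role name
#'   (`"outline"`, `"nuclei"`, `"type"`, `"object"`).
#' @return numeric matrix of intensities 0-255.
#' @export
get_channel <- function(image, which) {
  stopifnot(inherits(image, "section_image"))
  idx <- if (is.character(which)) image$roles[[match.arg(which,
           c("outline", "nuclei", "type", "object"))]] else as.integer(which)
  if (!idx %in% 1:3) stop("channel index must be in 1:3")
  ch <- image$pixels[, , idx]
  storage.mode(ch) <- "double"
  ch
}

#' Write / read a fiber label mask
#'
#' Masks are persisted as single-channel uncompressed TIFF label maps:
#' 16-bit, escalating to 32-bit when more than 65535 labels are present.
#' The round trip is lossless pixel-for-pixel.
#'
#' @param mask integer label matrix; 0 = background/boundary, k > 0 = fiber k.
#' @param path output path (`.tif`).
#' @return `write_mask` returns the path invisibly; `read_mask` returns the
#'   integer label matrix.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop("mask must be an integer matrix")
  storage.mode(mask) <- "integer"
  if (any(mask < 0L)) stop("mask labels must be non-negative")
  bits <- if (length(mask) && max(mask) > 65535L) 32L else 16L
  write_tiff_gray(mask, path, bits = bits)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  m <- read_tiff(path)
  if (!is.matrix(m)) stop("mask file is not a single-channel label map: ", path)
  storage.mode(m) <- "integer"
  attr(m, "bits") <- NULL
  m
}

#' Write an 8-bit image or raster to PNG
#'
#' Used for boundary overlays and diagnostic renderings.
#'
#' @param x a `section_image`, an h x w x 3 array (0-255) or a matrix (0-255).
#' @param path output `.png` path.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "section_image")) x <- x$pixels
  png::writePNG(x / 255, path)
  invisible(path)
}
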