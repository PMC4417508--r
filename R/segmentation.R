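# Fiber segmentation: h-minima suppression followed by the watershed
# transform on the outline-channel intensity. Bright membrane staining
# (laminin) forms the ridges, dark fiber interiors the basins. The h-minima
# step removes shallow minima created by noise, which otherwise cause the
# watershed to over-segment.

#' Suppress shallow local minima (h-minima suppression)
#'
#' Removes every regional minimum whose depth relative to its lowest
#' surrounding saddle is below `depth` (8-connectivity), filling its basin
#' up to the overflow level towards the surviving terrain, while minima of
#' depth >= `depth` are left untouched at their original values. The output
#' is everywhere >= the input, equals it where no suppression applies,
#' every regional minimum of the output has depth >= `depth`, the operator
#' is idempotent at fixed `depth`, and `depth = 0` is the identity.
#'
#' Implementation: the textbook reconstruction-based transform (grayscale
#' reconstruction by erosion of `gray + depth` over `gray`) identifies the
#' surviving minima; the result is then reconstructed from those minima at
#' their *original* values, so deep minima are not uniformly raised by
#' `depth` as the plain textbook transform would do (which is neither
#' idempotent nor depth-preserving).
#'
#' @param gray single-channel numeric matrix, values on the 8-bit 0-255 scale.
#' @param depth suppression depth h, in 8-bit intensity units (>= 0).
#' @return numeric matrix of the same shape.
#' @export
suppress_minima <- function(gray, depth) {
  stopifnot_gray(gray)
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth < 0)
    stop("depth must be a single number >= 0")
  if (depth == 0) return(gray)
  # textbook h-minima: imhmin(I, h) = -R^delta_{-I}(-I - h)
  filled <- -cpp_reconstruct_dilate(-gray - depth, -gray)
  keep <- cpp_regional_minima(filled) > 0L   # basins of the deep minima
  marker <- matrix(max(gray), nrow(gray), ncol(gray))
  marker[keep] <- gray[keep]
  # reconstruction by erosion of the kept minima (at original values) over
  # the input restores untouched deep basins and fills shallow ones
  -cpp_reconstruct_dilate(-marker, -gray)
}

# dual transform: remove maxima shallower than `depth`, keeping deep maxima
# at their original values (used to smooth bright nuclei / object channels,
# where artifacts are shallow maxima)
suppress_maxima <- function(gray, depth) {
  stopifnot_gray(gray)
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth < 0)
    stop("depth must be a single number >= 0")
  if (depth == 0) return(gray)
  -suppress_minima(-gray, depth)
}

#' Watershed segmentation of a smoothed outline channel
#'
#' Meyer flooding watershed with 8-connected basins. Every pixel receives
#' either a positive basin label or 0 on a watershed ridge line; distinct
#' regional minima yield distinct labels.
#'
#' @param gray single-channel numeric matrix (typically the output of
#'   [suppress_minima()]; bright ridges = fiber boundaries).
#' @return integer label matrix (a fiber mask).
#' @export
watershed_segment <- function(gray) {
  stopifnot_gray(gray)
  cpp_watershed(gray)
}

#' Initial fiber segmentation of a section image
#'
#' Extracts the outline channel, suppresses minima shallower than
#' `params$segmentation_smoothing` and applies the watershed transform.
#' Deterministic for fixed input. A smoothing depth around 5 (range 4-10)
#' gives robust fiber identification on typical laminin staining; lower
#' values over-segment, higher values merge fibers.
#'
#' @param image a `section_image`.
#' @param params an `analysis_params` object.
#' @param roles optional [channel_roles()] overriding the image's roles.
#' @return integer fiber label matrix; 0 marks ridge/background pixels.
#' @export
initial_segmentation <- function(image, params = default_params(),
                                 roles = NULL) {
  stopifnot(inherits(image, "section_image"))
  roles <- roles %||% image$roles
  gray <- get_channel(image, roles$outline)
  watershed_segment(suppress_minima(gray, params$segmentation_smoothing))
}

#' Read fiber-separation strokes from a JSON file
#'
#' The file-driven replacement for interactive freehand separation: a JSON
#' array of polylines, each polyline an array of `[x, y]` pixel vertices
#' (x = column, y = row, 1-based).
#'
#' @param path path to the strokes JSON file.
#' @return list of 2-column (x, y) matrices.
#' @export
read_strokes <- function(path) {
  if (!file.exists(path)) stop("cannot read strokes file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyVector = FALSE)
  lapply(raw, function(poly) {
    m <- do.call(rbind, lapply(poly, function(v) as.numeric(unlist(v))))
    if (is.null(m) || ncol(m) != 2L || nrow(m) < 2L)
      stop("each stroke needs >= 2 [x, y] vertices")
    m
  })
}

#' Apply manual separation strokes to a fiber mask
#'
#' Rasterizes each polyline (8-connected, width 1), sets the stroke pixels
#' to 0 (boundary) and relabels: a fiber split into several pieces keeps
#' its original label on the largest piece while the other pieces receive
#' fresh labels. Untouched fibers are preserved.
#'
#' @param mask integer fiber label matrix.
#' @param strokes list of 2-column (x, y) vertex matrices, as from
#'   [read_strokes()]; an empty list returns the mask unchanged.
#' @return relabelled integer fiber mask.
#' @export
apply_separations <- function(mask, strokes) {
  stopifnot(is.matrix(mask))
  if (length(strokes) == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  px <- list()
  for (s in strokes) {
    s <- as.matrix(s)
    if (ncol(s) != 2L || nrow(s) < 2L)
      stop("each stroke needs >= 2 [x, y] vertices")
    if (any(s[, 1] < 1 | s[, 1] > nc | s[, 2] < 1 | s[, 2] > nr))
      stop("stroke vertex outside image bounds")
    for (i in seq_len(nrow(s) - 1L))
      px[[length(px) + 1L]] <- bresenham(s[i, 2], s[i, 1],
                                         s[i + 1L, 2], s[i + 1L, 1])
  }
  pts <- unique(do.call(rbind, px))
  idx <- (pts[, 2] - 1L) * nr + pts[, 1]
  touched <- unique(mask[idx])
  touched <- touched[touched > 0L]
  out <- mask
  out[idx] <- 0L
  next_label <- max(mask)
  for (L in touched) {
    cc <- cpp_label(out == L, 8L)
    k <- max(cc)
    if (k <= 1L) next
    sizes <- tabulate(cc[cc > 0L], nbins = k)
    keep <- which.max(sizes)  # ties: first component in raster order
    for (j in seq_len(k)) {
      if (j == keep) next
      next_label <- next_label + 1L
      out[cc == j] <- next_label
    }
  }
  out
}

#' Overlay segmentation boundaries on the original image
#'
#' Paints ridge pixels (label 0) that touch at least two distinct fibers
#' in the given color (default white), reproducing the classic
#' boundaries-on-image inspection rendering. Export-only; no analysis
#' effect.
#'
#' @param image a `section_image` or h x w x 3 array (0-255).
#' @param mask integer fiber label matrix of the same height/width.
#' @param color length-3 RGB vector, 0-255.
#' @return h x w x 3 integer array.
#' @export
overlay_boundaries <- function(image, mask, color = c(255L, 255L, 255L)) {
  a <- if (inherits(image, "section_image")) image$pixels else image
  if (nrow(a) != nrow(mask) || ncol(a) != ncol(mask))
    stop("image and mask shapes differ")
  ridge <- cpp_ridge_pixels(mask, 2L)
  for (ch in 1:3) {
    plane <- a[, , ch]
    plane[ridge] <- color[ch]
    a[, , ch] <- plane
  }
  a
}
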