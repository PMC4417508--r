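# Shape-based removal of non-fiber objects from a label mask. Muscle fibers
# in cross-section are compact and roughly polygonal; interstitial space that
# survives the watershed is either elongated (high eccentricity) or stellate
# (low convexity), and partial fibers touch the image edge.

#' Eccentricity of a pixel region
#'
#' Eccentricity of the ellipse sharing the region's central second moments:
#' the ratio of the focal distance to the major-axis length. 0 for circular
#' regions, approaching 1 for line segments. Each pixel is treated as a unit
#' square (its own 1/12 second moment is included), so a single pixel is
#' circular.
#'
#' @param region logical matrix, or 2-column (row, col) matrix of pixel
#'   coordinates.
#' @return eccentricity in `[0, 1]`.
#' @export
region_eccentricity <- function(region) {
  rc <- region_rc(region)
  ecc_rc(rc$row, rc$col)
}

ecc_rc <- function(row, col) {
  n <- length(row)
  xc <- mean(col); yc <- mean(row)
  uxx <- sum((col - xc)^2) / n + 1 / 12
  uyy <- sum((row - yc)^2) / n + 1 / 12
  uxy <- sum((col - xc) * (row - yc)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(max(uxx + uyy - common, 0))
  sqrt(max(major^2 - minor^2, 0)) / major
}

#' Convexity (solidity) of a pixel region
#'
#' Region area divided by the area of the smallest convex polygon containing
#' it. The hull is taken over the pixel *corners* (each pixel a unit square),
#' so filled axis-aligned rectangles score exactly 1 and the measure is
#' consistent with areas counted in whole pixels.
#'
#' @inheritParams region_eccentricity
#' @return convexity in `(0, 1]`.
#' @export
region_convexity <- function(region) {
  rc <- region_rc(region)
  conv_rc(rc$row, rc$col)
}

conv_rc <- function(row, col) {
  hull <- corner_hull(row, col)
  length(row) / polygon_area(hull)
}

#' Filter non-fiber objects out of a label mask
#'
#' Applies the four rejection rules in fixed order -- edge contact, area
#' below `min_fiber_area`, area above `max_fiber_area` (um^2, via
#' `pixel_count * pixel_size^2`), eccentricity above `max_eccentricity`,
#' convexity below `min_convexity` -- recording the first failing rule per
#' object. Bounds are inclusive on the keep side. Fibers should be fully
#' separated before filtering, or merged objects may be rejected wholesale.
#'
#' @param mask integer fiber label matrix from [initial_segmentation()].
#' @param params an `analysis_params` object (uses `pixel_size`,
#'   `min_fiber_area`, `max_fiber_area`, `max_eccentricity`,
#'   `min_convexity`).
#' @return list with `mask` (filtered label matrix, kept labels unchanged)
#'   and `report` (data.frame: label, kept, reason, area_um2, eccentricity,
#'   convexity), of class `fiber_filter`.
#' @export
filter_fibers <- function(mask, params = default_params()) {
  stopifnot(is.matrix(mask))
  if (is.null(params$pixel_size) || !is.numeric(params$pixel_size) ||
      params$pixel_size <= 0)
    stop("pixel_size must be set (> 0) to evaluate areas in um^2")
  ps2 <- params$pixel_size^2
  sets <- label_pixel_sets(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  labs <- as.integer(names(sets))
  n <- length(labs)
  kept <- logical(n); reason <- rep(NA_character_, n)
  area <- ecc <- conv <- numeric(n)
  for (i in seq_len(n)) {
    rr <- sets[[i]]$row; cc <- sets[[i]]$col
    area[i] <- length(rr) * ps2
    ecc[i] <- ecc_rc(rr, cc)
    conv[i] <- conv_rc(rr, cc)
    reason[i] <- if (any(rr == 1L | rr == nr | cc == 1L | cc == nc)) "edge"
      else if (area[i] < params$min_fiber_area) "too_small"
      else if (area[i] > params$max_fiber_area) "too_large"
      else if (ecc[i] > params$max_eccentricity) "eccentricity"
      else if (conv[i] < params$min_convexity) "convexity"
      else NA_character_
    kept[i] <- is.na(reason[i])
  }
  out <- mask
  out[!(mask %in% c(0L, labs[kept]))] <- 0L
  structure(list(
    mask = out,
    report = data.frame(label = labs, kept = kept, reason = reason,
                        area_um2 = area, eccentricity = ecc,
                        convexity = conv)
  ), class = "fiber_filter")
}

#' @export
print.fiber_filter <- function(x, ...) {
  r <- x$report
  cat(sprintf("<fiber_filter> %d objects in, %d fibers kept\n",
              nrow(r), sum(r$kept)))
  if (any(!r$kept))
    print(table(rejected = r$reason[!r$kept]))
  invisible(x)
}

#' Remove listed objects from a mask
#'
#' File/list-driven replacement for interactive deletion of objects that
#' passed the filter but are not fibers. Unknown ids are reported with a
#' warning and ignored.
#'
#' @param mask integer fiber label matrix.
#' @param ids integer vector of labels to zero out.
#' @return the mask with the listed labels set to 0; other labels untouched.
#' @export
remove_objects <- function(mask, ids) {
  stopifnot(is.matrix(mask))
  ids <- as.integer(ids)
  if (length(ids) == 0L) return(mask)
  present <- unique(mask[mask > 0L])
  unknown <- setdiff(ids, present)
  if (length(unknown))
    warning("ignoring unknown label id(s): ", paste(unknown, collapse = ", "))
  mask[mask %in% ids] <- 0L
  mask
}
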