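# Extra-fiber object counting, designed for capillary density from an
# endothelial stain (PECAM) but applicable to any punctate channel. No size
# filtering is applied here by design: the exported per-object areas allow
# downstream filtering in a spreadsheet or in R.

#' Count and measure objects in a stain channel
#'
#' Smooths the channel (suppression of shallow bright extrema, as for
#' nuclei), thresholds it (Otsu over the pixel histogram by default) and
#' labels 8-connected components. Each object is reported with its area
#' (um^2) and centroid (x = column, y = row, pixels).
#'
#' @param channel object stain channel, numeric matrix 0-255.
#' @param smoothing suppression depth h in 8-bit units (>= 0).
#' @param pixel_size um per pixel.
#' @param threshold manual threshold in `[0, 255]`, or `NULL` for Otsu.
#' @return An `object_table`: list with `objects` (data.frame object,
#'   area_um2, centroid_x, centroid_y), `count`, `threshold`, and the
#'   `smoothed` and `binary` rasters for inspection.
#' @export
count_objects <- function(channel, smoothing, pixel_size, threshold = NULL) {
  stopifnot_gray(channel)
  sm <- suppress_maxima(channel, smoothing)
  if (is.null(threshold)) {
    if (length(unique(as.vector(sm))) < 2L)
      stop("constant channel: automatic thresholding impossible, ",
           "supply a manual threshold")
    threshold <- otsu_threshold(as.vector(sm))
  }
  binary <- sm > threshold
  lab <- cpp_label(binary, 8L)
  k <- max(lab)
  objects <- if (k == 0L) {
    data.frame(object = integer(), area_um2 = numeric(),
               centroid_x = numeric(), centroid_y = numeric())
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    nr <- nrow(lab)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    cnt <- tabulate(l, nbins = k)
    data.frame(object = seq_len(k),
               area_um2 = cnt * pixel_size^2,
               centroid_x = rowsum(as.numeric(cols), l)[, 1] / cnt,
               centroid_y = rowsum(as.numeric(rows), l)[, 1] / cnt)
  }
  structure(list(objects = objects, count = k, threshold = threshold,
                 smoothed = sm, binary = binary),
            class = "object_table")
}

#' @export
print.object_table <- function(x, ...) {
  cat(sprintf("<object_table> %d objects, threshold %.6g\n",
              x$count, x$threshold))
  if (x$count > 0) {
    cat(sprintf("  total object area %.4g um^2, mean %.4g um^2\n",
                sum(x$objects$area_um2), mean(x$objects$area_um2)))
  }
  invisible(x)
}

#' Four-panel diagnostic rendering of the object analysis
#'
#' Writes a single PNG with the original image, the raw object channel,
#' the smoothed channel, and the thresholded binary image.
#'
#' @param image the `section_image` analyzed.
#' @param result an `object_table` from [count_objects()].
#' @param path output `.png` path.
#' @param channel_index channel holding the object stain (defaults to the
#'   image's object role).
#' @export
render_objects <- function(image, result, path, channel_index = NULL) {
  stopifnot(inherits(result, "object_table"))
  ch <- get_channel(image, channel_index %||% image$roles$object)
  h <- nrow(ch); w <- ncol(ch)
  gray3 <- function(m) { a <- array(0, c(h, w, 3)); for (i in 1:3) a[, , i] <- m; a }
  top <- array(0, c(h, 2 * w, 3))
  top[, 1:w, ] <- image$pixels
  top[, (w + 1):(2 * w), ] <- gray3(ch)
  bottom <- array(0, c(h, 2 * w, 3))
  bottom[, 1:w, ] <- gray3(result$smoothed)
  bottom[, (w + 1):(2 * w), ] <- gray3(result$binary * 255)
  panel <- array(0, c(2 * h, 2 * w, 3))
  panel[1:h, , ] <- top
  panel[(h + 1):(2 * h), , ] <- bottom
  write_image_png(panel, path)
  invisible(path)
}

#' Write the object table with summary rows
#'
#' @param result an `object_table`.
#' @param path output `.csv` path.
#' @export
write_objects_csv <- function(result, path) {
  f <- result$objects
  f$object <- as.character(f$object)
  extra <- data.frame(object = c("COUNT", "TOTAL_AREA"),
                      area_um2 = c(NA_real_, sum(result$objects$area_um2)),
                      centroid_x = c(result$count, NA_real_),
                      centroid_y = NA_real_)
  utils::write.csv(rbind(f, extra), path, row.names = FALSE)
  invisible(path)
}
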