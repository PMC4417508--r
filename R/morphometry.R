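# Per-fiber geometry: centroid, cross-sectional area, and Feret (caliper)
# diameters from rotating calipers on the pixel-corner convex hull. The
# minimum Feret diameter is the field's preferred fiber-size measure because
# it is insensitive to oblique sectioning.

#' Feret (caliper) diameters of a pixel region
#'
#' Computes, on the convex hull of the region's pixel corners:
#' the maximum Feret diameter (largest pairwise hull-point distance), the
#' minimum Feret diameter (smallest caliper width over all rotation
#' angles, i.e. the width of the smallest bounding rectangle), and the
#' direction (radians, in `[0, pi)`, measured from the +x axis) along
#' which the minimal width is attained. A w-pixel-wide axis-aligned
#' rectangle has min Feret exactly w.
#'
#' @inheritParams region_eccentricity
#' @return named numeric vector `c(min_feret, max_feret, direction)` in
#'   pixel units / radians.
#' @export
feret_diameters <- function(region) {
  rc <- region_rc(region)
  feret_rc(rc$row, rc$col)
}

feret_rc <- function(row, col) {
  hull <- corner_hull(row, col)  # (x, y), convex, small
  n <- nrow(hull)
  d2 <- as.matrix(stats::dist(hull))
  max_feret <- max(d2)
  j <- c(2:n, 1L)
  ex <- hull[j, 1] - hull[, 1]
  ey <- hull[j, 2] - hull[, 2]
  len <- sqrt(ex^2 + ey^2)
  ok <- len > 0
  widths <- vapply(which(ok), function(i) {
    # distance of all vertices from the line through edge i
    max(abs((hull[, 1] - hull[i, 1]) * ey[i] -
            (hull[, 2] - hull[i, 2]) * ex[i]) / len[i])
  }, 0)
  k <- which.min(widths)
  i <- which(ok)[k]
  min_feret <- widths[k]
  # width is measured along the edge normal
  ang <- atan2(ex[i], -ey[i]) %% pi
  c(min_feret = min_feret, max_feret = max_feret, direction = ang)
}

#' Per-fiber morphometric properties
#'
#' One record per fiber label, ordered by ascending label: centroid (x =
#' column, y = row, pixels), maximum and minimum Feret diameter (um), Feret
#' direction (radians) and cross-sectional area (um^2, pixel count times
#' `pixel_size^2`).
#'
#' @param mask filtered integer fiber label matrix.
#' @param pixel_size um per pixel (> 0).
#' @return data.frame with columns label, centroid_x, centroid_y,
#'   max_feret, min_feret, feret_direction, area_um2.
#' @export
fiber_properties <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  sets <- label_pixel_sets(mask)
  empty <- data.frame(label = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), max_feret = numeric(),
                      min_feret = numeric(), feret_direction = numeric(),
                      area_um2 = numeric())
  if (length(sets) == 0L) {
    warning("mask contains no fibers")
    return(empty)
  }
  recs <- lapply(seq_along(sets), function(i) {
    rr <- sets[[i]]$row; cc <- sets[[i]]$col
    fer <- feret_rc(rr, cc)
    data.frame(label = as.integer(names(sets)[i]),
               centroid_x = mean(cc), centroid_y = mean(rr),
               max_feret = fer[["max_feret"]] * pixel_size,
               min_feret = fer[["min_feret"]] * pixel_size,
               feret_direction = fer[["direction"]],
               area_um2 = length(rr) * pixel_size^2)
  })
  out <- do.call(rbind, recs)
  out[order(out$label), , drop = FALSE]
}

#' Summary statistics over fiber records
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error
#' of the mean for every numeric property column. With a single fiber the
#' SD and SEM are reported as 0.
#'
#' @param records data.frame from [fiber_properties()] (or any data.frame
#'   of per-fiber numeric properties; a `label` column is ignored).
#' @return data.frame with one row per statistic (mean, sd, sem) and the
#'   fiber count as attribute `n`.
#' @export
summarize_fibers <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("no fibers to summarize")
  cols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)], "label")
  mu <- vapply(records[cols], mean, 0)
  s <- if (n == 1L) stats::setNames(rep(0, length(cols)), cols)
       else vapply(records[cols], stats::sd, 0)
  out <- rbind(mean = mu, sd = s, sem = s / sqrt(n))
  out <- as.data.frame(out)
  attr(out, "n") <- n
  out
}

#' Export per-fiber histograms of minimum Feret diameter and CSA
#'
#' Writes `<prefix>_MinFeret.png` and `<prefix>_CSA.png`. With an empty
#' record table no file is written and a warning is raised.
#'
#' @param records data.frame from [fiber_properties()].
#' @param prefix output path prefix.
#' @return character vector of paths written, invisibly.
#' @export
plot_fiber_histograms <- function(records, prefix) {
  if (nrow(records) == 0L) {
    warning("no fibers; no histogram written")
    return(invisible(character()))
  }
  paths <- paste0(prefix, c("_MinFeret.png", "_CSA.png"))
  open_png(paths[1])
  graphics::hist(records$min_feret, breaks = "FD", col = "steelblue",
                 main = "Minimum Feret diameter", xlab = "min Feret (um)")
  grDevices::dev.off()
  open_png(paths[2])
  graphics::hist(records$area_um2, breaks = "FD", col = "steelblue",
                 main = "Fiber cross-sectional area", xlab = "CSA (um^2)")
  grDevices::dev.off()
  invisible(paths)
}

# headless-safe png device
open_png <- function(path, width = 700, height = 500) {
  ok <- try(grDevices::png(path, width = width, height = height,
                           type = "cairo"), silent = TRUE)
  if (inherits(ok, "try-error"))
    grDevices::bitmap(path, width = width / 72, height = height / 72)
  invisible(NULL)
}

#' Write the fiber-properties table with summary rows
#'
#' CSV layout mirroring the published output: one row per fiber with the
#' six property columns, followed by mean / SD / SEM summary rows.
#'
#' @param records data.frame from [fiber_properties()].
#' @param path output `.csv` path.
#' @export
write_props_csv <- function(records, path) {
  tab <- records
  tab$label <- as.character(tab$label)
  if (nrow(records) > 0L) {
    s <- summarize_fibers(records)
    for (stat in rownames(s)) {
      row <- as.list(records[1, ])
      row$label <- toupper(stat)
      for (cn in names(s)) row[[cn]] <- s[stat, cn]
      for (cn in setdiff(names(records), c("label", names(s))))
        row[[cn]] <- NA
      tab <- rbind(tab, as.data.frame(row))
    }
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
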