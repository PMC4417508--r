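# Centrally nucleated fiber (CNF) detection: a fiber is called CNF when
# thresholded nuclear staining of at least a minimum area lies deeper than a
# border distance inside the fiber. Central nuclei mark regenerating fibers
# and are a standard readout of dystrophic muscle.

#' Central (border-eroded) region of every fiber
#'
#' For each fiber, keeps the pixels whose exact Euclidean distance to the
#' fiber's own boundary exceeds `border_distance` (um). The boundary is the
#' set of fiber pixels 8-adjacent to a different label, to background, or
#' to the image edge. Small fibers may lose their entire area, in which
#' case they can never be called CNF.
#'
#' @param mask integer fiber label matrix.
#' @param border_distance distance from the fiber border, um (>= 0).
#' @param pixel_size um per pixel.
#' @return integer label matrix of the central regions (subset of `mask`).
#' @export
central_region_mask <- function(mask, border_distance, pixel_size) {
  stopifnot(is.matrix(mask))
  if (border_distance < 0) stop("border_distance must be >= 0")
  if (border_distance == 0) return(mask)
  d_px <- border_distance / pixel_size
  bnd <- cpp_label_boundary(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  sets <- label_pixel_sets(mask)
  pad <- 1L
  for (i in seq_along(sets)) {
    L <- as.integer(names(sets)[i])
    rr <- sets[[i]]$row; cc <- sets[[i]]$col
    r0 <- max(1L, min(rr) - pad); r1 <- min(nrow(mask), max(rr) + pad)
    c0 <- max(1L, min(cc) - pad); c1 <- min(ncol(mask), max(cc) + pad)
    sub_lab <- mask[r0:r1, c0:c1, drop = FALSE]
    sub_bnd <- bnd[r0:r1, c0:c1, drop = FALSE] & sub_lab == L
    if (!any(sub_bnd)) next
    dist <- cpp_edt(sub_bnd)
    keep <- sub_lab == L & dist > d_px
    if (any(keep)) {
      sub_out <- out[r0:r1, c0:c1, drop = FALSE]
      sub_out[keep] <- L
      out[r0:r1, c0:c1] <- sub_out
    }
  }
  out
}

#' Detect nuclei in the nuclear channel
#'
#' Smooths the channel by suppressing local extrema shallower than
#' `smoothing` -- applied on the correct polarity for bright nuclei, i.e.
#' as h-maxima suppression, removing shallow bright artifacts such as DAPI
#' streaking -- then thresholds with Otsu's method over the pixel histogram
#' (user-overridable).
#'
#' @param channel nuclear stain channel, numeric matrix 0-255.
#' @param smoothing suppression depth h in 8-bit units (>= 0).
#' @param threshold manual threshold in `[0, 255]`, or `NULL` for Otsu.
#' @return list with `binary` (logical matrix of nuclear pixels),
#'   `threshold` used, and `smoothed` channel.
#' @export
detect_nuclei <- function(channel, smoothing, threshold = NULL) {
  stopifnot_gray(channel)
  sm <- suppress_maxima(channel, smoothing)
  if (is.null(threshold)) {
    if (length(unique(as.vector(sm))) < 2L)
      stop("constant channel: automatic thresholding impossible, ",
           "supply a manual threshold")
    threshold <- otsu_threshold(as.vector(sm))
  }
  list(binary = sm > threshold, threshold = threshold, smoothed = sm)
}

#' Call centrally nucleated fibers
#'
#' Per fiber, sums the thresholded nuclear pixels falling inside its
#' central region (aggregated over all such pixels) and calls the fiber
#' CNF when this central nuclear area is at least `min_nuclear_size` um^2.
#'
#' @param mask filtered integer fiber label matrix.
#' @param central central-region label matrix from [central_region_mask()].
#' @param nuclei logical matrix of nuclear pixels from [detect_nuclei()].
#' @param min_nuclear_size minimum central nuclear area, um^2.
#' @param pixel_size um per pixel.
#' @param threshold the nuclear threshold used (recorded in the result).
#' @return A `cnf_result`: list with `fibers` (data.frame label, area_um2,
#'   central_nuclear_area_um2, call), `threshold`, `percent_cnf` and
#'   `summary` (groups all/cnf/non_cnf).
#' @export
classify_cnf <- function(mask, central, nuclei, min_nuclear_size,
                         pixel_size, threshold = NA_real_) {
  if (!all(dim(mask) == dim(central)) || !all(dim(mask) == dim(nuclei)))
    stop("mask, central and nuclei shapes differ")
  idx <- which(mask > 0L)
  if (length(idx) == 0L) stop("mask contains no fibers")
  labs_all <- sort(unique(mask[idx]))
  ps2 <- pixel_size^2
  fib_area <- tabulate(mask[idx])[labs_all] * ps2
  cen_idx <- which(central > 0L & nuclei)
  nuc_area <- stats::setNames(rep(0, length(labs_all)), labs_all)
  if (length(cen_idx)) {
    agg <- rowsum(rep(ps2, length(cen_idx)), central[cen_idx])
    nuc_area[rownames(agg)] <- agg[, 1]
  }
  call <- as.integer(nuc_area >= min_nuclear_size)
  fibers <- data.frame(label = labs_all, area_um2 = fib_area,
                       central_nuclear_area_um2 = as.numeric(nuc_area),
                       call = call)
  grp <- function(sel, name) data.frame(
    group = name, n = sum(sel),
    mean_area_um2 = if (any(sel)) mean(fib_area[sel]) else NA_real_,
    mean_central_nuclear_area_um2 =
      if (any(sel)) mean(nuc_area[sel]) else NA_real_)
  structure(list(
    fibers = fibers,
    threshold = threshold,
    percent_cnf = 100 * sum(call) / length(call),
    summary = rbind(grp(rep(TRUE, length(call)), "all"),
                    grp(call == 1L, "cnf"),
                    grp(call == 0L, "non_cnf"))
  ), class = "cnf_result")
}

#' @export
print.cnf_result <- function(x, ...) {
  cat(sprintf("<cnf_result> %d fibers, %.1f%% CNF (nuclear threshold %s)\n",
              nrow(x$fibers), x$percent_cnf, format(x$threshold)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Full CNF analysis of a section image
#'
#' Convenience wrapper chaining [central_region_mask()], [detect_nuclei()]
#' and [classify_cnf()] with the relevant parameters.
#'
#' @param image a `section_image`.
#' @param mask filtered integer fiber label matrix.
#' @param params an `analysis_params` object.
#' @param threshold manual nuclear threshold, or `NULL` for Otsu.
#' @return A `cnf_result` (see [classify_cnf()]); the central-region and
#'   nuclei rasters are attached as attributes `central` and `nuclei`.
#' @export
cnf_analysis <- function(image, mask, params = default_params(),
                         threshold = NULL) {
  channel <- get_channel(image, params$nuclei_channel)
  central <- central_region_mask(mask, params$nuclear_border_distance,
                                 params$pixel_size)
  det <- detect_nuclei(channel, params$nuclear_smoothing, threshold)
  res <- classify_cnf(mask, central, det$binary, params$min_nuclear_size,
                      params$pixel_size, threshold = det$threshold)
  attr(res, "central") <- central
  attr(res, "nuclei") <- det$binary
  res
}

#' Diagnostic rendering of the CNF analysis
#'
#' Writes `<prefix>_Borders.png` (border ring red, nuclear pixels blue, so
#' peripheral nuclei appear purple) and `<prefix>_CNF.png` (CNF fibers
#' white on black).
#'
#' @param result a `cnf_result` from [cnf_analysis()].
#' @param mask the fiber mask the result was computed on.
#' @param prefix output path prefix.
#' @export
render_cnf <- function(result, mask, prefix) {
  central <- attr(result, "central")
  nuclei <- attr(result, "nuclei")
  if (is.null(central) || is.null(nuclei))
    stop("result lacks attached rasters; use cnf_analysis()")
  h <- nrow(mask); w <- ncol(mask)
  border_ring <- mask > 0L & central == 0L
  a <- array(0, dim = c(h, w, 3))
  a[, , 1][border_ring] <- 200
  a[, , 3][nuclei] <- 255
  p1 <- paste0(prefix, "_Borders.png")
  write_image_png(a, p1)
  cnf_labs <- result$fibers$label[result$fibers$call == 1L]
  b <- array(0, dim = c(h, w, 3))
  white <- mask %in% cnf_labs
  for (ch in 1:3) b[, , ch][white] <- 255
  p2 <- paste0(prefix, "_CNF.png")
  write_image_png(b, p2)
  invisible(c(p1, p2))
}

#' Write the CNF table with group summaries
#'
#' @param result a `cnf_result`.
#' @param path output `.csv` path.
#' @export
write_cnf_csv <- function(result, path) {
  f <- result$fibers
  f$label <- as.character(f$label)
  s <- result$summary
  extra <- data.frame(
    label = paste0("MEAN_", toupper(s$group)),
    area_um2 = s$mean_area_um2,
    central_nuclear_area_um2 = s$mean_central_nuclear_area_um2,
    call = NA_integer_)
  pct <- data.frame(label = "PERCENT_CNF", area_um2 = NA_real_,
                    central_nuclear_area_um2 = NA_real_,
                    call = result$percent_cnf)
  utils::write.csv(rbind(f, extra, pct), path, row.names = FALSE)
  invisible(path)
}
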