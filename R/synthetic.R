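# Ground-truthed synthetic immunofluorescent muscle sections. Fibers are
# cells of a Lloyd-relaxed Voronoi tessellation; the outline channel paints
# a bright membrane band along every inter-cell boundary over dark
# interiors, the type channel fills a chosen subset of fibers, the nuclei
# channel places one central disk per CNF fiber and peripheral disks
# elsewhere, and a serial "object section" carries bright capillary-like
# dots on the interstitial boundaries. Every random quantity is driven by
# the spec's seed, so a spec generates bit-identical data every time.

#' Specification of a synthetic muscle section
#'
#' Defaults describe a realistic full-thickness mouse-muscle field at the
#' published pixel scale: 0.645 um/px, ~2000 um^2 fibers, an 8-bit membrane
#' stain much brighter than the fiber interiors, 30% type-positive fibers,
#' 30% centrally nucleated fibers (a dystrophic-like prevalence), and mild
#' iid Gaussian camera noise (SD 2 intensity units) that stays well below
#' the default smoothing depth h = 5.
#'
#' @param size image side, pixels (square image).
#' @param pixel_size um per pixel.
#' @param n_fibers target number of Voronoi cells (fibers incl. edge cells).
#' @param boundary_intensity,boundary_width outline-band intensity (0-255)
#'   and full width in pixels.
#' @param interior_intensity fiber-interior intensity in the outline channel.
#' @param fraction_positive fraction of interior fibers stained positive in
#'   the type channel.
#' @param positive_intensity,negative_intensity type-channel intensities.
#' @param fraction_cnf fraction of interior fibers given a central nucleus.
#' @param nucleus_radius nuclear disk radius, pixels.
#' @param nucleus_intensity nuclei-channel disk intensity.
#' @param peripheral_nuclei place a peripheral nucleus on non-CNF fibers.
#' @param n_objects number of capillary-like dots in the object section.
#' @param object_radius,object_intensity object disk radius and intensity.
#' @param noise_sd iid Gaussian noise SD added to every channel (8-bit units).
#' @param streak_amplitude amplitude of soft streak artifacts added to the
#'   nuclei channel (0 disables; exercises the nuclear smoothing step).
#' @param seed integer seed fixing all randomness.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(size = 1024L, pixel_size = 0.645, n_fibers = 200L,
                         boundary_intensity = 220, boundary_width = 3,
                         interior_intensity = 30,
                         fraction_positive = 0.3,
                         positive_intensity = 180, negative_intensity = 10,
                         fraction_cnf = 0.3, nucleus_radius = 4,
                         nucleus_intensity = 200,
                         peripheral_nuclei = TRUE,
                         n_objects = 50L, object_radius = 2,
                         object_intensity = 200,
                         noise_sd = 2, streak_amplitude = 0,
                         seed = 1L) {
  spec <- list(size = as.integer(size), pixel_size = pixel_size,
               n_fibers = as.integer(n_fibers),
               boundary_intensity = boundary_intensity,
               boundary_width = boundary_width,
               interior_intensity = interior_intensity,
               fraction_positive = fraction_positive,
               positive_intensity = positive_intensity,
               negative_intensity = negative_intensity,
               fraction_cnf = fraction_cnf,
               nucleus_radius = nucleus_radius,
               nucleus_intensity = nucleus_intensity,
               peripheral_nuclei = isTRUE(peripheral_nuclei),
               n_objects = as.integer(n_objects),
               object_radius = object_radius,
               object_intensity = object_intensity,
               noise_sd = noise_sd,
               streak_amplitude = streak_amplitude,
               seed = as.integer(seed))
  for (f in c("fraction_positive", "fraction_cnf"))
    if (spec[[f]] < 0 || spec[[f]] > 1) stop(f, " must be in [0, 1]")
  for (f in c("boundary_intensity", "interior_intensity",
              "positive_intensity", "negative_intensity",
              "nucleus_intensity", "object_intensity"))
    if (spec[[f]] < 0 || spec[[f]] > 255) stop(f, " must be in [0, 255]")
  if (spec$noise_sd < 0 || spec$streak_amplitude < 0)
    stop("noise_sd and streak_amplitude must be >= 0")
  if (spec$size < 32L) stop("size must be >= 32")
  structure(spec, class = "section_spec")
}

#' Generate a synthetic section with ground truth
#'
#' Seeds `n_fibers` points, relaxes them by Lloyd iterations of the
#' discrete Voronoi tessellation, and renders the three stain channels plus
#' a serial object section (same outline and nuclei, object dots instead of
#' the type stain in the green channel -- mirroring the serial-section
#' staining used for capillary counting). Exact counts of positive and CNF
#' fibers are assigned among interior cells so truth fractions are
#' well-defined. Deterministic given `spec$seed`.
#'
#' @param spec a [section_spec()].
#' @return list of class `synthetic_section` with `image` (type/nuclei
#'   section), `object_image` (serial object section), `truth` (list:
#'   `labels` full Voronoi label map, `fibers` per-fiber data.frame with
#'   area_px, centroid, interior flag, type_positive, cnf, and `objects`
#'   data.frame of dot centroids), and `spec`.
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$size
  K <- spec$n_fibers
  if (K > (n / 8)^2) stop("infeasible packing: too many fibers for the image size")
  if (K < 1L) stop("need at least one fiber")
  # Lloyd-relaxed discrete Voronoi tessellation
  sr <- runif(K, 1, n); sc <- runif(K, 1, n)
  # Lloyd relaxation on a half-resolution grid (cell geometry only)
  n2 <- max(2L, n %/% 2L)
  sum_by <- function(v, g) { # group sums over labels 1..K, absent -> 0
    out <- numeric(K)
    a <- rowsum(v, g)
    out[as.integer(rownames(a))] <- a[, 1]
    out
  }
  for (it in 1:4) {
    lab2 <- cpp_nearest_seed(n2, n2, sr / 2, sc / 2)
    idx2 <- seq_along(lab2)
    l2 <- as.vector(lab2)
    cnt2 <- pmax(tabulate(l2, nbins = K), 1L)
    rows2 <- ((idx2 - 1L) %% n2) + 1L
    cols2 <- ((idx2 - 1L) %/% n2) + 1L
    sr <- pmax(2 * sum_by(as.numeric(rows2), l2) / cnt2, 1)
    sc <- pmax(2 * sum_by(as.numeric(cols2), l2) / cnt2, 1)
  }
  labels <- cpp_nearest_seed(n, n, sr, sc)
  # drop any cell that ended up empty and renumber compactly
  cnt0 <- tabulate(labels, nbins = K)
  if (any(cnt0 == 0L)) {
    remap <- cumsum(cnt0 > 0L)
    labels <- matrix(remap[labels], n, n)
    K <- max(labels)
  }
  # membrane band along inter-cell boundaries (not the image edge)
  transition <- matrix(FALSE, n, n)
  transition[-n, ] <- transition[-n, ] | labels[-n, ] != labels[-1, ]
  transition[, -n] <- transition[, -n] | labels[, -n] != labels[, -1]
  transition[-1, ] <- transition[-1, ] | labels[-1, ] != labels[-n, ]
  transition[, -1] <- transition[, -1] | labels[, -1] != labels[, -n]
  depth <- cpp_edt(transition)  # distance to nearest inter-cell boundary
  band <- depth <= spec$boundary_width / 2
  noise <- function() if (spec$noise_sd > 0)
    matrix(rnorm(n * n, 0, spec$noise_sd), n, n) else 0
  outline <- matrix(spec$interior_intensity, n, n)
  outline[band] <- spec$boundary_intensity
  outline <- clamp8(outline + noise())
  # per-fiber truth
  cnt <- tabulate(labels, nbins = K)
  idx <- which(labels > 0L)
  l <- labels[idx]
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  cx <- rowsum(as.numeric(cols), l)[, 1] / cnt
  cy <- rowsum(as.numeric(rows), l)[, 1] / cnt
  edge_labs <- unique(c(labels[1, ], labels[n, ], labels[, 1], labels[, n]))
  interior <- !(seq_len(K) %in% edge_labs)
  n_int <- sum(interior)
  if (n_int == 0L) stop("infeasible packing: no interior fibers")
  pixels_by_label <- split(idx, l)
  pole <- rep(NA_integer_, K)  # linear index of deepest pixel per cell
  dmax <- rep(0, K)
  for (L in seq_len(K)) {
    sel <- pixels_by_label[[L]]
    pole[L] <- sel[which.max(depth[sel])]
    dmax[L] <- depth[pole[L]]
  }
  # fiber types: exact count among interior cells, Bernoulli on edge cells
  type_pos <- logical(K)
  n_pos <- round(spec$fraction_positive * n_int)
  if (n_pos > 0)
    type_pos[sample(which(interior), n_pos)] <- TRUE
  if (any(!interior))
    type_pos[!interior] <- runif(sum(!interior)) < spec$fraction_positive
  # CNF flags: exact count among interior cells deep enough to host a
  # clearly central nucleus
  border_px <- 10 / spec$pixel_size  # evaluated against the default border distance
  cnf <- logical(K)
  candidates <- which(interior & dmax > border_px + spec$nucleus_radius + 2)
  n_cnf <- round(spec$fraction_cnf * n_int)
  if (n_cnf > length(candidates))
    stop("infeasible packing: not enough deep interior fibers for ",
         n_cnf, " CNFs")
  if (n_cnf > 0) cnf[sample(candidates, n_cnf)] <- TRUE
  # type channel
  type_ch <- matrix(spec$negative_intensity, n, n)
  if (any(type_pos)) {
    fill <- !band & matrix(type_pos[labels], n, n)
    type_ch[fill] <- spec$positive_intensity
  }
  type_ch <- clamp8(type_ch + noise())
  # nuclei channel: central disk for CNFs at the cell's deepest point,
  # peripheral disk (centered on the membrane band) otherwise
  nuc <- matrix(8, n, n)
  centers <- integer(0)
  for (L in seq_len(K)) {
    if (cnf[L]) {
      centers <- c(centers, pole[L])
    } else if (spec$peripheral_nuclei) {
      sel <- pixels_by_label[[L]]
      on_band <- sel[band[sel]]
      if (length(on_band))
        centers <- c(centers, on_band[sample.int(length(on_band), 1L)])
    }
  }
  rad <- spec$nucleus_radius
  for (p in centers) {
    r0 <- ((p - 1L) %% n) + 1L; c0 <- ((p - 1L) %/% n) + 1L
    rr <- max(1L, floor(r0 - rad)):min(n, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(n, ceiling(c0 + rad))
    sub <- outer(rr - r0, cc - c0, function(a, b) a * a + b * b) <= rad^2
    block <- nuc[rr, cc]
    block[sub] <- spec$nucleus_intensity
    nuc[rr, cc] <- block
  }
  if (spec$streak_amplitude > 0) {
    # soft linear streaks: a few gaussian-profile bands at random angles
    xs <- matrix(rep(seq_len(n), each = n), n, n)
    ys <- matrix(rep(seq_len(n), times = n), n, n)
    for (s in 1:4) {
      th <- runif(1, 0, pi)
      off <- runif(1, 0, n)
      d <- (xs * cos(th) + ys * sin(th)) %% n - off
      nuc <- nuc + spec$streak_amplitude * exp(-d^2 / (2 * 12^2))
    }
  }
  nuc <- clamp8(nuc + noise())
  # object dots on the interstitial boundaries, kept well separated
  obj_ch <- matrix(5, n, n)
  obj_xy <- data.frame(x = numeric(0), y = numeric(0))
  if (spec$n_objects > 0L) {
    margin <- spec$object_radius + 2
    cand <- which(band)
    crow <- ((cand - 1L) %% n) + 1L
    ccol <- ((cand - 1L) %/% n) + 1L
    inb <- crow > margin & crow <= n - margin & ccol > margin & ccol <= n - margin
    cand <- cand[inb]; crow <- crow[inb]; ccol <- ccol[inb]
    ord <- sample.int(length(cand))
    min_sep <- 6 * spec$object_radius + 4
    keep_r <- numeric(0); keep_c <- numeric(0)
    for (i in ord) {
      if (length(keep_r) >= spec$n_objects) break
      if (length(keep_r) == 0L ||
          min((keep_r - crow[i])^2 + (keep_c - ccol[i])^2) >= min_sep^2) {
        keep_r <- c(keep_r, crow[i]); keep_c <- c(keep_c, ccol[i])
      }
    }
    if (length(keep_r) < spec$n_objects)
      stop("infeasible packing: cannot place ", spec$n_objects,
           " separated objects")
    for (i in seq_along(keep_r))
      obj_ch <- draw_disk(obj_ch, keep_r[i], keep_c[i], spec$object_radius,
                          spec$object_intensity)
    obj_xy <- data.frame(x = keep_c, y = keep_r)
  }
  obj_ch <- clamp8(obj_ch + noise())
  to_img <- function(g) { # assemble R/G/B planes
    a <- array(0L, dim = c(n, n, 3))
    a[, , 1] <- outline; a[, , 2] <- g; a[, , 3] <- nuc
    storage.mode(a) <- "integer"
    section_image(a, pixel_size = spec$pixel_size, roles = channel_roles())
  }
  fibers <- data.frame(label = seq_len(K), area_px = as.integer(cnt),
                       centroid_x = unname(cx), centroid_y = unname(cy),
                       interior = interior, type_positive = type_pos,
                       cnf = cnf)
  rownames(fibers) <- NULL
  truth <- list(labels = labels, fibers = fibers, objects = obj_xy)
  structure(list(image = to_img(type_ch), object_image = to_img(obj_ch),
                 truth = truth, spec = spec),
            class = "synthetic_section")
}

#' @export
print.synthetic_section <- function(x, ...) {
  tf <- x$truth$fibers
  cat(sprintf(paste0("<synthetic_section> %d x %d px, %d fibers ",
                     "(%d interior), %d objects, seed %d\n"),
              x$spec$size, x$spec$size, nrow(tf), sum(tf$interior),
              nrow(x$truth$objects), x$spec$seed))
  invisible(x)
}

#' Write / read ground truth files
#'
#' Persists the truth label map as a 16/32-bit TIFF plus the per-fiber and
#' object tables as CSV; `read_ground_truth()` round-trips them.
#'
#' @param truth the `truth` element of a [generate_section()] result.
#' @param dir output directory (created if missing).
#' @param basename file stem for the three files.
#' @return file paths (write) or a truth list (read).
#' @export
write_ground_truth <- function(truth, dir, basename = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_lab <- file.path(dir, paste0(basename, "_labels.tif"))
  p_fib <- file.path(dir, paste0(basename, "_fibers.csv"))
  p_obj <- file.path(dir, paste0(basename, "_objects.csv"))
  write_mask(truth$labels, p_lab)
  utils::write.csv(truth$fibers, p_fib, row.names = FALSE)
  utils::write.csv(truth$objects, p_obj, row.names = FALSE)
  invisible(c(p_lab, p_fib, p_obj))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir, basename = "truth") {
  fib <- utils::read.csv(file.path(dir, paste0(basename, "_fibers.csv")))
  fib$interior <- as.logical(fib$interior)
  fib$type_positive <- as.logical(fib$type_positive)
  fib$cnf <- as.logical(fib$cnf)
  list(labels = read_mask(file.path(dir, paste0(basename, "_labels.tif"))),
       fibers = fib,
       objects = utils::read.csv(file.path(dir, paste0(basename,
                                                       "_objects.csv"))))
}

#' Match segmented fibers to ground-truth cells
#'
#' For every positive label of `mask`, finds the truth label with the
#' largest pixel overlap.
#'
#' @param mask segmented integer label matrix.
#' @param truth_labels ground-truth label matrix of the same shape.
#' @return named integer vector: names = mask labels, values = truth labels.
#' @export
match_to_truth <- function(mask, truth_labels) {
  if (!all(dim(mask) == dim(truth_labels))) stop("shapes differ")
  sel <- mask > 0L & truth_labels > 0L
  pair <- paste(mask[sel], truth_labels[sel])
  tab <- table(pair)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  df <- data.frame(seg = as.integer(parts[, 1]),
                   tru = as.integer(parts[, 2]),
                   n = as.integer(tab))
  df <- df[order(df$seg, -df$n, df$tru), ]
  best <- df[!duplicated(df$seg), ]
  stats::setNames(best$tru, best$seg)
}
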