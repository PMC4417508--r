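`%||%` <- function(a, b) if (is.null(a)) b else a

clamp8 <- function(x) pmin(pmax(round(x), 0), 255)

stopifnot_gray <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("expected a single-channel raster (numeric matrix)", call. = FALSE)
}

# linear pixel indices of an 8-connected Bresenham segment (r0,c0)-(r1,c1)
bresenham <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 <  dc) { err <- err + dc; r <- r + sr }
  }
  out
}

# stamp a filled disk of pixel centers into `mat`
draw_disk <- function(mat, r0, c0, radius, value) {
  rr <- max(1L, floor(r0 - radius)):min(nrow(mat), ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(ncol(mat), ceiling(c0 + radius))
  sub <- outer(rr - r0, cc - c0, function(a, b) a * a + b * b) <= radius^2
  mat[rr, cc][sub] <- value
  mat
}

# split positive-label pixels into per-label (row, col) lists
label_pixel_sets <- function(mask) {
  idx <- which(mask > 0L)
  if (length(idx) == 0L) return(list())
  labs <- mask[idx]
  nr <- nrow(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  ord <- order(labs)
  split(data.frame(row = rows[ord], col = cols[ord]), labs[ord])
}

# coerce a region argument (logical matrix or 2-column row/col matrix) to
# row/col vectors
region_rc <- function(region) {
  if (is.matrix(region) && is.logical(region)) {
    idx <- which(region)
    if (length(idx) == 0L) stop("empty region", call. = FALSE)
    nr <- nrow(region)
    list(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
  } else if ((is.matrix(region) || is.data.frame(region)) && ncol(region) == 2L) {
    if (nrow(region) == 0L) stop("empty region", call. = FALSE)
    region <- as.matrix(region)
    list(row = as.numeric(region[, 1]), col = as.numeric(region[, 2]))
  } else stop("region must be a logical matrix or a 2-column (row, col) matrix",
              call. = FALSE)
}

# convex hull (x = col, y = row) of the pixel-corner cloud of a region;
# returns hull vertices counter-clockwise as a 2-column matrix (x, y)
corner_hull <- function(row, col) {
  # boundary pixels suffice for the hull; cheap 4-neighbour test
  if (length(row) > 400L) {
    set <- unique(complex(real = col, imaginary = row))
    inside <- function(r, c) complex(real = c, imaginary = r) %in% set
    keep <- !(inside(row - 1L, col) & inside(row + 1L, col) &
              inside(row, col - 1L) & inside(row, col + 1L))
    row <- row[keep]; col <- col[keep]
  }
  x <- c(col - 0.5, col + 0.5, col - 0.5, col + 0.5)
  y <- c(row - 0.5, row - 0.5, row + 0.5, row + 0.5)
  pts <- unique(cbind(x, y))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

# shoelace area of a polygon given as 2-column matrix
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}
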