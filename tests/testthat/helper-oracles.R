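# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use direct definitions (gift-wrapping, exhaustive
# scans, iterative reconstruction) rather than the package's algorithms.

# ---- raster fixtures ------------------------------------------------------

raster_disk <- function(radius, size = 2 * radius + 9, cr = NULL, cc = NULL) {
  cr <- cr %||% ((size + 1) / 2); cc <- cc %||% ((size + 1) / 2)
  m <- matrix(FALSE, size, size)
  m[(row(m) - cr)^2 + (col(m) - cc)^2 <= radius^2] <- TRUE
  m
}

raster_rect <- function(nrow_px, ncol_px, size_r = nrow_px + 10,
                        size_c = ncol_px + 10, at_r = 6, at_c = 6) {
  m <- matrix(FALSE, size_r, size_c)
  m[at_r:(at_r + nrow_px - 1), at_c:(at_c + ncol_px - 1)] <- TRUE
  m
}

raster_ellipse <- function(a, b, size = 2 * max(a, b) + 9) {
  ctr <- (size + 1) / 2
  m <- matrix(FALSE, size, size)
  m[((row(m) - ctr) / b)^2 + ((col(m) - ctr) / a)^2 <= 1] <- TRUE
  m
}

rc_of <- function(region) {
  idx <- which(region)
  nr <- nrow(region)
  list(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

# random convex raster: rasterize a random convex polygon
random_convex_raster <- function(size = 48, npts = 12) {
  pts <- cbind(runif(npts, 4, size - 3), runif(npts, 4, size - 3))
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  m <- matrix(FALSE, size, size)
  rr <- row(m); cc <- col(m)
  inside <- rep(TRUE, length(rr))
  n <- nrow(poly)
  for (i in seq_len(n)) {       # chull returns clockwise order
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    inside <- inside & ((cc - poly[i, 1]) * ey - (rr - poly[i, 2]) * ex >= 0)
  }
  m[inside] <- TRUE
  m
}

# ---- geometry oracles -----------------------------------------------------

# gift-wrapping (Jarvis march) convex hull of a point cloud
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- 1L
    for (k in seq_len(n)) {
      if (k == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_cand <- sum((pts[cand, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cand == cur || cr < 0 || (cr == 0 && d_k > d_cand)) cand <- k
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stop("gift wrap failed")
  }
  pts[hull, , drop = FALSE]
}

oracle_polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# convexity by direct definition: pixel count / gift-wrapped corner-hull area
oracle_convexity <- function(region) {
  rc <- rc_of(region)
  pts <- cbind(c(rc$col - 0.5, rc$col + 0.5, rc$col - 0.5, rc$col + 0.5),
               c(rc$row - 0.5, rc$row - 0.5, rc$row + 0.5, rc$row + 0.5))
  length(rc$row) / oracle_polygon_area(oracle_hull(pts))
}

# eccentricity by direct second-moment definition (unit-square pixels)
oracle_eccentricity <- function(region) {
  rc <- rc_of(region)
  x <- rc$col; y <- rc$row; n <- length(x)
  uxx <- sum((x - mean(x))^2) / n + 1 / 12
  uyy <- sum((y - mean(y))^2) / n + 1 / 12
  uxy <- sum((x - mean(x)) * (y - mean(y))) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major2 <- 8 * (uxx + uyy + common)
  minor2 <- 8 * max(uxx + uyy - common, 0)
  sqrt(max(major2 - minor2, 0) / major2)
}

# Feret oracle: caliper sweep over a fine angle grid on all pixel corners
oracle_feret <- function(region, step_deg = 0.1) {
  rc <- rc_of(region)
  x <- c(rc$col - 0.5, rc$col + 0.5, rc$col - 0.5, rc$col + 0.5)
  y <- c(rc$row - 0.5, rc$row - 0.5, rc$row + 0.5, rc$row + 0.5)
  th <- seq(0, pi, by = step_deg * pi / 180)
  proj <- outer(x, cos(th)) + outer(y, sin(th))
  widths <- apply(proj, 2, function(v) max(v) - min(v))
  list(min_feret = min(widths), max_feret = max(widths),
       min_angle = th[which.min(widths)])
}

# ---- intensity oracles ----------------------------------------------------

# exhaustive Otsu: minimize within-class variance over all 256 candidate
# thresholds of the floored 8-bit histogram
oracle_otsu <- function(values) {
  bins <- pmin(floor(values), 255)
  best_t <- NA_integer_; best_v <- Inf
  for (t in 0:255) {
    lo <- bins[bins <= t]; hi <- bins[bins > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    v <- length(lo) * pvar(lo) + length(hi) * pvar(hi)
    if (v < best_v - 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}
pvar <- function(x) if (length(x) <= 1L) 0 else mean((x - mean(x))^2)

# ---- morphology oracles ---------------------------------------------------

# naive grayscale reconstruction by dilation (iterate to fixpoint), 8-conn
oracle_reconstruct <- function(marker, mask) {
  cur <- pmin(marker, mask)
  repeat {
    d <- dilate8(cur)
    nxt <- pmin(d, mask)
    if (all(nxt == cur)) return(cur)
    cur <- nxt
  }
}
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- m
  for (dr in 0:2) for (dc in 0:2)
    out <- pmax(out, pad[(1:nr) + dr, (1:nc) + dc])
  out
}
# textbook h-minima (uniformly raises surviving minima by up to h)
oracle_hminima_textbook <- function(im, h) -oracle_reconstruct(-im - h, -im)

# naive regional minima via the depth-epsilon fill (integer images)
oracle_regional_minima <- function(im) oracle_hminima_textbook(im, 1) - im > 0

# depth-preserving minima suppression: fill shallow minima only, keep deep
# minima at original values (naive composition, independent of the C++ path)
oracle_hminima <- function(im, h) {
  filled <- oracle_hminima_textbook(im, h)
  keep <- oracle_regional_minima(filled)
  marker <- matrix(max(im), nrow(im), ncol(im))
  marker[keep] <- im[keep]
  -oracle_reconstruct(-marker, -im)
}

# brute-force exact EDT to the nearest TRUE pixel
oracle_edt <- function(features) {
  idx <- which(features)
  nr <- nrow(features)
  fr <- ((idx - 1L) %% nr) + 1L
  fc <- ((idx - 1L) %/% nr) + 1L
  out <- matrix(Inf, nr, ncol(features))
  for (r in seq_len(nr)) for (c in seq_len(ncol(features)))
    out[r, c] <- sqrt(min((fr - r)^2 + (fc - c)^2))
  out
}
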