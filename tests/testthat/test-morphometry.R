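test_that("Feret diameters match closed forms on canonical shapes", {
  # 30 x 40 px rectangle (30 wide, 40 tall): min 30, max 50, direction 0
  f <- feret_diameters(raster_rect(40, 30))
  expect_equal(f[["min_feret"]], 30)
  expect_equal(f[["max_feret"]], 50)
  expect_equal(f[["direction"]], 0)
  # filled disk: min ~ max ~ 2r
  fd <- feret_diameters(raster_disk(20))
  expect_equal(fd[["min_feret"]], 40, tolerance = 0.05)
  expect_equal(fd[["max_feret"]], 40, tolerance = 0.05)
  # single pixel: unit-square corners -> min 1, max = diagonal sqrt(2)
  fp <- feret_diameters(raster_rect(1, 1))
  expect_equal(fp[["min_feret"]], 1)
  expect_equal(fp[["max_feret"]], sqrt(2))
  expect_error(feret_diameters(matrix(FALSE, 2, 2)), "empty")
})

test_that("Feret values agree with the angle-sweep oracle on random shapes", {
  set.seed(11)
  for (rep in 1:10) {
    m <- random_convex_raster(sample(20:64, 1))
    if (sum(m) < 4) next
    f <- feret_diameters(m)
    o <- oracle_feret(m)
    expect_lt(abs(f[["min_feret"]] - o$min_feret) / o$min_feret, 0.005)
    expect_lt(abs(f[["max_feret"]] - o$max_feret) / o$max_feret, 0.005)
    expect_true(f[["min_feret"]] <= f[["max_feret"]])
    expect_true(f[["min_feret"]] >= 1)
    expect_true(f[["direction"]] >= 0 && f[["direction"]] < pi)
  }
})

test_that("Feret and area are rotation invariant", {
  set.seed(13)
  m <- random_convex_raster(48)
  f0 <- feret_diameters(m)
  # 90 degree rotation: exact invariance
  m90 <- t(m)[ncol(m):1, ]
  f90 <- feret_diameters(m90)
  expect_equal(f90[["min_feret"]], f0[["min_feret"]])
  expect_equal(f90[["max_feret"]], f0[["max_feret"]])
  expect_identical(sum(m90), sum(m))
  # arbitrary rotation: rasterize the same ellipse at two angles, invariant
  # within 2% raster error
  # pixel-corner widths carry a ~(|cos|+|sin|) px footprint term, so the
  # shape must be large for the 2% raster-error bound to be meaningful
  ell <- function(th, a = 80, b = 50, size = 180) {
    ctr <- (size + 1) / 2
    g <- matrix(FALSE, size, size)
    dx <- col(g) - ctr; dy <- row(g) - ctr
    g[((dx * cos(th) + dy * sin(th)) / a)^2 +
      ((-dx * sin(th) + dy * cos(th)) / b)^2 <= 1] <- TRUE
    g
  }
  fa <- feret_diameters(ell(0))
  fb <- feret_diameters(ell(0.61))
  expect_equal(fb[["min_feret"]], fa[["min_feret"]], tolerance = 0.02)
  expect_equal(fb[["max_feret"]], fa[["max_feret"]], tolerance = 0.02)
  expect_equal(sum(ell(0.61)), sum(ell(0)), tolerance = 0.02)
})

test_that("fiber_properties scales lengths and areas by pixel size", {
  m <- matrix(0L, 30, 30)
  m[10:19, 10:19] <- 1L  # 10x10 square
  rec <- fiber_properties(m, pixel_size = 1)
  expect_equal(rec$area_um2, 100)
  expect_equal(rec$min_feret, 10)
  expect_equal(rec$max_feret, 10 * sqrt(2))
  expect_equal(rec$centroid_x, 14.5)
  expect_equal(rec$centroid_y, 14.5)
  rec2 <- fiber_properties(m, pixel_size = 0.645)
  expect_equal(rec2$area_um2, 100 * 0.645^2)
  expect_equal(rec2$min_feret, 10 * 0.645)
  # three fibers -> three records, ascending labels
  m[2:4, 2:4] <- 5L; m[25:28, 25:28] <- 3L
  rec3 <- fiber_properties(m, 1)
  expect_identical(rec3$label, c(1L, 3L, 5L))
  # area conservation: sum of pixel areas = count of positive pixels
  expect_identical(sum(rec3$area_um2), as.numeric(sum(m > 0)))
  expect_warning(out <- fiber_properties(matrix(0L, 5, 5), 1), "no fibers")
  expect_identical(nrow(out), 0L)
})

test_that("summaries use sample SD and SEM = SD/sqrt(n)", {
  rec <- data.frame(area_um2 = c(90, 110))
  s <- summarize_fibers(rec)
  expect_equal(s["mean", "area_um2"], 100)
  expect_equal(s["sd", "area_um2"], sqrt(200), tolerance = 1e-12)  # 14.142
  expect_equal(s["sem", "area_um2"], 10)
  expect_identical(attr(s, "n"), 2L)
  # single fiber: SD and SEM reported as 0
  s1 <- summarize_fibers(data.frame(area_um2 = 100))
  expect_identical(s1["sd", "area_um2"], 0)
  expect_identical(s1["sem", "area_um2"], 0)
  # order invariance
  rec4 <- data.frame(area_um2 = c(5, 1, 9, 2))
  expect_equal(summarize_fibers(rec4), summarize_fibers(rec4[c(3, 1, 4, 2), , drop = FALSE]))
  expect_error(summarize_fibers(data.frame(area_um2 = numeric())), "no fibers")
})

test_that("histograms and the props CSV are written", {
  d <- withr::local_tempdir()
  m <- matrix(0L, 40, 40)
  m[5:14, 5:14] <- 1L; m[20:31, 20:33] <- 2L
  rec <- fiber_properties(m, 0.645)
  paths <- plot_fiber_histograms(rec, file.path(d, "sec"))
  expect_true(all(file.exists(paths)))
  expect_warning(plot_fiber_histograms(rec[0, ], file.path(d, "empty")),
                 "no fibers")
  csv <- write_props_csv(rec, file.path(d, "sec_Props.csv"))
  tab <- read.csv(csv)
  expect_identical(nrow(tab), nrow(rec) + 3L)  # fibers + mean/sd/sem rows
  expect_identical(tab$label[nrow(rec) + 1L], "MEAN")
  expect_equal(tab$area_um2[nrow(rec) + 1L], mean(rec$area_um2))
})
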