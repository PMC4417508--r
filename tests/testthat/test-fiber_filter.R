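test_that("eccentricity matches the analytic shape statements", {
  # filled circle radius 100 -> 0 within discretization tolerance
  expect_lt(region_eccentricity(raster_disk(100)), 0.05)
  # 1-px-wide 100-px line -> ~1
  expect_gt(region_eccentricity(raster_rect(1, 100)), 0.99)
  # filled ellipse with a = 2b -> sqrt(1 - b^2/a^2) = sqrt(0.75)
  expect_equal(region_eccentricity(raster_ellipse(60, 30)), sqrt(0.75),
               tolerance = 0.01)
  expect_error(region_eccentricity(matrix(FALSE, 3, 3)), "empty")
})

test_that("convexity matches the pixel-corner hull definition", {
  # filled convex lattice-aligned shapes score exactly 1
  expect_identical(region_convexity(raster_rect(40, 40)), 1)
  expect_identical(region_convexity(raster_rect(3, 17)), 1)
  # single pixel is degenerate convex
  expect_identical(region_convexity(raster_rect(1, 1)), 1)
  # plus-sign of five unit squares: hull is the area-7 octagon
  plus <- matrix(FALSE, 5, 5)
  plus[2:4, 2:4] <- TRUE; plus[c(2, 4), c(2, 4)] <- FALSE
  expect_equal(region_convexity(plus), 5 / 7)
  expect_equal(oracle_convexity(plus), 5 / 7)
  # rasterized disk: slightly below 1 (staircase corners cut by the hull),
  # dual-route check against the gift-wrapping oracle
  d50 <- raster_disk(50)
  expect_equal(region_convexity(d50), oracle_convexity(d50), tolerance = 1e-12)
  expect_lt(region_convexity(d50), 1)
  expect_gt(region_convexity(d50), 0.95)
  expect_error(region_convexity(matrix(FALSE, 2, 2)), "empty")
})

test_that("shape measures agree with brute-force oracles on random masks", {
  set.seed(7)
  for (rep in 1:8) {
    m <- random_convex_raster(sample(24:64, 1))
    if (!any(m)) next
    expect_equal(region_eccentricity(m), oracle_eccentricity(m),
                 tolerance = 1e-9)
    expect_equal(region_convexity(m), oracle_convexity(m), tolerance = 1e-9)
  }
})

test_that("fiber filter applies rules in fixed order with inclusive bounds", {
  p <- default_params()
  nr <- 120; nc <- 160
  m <- matrix(0L, nr, nc)
  m[1:6, 40:60] <- 1L                       # touches row 1 -> edge
  m[20:29, 20:29] <- 2L                     # 100 px -> 41.6 um^2 -> too_small
  m[40:79, 40:79] <- 3L                     # 40x40 -> 666 um^2, kept
  m[90:92, 10:150] <- 4L                    # long bar -> eccentricity
  plus_at <- function(m, r, c, arm, th, lab) {  # thick plus: low convexity
    m[(r - arm):(r + arm), (c - th):(c + th)] <- lab
    m[(r - th):(r + th), (c - arm):(c + arm)] <- lab
    m
  }
  m <- plus_at(m, 30, 120, 24, 7, 5L)
  res <- filter_fibers(m, p)
  r <- res$report
  expect_identical(r$reason[r$label == 1L], "edge")
  expect_identical(r$reason[r$label == 2L], "too_small")
  expect_true(r$kept[r$label == 3L])
  expect_identical(r$reason[r$label == 4L], "eccentricity")
  expect_identical(r$reason[r$label == 5L], "convexity")
  expect_equal(r$area_um2[r$label == 2L], 100 * 0.645^2)
  # exactly one reason per rejected label; kept labels satisfy all rules
  expect_true(all(is.na(r$reason) == r$kept))
  expect_true(all(r$area_um2[r$kept] >= p$min_fiber_area &
                  r$area_um2[r$kept] <= p$max_fiber_area))
  expect_true(all(r$eccentricity[r$kept] <= p$max_eccentricity))
  expect_true(all(r$convexity[r$kept] >= p$min_convexity))
  # output mask contains exactly the kept labels, pixels unchanged
  expect_identical(sort(unique(res$mask[res$mask > 0])), r$label[r$kept])
  expect_identical(res$mask == 3L, m == 3L)
  # filtering is idempotent
  res2 <- filter_fibers(res$mask, p)
  expect_identical(res2$mask, res$mask)
  expect_true(all(res2$report$kept))
  # too_large: oversized square on a big canvas
  big <- matrix(0L, 200, 200)
  big[30:160, 30:160] <- 9L   # 131^2 px * 0.416 um^2 >> 5000
  expect_identical(filter_fibers(big, p)$report$reason, "too_large")
  p_bad <- p; p_bad$pixel_size <- NULL
  expect_error(filter_fibers(m, p_bad), "pixel_size")
})

test_that("manual object removal zeroes listed labels only", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:3] <- 1L; m[5:6, 5:6] <- 2L; m[8:9, 8:9] <- 3L
  expect_identical(remove_objects(m, integer(0)), m)
  out <- remove_objects(m, 2L)
  expect_identical(sort(unique(out[out > 0])), c(1L, 3L))
  expect_identical(out == 1L, m == 1L)
  all_gone <- remove_objects(m, 1:3)
  expect_identical(max(all_gone), 0L)
  expect_warning(remove_objects(m, c(1L, 99L)), "99")
})
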