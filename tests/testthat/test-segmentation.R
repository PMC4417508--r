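test_that("h-minima suppression matches the reconstruction oracle", {
  # worked 1-D profile: shallow minimum (8, depth 2) fills to 10, the deep
  # minimum (3, depth 7) survives untouched
  prof <- matrix(c(10, 8, 10, 3, 10), nrow = 1)
  out <- suppress_minima(prof, 5)
  expect_equal(out, oracle_hminima(prof, 5))
  expect_equal(as.vector(out), c(10, 10, 10, 3, 10))
  # identity at h = 0; constant image unchanged at any depth
  expect_identical(suppress_minima(prof, 0), prof)
  cst <- matrix(7, 9, 9)
  expect_equal(suppress_minima(cst, 20), cst)
  expect_error(suppress_minima(prof, -1), "depth")
})

test_that("h-minima properties hold on random rasters", {
  set.seed(42)
  for (rep in 1:6) {
    im <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
    h <- sample(c(1, 3, 10, 40), 1)
    out <- suppress_minima(im, h)
    expect_true(all(out >= im))                       # pointwise >= input
    expect_equal(suppress_minima(out, h), out)        # idempotent
    expect_equal(out, oracle_hminima(im, h))          # matches naive oracle
  }
})

test_that("watershed labels basins and ridge pixels as specified", {
  # two dark disks separated by bright ground -> exactly 2 labels
  img <- matrix(200, 60, 60)
  img <- fiberseg:::draw_disk(img, 20, 20, 10, 20)
  img <- fiberseg:::draw_disk(img, 40, 40, 10, 20)
  ws <- watershed_segment(img)
  expect_identical(sort(unique(ws[ws > 0])), c(1L, 2L))
  expect_gt(sum(ws == 0), 0)
  # basins partition non-ridge pixels and are connected
  for (L in 1:2) {
    cc <- fiberseg:::cpp_label(ws == L, 8L)
    expect_identical(max(cc), 1L)
  }
  # constant image: single basin, no ridge
  cst <- watershed_segment(matrix(5, 20, 20))
  expect_identical(max(cst), 1L)
  expect_identical(sum(cst == 0L), 0L)
  expect_error(watershed_segment(array(0, c(2, 2, 2))), "matrix")
})

test_that("initial segmentation recovers a clean synthetic tessellation", {
  sec <- small_section(seed = 3, size = 300, n_fibers = 25)
  p <- default_params()
  mask <- initial_segmentation(sec$image, p)
  # one basin per Voronoi cell (interior + border-region basins)
  expect_identical(max(mask), nrow(sec$truth$fibers))
  # deterministic
  expect_identical(mask, initial_segmentation(sec$image, p))
  # over/under-segmentation directions at h = 2 / h = 12, and monotonicity
  counts <- vapply(c(2, 5, 12), function(h) {
    p$segmentation_smoothing <- h
    max(initial_segmentation(sec$image, p))
  }, 0L)
  expect_true(counts[1] >= counts[2])
  expect_true(counts[2] >= counts[3])
})

test_that("separation strokes split labels and relabel deterministically", {
  # dumbbell: two 8x8 squares joined by a 2-px neck
  m <- matrix(0L, 24, 30)
  m[8:15, 3:10] <- 1L
  m[8:15, 17:24] <- 1L
  m[11:12, 11:16] <- 1L
  stroke <- list(cbind(c(13.4, 13.6), c(5, 20)))  # vertical cut x=13, y 5..20
  out <- apply_separations(m, stroke)
  labs <- sort(unique(out[out > 0]))
  expect_length(labs, 2L)
  expect_true(1L %in% labs)          # largest piece keeps original label
  # pieces partition the original minus stroke pixels (connected-components oracle)
  cut <- m
  cut[5:20, 13] <- 0L
  cc <- fiberseg:::cpp_label(cut > 0, 8L)
  expect_identical(max(cc), 2L)
  expect_identical(out > 0, cc > 0)
  expect_true(all(tapply(out[out > 0], cc[cc > 0], function(v) length(unique(v))) == 1))
  # stroke in background changes nothing
  bg <- apply_separations(m, list(cbind(c(2, 2), c(2, 20))))
  expect_identical(bg, m)
  # empty stroke list is identity; out-of-bounds vertices error
  expect_identical(apply_separations(m, list()), m)
  expect_error(apply_separations(m, list(cbind(c(-3, 5), c(1, 1)))), "bounds")
})

test_that("strokes files parse and labels stay disjoint after separation", {
  d <- withr::local_tempdir()
  path <- file.path(d, "strokes.json")
  writeLines('[[[5, 1], [5, 24]], [[1, 12], [30, 12]]]', path)
  s <- read_strokes(path)
  expect_length(s, 2L)
  expect_identical(s[[1]][1, ], c(5, 1))
  m <- matrix(1L, 24, 30)
  out <- apply_separations(m, s)
  expect_identical(sum(out == 0L), sum(m == 1L) - sum(out > 0L))
  expect_gt(max(out), 1L)
})

test_that("boundary overlay paints shared ridges white only", {
  img <- array(10L, c(12, 12, 3))
  blank <- matrix(0L, 12, 12)
  expect_identical(overlay_boundaries(img, blank), img)
  two <- matrix(0L, 12, 12)
  two[2:11, 2:5] <- 1L; two[2:11, 7:11] <- 2L  # column 6 = shared ridge
  ov <- overlay_boundaries(img, two)
  expect_true(all(ov[3:10, 6, ] == 255L))
  expect_true(all(ov[, 1, ] == 10L))  # untouched background
  expect_error(overlay_boundaries(img, matrix(0L, 5, 5)), "differ|shape")
})
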