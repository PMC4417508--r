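test_that("mean fiber intensity averages channel values over each label", {
  m <- matrix(0L, 10, 10)
  m[2:5, 2:5] <- 1L; m[7:8, 7:8] <- 2L
  ch <- matrix(40, 10, 10)
  expect_equal(unname(mean_fiber_intensity(m, ch)), c(40, 40))
  ch2 <- matrix(0, 10, 10)
  ch2[2:5, 2:3] <- 0; ch2[2:5, 4:5] <- 200  # half 0 / half 200
  expect_equal(unname(mean_fiber_intensity(m, ch2))[1], 100)
  expect_error(mean_fiber_intensity(m, matrix(0, 3, 3)), "differ")
})

test_that("Otsu threshold equals the exhaustive minimizer", {
  # perfect bimodal: split {0,0} vs {255,255}
  thr <- otsu_threshold(c(0, 0, 255, 255))
  v <- c(0, 0, 255, 255)
  expect_identical(v > thr, c(FALSE, FALSE, TRUE, TRUE))
  # small awkward set: same partition as brute force
  v2 <- c(5, 6, 7, 250)
  expect_identical(v2 > otsu_threshold(v2), v2 > oracle_otsu(v2))
  # two clusters: threshold strictly between them
  set.seed(3)
  v3 <- c(round(rnorm(50, 20, 3)), round(rnorm(50, 200, 6)))
  v3 <- pmin(pmax(v3, 0), 255)
  thr3 <- otsu_threshold(v3)
  expect_gt(thr3, max(v3[v3 < 100]))
  expect_lt(thr3, min(v3[v3 > 100]))
  # error contracts
  expect_error(otsu_threshold(c(7, 7, 7)), "separable|identical")
  expect_error(otsu_threshold(5), ">= 2")
  expect_error(otsu_threshold(c(-2, 8)), "0, 255")
})

test_that("Otsu partition equals brute force on random 8-bit value sets", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:200, 1)
    v <- sample(0:255, n, replace = TRUE)
    if (length(unique(pmin(floor(v), 255))) < 2) next
    expect_identical(v > otsu_threshold(v), v > oracle_otsu(v))
  }
})

test_that("fiber typing calls, summaries and bounds behave as specified", {
  sec <- small_section(seed = 5, size = 320, n_fibers = 30)
  p <- default_params()
  res <- filter_fibers(initial_segmentation(sec$image, p), p)
  ch <- get_channel(sec$image, "type")
  ty <- classify_fiber_types(res$mask, ch, p$pixel_size)
  expect_true(ty$auto)
  # calls equal ground truth through the overlap matching
  m <- match_to_truth(res$mask, sec$truth$labels)
  truth_pos <- sec$truth$fibers$type_positive[m[as.character(ty$fibers$label)]]
  expect_identical(ty$fibers$call == 1L, truth_pos)
  expect_equal(ty$percent_positive, 100 * mean(truth_pos))
  # threshold bounds: 255 -> 0% positive, 0 -> all stained fibers positive
  expect_identical(classify_fiber_types(res$mask, ch, p$pixel_size,
                                        threshold = 255)$percent_positive, 0)
  expect_identical(classify_fiber_types(res$mask, ch, p$pixel_size,
                                        threshold = 0)$percent_positive, 100)
  # percent positive non-increasing in threshold
  pcts <- vapply(c(0, 50, 120, 200, 255), function(t)
    classify_fiber_types(res$mask, ch, p$pixel_size, threshold = t)$percent_positive, 0)
  expect_true(all(diff(pcts) <= 0))
  # group conservation: n_all * mean_all = n_pos * mean_pos + n_neg * mean_neg
  s <- ty$summary
  n <- s$n; ma <- s$mean_area_um2
  expect_equal(n[1] * ma[1], sum(n[2:3] * ma[2:3], na.rm = TRUE))
  expect_error(classify_fiber_types(matrix(0L, 5, 5), matrix(0, 5, 5), 1),
               "no fibers")
  expect_error(classify_fiber_types(res$mask, ch, p$pixel_size, threshold = 300),
               "0, 255")
})

test_that("typing outputs (CSV, plots, print) are produced", {
  d <- withr::local_tempdir()
  sec <- small_section(seed = 6, size = 256, n_fibers = 16)
  p <- default_params()
  res <- filter_fibers(initial_segmentation(sec$image, p), p)
  ty <- classify_fiber_types(res$mask, get_channel(sec$image, "type"),
                             p$pixel_size)
  csv <- write_typing_csv(ty, file.path(d, "t.csv"))
  tab <- read.csv(csv)
  expect_identical(nrow(tab), nrow(ty$fibers) + 4L)
  expect_equal(tab$call[tab$label == "PERCENT_POSITIVE"], ty$percent_positive)
  paths <- plot_typing(ty, file.path(d, "t"))
  expect_true(all(file.exists(paths)))
  expect_output(print(ty), "positive")
})
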