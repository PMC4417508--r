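test_that("central regions erode fibers by the exact Euclidean distance", {
  ps <- 0.645
  m <- matrix(0L, 60, 60)
  m[10:50, 10:50] <- 1L  # 41x41 square fiber
  # distance 0 -> identity
  expect_identical(central_region_mask(m, 0, ps), m)
  # 10 um at 0.645 um/px ~ 15.5 px: compare against the brute EDT oracle
  cen <- central_region_mask(m, 10, ps)
  bnd <- matrix(FALSE, 60, 60)
  bnd[10:50, 10:50][row(matrix(0, 41, 41)) %in% c(1, 41) |
                    col(matrix(0, 41, 41)) %in% c(1, 41)] <- TRUE
  dist <- oracle_edt(bnd)
  expected <- m > 0 & dist > 10 / ps
  expect_identical(cen > 0, expected)
  # ~10x10 core survives (41 - 2*16 = 9 plus the discrete boundary row)
  expect_identical(sum(cen > 0), sum(expected))
  expect_gt(sum(cen > 0), 0)
  # a disk smaller than the border distance vanishes entirely
  small <- matrix(0L, 30, 30)
  small[(row(small) - 15)^2 + (col(small) - 15)^2 <= 10^2] <- 1L
  expect_identical(max(central_region_mask(small, 10, ps)), 0L)
  # central regions are subsets of their fibers and disjoint across fibers
  m2 <- m; m2[10:50, 26] <- 0L; m2[10:50, 27:50] <- 2L
  cen2 <- central_region_mask(m2, 3, ps)
  expect_true(all(cen2[cen2 > 0] == m2[cen2 > 0]))
})

test_that("nuclei detection smooths shallow artifacts and thresholds", {
  ch <- matrix(5, 80, 80)
  ch <- fiberseg:::draw_disk(ch, 20, 20, 5, 220)
  ch <- fiberseg:::draw_disk(ch, 60, 60, 5, 220)
  det <- detect_nuclei(ch, smoothing = 5)
  expect_identical(max(fiberseg:::cpp_label(det$binary, 8L)), 2L)
  # blank/constant channel: auto threshold errors, manual threshold works
  expect_error(detect_nuclei(matrix(0, 10, 10), 5), "manual threshold")
  man <- detect_nuclei(matrix(0, 10, 10), 5, threshold = 50)
  expect_identical(sum(man$binary), 0L)
  # shallow streaks (amplitude < h) are suppressed, nuclei retained
  streak <- ch + outer(rep(1, 80), 3 * sin(seq(0, 6 * pi, length.out = 80)))
  det2 <- detect_nuclei(pmax(streak, 0), smoothing = 8)
  expect_identical(max(fiberseg:::cpp_label(det2$binary, 8L)), 2L)
  expect_gte(min(det2$smoothed), 0)
})

test_that("CNF calls follow the central nuclear area rule", {
  ps <- 1
  m <- matrix(0L, 90, 40)
  m[3:38, 3:38] <- 1L    # large fiber, central nucleus
  m[45:80, 3:38] <- 2L   # large fiber, peripheral nucleus only
  nucmat <- matrix(FALSE, 90, 40)
  nucmat[18:22, 18:22] <- TRUE   # 25 px at centroid of fiber 1
  nucmat[46:48, 10:14] <- TRUE   # hugging fiber 2's border
  central <- central_region_mask(m, 8, ps)
  res <- classify_cnf(m, central, nucmat, min_nuclear_size = 5, pixel_size = ps)
  expect_identical(res$fibers$call, c(1L, 0L))
  expect_equal(res$fibers$central_nuclear_area_um2[1], 25)
  expect_equal(res$fibers$central_nuclear_area_um2[2], 0)
  expect_equal(res$percent_cnf, 50)
  expect_true(all(res$fibers$central_nuclear_area_um2 <= res$fibers$area_um2))
  # empty central region forces a PNF call even with nuclear staining
  tiny <- matrix(0L, 20, 20); tiny[8:12, 8:12] <- 1L
  allnuc <- matrix(TRUE, 20, 20)
  res2 <- classify_cnf(tiny, central_region_mask(tiny, 10, ps), allnuc,
                       min_nuclear_size = 1, pixel_size = ps)
  expect_identical(res2$fibers$call, 0L)
})

test_that("synthetic CNF analysis recovers ground truth exactly", {
  sec <- small_section(seed = 9, size = 360, n_fibers = 30)
  p <- default_params()
  res <- filter_fibers(initial_segmentation(sec$image, p), p)
  cn <- cnf_analysis(sec$image, res$mask, p)
  m <- match_to_truth(res$mask, sec$truth$labels)
  truth_cnf <- sec$truth$fibers$cnf[m[as.character(cn$fibers$label)]]
  expect_identical(cn$fibers$call == 1L, truth_cnf)
  expect_equal(cn$percent_cnf, 100 * mean(truth_cnf))
  # percent CNF non-increasing in border distance
  pct_d <- vapply(c(0, 5, 10, 20), function(d) {
    p2 <- p; p2$nuclear_border_distance <- d
    cnf_analysis(sec$image, res$mask, p2)$percent_cnf
  }, 0)
  expect_true(all(diff(pct_d) <= 0))
  # ... and in minimum nuclear size
  pct_s <- vapply(c(1, 5, 20, 60), function(s) {
    p2 <- p; p2$min_nuclear_size <- s
    cnf_analysis(sec$image, res$mask, p2)$percent_cnf
  }, 0)
  expect_true(all(diff(pct_s) <= 0))
})

test_that("CNF outputs (CSV, renderings, print) are produced", {
  d <- withr::local_tempdir()
  sec <- small_section(seed = 10, size = 256, n_fibers = 16)
  p <- default_params()
  res <- filter_fibers(initial_segmentation(sec$image, p), p)
  cn <- cnf_analysis(sec$image, res$mask, p)
  csv <- write_cnf_csv(cn, file.path(d, "c.csv"))
  tab <- read.csv(csv)
  expect_identical(nrow(tab), nrow(cn$fibers) + 4L)
  expect_equal(tab$call[tab$label == "PERCENT_CNF"], cn$percent_cnf)
  paths <- render_cnf(cn, res$mask, file.path(d, "c"))
  expect_true(all(file.exists(paths)))
  expect_output(print(cn), "CNF")
})
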