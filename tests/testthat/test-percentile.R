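test_that("percentile-to-threshold mapping and its anchors", {
  expect_identical(percentile_to_threshold(50), 0.5)
  expect_equal(percentile_to_threshold(84.1), 0.159, tolerance = 1e-12)
  expect_equal(percentile_to_threshold(15.9), 0.841, tolerance = 1e-12)
  expect_identical(percentile_to_threshold(80), 0.2)
  expect_error(percentile_to_threshold(0), "strictly inside")
  expect_error(percentile_to_threshold(100), "strictly inside")
})

test_that("the printed standard percentiles are the rounded normal CDF at +-1 sigma", {
  expect_identical(round(100 * pnorm(c(-1, 1)), 1), c(15.9, 84.1))
  expect_identical(unname(standard_percentiles()), c(15.9, 50.0, 84.1))
})

test_that("thresholding is inclusive: ties belong to the segmentation", {
  eps <- array(c(0.0, 0.2, 0.5, 1.0), c(4, 1, 1))
  seg <- threshold_map(probability_map(eps), P = 80)   # t = 0.20
  expect_identical(as.vector(seg$mask), c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(seg$threshold, 0.2)
  # P -> 0+ keeps only eps = 1 voxels
  tiny <- threshold_map(probability_map(eps), P = 1e-9)
  expect_identical(as.vector(tiny$mask), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("masks are nested and match the brute-force rule on random maps", {
  set.seed(41)
  pm <- probability_map(array(runif(16^3), c(16, 16, 16)))
  prev <- NULL
  for (P in seq(10, 90, by = 10)) {
    seg <- threshold_map(pm, P = P)
    expect_identical(seg$mask, class_map(pm, 1) >= (1 - P / 100))
    if (!is.null(prev)) expect_false(any(prev & !seg$mask))
    prev <- seg$mask
  }
})

test_that("mask voxel count steps exactly at percentiles 100*(1 - eps)", {
  set.seed(43)
  vals <- round(runif(27), 2)
  vals[1] <- 0.5
  pm <- probability_map(array(vals, c(3, 3, 3)))
  counts <- vapply(seq(0.5, 99.5, by = 0.5),
                   function(P) sum(threshold_map(pm, P = P)$mask), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # oracle: count at P equals #{eps >= 1 - P/100} from the sorted values
  for (P in c(12.5, 50, 77)) {
    expect_identical(sum(threshold_map(pm, P = P)$mask),
                     sum(vals >= 1 - P / 100))
  }
})

test_that("standard segmentations are nested and handle the constant map", {
  pmc <- probability_map(array(0.5, c(3, 3, 3)))
  ss <- standard_segmentations(pmc)
  expect_identical(sum(ss$low$mask), 0L)     # 0.5 < 0.841
  expect_identical(mean(ss$mid$mask), 1)     # inclusive at 0.5
  expect_identical(mean(ss$high$mask), 1)

  set.seed(47)
  pm <- probability_map(array(runif(8^3), c(8, 8, 8)))
  ss2 <- standard_segmentations(pm)
  expect_false(any(ss2$low$mask & !ss2$mid$mask))
  expect_false(any(ss2$mid$mask & !ss2$high$mask))
})

test_that("standard segmentation interfaces sit at the analytic offsets", {
  w <- 3; x0 <- 16
  sc <- make_planar_interface(c(32, 8, 8), x0 = x0, w = w)
  pm <- probability_map(sc$grayscale)
  ss <- standard_segmentations(pm)
  for (nm in c("low", "mid", "high")) {
    seg <- ss[[nm]]
    # g(x) >= t  <=>  x >= x0 + w * qnorm(t); first included voxel center
    pred <- x0 + w * qnorm(seg$threshold)
    first <- which(apply(seg$mask, 1, any))[1]
    expect_lt(abs((first - 0.5) - pred), 1)
  }
})
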