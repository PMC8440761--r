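test_that("planar interface has the analytic erf profile", {
  sc <- make_planar_interface(c(32, 8, 8), x0 = 16.5, w = 3)
  g <- sc$grayscale
  # voxel centers at x = i - 0.5: voxel 17 sits exactly on the interface
  expect_identical(g[17, 1, 1], 0.5)
  expect_equal(g[20, 1, 1], pnorm(1), tolerance = 1e-15)  # center at x0 + w
  expect_identical(sc$truth[16, 1, 1], FALSE)
  expect_identical(sc$truth[17, 1, 1], TRUE)
  # w -> 0 approaches the sharp step
  sharp <- make_planar_interface(c(32, 2, 2), x0 = 16, w = 1e-6)
  expect_equal(sharp$grayscale, array(as.numeric(sharp$truth), dim(sharp$truth)))
  expect_error(make_planar_interface(c(32, 8, 8), x0 = 40, w = 1), "inside")
  expect_error(make_planar_interface(c(32, 8, 8), x0 = 16, w = 0), "> 0")
})

test_that("blob microstructure hits its volume fraction and is reproducible", {
  s1 <- make_blob_microstructure(c(32, 32, 32), phi = 0.5, ell = 2, seed = 3)
  expect_lt(abs(mean(s1$truth) - 0.5), 0.01)
  s1b <- make_blob_microstructure(c(32, 32, 32), phi = 0.5, ell = 2, seed = 3)
  expect_identical(s1$truth, s1b$truth)
  expect_identical(s1$grayscale, s1b$grayscale)
  s2 <- make_blob_microstructure(c(32, 32, 32), phi = 0.3, ell = 2, seed = 3)
  expect_lt(abs(mean(s2$truth) - 0.3), 0.01)
})

test_that("doubling the correlation length doubles the truth's correlation length", {
  corr_len <- function(truth) {
    f <- truth - mean(truth)
    ac <- Re(fft(abs(fft(f))^2, inverse = TRUE)) / length(f)
    ac1 <- ac[, 1, 1] / ac[1, 1, 1]
    i <- which(ac1 < 0.5)[1]
    (i - 2) + (ac1[i - 1] - 0.5) / (ac1[i - 1] - ac1[i])
  }
  s1 <- make_blob_microstructure(c(48, 48, 48), 0.5, 2, seed = 3)
  s2 <- make_blob_microstructure(c(48, 48, 48), 0.5, 4, seed = 3)
  ratio <- corr_len(s2$truth) / corr_len(s1$truth)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("threshold-jitter ensembles converge to the grayscale probability", {
  sc <- make_planar_interface(c(32, 32, 8), x0 = 16, w = 3)
  st <- sample_segmentations(sc, N = 2000, "threshold_jitter", seed = 7)
  pm <- compute_probability_map(st)
  g <- analytic_inclusion_probability(sc, "threshold_jitter")
  se <- sqrt(g * (1 - g) / 2000)
  frac_ok <- mean(abs(class_map(pm, 1) - g) <= 3 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("samplers honour their contracts at the edges", {
  sc <- make_planar_interface(c(16, 4, 4), x0 = 8, w = 2)
  st1 <- sample_segmentations(sc, N = 1, seed = 5)
  expect_length(st1$samples, 1)
  expect_true(all(st1$samples[[1]] %in% 0:1))

  st0 <- sample_segmentations(sc, N = 5, "noise_then_threshold", seed = 5,
                              noise_amp = 1e-12)
  collapse <- array(as.integer(sc$grayscale >= 0.5), dim(sc$grayscale))
  for (s in st0$samples) expect_identical(s, collapse)

  expect_error(sample_segmentations(sc, 2, "bogus"), "arg")
  # identical recipe and seed reproduce the ensemble exactly
  a <- sample_segmentations(sc, 10, seed = 42)
  b <- sample_segmentations(sc, 10, seed = 42)
  expect_identical(a$samples, b$samples)
})

test_that("noise-then-threshold matches its closed-form inclusion probability", {
  sc <- make_planar_interface(c(16, 16, 4), x0 = 8, w = 2)
  a <- 0.15
  st <- sample_segmentations(sc, N = 1500, "noise_then_threshold", seed = 9,
                             noise_amp = a)
  pm <- compute_probability_map(st)
  pr <- analytic_inclusion_probability(sc, "noise_then_threshold", noise_amp = a)
  se <- sqrt(pr * (1 - pr) / 1500)
  expect_gte(mean(abs(class_map(pm, 1) - pr) <= 4 * se + 1e-12), 0.99)
})

test_that("quantity tables evaluate the requested quantile function", {
  tab <- make_quantity_table("normal", list(mean = 0, sd = 1), c(50, 84.1))
  expect_identical(tab$value[1], 0)
  expect_equal(tab$value[2], 0.99858, tolerance = 1e-4)  # qnorm(0.841)
  hc <- make_quantity_table("half_cauchy", list(location = 0, scale = 1), 50)
  expect_equal(hc$value, 1, tolerance = 1e-12)           # tan(pi/4)
})
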