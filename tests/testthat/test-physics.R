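test_that("volume fraction counts voxels", {
  expect_identical(volume_fraction(array(TRUE, c(3, 3, 3)))$value, 1)
  m <- array(FALSE, c(4, 4, 4)); m[1:16] <- TRUE
  expect_identical(volume_fraction(m)$value, 0.25)
  set.seed(51)
  r <- array(sample(c(TRUE, FALSE), 5 * 6 * 7, TRUE), c(5, 6, 7))
  expect_identical(volume_fraction(r)$value, sum(r) / length(r))
})

test_that("a homogeneous medium returns its own conductivity exactly", {
  for (k in c(1, 0.278, 4)) {
    r <- solve_effective_transport(
      conductivity_field(array(TRUE, c(5, 4, 3)), k_in = k, k_out = k), "x")
    expect_equal(r$value, k, tolerance = 1e-12)
  }
})

test_that("series and parallel slabs match the closed-form means", {
  slab <- array(FALSE, c(8, 4, 4)); slab[1:4, , ] <- TRUE
  f <- conductivity_field(slab, k_in = 1, k_out = 1e-6)
  series <- solve_effective_transport(f, "x")
  expect_equal(series$value, 2 / (1 + 1e6), tolerance = 1e-10)
  parallel <- solve_effective_transport(f, "y")
  expect_equal(parallel$value, (1 + 1e-6) / 2, tolerance = 1e-10)
  # moderate contrast too
  f2 <- conductivity_field(slab, k_in = 4, k_out = 0.278)
  expect_equal(solve_effective_transport(f2, "x")$value,
               2 / (1 / 4 + 1 / 0.278), tolerance = 1e-10)
  expect_equal(solve_effective_transport(f2, "z")$value, (4 + 0.278) / 2,
               tolerance = 1e-10)
})

test_that("iterative solve agrees with the dense direct oracle", {
  set.seed(53)
  for (d in list(c(6, 5, 4), c(8, 8, 8), c(12, 6, 5))) {
    mask <- array(runif(prod(d)) < 0.5, d)
    r <- solve_effective_transport(conductivity_field(mask), "x")
    expect_equal(r$value, dense_keff(mask), tolerance = 1e-8)
  }
  # anisotropic axis-diagonal conductivities (transversely isotropic fabric)
  mask <- array(runif(6 * 6 * 6) < 0.5, c(6, 6, 6))
  fld <- conductivity_field(mask, k_in = c(4, 4, 2), k_out = 0.278)
  r <- solve_effective_transport(fld, "x")
  expect_equal(r$value, dense_keff(mask, k_in = c(4, 4, 2),
                                   k_out = rep(0.278, 3)), tolerance = 1e-8)
})

test_that("Wiener bounds and flux conservation hold on random fields", {
  set.seed(59)
  for (i in 1:20) {
    d <- sample(3:7, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < runif(1, 0.2, 0.8), d)
    kin <- runif(1, 0.5, 5); kout <- 10^runif(1, -6, -0.3)
    r <- solve_effective_transport(conductivity_field(mask, kin, kout), "x",
                                   maxit = 20000)
    s <- r$solver_stats
    expect_gte(r$value, s$wiener_lower * (1 - 1e-8))
    expect_lte(r$value, s$wiener_upper * (1 + 1e-8))
    expect_lt(s$flux_imbalance, 10 * 1e-9)
  }
})

test_that("rotating the field and swapping axes leaves the value unchanged", {
  set.seed(61)
  mask <- array(runif(5 * 6 * 7) < 0.5, c(5, 6, 7))
  rx <- solve_effective_transport(conductivity_field(mask), "x")
  rz <- solve_effective_transport(conductivity_field(aperm(mask, c(3, 2, 1))), "z")
  expect_equal(rx$value, rz$value, tolerance = 1e-10)
})

test_that("effective conductivity grows with percentile (Rayleigh monotonicity)", {
  set.seed(67)
  pm <- probability_map(array(runif(10^3), c(10, 10, 10)))
  sweep <- run_physics_sweep(pm, percentiles = seq(20, 80, by = 15),
                             quantities = "effective_conductivity")
  expect_true(all(diff(sweep$value) >= -1e-10))
})

test_that("tortuosity anchors: open domain, straight channel, serpentine", {
  open <- tortuosity(array(TRUE, c(6, 6, 6)), "x")
  expect_lt(abs(open$value - 1), 2e-6)

  ch <- array(FALSE, c(8, 4, 4)); ch[, 1:2, 1:2] <- TRUE
  qc <- tortuosity(ch, "x")
  expect_lt(abs(qc$solver_stats$k_eff - (0.25 + 0.75e-6)), 1e-6)
  expect_lt(abs(qc$value - 1), 1e-3)

  serp <- serpentine_mask(c(6, 6, 3))
  ts <- tortuosity(serp, "y")
  expect_gt(ts$value, 1)
  # oracle on the permuted mask (transport along its x axis)
  k_or <- dense_keff(aperm(serp, c(2, 1, 3)))
  expect_equal(ts$value, mean(serp) / k_or, tolerance = 1e-6)

  expect_error(tortuosity(array(FALSE, c(3, 3, 3)), "x"), "porosity")
})

test_that("physics sweep emits a tidy, monotone, deterministic table", {
  set.seed(71)
  pm <- probability_map(array(runif(8^3), c(8, 8, 8)))
  sw <- run_physics_sweep(pm, percentiles = c(15.9, 50, 84.1),
                          quantities = "volume_fraction")
  expect_identical(nrow(sw), 3L)
  expect_true(all(diff(sw$value) >= 0))
  expect_identical(sw$threshold, percentile_to_threshold(c(15.9, 50, 84.1)))

  sw10 <- run_physics_sweep(pm, percentiles = seq(5, 95, by = 10),
                            quantities = c("volume_fraction", "tortuosity"),
                            pore = "mask")
  expect_identical(nrow(sw10), 20L)
  expect_identical(sw10, run_physics_sweep(
    pm, percentiles = seq(5, 95, by = 10),
    quantities = c("volume_fraction", "tortuosity"), pore = "mask"))

  empty <- run_physics_sweep(pm, percentiles = numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("degenerate grids and non-convergence raise typed errors", {
  expect_error(solve_effective_transport(
    conductivity_field(array(TRUE, c(1, 4, 4))), "x"), "at least 2 voxels")
  mask <- array(runif(6^3) < 0.5, c(6, 6, 6))
  err <- tryCatch(
    solve_effective_transport(conductivity_field(mask), "x", maxit = 2L),
    error = identity)
  expect_s3_class(err, "voxuq_convergence_error")
  expect_true(length(err$residual_history) == 2)
})
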