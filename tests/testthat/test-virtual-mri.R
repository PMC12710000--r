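# Small grids throughout: voxelization, noise and smoothing behaviour are
# resolution-independent, so tests use capsules a few mm across.

test_that("raw volume round-trip is bit-exact and NIfTI preserves geometry", {
  set.seed(81)
  v <- volume_grid(array(round(runif(4 * 5 * 6), 4), c(4L, 5L, 6L)),
                   voxel_size = 0.05, origin = c(-0.1, 0.2, 0))
  raw <- withr::local_tempfile(fileext = ".raw")
  write_volume(v, raw)
  got <- read_volume(raw)
  # float32 storage: identical after a float32 round trip of the source
  expect_equal(dim(got$values), dim(v$values))
  expect_lt(max(abs(got$values - v$values)), 1e-7)
  expect_identical(read_volume(raw)$values, got$values)  # deterministic
  expect_equal(got$voxel_size, 0.05)
  expect_equal(got$origin, v$origin)

  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, nii)
  gn <- read_volume(nii)
  expect_equal(gn$voxel_size, 0.05, tolerance = 1e-6)
  expect_equal(gn$origin, v$origin, tolerance = 1e-5)
  expect_lt(max(abs(gn$values - v$values)), 1e-6)
})

test_that("a raw volume without its sidecar is a format error", {
  raw <- withr::local_tempfile(fileext = ".raw")
  writeBin(numeric(8), raw, size = 4L)
  expect_error(read_volume(raw), class = "rsaeval_format_error")
})

test_that("voxelizing an empty system gives an all-zero volume", {
  v <- voxelize(root_system(), voxel_size = 0.1, shape = c(5L, 5L, 5L),
                origin = c(0, 0, 0))
  expect_equal(sum(v$values), 0)
})

test_that("a thick segment through a voxel saturates it at 1", {
  rsa <- root_system(list(root("r", rbind(c(-0.5, 0.05, 0.05),
                                          c(0.5, 0.05, 0.05)),
                               diameters = 0.4)))
  v <- suppressWarnings(  # the capsule deliberately overhangs this 1D grid
    voxelize(rsa, voxel_size = 0.1, shape = c(10L, 1L, 1L),
             origin = c(-0.5, 0, 0), supersampling = 4L))
  expect_equal(max(v$values), 1)
  expect_true(all(v$values[3:8, 1, 1] == 1))
})

test_that("interior capsule mass matches the analytic capsule volume", {
  r <- 0.15; l <- 2
  rsa <- root_system(list(root("r", rbind(c(0, 0, -1), c(0, 0, 1)),
                               diameters = 2 * r)))
  v <- voxelize(rsa, voxel_size = 0.05, shape = c(40L, 40L, 80L),
                origin = c(-1, -1, -2), supersampling = 4L)
  mass <- sum(v$values) * 0.05^3
  analytic <- pi * r^2 * l + 4 / 3 * pi * r^3
  expect_lt(abs(mass - analytic) / analytic, 0.05)
})

test_that("signal mass is stable under grid refinement", {
  r <- 0.15
  rsa <- root_system(list(root("r", rbind(c(0, 0, -0.8), c(0, 0, 0.8)),
                               diameters = 2 * r)))
  coarse <- voxelize(rsa, voxel_size = 0.1, shape = c(20L, 20L, 30L),
                     origin = c(-1, -1, -1.5), supersampling = 4L)
  fine <- voxelize(rsa, voxel_size = 0.05, shape = c(40L, 40L, 60L),
                   origin = c(-1, -1, -1.5), supersampling = 4L)
  m1 <- sum(coarse$values) * 0.1^3
  m2 <- sum(fine$values) * 0.05^3
  expect_lt(abs(m1 - m2) / m2, 0.02)
})

test_that("voxelize warns and clips when the grid does not cover the system", {
  rsa <- root_system(list(straight_root("r", c(0, 0, 0), c(0, 0, 5))))
  expect_warning(
    v <- voxelize(rsa, voxel_size = 0.1, shape = c(10L, 10L, 10L),
                  origin = c(-0.5, -0.5, 0)),
    "clip")
  expect_true(all(is.finite(v$values)))
})

test_that("weierstrass transform: identity at zero, kernel response, mass", {
  set.seed(82)
  v <- volume_grid(array(runif(16^3), c(16L, 16L, 16L)), 0.05)
  expect_identical(weierstrass_transform(v, 0)$values, v$values)

  flat <- volume_grid(array(1, c(16L, 16L, 16L)), 0.05)
  sm <- weierstrass_transform(flat, 0.05)
  expect_equal(sm$values[8, 8, 8], 1, tolerance = 1e-9)

  # single central impulse reproduces the sampled normalized kernel
  imp <- array(0, c(17L, 17L, 17L)); imp[9, 9, 9] <- 1
  vi <- volume_grid(imp, 0.05)
  out <- weierstrass_transform(vi, 0.05)  # sigma = 1 voxel
  h <- 4L
  g <- dnorm(-h:h, sd = 1); g <- g / sum(g)
  expected <- outer(outer(g, g), g)
  got <- out$values[5:13, 5:13, 5:13]
  expect_lt(max(abs(got - expected)), 1e-6)
  # total mass of an interior-supported field is preserved
  expect_equal(sum(out$values), 1, tolerance = 1e-6)
  expect_error(weierstrass_transform(vi, -0.1),
               class = "rsaeval_parameter_error")
})

test_that("water noise is seed-reproducible and confined to the cylinder", {
  rsa <- root_system(list(straight_root("tap", c(0, 0, 0.1), c(0, 0, 1.9),
                                        n = 10L, diameter = 0.15)))
  clean <- voxelize(rsa, voxel_size = 0.05, shape = c(40L, 40L, 40L),
                    origin = c(-1, -1, 0))
  cfg <- noise_config(snr = 4.3, cylinder_diameter = 1.5, seed = 7)
  n1 <- seed_water_noise(clean, cfg)
  n2 <- seed_water_noise(clean, cfg)
  expect_identical(n1$values, n2$values)
  n3 <- seed_water_noise(clean, noise_config(seed = 8))
  expect_false(identical(n1$values, n3$values))

  mask <- cylinder_mask(clean, c(0, 0), 1.5, "z")
  expect_identical(n1$values[!mask], clean$values[!mask])
  expect_gt(sum(n1$values[mask] != clean$values[mask]), 0)
})

test_that("a cylinder outside the grid is a placement error", {
  clean <- volume_grid(array(0, c(10L, 10L, 10L)), 0.05)
  expect_error(seed_water_noise(clean, noise_config(cylinder_center = c(9, 9))),
               class = "rsaeval_placement_error")
})

test_that("measure_snr is the peak-over-RMS ratio with an Inf sentinel", {
  clean <- volume_grid(array(0, c(8L, 8L, 8L)), 0.1)
  clean$values[4, 4, 4] <- 1
  region <- array(TRUE, c(8L, 8L, 8L))
  noisy <- clean
  expect_identical(measure_snr(clean, noisy, region), Inf)
  noisy$values <- clean$values + 0.25  # RMS 0.25 everywhere
  expect_equal(measure_snr(clean, noisy, region), 4)
})

test_that("the generated phantom closes the SNR loop at the configured value", {
  rsa <- root_system(list(straight_root("tap", c(0, 0, 0.1), c(0, 0, 1.9),
                                        n = 10L, diameter = 0.15)))
  ph <- simulate_phantom(rsa, voxel_size = 0.05,
                         config = noise_config(snr = 4.3, seed = 9),
                         shape = c(40L, 40L, 40L), origin = c(-1, -1, 0))
  expect_equal(ph$snr, 4.3, tolerance = 0.02)
})
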