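test_that("NIfTI round-trips preserve values, grids and label codes", {
  g <- voxel_grid(c(8, 8, 8), spacing = c(1, 1.5, 2))
  set.seed(42)

  pv <- probability_volume(array(runif(512), dim = c(8, 8, 8)), g)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(pv, f)
  pv2 <- read_volume(f, kind = "probability")
  expect_equal(pv2$values, pv$values, tolerance = 1e-6)
  expect_lt(max(abs(pv2$grid$affine - g$affine)), 1e-5)
  expect_equal(pv2$grid$shape, g$shape)

  lv <- label_volume(array(sample(0:9, 512, TRUE), dim = c(8, 8, 8)), g)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(lv, f2)
  lv2 <- read_volume(f2, kind = "label")
  expect_identical(as.integer(lv2$values), as.integer(lv$values))

  tm <- thickness_map(array(abs(rnorm(512)) * 3, dim = c(8, 8, 8)), g)
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(tm, f3)
  tm2 <- read_volume(f3, kind = "thickness")
  expect_equal(tm2$values, tm$values, tolerance = 1e-5)

  zero <- thickness_map(array(0, dim = c(8, 8, 8)), g)
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(zero, f4)
  expect_equal(max(read_volume(f4, kind = "thickness")$values), 0)
})

test_that("probability validation clips float noise but rejects real violations", {
  g <- grid_for(c(4, 4, 4))
  v <- array(0.5, dim = c(4, 4, 4))

  v[1] <- 1 + 5e-7
  expect_warning(pv <- probability_volume(v, g), "clipped 1 voxel")
  expect_equal(max(pv$values), 1)

  v[1] <- -5e-7
  expect_warning(pv <- probability_volume(v, g), "clipped")
  expect_equal(min(pv$values), 0)

  v[1] <- 1.01; v[2] <- 1.02
  expect_error(probability_volume(v, g), "2 voxel\\(s\\) outside \\[0,1\\]")

  # through the file layer: out-of-range data read as probability errors
  bad <- thickness_map(array(c(1.5, rep(0.2, 63)), dim = c(4, 4, 4)), g)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(bad, f)
  expect_error(read_volume(f, kind = "probability"), "outside \\[0,1\\]")
})

test_that("label volumes must be integer-coded", {
  g <- grid_for(c(4, 4, 4))
  v <- array(1, dim = c(4, 4, 4))
  v[2, 2, 2] <- 2.5
  expect_error(label_volume(v, g), "non-integer")

  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(thickness_map(v, g), f)
  expect_error(read_volume(f, kind = "label"), "non-integer")

  expect_error(label_volume(array(-1, dim = c(4, 4, 4)), g), "non-negative")
  # codes absent from a supplied legend are rejected
  expect_error(
    label_volume(array(7L, dim = c(4, 4, 4)), g,
                 legend = data.frame(code = 1L, region = "a", hemisphere = "none")),
    "missing from legend")
})

test_that("alignment check passes within tolerance and names mismatches", {
  g1 <- grid_for(c(8, 8, 8))
  v1 <- probability_volume(array(0.5, c(8, 8, 8)), g1)
  v2 <- probability_volume(array(0.1, c(8, 8, 8)), g1)
  expect_silent(assert_aligned(list(v1, v2)))

  aff <- g1$affine; aff[1, 4] <- aff[1, 4] + 1e-7
  v3 <- probability_volume(array(0.1, c(8, 8, 8)),
                           voxel_grid(c(8, 8, 8), affine = aff))
  expect_silent(assert_aligned(list(v1, v3)))

  aff[1, 4] <- aff[1, 4] + 1e-3
  v4 <- probability_volume(array(0.1, c(8, 8, 8)),
                           voxel_grid(c(8, 8, 8), affine = aff))
  expect_error(assert_aligned(list(v1, v4)), "affines differ")

  v5 <- probability_volume(array(0.1, c(6, 8, 8)), grid_for(c(6, 8, 8)))
  expect_error(assert_aligned(list(v1, v5)), "shape 8x8x8 vs 6x8x8")
})

test_that("invalid thickness maps are refused on construction and write", {
  g <- grid_for(c(4, 4, 4))
  expect_error(thickness_map(array(-0.1, c(4, 4, 4)), g), "negative")
  tm <- thickness_map(array(1, c(4, 4, 4)), g)
  tm$values[1] <- -1  # corrupt after construction
  expect_error(write_volume(tm, withr::local_tempfile(fileext = ".nii.gz")),
               "negative")
})

test_that("LUT reader handles both the native and FreeSurfer dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  legend <- data.frame(code = c(1L, 2L), region = c("banks_sts", "cuneus"),
                       hemisphere = c("left", "right"))
  write_lut(legend, f)
  expect_equal(read_lut(f), legend)

  fs <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# FreeSurfer-style color LUT",
               "1001  ctx-lh-bankssts   25 100  40  0",
               "2001  ctx-rh-bankssts   25 100  40  0",
               "17    Left-Hippocampus  220 216 20 0",
               "10    Thalamus          0 118 14 0"), fs)
  lut <- read_lut(fs)
  expect_equal(lut$code, c(1001L, 2001L, 17L, 10L))
  expect_equal(lut$hemisphere, c("left", "right", "left", "none"))
})
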