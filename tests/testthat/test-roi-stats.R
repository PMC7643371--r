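# brute-force oracle: GM voxels with a face-adjacent WM voxel, by explicit
# triple loop over the array
oracle_boundary <- function(seg) {
  d <- dim(seg)
  out <- NULL
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (seg[i, j, k] != 2L) next
    for (r in 1:6) {
      n <- c(i, j, k) + offs[r, ]
      if (all(n >= 1) && all(n <= d) && seg[n[1], n[2], n[3]] == 3L) {
        out <- rbind(out, c(i, j, k)); break
      }
    }
  }
  out
}

test_that("inner boundary matches brute-force enumeration", {
  seg <- array(2L, dim = c(7, 7, 7))
  seg[4, 4, 4] <- 3L
  b <- inner_boundary(toy_input(seg)$p_seg)
  expect_equal(nrow(b), 6)

  set.seed(5)
  seg2 <- array(sample(c(0L, 2L, 3L), 12^3, TRUE), dim = c(12, 12, 12))
  b2 <- inner_boundary(label_volume(seg2, grid_for(c(12, 12, 12))))
  o2 <- oracle_boundary(seg2)
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(unname(b2)), key(o2))

  # no WM contact: empty set with a warning
  seg3 <- slab_seg(0, 3, 4)
  expect_warning(b3 <- inner_boundary(label_volume(seg3, grid_for(dim(seg3)))),
                 "no white-matter contact")
  expect_equal(nrow(b3), 0)
})

test_that("shell boundary voxel count roughly tracks the inner sphere area", {
  sh <- small_shell_input(thickness = 3, shape = 40L, inner = 7)
  b <- inner_boundary(sh$input$p_seg)
  area_est <- 4 * pi * 7^2
  # boundary voxels undercount the lattice area (multi-face voxels count
  # once); the count stays within a 15% band of the analytic area
  expect_lt(abs(nrow(b) - area_est) / area_est, 0.15)
})

test_that("parcel assignment: distance 0, masking radius, and tie-breaks", {
  shape <- c(11, 11, 11)
  parc <- array(0L, dim = shape)
  parc[6, 6, 6] <- 4L
  pv <- label_volume(parc, grid_for(shape))

  on_parcel <- assign_parcel_labels(matrix(c(6, 6, 6), 1), pv)
  expect_equal(on_parcel$code, 4L)
  expect_equal(on_parcel$dist, 0)

  near <- assign_parcel_labels(matrix(c(6, 6, 3), 1), pv)  # distance 3.0
  expect_equal(near$code, 4L)
  expect_equal(near$dist, 3)

  far <- assign_parcel_labels(matrix(c(6, 6, 2), 1), pv)   # distance 4.0
  expect_equal(nrow(far), 0)

  # equidistant parcels resolve to the lower numeric code
  parc2 <- array(0L, dim = shape)
  parc2[4, 6, 6] <- 5L
  parc2[8, 6, 6] <- 3L
  pv2 <- label_volume(parc2, grid_for(shape))
  tie <- assign_parcel_labels(matrix(c(6, 6, 6), 1), pv2)
  expect_equal(tie$code, 3L)
  expect_equal(tie$dist, 2)

  expect_error(assign_parcel_labels(matrix(c(6, 6, 6), 1),
                                    label_volume(array(0L, shape), grid_for(shape))),
               "entirely zero")
})

test_that("region means exclude zero-thickness voxels and mark empty regions", {
  shape <- c(5, 5, 5)
  g <- grid_for(shape)
  labeled <- data.frame(i = c(1, 2, 3, 4), j = 1, k = 1,
                        code = c(1L, 1L, 1L, 2L), dist = 0)
  tv <- array(0, shape)
  tv[1, 1, 1] <- 2; tv[2, 1, 1] <- 0; tv[3, 1, 1] <- 4; tv[4, 1, 1] <- 0
  rec <- roi_mean_thickness(labeled, thickness_map(tv, g))
  r1 <- rec[rec$region == "region_1", ]
  expect_equal(r1$mean_thickness_mm, 3)   # zero excluded
  expect_equal(r1$n_voxels, 2)
  r2 <- rec[rec$region == "region_2", ]
  expect_true(is.na(r2$mean_thickness_mm)) # missing marker, never 0
  expect_equal(r2$n_voxels, 0)
})

test_that("hemisphere and global means follow the documented weighting", {
  rec <- data.frame(subject = "s", session = "ses", scan = "sc", method = "m",
                    region = c("a", "b"), hemisphere = c("left", "right"),
                    mean_thickness_mm = c(2, 3), n_voxels = c(10, 30))
  out <- hemisphere_and_global_means(rec)
  gl <- out[out$region == "global_mean", ]
  expect_equal(gl$mean_thickness_mm, 2.5)  # unweighted mean of hemisphere means

  # weighting matters within a hemisphere ...
  rec2 <- data.frame(subject = "s", session = "ses", scan = "sc", method = "m",
                     region = c("a", "b", "c"),
                     hemisphere = c("left", "left", "right"),
                     mean_thickness_mm = c(2, 4, 3), n_voxels = c(30, 10, 10))
  outw <- hemisphere_and_global_means(rec2)
  outu <- hemisphere_and_global_means(rec2, weighted = FALSE)
  lw <- outw[outw$region == "hemisphere_mean" & outw$hemisphere == "left", ]
  lu <- outu[outu$region == "hemisphere_mean" & outu$hemisphere == "left", ]
  expect_equal(lw$mean_thickness_mm, 2.5)  # (2*30 + 4*10) / 40
  expect_equal(lu$mean_thickness_mm, 3)

  # ... but not when all regions agree
  rec3 <- rec2; rec3$mean_thickness_mm <- 2.2
  out3 <- hemisphere_and_global_means(rec3)
  expect_true(all(abs(out3$mean_thickness_mm - 2.2) < 1e-12))

  # single hemisphere: global mean missing
  rec4 <- rec[rec$hemisphere == "left", ]
  out4 <- hemisphere_and_global_means(rec4)
  expect_true(is.na(out4$mean_thickness_mm[out4$region == "global_mean"]))
})

test_that("shrinking the masking radius never grows a region", {
  sh <- small_shell_input(thickness = 3, shape = 40L, inner = 7)
  b <- inner_boundary(sh$input$p_seg)
  counts <- lapply(c(3, 2, 1), function(md) {
    lab <- assign_parcel_labels(b, sh$phantom$parc, max_dist = md)
    table(factor(lab$code, levels = 1:8))
  })
  expect_true(all(as.integer(counts[[2]]) <= as.integer(counts[[1]])))
  expect_true(all(as.integer(counts[[3]]) <= as.integer(counts[[2]])))
})

test_that("ROI means stay inside the range of the values they average", {
  sh <- small_shell_input(thickness = 3, shape = 40L, inner = 7)
  th <- laplacian_thickness(sh$input)
  b <- inner_boundary(sh$input$p_seg)
  lab <- assign_parcel_labels(b, sh$phantom$parc)
  rec <- roi_mean_thickness(lab, th, legend = sh$phantom$parc$legend)
  shp <- th$grid$shape
  for (r in seq_len(nrow(rec))) {
    code <- sh$phantom$parc$legend$code[
      sh$phantom$parc$legend$region == rec$region[r] &
      sh$phantom$parc$legend$hemisphere == rec$hemisphere[r]]
    sel <- lab[lab$code == code, ]
    v <- th$values[cbind(sel$i, sel$j, sel$k)]
    v <- v[v > 0]
    expect_gte(rec$mean_thickness_mm[r], min(v))
    expect_lte(rec$mean_thickness_mm[r], max(v))
  }
})
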